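test_that("GPR parsing respects precedence, flattening and the empty rule", {
  r <- parse_gpr("G1 and G2 or G3")
  expect_equal(r$kind, "any")
  expect_length(r$children, 2)
  expect_equal(r$children[[1]]$kind, "all")
  expect_setequal(gpr_genes(r), c("G1", "G2", "G3"))

  r2 <- parse_gpr("(G1 and G2) or G3")
  expect_equal(gpr_to_string(r2), "G1 and G2 or G3")

  # and binds tighter than or, case-insensitive keywords
  r3 <- parse_gpr("g1 OR g2 AND g3")
  expect_equal(r3$kind, "any")
  expect_equal(r3$children[[2]]$kind, "all")

  expect_true(parse_gpr("")$kind == "none")
  expect_true(parse_gpr("   ")$kind == "none")
  expect_equal(gpr_to_string(parse_gpr("")), "")
  expect_equal(gpr_genes(parse_gpr("")), character())
})

test_that("malformed GPR strings fail with positional parse errors", {
  expect_error(parse_gpr("G1 and (G2"), "unbalanced")
  expect_error(parse_gpr("G1 and"), "unexpected end")
  expect_error(parse_gpr("and G1"), "dangling operator")
  expect_error(parse_gpr("G1 G2"), "unexpected")
})

test_that("parse_gpr . gpr_to_string is the identity on canonical strings", {
  cases <- c("G1", "G1 and G2", "G1 or G2", "G1 and G2 or G3",
             "(G1 or G2) and G3", "G1 and (G2 or G3) and G4")
  for (s in cases) {
    canon <- gpr_to_string(parse_gpr(s))
    expect_equal(gpr_to_string(parse_gpr(canon)), canon)
  }
})

test_that("BiGG-JSON round trip preserves the model exactly", {
  m <- build_toy_model(check_feasible = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(m2$reactions$id, m$reactions$id)
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
  expect_equal(m2$reactions$subsystem, m$reactions$subsystem)
  expect_equal(m2$metabolites, m$metabolites)
  for (i in seq_len(nrow(m$reactions))) {
    expect_equal(sort(names(m2$reactions$stoich[[i]])),
                 sort(names(m$reactions$stoich[[i]])))
    expect_equal(m2$reactions$stoich[[i]][names(m$reactions$stoich[[i]])],
                 m$reactions$stoich[[i]])
    expect_equal(gpr_to_string(m2$reactions$gpr[[i]]),
                 gpr_to_string(m$reactions$gpr[[i]]))
  }
})

test_that("read_model_json validates its input", {
  path <- withr::local_tempfile(fileext = ".json")
  # minimal single-reaction file with an empty rule
  jsonlite::write_json(list(
    id = "mini",
    metabolites = list(list(id = "A"), list(id = "B")),
    reactions = list(list(id = "R1", metabolites = list(A = -1, B = 1),
                          lower_bound = 0, upper_bound = 10,
                          gene_reaction_rule = ""))
  ), path, auto_unbox = TRUE)
  m <- read_model_json(path)
  expect_equal(nrow(m$reactions), 1)
  expect_true(m$reactions$gpr[[1]]$kind == "none")

  # undeclared metabolite
  jsonlite::write_json(list(
    metabolites = list(list(id = "A")),
    reactions = list(list(id = "R1", metabolites = list(A = -1, Z = 1)))
  ), path, auto_unbox = TRUE)
  expect_error(read_model_json(path), "undeclared metabolite")

  # duplicate reaction id
  jsonlite::write_json(list(
    metabolites = list(list(id = "A"), list(id = "B")),
    reactions = list(list(id = "R1", metabolites = list(A = -1, B = 1)),
                     list(id = "R1", metabolites = list(B = -1, A = 1)))
  ), path, auto_unbox = TRUE)
  expect_error(read_model_json(path), "duplicate reaction id")

  expect_error(read_model_json("does/not/exist.json"), "not found")
})

test_that("GPR rule strings survive the JSON round trip", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    metabolites = list(list(id = "A"), list(id = "B")),
    reactions = list(list(id = "R1", metabolites = list(A = -1, B = 1),
                          gene_reaction_rule = "(G1 and G2) or G3"))
  ), path, auto_unbox = TRUE)
  m <- read_model_json(path)
  r <- m$reactions$gpr[[1]]
  expect_equal(r$kind, "any")
  expect_equal(r$children[[1]]$kind, "all")
  expect_setequal(gpr_genes(r), c("G1", "G2", "G3"))
})

test_that("validate_model reports violations instead of raising", {
  m <- build_toy_model(check_feasible = FALSE)
  expect_length(validate_model(m), 0)

  bad <- m
  bad$reactions$lower_bound[2] <- bad$reactions$upper_bound[2] + 1
  expect_match(validate_model(bad), "lower_bound > upper_bound",
               all = FALSE)

  bad2 <- m
  bad2$reactions$id[2] <- bad2$reactions$id[1]
  expect_match(validate_model(bad2), "duplicate reaction id", all = FALSE)

  bad3 <- m
  bad3$metabolites <- setdiff(bad3$metabolites, "glc_c")
  expect_match(validate_model(bad3), "undeclared", all = FALSE)
})

test_that("the SBML FBC reader agrees with the JSON reader on a toy file", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1">
 <model id="mini">
  <listOfParameters>
   <parameter id="lb0" value="0"/><parameter id="ub10" value="10"/>
   <parameter id="lbm5" value="-5"/>
  </listOfParameters>
  <listOfSpecies>
   <species id="A"/><species id="B"/>
  </listOfSpecies>
  <fbc:listOfGeneProducts>
   <fbc:geneProduct fbc:id="gp1" fbc:label="G1"/>
   <fbc:geneProduct fbc:id="gp2" fbc:label="G2"/>
  </fbc:listOfGeneProducts>
  <listOfReactions>
   <reaction id="R1" reversible="false" fbc:lowerFluxBound="lb0"
             fbc:upperFluxBound="ub10">
    <listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>
    <fbc:geneProductAssociation>
     <fbc:and>
      <fbc:geneProductRef fbc:geneProduct="gp1"/>
      <fbc:geneProductRef fbc:geneProduct="gp2"/>
     </fbc:and>
    </fbc:geneProductAssociation>
   </reaction>
   <reaction id="R2" reversible="true" fbc:lowerFluxBound="lbm5"
             fbc:upperFluxBound="ub10">
    <listOfReactants><speciesReference species="B"/></listOfReactants>
    <listOfProducts><speciesReference species="A"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, path)
  m <- read_model_sbml(path)
  expect_equal(m$reactions$id, c("R1", "R2"))
  expect_equal(m$reactions$stoich[[1]], c(A = -1, B = 2))
  expect_equal(m$reactions$lower_bound, c(0, -5))
  expect_equal(m$reactions$upper_bound, c(10, 10))
  expect_equal(gpr_to_string(m$reactions$gpr[[1]]), "G1 and G2")
  expect_setequal(m$genes, c("G1", "G2"))
})

test_that("the toy model covers the nine energy subsystems and its sentinels", {
  m <- build_toy_model()
  subs <- tolower(unique(m$reactions$subsystem))
  expect_true(all(energy_subsystems() %in% subs))
  smap <- toy_sentinel_gene_map()
  for (rid in names(smap)) {
    i <- match(rid, m$reactions$id)
    expect_false(is.na(i))
    expect_equal(gpr_genes(m$reactions$gpr[[i]]), unname(smap[[rid]]))
  }
  # strictly positive optimum of the energy objective at default bounds
  sol <- fluxdiff:::solve_flux_lp(m, m$reactions$lower_bound,
                                  m$reactions$upper_bound,
                                  energy_objective(m))
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective, 0)
})

test_that("a dead-end toy branch carries zero flux under any bounds", {
  m <- build_toy_model(dead_end_branch = TRUE)
  # maximize flux through the dead-end reaction itself: still zero,
  # because its product has no consumer
  obj <- setNames(as.numeric(m$reactions$id == "DEADRXN"), m$reactions$id)
  sol <- fluxdiff:::solve_flux_lp(m, m$reactions$lower_bound,
                                  m$reactions$upper_bound, obj)
  expect_equal(sol$status, "optimal")
  expect_equal(unname(sol$flux[["DEADRXN"]]), 0, tolerance = 1e-9)
})

test_that("tidy and glance summarize a model", {
  m <- build_toy_model(check_feasible = FALSE)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(m$reactions))
  expect_true(all(c("id", "subsystem", "gpr", "genes") %in% names(td)))
  g <- glance(m)
  expect_equal(g$n_reactions, nrow(m$reactions))
  expect_equal(g$n_genes, length(m$genes))
})
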
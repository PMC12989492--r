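test_that("GPR activity follows min/sum semantics", {
  expect_equal(reaction_activity(parse_gpr("G1 and G2"),
                                 c(G1 = 2, G2 = 3)), 2)
  expect_equal(reaction_activity(parse_gpr("G1 or G2"),
                                 c(G1 = 2, G2 = 3)), 5)
  expect_equal(reaction_activity(parse_gpr("(G1 and G2) or G3"),
                                 c(G1 = 2, G2 = 3, G3 = 1)), 3)
  # empty rule and fully absent rules are unconstrained
  expect_true(is.na(reaction_activity(parse_gpr(""), c(G1 = 2))))
  expect_true(is.na(reaction_activity(parse_gpr("GX or GY"), c(G1 = 2))))
  # absent genes drop from or-branches and are skipped in and-branches
  expect_equal(reaction_activity(parse_gpr("G1 or GX"), c(G1 = 2)), 2)
  expect_equal(reaction_activity(parse_gpr("G1 and GX"), c(G1 = 2)), 2)
  expect_error(reaction_activity(parse_gpr("G1"), c(G1 = -1)), ">= 0")
})

test_that("GPR activity is monotone in every gene's expression", {
  rules <- lapply(c("G1", "G1 and G2", "G1 or G2", "(G1 and G2) or G3",
                    "G1 and (G2 or G3)"), parse_gpr)
  set.seed(7)
  for (rep_i in 1:50) {
    expr <- setNames(runif(3, 0, 10), c("G1", "G2", "G3"))
    g <- sample(names(expr), 1)
    lower <- expr
    lower[g] <- lower[g] / 2
    for (r in rules) {
      expect_lte(reaction_activity(r, lower), reaction_activity(r, expr))
    }
  }
})

test_that("expression bounds scale, clip and block as specified", {
  m <- metabolic_model(tibble::tibble(
    id = c("SRC_A", "R1", "R2", "DM_B"),
    stoich = list(c(A = 1), c(A = -1, B = 1), c(A = -1, B = 1), c(B = -1)),
    lower_bound = c(0, 0, -100, 0),
    upper_bound = c(1000, 100, 100, 1000),
    subsystem = c("Exchange", "p", "p", "Biomass and Maintenance Functions"),
    gpr = list("", "G1", "G2", "")
  ))
  act <- activity_matrix(m, tibble::tibble(gene = c("G1", "G2"),
                                           s1 = c(5, 10)))
  prob <- set_expression_bounds(m, act, percentile = 1)
  b <- prob$bounds$s1
  # a_hat: R1 = 5/10, R2 = 10/10 (clipped at 1)
  expect_equal(b$ub[2], 50)
  expect_equal(b$ub[3], 100)
  # reversible reaction scales its lower bound too
  expect_equal(b$lb[3], -100)
  # unconstrained reactions keep defaults
  expect_equal(b$ub[c(1, 4)], c(1000, 1000))

  # zero activity blocks the reaction (0/0 for irreversible)
  act0 <- activity_matrix(m, tibble::tibble(gene = c("G1", "G2"),
                                            s1 = c(0, 10)))
  b0 <- set_expression_bounds(m, act0, percentile = 1)$bounds$s1
  expect_equal(b0$ub[2], 0)
  expect_equal(b0$lb[2], 0)

  # all-zero sample errors with the sample name
  act00 <- activity_matrix(m, tibble::tibble(gene = c("G1", "G2"),
                                             s1 = c(0, 0)))
  expect_error(set_expression_bounds(m, act00), "zero in sample s1")
})

test_that("normalized bounds are invariant to per-sample rescaling", {
  m <- build_toy_model(check_feasible = FALSE)
  d <- toy_cohort_design(m, seed = 17)
  cohort <- generate_counts(d)
  tpm <- counts_to_tpm(cohort$counts, cohort$lengths)
  act <- activity_matrix(m, tpm)
  ref <- set_expression_bounds(m, act)$bounds[[1]]
  for (lambda in c(0.1, 10)) {
    tpm_l <- tpm
    tpm_l[[2]] <- tpm_l[[2]] * lambda
    act_l <- activity_matrix(m, tpm_l)
    b <- set_expression_bounds(m, act_l)$bounds[[1]]
    expect_equal(b$ub, ref$ub, tolerance = 1e-12)
    expect_equal(b$lb, ref$lb, tolerance = 1e-12)
  }
})

test_that("halving a sentinel gene's expression never raises its bound", {
  m <- build_toy_model(check_feasible = FALSE)
  d <- toy_cohort_design(m, seed = 19)
  cohort <- generate_counts(d)
  tpm <- counts_to_tpm(cohort$counts, cohort$lengths)
  i_dhcrd2 <- match("DHCRD2", m$reactions$id)
  for (gene in c("DEGS1_toy", "PISD_toy", "ELOVL5_toy")) {
    i_rxn <- match(names(which(toy_sentinel_gene_map() == gene)),
                   m$reactions$id)
    ub_ref <- set_expression_bounds(
      m, activity_matrix(m, tpm))$bounds[[1]]$ub[i_rxn]
    tpm_h <- tpm
    tpm_h[[2]][tpm_h$gene == gene] <- tpm_h[[2]][tpm_h$gene == gene] / 2
    ub_half <- set_expression_bounds(
      m, activity_matrix(m, tpm_h))$bounds[[1]]$ub[i_rxn]
    expect_lte(ub_half, ub_ref + 1e-12)
  }
})

test_that("energy_objective matches subsystem labels and synonyms", {
  m <- build_toy_model(check_feasible = FALSE)
  obj <- energy_objective(m)
  energy_ids <- m$reactions$id[tolower(m$reactions$subsystem) %in%
                               energy_subsystems()]
  expect_setequal(names(obj[obj != 0]), energy_ids)
  expect_true(all(obj[energy_ids] == 1))

  # synonym table maps alternative labels onto canonical subsystems
  m2 <- metabolic_model(tibble::tibble(
    id = c("SRC_A", "R1", "DM_B"),
    stoich = list(c(A = 1), c(A = -1, B = 1), c(B = -1)),
    subsystem = c("", "Glycolysis/Gluconeogenesis", "")
  ))
  obj2 <- energy_objective(m2)
  expect_equal(unname(obj2[["R1"]]), 1)

  m3 <- metabolic_model(tibble::tibble(
    id = c("SRC_A", "R1", "DM_B"),
    stoich = list(c(A = 1), c(A = -1, B = 1), c(B = -1)),
    subsystem = c("", "transport", "")
  ))
  expect_error(energy_objective(m3), "no reaction matches")
})

test_that("the LP finds the bottleneck optimum on a linear chain", {
  m <- chain_model()
  obj <- energy_objective(m)
  sol <- fluxdiff:::solve_flux_lp(m, m$reactions$lower_bound,
                                  m$reactions$upper_bound, obj)
  expect_equal(sol$status, "optimal")
  # R2's bound of 4 is the bottleneck; every chain flux equals 4
  expect_equal(unname(sol$flux), rep(4, 4), tolerance = 1e-8)
  expect_equal(sol$objective, 4, tolerance = 1e-8)

  # all bounds zero -> zero flux, zero objective
  sol0 <- fluxdiff:::solve_flux_lp(m, rep(0, 4), rep(0, 4), obj)
  expect_equal(unname(sol0$flux), rep(0, 4))
  expect_equal(sol0$objective, 0)
})

test_that("the parsimonious stage removes futile cycles", {
  m <- metabolic_model(tibble::tibble(
    id = c("SRC_A", "FWD", "BCK", "DM_A"),
    stoich = list(c(A = 1), c(A = -1, B = 1), c(B = -1, A = 1), c(A = -1)),
    lower_bound = 0,
    upper_bound = c(10, 1000, 1000, 5),
    subsystem = c("Exchange", "loop", "loop",
                  "Biomass and Maintenance Functions")
  ))
  obj <- energy_objective(m)
  sol <- fluxdiff:::solve_flux_lp(m, m$reactions$lower_bound,
                                  m$reactions$upper_bound, obj)
  expect_equal(unname(sol$flux[["DM_A"]]), 5, tolerance = 1e-8)
  # the A <-> B cycle carries no flux in the parsimonious solution
  expect_equal(unname(sol$flux[["FWD"]]), 0, tolerance = 1e-8)
  expect_equal(unname(sol$flux[["BCK"]]), 0, tolerance = 1e-8)
})

test_that("parallel equivalent paths carry no duplicated flux", {
  m <- parallel_model(ub_each = 5, ub_dm = 4)
  obj <- energy_objective(m)
  sol <- fluxdiff:::solve_flux_lp(m, m$reactions$lower_bound,
                                  m$reactions$upper_bound, obj)
  expect_equal(unname(sol$flux[["DM_B"]]), 4, tolerance = 1e-8)
  # the split across P1/P2 is a known degeneracy, but the total through
  # the parallel section equals the single-path requirement
  expect_equal(unname(sol$flux[["P1"]] + sol$flux[["P2"]]), 4,
               tolerance = 1e-8)
  expect_equal(sol$total_flux, 12, tolerance = 1e-8)
})

test_that("stage-2 total flux matches the vertex-enumeration oracle", {
  models <- list(chain_model(),
                 chain_model(ubs = c(SRC_A = 3, R1 = 10, R2 = 10, DM_C = 10)),
                 parallel_model(ub_each = 5, ub_dm = 4),
                 parallel_model(ub_each = 2, ub_dm = 10))
  for (m in models) {
    obj <- energy_objective(m)
    lb <- m$reactions$lower_bound
    ub <- m$reactions$upper_bound
    sol <- fluxdiff:::solve_flux_lp(m, lb, ub, obj)
    oracle <- pfba_oracle(m, lb, ub, obj, sol$objective)
    expect_equal(sol$total_flux, oracle, tolerance = 1e-6)
  }
})

test_that("simulate_cohort returns steady-state fluxes per sample", {
  m <- build_toy_model()
  d <- toy_cohort_design(m, seed = 23)
  cohort <- generate_counts(d)
  tpm <- counts_to_tpm(cohort$counts, cohort$lengths)
  fit <- simulate_cohort(m, tpm, samples = cohort$samples)
  expect_equal(length(fit$status), 14)
  expect_true(all(fit$status == "optimal"))
  S <- as.matrix(stoich_matrix(m))
  v <- as.matrix(fit$fluxes[, -(1:2)])
  expect_lt(max(abs(S %*% v)), 1e-6)
  # fluxes respect the effective bounds
  for (s in names(fit$problem$bounds)) {
    b <- fit$problem$bounds[[s]]
    expect_true(all(fit$fluxes[[s]] <= b$ub + 1e-7))
    expect_true(all(fit$fluxes[[s]] >= b$lb - 1e-7))
  }
  # identical TPM columns give identical flux vectors
  tpm2 <- tpm
  s_a <- names(tpm)[2]; s_b <- names(tpm)[3]
  tpm2[[s_b]] <- tpm2[[s_a]]
  fit2 <- simulate_cohort(m, tpm2, samples = cohort$samples)
  expect_equal(fit2$fluxes[[s_a]], fit2$fluxes[[s_b]], tolerance = 1e-12)
})

test_that("a planted knockdown lowers the sentinel's lesion flux", {
  m <- build_toy_model()
  # deterministic expression: all genes flat except DEGS1_toy, knocked
  # down 4x in lesion samples
  sheet <- sample_sheet_7v7()
  tpm <- tibble::tibble(gene = m$genes)
  for (s in sheet$sample) {
    expr <- rep(1000, length(m$genes))
    names(expr) <- m$genes
    expr[toy_sentinel_gene_map()] <- 100
    if (sheet$group[match(s, sheet$sample)] == "lesion") {
      expr["DEGS1_toy"] <- 25
    }
    tpm[[s]] <- unname(expr[tpm$gene])
  }
  fit <- simulate_cohort(m, tpm, samples = sheet)
  fx <- tidy(fit) |> dplyr::filter(.data$reaction == "DHCRD2")
  m_lesion <- mean(fx$flux[fx$group == "lesion"])
  m_control <- mean(fx$flux[fx$group == "control"])
  expect_lt(m_lesion, m_control)
  expect_equal(m_lesion / m_control, 0.25, tolerance = 0.01)
})
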
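#' Build the bundled toy metabolic model
#'
#' Constructs a small, fully connected, feasible metabolic model for
#' demonstrations, simulations and parameter-recovery studies. The model
#' has two parts:
#'
#' * a **core energy network** (glucose uptake through glycolysis,
#'   pyruvate oxidation, the citric acid cycle, oxidative phosphorylation,
#'   NAD and CoA turnover, a fatty-acid synthesis/oxidation pair and an
#'   ATP maintenance demand) with at least one reaction in each of the
#'   nine energy subsystems used by [energy_objective()]: Citric Acid
#'   Cycle, Oxidative Phosphorylation, CoA Synthesis, CoA Catabolism,
#'   Glycolysis and Gluconeogenesis, NAD Metabolism, Fatty Acid Synthesis,
#'   Fatty Acid Oxidation, and Biomass and Maintenance Functions;
#' * a set of **sentinel branches**, one per requested lipid-pathway
#'   sentinel reaction. Each branch is an independent linear chain
#'   (source -> sentinel reaction -> maintenance demand) whose sentinel
#'   carries a BiGG-style id (e.g. `DHCRD2`, dihydroceramide desaturase;
#'   `FAEL183`, fatty-acyl-CoA elongation; `SQLEr`, squalene epoxidase;
#'   `PSDm_hs`, phosphatidylserine decarboxylase) and is gated by a
#'   dedicated toy gene. Because each branch ends in a maintenance demand,
#'   the two-stage flux simulation drives every sentinel to its
#'   expression-scaled bound, so a planted knockdown or upregulation of
#'   the gating gene moves that branch's flux and no other.
#'
#' @param sentinels Character vector of sentinel reaction ids to include;
#'   any subset of `names(toy_sentinel_gene_map())`. Default: all nine.
#' @param extra_branches Number of additional anonymous gene-gated
#'   branches (`BR1`, `BR2`, ... gated by `GB1_toy`, ...) to append.
#' @param dead_end_branch If `TRUE`, append a branch whose product has no
#'   consumer; its flux is forced to zero by the steady-state constraint
#'   (useful for testing blocked-reaction handling).
#' @param core_ub,branch_ub Default upper bounds for core and branch
#'   reactions (flux units).
#' @param check_feasible If `TRUE` (default) solve the energy-maximization
#'   LP at default bounds and abort unless the optimum is strictly
#'   positive.
#' @return A validated [metabolic_model()].
#' @examples
#' m <- build_toy_model()
#' glance(m)
#' @export
build_toy_model <- function(sentinels = names(toy_sentinel_gene_map()),
                            extra_branches = 0,
                            dead_end_branch = FALSE,
                            core_ub = 1000, branch_ub = 1000,
                            check_feasible = TRUE) {
  smap <- toy_sentinel_gene_map()
  unknown <- setdiff(sentinels, names(smap))
  if (length(unknown) > 0) {
    abort(sprintf("unknown sentinel reaction(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  rx <- function(id, stoich, subsystem, gpr = "", lb = 0, ub = core_ub) {
    tibble(id = id, stoich = list(stoich), lower_bound = lb,
           upper_bound = ub, reversible = lb < 0, subsystem = subsystem,
           gpr = list(parse_gpr(gpr)))
  }
  core <- dplyr::bind_rows(
    rx("SRC_glc", c(glc_c = 1), "Exchange"),
    rx("GLYC", c(glc_c = -1, pyr_c = 2, atp_c = 2),
       "Glycolysis and Gluconeogenesis", "PFK_toy"),
    rx("NADS", c(pyr_c = -1, nad_c = 1), "NAD Metabolism", "NADS_toy"),
    rx("DM_nad", c(nad_c = -1), "Biomass and Maintenance Functions"),
    rx("COASYN", c(pyr_c = -1, coa_c = 1), "CoA Synthesis", "PANK_toy"),
    rx("COACAT", c(coa_c = -1, pnto_c = 1), "CoA Catabolism", "VNN_toy"),
    rx("DM_pnto", c(pnto_c = -1), "Biomass and Maintenance Functions"),
    rx("PDH", c(pyr_c = -1, coa_c = -1, accoa_c = 1), "Citric Acid Cycle",
       "PDH_toy"),
    rx("TCA", c(accoa_c = -1, nadh_c = 2, coa_c = 1), "Citric Acid Cycle",
       "CS_toy"),
    rx("OXPHOS", c(nadh_c = -1, atp_c = 2), "Oxidative Phosphorylation",
       "NDUFA_toy and NDUFB_toy"),
    rx("FAS", c(accoa_c = -2, atp_c = -1, fa_c = 1, coa_c = 2),
       "Fatty Acid Synthesis", "ACACA_toy and FASN_toy"),
    rx("FAO", c(fa_c = -1, coa_c = -2, accoa_c = 2), "Fatty Acid Oxidation",
       "CPT1A_toy or CPT2_toy"),
    rx("ATPM", c(atp_c = -1), "Biomass and Maintenance Functions")
  )
  branch_defs <- list(
    PSDm_hs = list(
      rx("SRC_ps", c(ps_c = 1), "Exchange"),
      rx("PSDm_hs", c(ps_c = -1, pe_c = 1),
         "Glycerophospholipid metabolism", smap[["PSDm_hs"]], ub = branch_ub),
      rx("DM_pe", c(pe_c = -1), "Biomass and Maintenance Functions",
         ub = branch_ub),
      # side route pe <-> pc; parsimonious stage leaves it at zero because
      # draining pe directly costs less total flux
      rx("PETOHMr_hs", c(pe_c = -1, pc_c = 1),
         "Glycerophospholipid metabolism", smap[["PETOHMr_hs"]],
         lb = -branch_ub, ub = branch_ub),
      rx("DM_pc", c(pc_c = -1), "Biomass and Maintenance Functions",
         ub = branch_ub)
    ),
    DHCRD2 = list(
      rx("SRC_dhcer", c(dhcer_c = 1), "Exchange"),
      rx("DHCRD2", c(dhcer_c = -1, cer_c = 1), "Sphingolipid metabolism",
         smap[["DHCRD2"]], ub = branch_ub),
      rx("DM_cer", c(cer_c = -1), "Biomass and Maintenance Functions",
         ub = branch_ub)
    ),
    FAEL183 = list(
      rx("SRC_lnlccoa", c(lnlccoa_c = 1), "Exchange"),
      rx("FAEL183", c(lnlccoa_c = -1, dlnlcgcoa_c = 1),
         "Fatty acid elongation", smap[["FAEL183"]], ub = branch_ub),
      rx("DM_dlnlcg", c(dlnlcgcoa_c = -1),
         "Biomass and Maintenance Functions", ub = branch_ub)
    ),
    DESAT18_3 = list(
      rx("SRC_stcoa", c(stcoa_c = 1), "Exchange"),
      rx("DESAT18_3", c(stcoa_c = -1, odecoa_c = 1),
         "Fatty acid metabolism", smap[["DESAT18_3"]], ub = branch_ub),
      rx("DM_odecoa", c(odecoa_c = -1),
         "Biomass and Maintenance Functions", ub = branch_ub)
    ),
    SQLSr = list(
      rx("SRC_frdp", c(frdp_c = 1), "Exchange"),
      rx("SQLSr", c(frdp_c = -1, sql_c = 1), "Cholesterol metabolism",
         smap[["SQLSr"]], ub = branch_ub)
    ),
    SQLEr = list(
      rx("SQLEr", c(sql_c = -1, Ssq23epx_c = 1), "Cholesterol metabolism",
         smap[["SQLEr"]], ub = branch_ub),
      rx("DM_ssq23epx", c(Ssq23epx_c = -1),
         "Biomass and Maintenance Functions", ub = branch_ub)
    ),
    H2O2syn = list(
      rx("SRC_o2", c(o2_c = 1), "Exchange"),
      rx("H2O2syn", c(o2_c = -1, h2o2_c = 1), "Tyrosine metabolism",
         smap[["H2O2syn"]], ub = branch_ub),
      rx("DM_h2o2", c(h2o2_c = -1), "Biomass and Maintenance Functions",
         ub = branch_ub)
    ),
    PI345P3Pn = list(
      rx("SRC_pail345p", c(pail345p_n = 1), "Exchange"),
      rx("PI345P3Pn", c(pail345p_n = -1, pail45p_n = 1),
         "Inositol phosphate metabolism", smap[["PI345P3Pn"]],
         ub = branch_ub),
      rx("DM_pail45p", c(pail45p_n = -1),
         "Biomass and Maintenance Functions", ub = branch_ub)
    )
  )
  # PETOHMr_hs rides on the PSDm_hs branch; SQLEr consumes SQLSr's product,
  # so requesting SQLEr pulls in SQLSr's source chain.
  chosen <- unique(sentinels)
  if ("PETOHMr_hs" %in% chosen) chosen <- union(chosen, "PSDm_hs")
  if ("SQLEr" %in% chosen) chosen <- union(chosen, "SQLSr")
  chosen <- setdiff(chosen, "PETOHMr_hs")
  branch_rows <- dplyr::bind_rows(
    lapply(branch_defs[intersect(names(branch_defs), chosen)],
           dplyr::bind_rows))
  # SQLSr without SQLEr needs its own demand to avoid a dead end
  if ("SQLSr" %in% chosen && !"SQLEr" %in% chosen) {
    branch_rows <- dplyr::bind_rows(
      branch_rows,
      rx("DM_sql", c(sql_c = -1), "Biomass and Maintenance Functions",
         ub = branch_ub))
  }
  extra <- list()
  if (extra_branches > 0) {
    for (b in seq_len(extra_branches)) {
      met_in <- sprintf("xbr%d_a_c", b); met_out <- sprintf("xbr%d_b_c", b)
      extra[[length(extra) + 1]] <- rx(
        sprintf("SRC_BR%d", b), setNames(1, met_in), "Exchange")
      extra[[length(extra) + 1]] <- rx(
        sprintf("BR%d", b), setNames(c(-1, 1), c(met_in, met_out)),
        "Accessory branch", sprintf("GB%d_toy", b), ub = branch_ub)
      extra[[length(extra) + 1]] <- rx(
        sprintf("DM_BR%d", b), setNames(-1, met_out),
        "Biomass and Maintenance Functions", ub = branch_ub)
    }
  }
  if (dead_end_branch) {
    extra[[length(extra) + 1]] <- rx(
      "SRC_dead", c(dead_a_c = 1), "Exchange")
    extra[[length(extra) + 1]] <- rx(
      "DEADRXN", c(dead_a_c = -1, dead_b_c = 1), "Accessory branch",
      "GDEAD_toy", ub = branch_ub)
  }
  rxn <- dplyr::bind_rows(c(list(core, branch_rows), extra))
  model <- metabolic_model(rxn, id = "toy_energy_lipid", check = FALSE)
  viol <- validate_model(model)
  viol <- viol[!grepl("not mass-connected", viol)]  # dead-end stub allowed
  if (length(viol) > 0) abort(c("toy model construction failed:", viol))
  if (check_feasible) {
    obj <- energy_objective(model)
    sol <- solve_flux_lp(model, lb = model$reactions$lower_bound,
                         ub = model$reactions$upper_bound, obj = obj)
    if (sol$status != "optimal" || sol$objective <= 1e-9) {
      abort("toy model specification is infeasible: maximal energy objective is not strictly positive")
    }
  }
  model
}

#' Sentinel reaction to gating gene map of the toy model
#'
#' Each sentinel reaction in [build_toy_model()] is gated by a single
#' dedicated toy gene, so planted expression effects on that gene map
#' one-to-one onto the sentinel's flux bound.
#'
#' @return A named character vector: sentinel reaction id -> gene id.
#' @export
toy_sentinel_gene_map <- function() {
  c(PSDm_hs = "PISD_toy",
    PETOHMr_hs = "PEMT_toy",
    DHCRD2 = "DEGS1_toy",
    FAEL183 = "ELOVL5_toy",
    DESAT18_3 = "SCD_toy",
    SQLSr = "FDFT1_toy",
    SQLEr = "SQLE_toy",
    H2O2syn = "DUOX2_toy",
    PI345P3Pn = "PTEN_toy")
}
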
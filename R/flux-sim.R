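#' The nine energy subsystems and their synonyms
#'
#' The flux simulation maximizes throughput of the main energy-associated
#' pathways: Citric Acid Cycle, Oxidative Phosphorylation, CoA Synthesis,
#' CoA Catabolism, Glycolysis and Gluconeogenesis, NAD Metabolism, Fatty
#' Acid Synthesis, Fatty Acid Oxidation, and Biomass and Maintenance
#' Functions. Matching is case-insensitive; `energy_synonyms()` maps
#' common alternative labels onto the canonical ones and can be extended
#' via the `synonyms` argument of [energy_objective()].
#'
#' @return `energy_subsystems()`: lowercase canonical subsystem names.
#'   `energy_synonyms()`: named character vector alternative -> canonical
#'   (both lowercase).
#' @export
energy_subsystems <- function() {
  c("citric acid cycle", "oxidative phosphorylation", "coa synthesis",
    "coa catabolism", "glycolysis and gluconeogenesis", "nad metabolism",
    "fatty acid synthesis", "fatty acid oxidation",
    "biomass and maintenance functions")
}

#' @rdname energy_subsystems
#' @export
energy_synonyms <- function() {
  c("glycolysis/gluconeogenesis" = "glycolysis and gluconeogenesis",
    "citrate cycle (tca cycle)" = "citric acid cycle",
    "tca cycle" = "citric acid cycle",
    "fatty acid beta-oxidation" = "fatty acid oxidation",
    "fatty acid biosynthesis" = "fatty acid synthesis")
}

#' Reaction activity from expression through a GPR rule
#'
#' Evaluates a GPR tree against per-gene expression (TPM): an `and` node
#' (enzyme complex) takes the minimum of its children — capacity is
#' limited by the scarcest subunit; an `or` node (isozymes) takes the sum
#' — isozymes add capacity; a leaf reads that gene's expression. Genes
#' absent from `expr` are dropped from `or` branches and skipped in `and`
#' branches; a rule whose genes are all absent, or an empty rule, is
#' unconstrained and evaluates to `NA`.
#'
#' @param gpr A `gpr_rule` (see [parse_gpr()]).
#' @param expr Named numeric vector gene -> expression (>= 0).
#' @return A non-negative number, or `NA_real_` for unconstrained.
#' @examples
#' reaction_activity(parse_gpr("(G1 and G2) or G3"),
#'                   c(G1 = 2, G2 = 3, G3 = 1))
#' @export
reaction_activity <- function(gpr, expr) {
  stopifnot(inherits(gpr, "gpr_rule"))
  if (any(expr < 0, na.rm = TRUE)) abort("expression values must be >= 0")
  eval_gpr(gpr, expr)
}

eval_gpr <- function(node, expr) {
  switch(node$kind,
    none = NA_real_,
    leaf = if (node$gene %in% names(expr)) unname(expr[[node$gene]])
           else NA_real_,
    any = {
      vals <- vapply(node$children, eval_gpr, 0, expr = expr)
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) NA_real_ else sum(vals)
    },
    all = {
      vals <- vapply(node$children, eval_gpr, 0, expr = expr)
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) NA_real_ else min(vals)
    }
  )
}

#' Per-sample reaction activity matrix
#'
#' Applies [reaction_activity()] to every reaction and sample of a TPM
#' table.
#'
#' @param model A [metabolic_model()].
#' @param tpm TPM tibble (first column `gene`, one column per sample).
#' @return A tibble: `reaction`, then one numeric column per sample
#'   (`NA` = unconstrained).
#' @export
activity_matrix <- function(model, tpm) {
  samples <- names(tpm)[-1]
  out <- tibble(reaction = model$reactions$id)
  for (s in samples) {
    expr <- setNames(tpm[[s]], tpm$gene)
    out[[s]] <- vapply(model$reactions$gpr, eval_gpr, 0, expr = expr)
  }
  out
}

#' Impose expression-scaled flux bounds
#'
#' E-Flux-style constraint construction: within each sample, constrained
#' reaction activities are normalized by the sample's `percentile`-th
#' activity quantile and clipped to \[0, 1\], making the scaling
#' unit-free (multiplying a sample's expression by any positive constant
#' leaves the normalized activities unchanged). Effective bounds are
#' `ub_eff = ub * a_hat` and, for reversible reactions,
#' `lb_eff = lb * a_hat`; unconstrained reactions keep their default
#' bounds.
#'
#' @param model A [metabolic_model()].
#' @param activity Activity tibble from [activity_matrix()] (`reaction`
#'   column plus one column per sample).
#' @param percentile Normalization quantile in (0, 1\]; default 0.95.
#' @param objective Optional named objective coefficient vector; defaults
#'   to [energy_objective()] of the model.
#' @return A `flux_problem`: the model, per-sample effective bounds, and
#'   the objective vector.
#' @export
set_expression_bounds <- function(model, activity, percentile = 0.95,
                                  objective = NULL) {
  stopifnot(percentile > 0, percentile <= 1)
  if (!identical(activity$reaction, model$reactions$id)) {
    activity <- activity[match(model$reactions$id, activity$reaction), ]
    if (anyNA(activity$reaction)) {
      abort("activity must cover every reaction in the model")
    }
  }
  if (is.null(objective)) objective <- energy_objective(model)
  lb0 <- model$reactions$lower_bound
  ub0 <- model$reactions$upper_bound
  if (any(lb0 > 0)) {
    abort("expression scaling requires lb <= 0 <= ub for every reaction")
  }
  samples <- names(activity)[-1]
  bounds <- lapply(samples, function(s) {
    a <- activity[[s]]
    constrained <- !is.na(a)
    if (!any(constrained)) {
      return(list(lb = lb0, ub = ub0))
    }
    if (all(a[constrained] == 0)) {
      abort(sprintf("all reaction activities are zero in sample %s", s))
    }
    q <- unname(quantile(a[constrained], percentile, names = FALSE))
    a_hat <- pmin(a / q, 1)
    lb <- lb0; ub <- ub0
    ub[constrained] <- ub0[constrained] * a_hat[constrained]
    rev <- model$reactions$reversible
    lb[constrained & rev] <- lb0[constrained & rev] * a_hat[constrained & rev]
    list(lb = lb, ub = ub)
  })
  names(bounds) <- samples
  structure(list(model = model, bounds = bounds, objective = objective,
                 percentile = percentile),
            class = "flux_problem")
}

#' @export
print.flux_problem <- function(x, ...) {
  cat(sprintf("<flux_problem: %d reactions x %d samples, %d objective terms, percentile %.2f>\n",
              nrow(x$model$reactions), length(x$bounds),
              sum(x$objective != 0), x$percentile))
  invisible(x)
}

#' Energy-pathway objective coefficients
#'
#' Builds the stage-1 objective: coefficient `weight` on every reaction
#' whose subsystem matches one of the nine energy subsystems
#' (case-insensitively, after mapping synonyms), 0 elsewhere. When the
#' linear program splits reversible reactions into non-negative halves,
#' the coefficient applies to both halves, so the objective rewards
#' energy-pathway throughput in either direction.
#'
#' @param model A [metabolic_model()].
#' @param subsystems Canonical subsystem names (lowercase); default
#'   [energy_subsystems()].
#' @param synonyms Named map alternative -> canonical (lowercase);
#'   default [energy_synonyms()].
#' @param weight Coefficient for matched reactions (default 1; a named
#'   vector over canonical subsystem names gives per-pathway weights).
#' @return Named numeric vector over reaction ids.
#' @export
energy_objective <- function(model, subsystems = energy_subsystems(),
                             synonyms = energy_synonyms(), weight = 1) {
  labels <- tolower(trimws(model$reactions$subsystem))
  hit <- names(synonyms) %in% labels
  labels[labels %in% names(synonyms)] <-
    synonyms[labels[labels %in% names(synonyms)]]
  matched <- labels %in% subsystems
  if (!any(matched)) {
    abort("no reaction matches any energy subsystem")
  }
  w <- if (length(weight) == 1) {
    ifelse(matched, weight, 0)
  } else {
    out <- numeric(length(labels))
    out[matched] <- unname(weight[labels[matched]])
    out
  }
  setNames(w, model$reactions$id)
}

# Two-stage flux LP on split non-negative variables.
#
# Stage 1 maximizes obj . v subject to S v = 0 and lb <= v <= ub (after
# splitting each reaction into forward/backward halves the objective
# coefficient applies to both halves). Stage 2 fixes the stage-1 optimum
# (within 1e-9 relative) and minimizes total flux sum(|v|), the
# parsimonious step that removes alternate-optima degeneracy. Solved
# with the package's bounded-variable simplex (R/simplex.R).
solve_flux_lp <- function(model, lb, ub, obj, parsimonious = TRUE,
                          opt_tol = 1e-9) {
  rxn_ids <- model$reactions$id
  n_rxn <- length(rxn_ids)
  if (any(lb > 0)) abort("solve_flux_lp requires lb <= 0 <= ub")
  S <- as.matrix(stoich_matrix(model))
  # split variables: forward half for every reaction, backward half where
  # lb < 0; drop halves with zero capacity
  ub_f <- pmax(ub, 0)
  ub_b <- pmax(-lb, 0)
  keep_f <- which(ub_f > 0)
  keep_b <- which(ub_b > 0)
  nv <- length(keep_f) + length(keep_b)
  zero_sol <- function() {
    list(flux = setNames(numeric(n_rxn), rxn_ids), objective = 0,
         total_flux = 0, status = "optimal")
  }
  if (nv == 0) return(zero_sol())
  A_eq <- cbind(S[, keep_f, drop = FALSE], -S[, keep_b, drop = FALSE])
  # drop all-zero metabolite rows (unused metabolites)
  nz <- rowSums(A_eq != 0) > 0
  A_eq <- A_eq[nz, , drop = FALSE]
  cvec <- c(obj[keep_f], obj[keep_b])
  ub_vec <- c(ub_f[keep_f], ub_b[keep_b])
  s1 <- bounded_simplex(cvec, A_eq, rep(0, nrow(A_eq)), ub_vec,
                        maximize = TRUE)
  if (s1$status != "optimal") {
    return(list(flux = setNames(rep(NA_real_, n_rxn), rxn_ids),
                objective = NA_real_, total_flux = NA_real_,
                status = s1$status))
  }
  opt <- s1$value
  x <- s1$x
  total <- sum(x)
  if (parsimonious && any(cvec != 0)) {
    floor_val <- opt - opt_tol * max(1, abs(opt))
    if (floor_val > 0) {
      # c'x >= floor as an equality via a non-negative surplus slack
      A2 <- cbind(rbind(A_eq, cvec), c(rep(0, nrow(A_eq)), -1))
      s2 <- bounded_simplex(c(rep(1, nv), 0), A2,
                            c(rep(0, nrow(A_eq)), floor_val),
                            c(ub_vec, Inf), maximize = FALSE)
      if (s2$status == "optimal") {
        x <- s2$x[seq_len(nv)]
        total <- s2$value
      }
    } else {
      # optimum is (numerically) zero: the parsimonious solution is v = 0
      x <- rep(0, nv)
      total <- 0
    }
  }
  v <- numeric(n_rxn)
  v[keep_f] <- x[seq_along(keep_f)]
  v[keep_b] <- v[keep_b] - x[length(keep_f) + seq_along(keep_b)]
  list(flux = setNames(v, rxn_ids), objective = opt, total_flux = total,
       status = "optimal")
}

#' Solve the flux problem for one sample
#'
#' Runs the two-stage linear program for a single sample of a
#' [set_expression_bounds()] problem: stage 1 maximizes the energy
#' objective subject to steady state (`S v = 0`) and the sample's
#' effective bounds; stage 2 fixes the optimum (1e-9 relative tolerance)
#' and minimizes total flux `sum(|v|)` over split non-negative halves,
#' returning the parsimonious flux vector.
#'
#' @param problem A `flux_problem`.
#' @param sample Sample id (a name of `problem$bounds`).
#' @return A `flux_solution`: list with `flux` (named vector), `objective`,
#'   `total_flux`, `status`.
#' @export
solve_sample_flux <- function(problem, sample) {
  stopifnot(inherits(problem, "flux_problem"))
  if (!sample %in% names(problem$bounds)) {
    abort(sprintf("unknown sample: %s", sample))
  }
  b <- problem$bounds[[sample]]
  sol <- solve_flux_lp(problem$model, b$lb, b$ub, problem$objective)
  if (sol$status != "optimal") {
    abort(sprintf("LP solver failed for sample %s: %s", sample, sol$status))
  }
  structure(c(sol, list(sample = sample)), class = "flux_solution")
}

#' Simulate fluxes across a cohort
#'
#' End-to-end per-sample flux simulation: GPR activities from TPM
#' ([activity_matrix()]), expression-scaled bounds
#' ([set_expression_bounds()]), then the two-stage LP per sample. The
#' result is deterministic given inputs and tolerances.
#'
#' @param model A validated [metabolic_model()].
#' @param tpm TPM tibble (first column `gene`).
#' @param samples Optional sample sheet (carried into the result for
#'   downstream group contrasts).
#' @param percentile Normalization quantile for
#'   [set_expression_bounds()].
#' @param objective Optional objective vector; defaults to
#'   [energy_objective()].
#' @return A `flux_fit`: list with `fluxes` (tibble: `reaction`,
#'   `subsystem`, one column per sample), `objective_values`, `status`
#'   (per sample), `samples`, `problem`. Samples whose LP fails are kept
#'   with `NA` fluxes and a non-"optimal" status rather than dropped.
#' @export
simulate_cohort <- function(model, tpm, samples = NULL, percentile = 0.95,
                            objective = NULL) {
  viol <- validate_model(model)
  if (length(viol) > 0) abort(c("model failed validation:", viol))
  act <- activity_matrix(model, tpm)
  problem <- set_expression_bounds(model, act, percentile = percentile,
                                   objective = objective)
  sample_ids <- names(problem$bounds)
  flux_mat <- matrix(NA_real_, nrow = nrow(model$reactions),
                     ncol = length(sample_ids),
                     dimnames = list(model$reactions$id, sample_ids))
  obj_vals <- setNames(rep(NA_real_, length(sample_ids)), sample_ids)
  status <- setNames(character(length(sample_ids)), sample_ids)
  for (s in sample_ids) {
    b <- problem$bounds[[s]]
    sol <- solve_flux_lp(problem$model, b$lb, b$ub, problem$objective)
    status[s] <- sol$status
    if (sol$status == "optimal") {
      flux_mat[, s] <- sol$flux
      obj_vals[s] <- sol$objective
    } else {
      warn(sprintf("LP solver failed for sample %s: %s", s, sol$status))
    }
  }
  structure(
    list(fluxes = dplyr::bind_cols(
           tibble(reaction = model$reactions$id,
                  subsystem = model$reactions$subsystem),
           as_tibble(flux_mat)),
         objective_values = obj_vals, status = status,
         samples = samples, problem = problem),
    class = "flux_fit")
}

#' @export
print.flux_fit <- function(x, ...) {
  cat(sprintf("<flux_fit: %d reactions x %d samples (%d optimal)>\n",
              nrow(x$fluxes), length(x$status),
              sum(x$status == "optimal")))
  invisible(x)
}

#' Tidy a flux fit into long form
#'
#' @param x A `flux_fit` from [simulate_cohort()].
#' @param ... Unused.
#' @return Long tibble: `reaction`, `subsystem`, `sample`, `flux` (plus
#'   `group`/`patient` when a sample sheet was attached).
#' @method tidy flux_fit
#' @export
tidy.flux_fit <- function(x, ...) {
  out <- tidyr::pivot_longer(x$fluxes, -c("reaction", "subsystem"),
                             names_to = "sample", values_to = "flux")
  if (!is.null(x$samples)) {
    out <- dplyr::left_join(out, x$samples, by = "sample")
  }
  out
}

#' @method glance flux_fit
#' @export
glance.flux_fit <- function(x, ...) {
  tibble(n_reactions = nrow(x$fluxes),
         n_samples = length(x$status),
         n_optimal = sum(x$status == "optimal"),
         mean_objective = mean(x$objective_values, na.rm = TRUE))
}
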
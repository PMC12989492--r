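#' Van der Waerden normal scores
#'
#' Replaces values by normal quantiles of their relative ranks: value
#' with (mid-)rank `R` among `N` observations scores
#' `A = qnorm(R / (N + 1))`. Ties receive mid-ranks, so tied values get
#' equal scores; untied scores sum to zero exactly by quantile symmetry.
#'
#' @param values Numeric vector (length >= 2).
#' @return Numeric vector of normal scores, same length and order.
#' @examples
#' vdw_scores(c(1.2, 3.4, 2.2))
#' @export
vdw_scores <- function(values) {
  n <- length(values)
  stopifnot(n >= 2)
  r <- rank(values, ties.method = "average")
  qnorm(r / (n + 1))
}

#' Two-sample Van der Waerden test
#'
#' Normal-scores location test between two groups. The statistic is
#' `T = sum` of the pooled Van der Waerden scores falling in group A.
#' In `exact` mode the two-sided p-value is the proportion of all
#' `choose(N, n_a)` group assignments with `|T*| >= |T|` (full
#' enumeration); in `normal` mode `T` is standardized by its permutation
#' variance `Var(T) = n_a * n_b * sum(A^2) / (N * (N - 1))` — the exact
#' variance of a sum of `n_a` scores drawn without replacement from
#' scores that total zero — and referred to the standard normal. `auto`
#' (the default) uses exact enumeration when `choose(N, n_a) <= 2e5`.
#'
#' @param group_a,group_b Numeric vectors (length >= 2 each).
#' @param mode One of `"auto"`, `"exact"`, `"normal"`.
#' @return A list: `statistic` (T), `p`, `mode` used.
#' @examples
#' vdw_test(c(1, 2, 3, 4), c(5, 6, 7, 8), mode = "exact")
#' @export
vdw_test <- function(group_a, group_b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  n_a <- length(group_a); n_b <- length(group_b)
  stopifnot(n_a >= 2, n_b >= 2)
  pooled <- c(group_a, group_b)
  if (max(pooled) == min(pooled)) {
    return(list(statistic = 0, p = 1, mode = mode))
  }
  scores <- vdw_scores(pooled)
  T_obs <- sum(scores[seq_len(n_a)])
  n_comb <- choose(n_a + n_b, n_a)
  if (mode == "auto") mode <- if (n_comb <= 2e5) "exact" else "normal"
  if (mode == "exact") {
    if (n_comb > 2e5) {
      abort(sprintf("exact mode needs choose(N, n_a) <= 2e5, got %g", n_comb))
    }
    p <- vdw_exact_p(scores, n_a, T_obs)
  } else {
    v <- n_a * n_b * sum(scores^2) / ((n_a + n_b) * (n_a + n_b - 1))
    p <- if (v <= 0) 1 else min(1, 2 * stats::pnorm(-abs(T_obs) / sqrt(v)))
  }
  list(statistic = T_obs, p = p, mode = mode)
}

# enumeration over all assignments of n_a of the N scores to group A;
# the 0/1 indicator matrix is cached per (N, n_a) since every reaction
# of a cohort shares the same design
vdw_enum_cache <- new.env(parent = emptyenv())

vdw_indicator_matrix <- function(n, k) {
  key <- paste(n, k, sep = "_")
  if (!is.null(vdw_enum_cache[[key]])) return(vdw_enum_cache[[key]])
  idx <- combn(n, k)
  Z <- matrix(0, nrow = ncol(idx), ncol = n)
  Z[cbind(rep(seq_len(ncol(idx)), each = k), as.vector(idx))] <- 1
  vdw_enum_cache[[key]] <- Z
  Z
}

vdw_exact_p <- function(scores, n_a, T_obs) {
  Z <- vdw_indicator_matrix(length(scores), n_a)
  T_star <- as.vector(Z %*% scores)
  mean(abs(T_star) >= abs(T_obs) - 1e-12)
}

#' Per-reaction differential flux table
#'
#' Contrasts per-sample fluxes between the two groups with the Van der
#' Waerden test reaction by reaction, then applies Benjamini-Hochberg
#' correction across the tested reactions. Reactions with degenerate
#' flux (identical in every sample) are not tested: they keep `p = 1`,
#' `fdr = NA`, direction `"none"`, and are excluded from the BH
#' correction so structurally blocked reactions do not dilute it.
#'
#' @param fluxes A `flux_fit` from [simulate_cohort()], or a tibble with
#'   columns `reaction`, optionally `subsystem`, and one numeric column
#'   per sample.
#' @param samples Sample sheet tibble (`sample`, `group`); taken from the
#'   `flux_fit` when omitted.
#' @param alpha FDR significance threshold (default 0.05, strict `<`).
#' @param mode Test mode passed to [vdw_test()] (default `"auto"`:
#'   exact enumeration for the 7-vs-7 design, normal approximation for
#'   larger cohorts).
#' @param case,control Group labels.
#' @return A `flux_diff_tbl` tibble: `reaction`, `subsystem`,
#'   `mean_lesion`, `mean_control`, `statistic`, `p`, `fdr`, `direction`
#'   (up/down/none, by the sign of the statistic), `tested`,
#'   `significant` (`fdr < alpha`).
#' @export
differential_flux <- function(fluxes, samples = NULL, alpha = 0.05,
                              mode = c("auto", "exact", "normal"),
                              case = "lesion", control = "control") {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1)
  if (inherits(fluxes, "flux_fit")) {
    if (is.null(samples)) samples <- fluxes$samples
    fluxes <- fluxes$fluxes
  }
  if (is.null(samples)) abort("a sample sheet with a `group` column is required")
  fluxes <- as_tibble(fluxes)
  if (!"subsystem" %in% names(fluxes)) fluxes$subsystem <- ""
  grp <- split(samples$sample, samples$group)
  if (!all(c(case, control) %in% names(grp))) {
    abort(sprintf("sample sheet must contain groups '%s' and '%s'",
                  case, control))
  }
  a_cols <- intersect(grp[[case]], names(fluxes))
  b_cols <- intersect(grp[[control]], names(fluxes))
  if (length(a_cols) < 2 || length(b_cols) < 2) {
    abort("need >= 2 samples per group")
  }
  A <- as.matrix(fluxes[, a_cols, drop = FALSE])
  B <- as.matrix(fluxes[, b_cols, drop = FALSE])
  n <- nrow(fluxes)
  stat <- numeric(n); p <- rep(1, n); tested <- logical(n)
  dir <- rep("none", n)
  for (i in seq_len(n)) {
    x <- A[i, ]; y <- B[i, ]
    if (anyNA(c(x, y)) || max(c(x, y)) == min(c(x, y))) next
    res <- vdw_test(x, y, mode = mode)
    stat[i] <- res$statistic
    p[i] <- res$p
    tested[i] <- TRUE
    if (res$statistic > 0) dir[i] <- "up"
    else if (res$statistic < 0) dir[i] <- "down"
  }
  fdr <- rep(NA_real_, n)
  fdr[tested] <- bh_fdr(p[tested])
  out <- tibble(
    reaction = fluxes$reaction,
    subsystem = fluxes$subsystem,
    mean_lesion = rowMeans(A),
    mean_control = rowMeans(B),
    statistic = stat,
    p = p,
    fdr = fdr,
    direction = dir,
    tested = tested,
    significant = !is.na(fdr) & fdr < alpha
  )
  class(out) <- c("flux_diff_tbl", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Glance at a differential flux table
#'
#' @param x A `flux_diff_tbl` from [differential_flux()].
#' @param ... Unused.
#' @return One-row tibble: reactions tested, number significant, numbers
#'   up/down, and the alpha used.
#' @method glance flux_diff_tbl
#' @export
glance.flux_diff_tbl <- function(x, ...) {
  tibble(
    n_reactions = nrow(x),
    n_tested = sum(x$tested),
    n_significant = sum(x$significant),
    n_up = sum(x$significant & x$direction == "up"),
    n_down = sum(x$significant & x$direction == "down"),
    alpha = attr(x, "alpha") %||% 0.05
  )
}
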
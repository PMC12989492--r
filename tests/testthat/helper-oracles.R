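# Independent brute-force oracles used to validate the package's
# implementations. These deliberately favor clarity over speed and avoid
# reusing package internals.

# Benjamini-Hochberg step-up, literal definition:
# q_(i) = min_{j >= i} min(1, p_(j) * n / j), reported in input order.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(ps[i:n] * (n / (i:n))))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# Exact two-sided Van der Waerden p by direct enumeration of all
# assignments of n_a of the pooled values to group A (plain loop over
# combn columns).
vdw_oracle_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  r <- rank(pooled, ties.method = "average")
  sc <- qnorm(r / (n + 1))
  t_obs <- sum(sc[seq_along(a)])
  idx <- combn(n, length(a))
  hits <- 0
  for (j in seq_len(ncol(idx))) {
    if (abs(sum(sc[idx[, j]])) >= abs(t_obs) - 1e-12) hits <- hits + 1
  }
  hits / ncol(idx)
}

# Upper-tail hypergeometric P(X >= k) by enumerating every possible draw
# of n items from a universe of size N containing K marked items.
hyper_oracle_p <- function(N, K, n, k) {
  draws <- combn(N, n)
  marked <- seq_len(K)
  hits <- 0
  for (j in seq_len(ncol(draws))) {
    if (sum(draws[, j] %in% marked) >= k) hits <- hits + 1
  }
  hits / ncol(draws)
}

# Minimal total flux at the fixed stage-1 optimum, by vertex enumeration
# of the stage-2 polytope over split non-negative variables:
#   A x = 0 (steady state), c'x = opt, 0 <= x <= u.
# Every vertex fixes (nv - rank) variables at a bound; all such
# active-set choices are enumerated and the feasible vertex with the
# smallest 1'x wins.
pfba_oracle <- function(model, lb, ub, obj, opt) {
  S <- as.matrix(fluxdiff::stoich_matrix(model))
  ub_f <- pmax(ub, 0); ub_b <- pmax(-lb, 0)
  keep_f <- which(ub_f > 0); keep_b <- which(ub_b > 0)
  A <- cbind(S[, keep_f, drop = FALSE], -S[, keep_b, drop = FALSE])
  A <- A[rowSums(A != 0) > 0, , drop = FALSE]
  cvec <- c(obj[keep_f], obj[keep_b])
  u <- c(ub_f[keep_f], ub_b[keep_b])
  Aeq <- rbind(A, cvec)
  beq <- c(rep(0, nrow(A)), opt)
  nv <- length(u)
  qr_rank <- qr(Aeq)$rank
  n_free <- qr_rank
  n_fixed <- nv - n_free
  best <- Inf
  if (n_fixed < 0) return(NA_real_)
  fix_sets <- combn(nv, n_fixed)
  for (j in seq_len(ncol(fix_sets))) {
    fixed <- fix_sets[, j]
    free <- setdiff(seq_len(nv), fixed)
    # each fixed variable sits at 0 or at its upper bound
    for (mask in 0:(2^n_fixed - 1)) {
      xf <- numeric(n_fixed)
      if (n_fixed > 0) {
        bits <- as.integer(intToBits(mask))[seq_len(n_fixed)]
        xf <- ifelse(bits == 1, u[fixed], 0)
      }
      rhs <- beq - if (n_fixed > 0) Aeq[, fixed, drop = FALSE] %*% xf
                   else 0
      Af <- Aeq[, free, drop = FALSE]
      sol <- tryCatch(qr.solve(Af, rhs, tol = 1e-10),
                      error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(Af %*% sol - rhs)) > 1e-8) next
      x <- numeric(nv)
      x[free] <- sol
      x[fixed] <- xf
      if (any(x < -1e-9) || any(x > u + 1e-9)) next
      best <- min(best, sum(x))
    }
  }
  best
}

# tiny linear-chain model: SRC -> A -(R1)-> B -(R2)-> C -(DM, objective)
chain_model <- function(ubs = c(SRC_A = 1000, R1 = 10, R2 = 4, DM_C = 7)) {
  metabolic_model(tibble::tibble(
    id = c("SRC_A", "R1", "R2", "DM_C"),
    stoich = list(c(A = 1), c(A = -1, B = 1), c(B = -1, C = 1), c(C = -1)),
    lower_bound = 0,
    upper_bound = unname(ubs[c("SRC_A", "R1", "R2", "DM_C")]),
    subsystem = c("Exchange", "pathway", "pathway",
                  "Biomass and Maintenance Functions")
  ))
}

# two equivalent parallel routes A -> B feeding one demand
parallel_model <- function(ub_each = 5, ub_dm = 20) {
  metabolic_model(tibble::tibble(
    id = c("SRC_A", "P1", "P2", "DM_B"),
    stoich = list(c(A = 1), c(A = -1, B = 1), c(A = -1, B = 1), c(B = -1)),
    lower_bound = 0,
    upper_bound = c(1000, ub_each, ub_each, ub_dm),
    subsystem = c("Exchange", "pathway", "pathway",
                  "Biomass and Maintenance Functions")
  ))
}

sample_sheet_7v7 <- function() {
  tibble::tibble(
    sample = c(sprintf("lesion_p%02d", 1:7), sprintf("control_p%02d", 1:7)),
    patient = rep(sprintf("p%02d", 1:7), 2),
    group = rep(c("lesion", "control"), each = 7)
  )
}
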
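# Bounded-variable primal simplex with Bland's rule.
#
# Solves  min / max  c'x   s.t.  A x = b,  0 <= x <= u.
#
# Flux problems make maximally degenerate bases (every equality has zero
# right-hand side), which trips Dantzig-rule tableau implementations: a
# pricing step can select a column with an empty ratio set and the
# tableau fills with NaN. Bland's smallest-index rule terminates finitely
# under degeneracy, and the bounded formulation keeps the box constraints
# out of the constraint matrix, so the basis stays at the size of the
# equality system.
#
# Nonbasic variables sit at 0 or at their upper bound; an entering
# variable may also traverse its whole range and "bound flip" without a
# basis change. Phase 1 minimizes the sum of artificial variables (rows
# pre-flipped so b >= 0); artificials are then frozen at [0, 0] for
# phase 2 so a degenerate basic artificial can never re-enter at a
# positive value.
bounded_simplex <- function(cvec, A, b, u, maximize = FALSE,
                            tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A)
  n <- ncol(A)
  if (maximize) cvec <- -cvec
  flip <- b < 0
  A1 <- A
  A1[flip, ] <- -A1[flip, ]
  b1 <- abs(b)
  A_ext <- cbind(A1, diag(m))
  u_ext <- c(u, rep(Inf, m))

  run_phase <- function(cost, basis, at_upper, fixed_zero) {
    ub <- u_ext
    ub[fixed_zero] <- 0
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) return(list(status = "iteration limit"))
      Bmat <- A_ext[, basis, drop = FALSE]
      nonbasic <- setdiff(seq_len(n + m), basis)
      xN <- ifelse(at_upper[nonbasic], ub[nonbasic], 0)
      rhs <- b1 - as.vector(A_ext[, nonbasic, drop = FALSE] %*% xN)
      xB <- tryCatch(as.vector(solve(Bmat, rhs)),
                     error = function(e) NULL)
      if (is.null(xB)) return(list(status = "singular basis"))
      y <- tryCatch(as.vector(solve(t(Bmat), cost[basis])),
                    error = function(e) NULL)
      if (is.null(y)) return(list(status = "singular basis"))
      d <- cost[nonbasic] -
        as.vector(t(A_ext[, nonbasic, drop = FALSE]) %*% y)
      # Bland: smallest-index eligible entering variable
      eligible <- which((!at_upper[nonbasic] & d < -tol) |
                        (at_upper[nonbasic] & d > tol))
      if (length(eligible) == 0) {
        xfull <- numeric(n + m)
        xfull[nonbasic] <- xN
        xfull[basis] <- xB
        return(list(status = "optimal", x = xfull, basis = basis,
                    at_upper = at_upper, value = sum(cost * xfull)))
      }
      e_var <- min(nonbasic[eligible])
      s <- if (at_upper[e_var]) -1 else 1
      dir <- tryCatch(as.vector(solve(Bmat, A_ext[, e_var])),
                      error = function(e) NULL)
      if (is.null(dir)) return(list(status = "singular basis"))
      delta <- -s * dir
      # ratio test: basic variables stay within [0, ub]; the entering
      # variable can at most traverse its own range
      cand_i <- integer(0)
      cand_t <- numeric(0)
      cand_up <- logical(0)
      for (i in seq_len(m)) {
        if (delta[i] < -tol) {
          cand_i <- c(cand_i, i)
          cand_t <- c(cand_t, max(0, -xB[i] / delta[i]))
          cand_up <- c(cand_up, FALSE)
        } else if (delta[i] > tol && is.finite(ub[basis[i]])) {
          cand_i <- c(cand_i, i)
          cand_t <- c(cand_t, max(0, (ub[basis[i]] - xB[i]) / delta[i]))
          cand_up <- c(cand_up, TRUE)
        }
      }
      t_flip <- ub[e_var]
      min_row_t <- if (length(cand_t) > 0) min(cand_t) else Inf
      if (!is.finite(min(min_row_t, t_flip))) {
        return(list(status = "unbounded"))
      }
      if (min_row_t <= t_flip + tol) {
        # a basic variable hits its bound first; Bland tie-break by
        # smallest leaving-variable index among the minimal ratios
        ties <- which(cand_t <= min_row_t + tol)
        pick <- ties[which.min(basis[cand_i[ties]])]
        leave_local <- cand_i[pick]
        leave_var <- basis[leave_local]
        basis[leave_local] <- e_var
        at_upper[e_var] <- FALSE
        at_upper[leave_var] <- cand_up[pick]
      } else {
        at_upper[e_var] <- !at_upper[e_var]  # bound flip
      }
    }
  }

  basis0 <- n + seq_len(m)
  at_upper0 <- rep(FALSE, n + m)
  p1 <- run_phase(c(rep(0, n), rep(1, m)), basis0, at_upper0,
                  fixed_zero = integer())
  if (p1$status != "optimal") return(list(status = p1$status))
  if (p1$value > 1e-7) return(list(status = "infeasible"))
  p2 <- run_phase(c(cvec, rep(0, m)), p1$basis, p1$at_upper,
                  fixed_zero = n + seq_len(m))
  if (p2$status != "optimal") return(list(status = p2$status))
  x_out <- pmin(pmax(p2$x[seq_len(n)], 0), u)
  value <- sum(cvec * x_out)
  list(status = "optimal", x = x_out,
       value = if (maximize) -value else value)
}
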
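# Bounded-variable linear programming.
#
# Solves   maximize c'x   s.t.  A x = b,  l <= x <= u
# with a dense two-phase primal simplex using the bounded-variable pivoting
# rules and Bland's smallest-index rule throughout (anti-cycling; FBA LPs are
# massively degenerate). Phase 1 introduces one artificial variable per row
# with sign chosen so the initial basic solution is feasible; phase 2 pins
# the artificials to [0, 0] (they may stay basic at zero) and optimises the
# true objective. The basis inverse is refactorised at every pivot via
# solve(); problems handled here are small (fixture networks, tens to a few
# hundred variables), so exactness beats factorisation updates.

#' Solve a bounded linear program (maximisation)
#'
#' @param c_obj objective coefficients (length n).
#' @param A constraint matrix (m x n), equality constraints \code{A x = b}.
#' @param b right-hand side (length m).
#' @param lower,upper variable bounds; infinities allowed on at most one
#'   side of each variable.
#' @param tol numerical tolerance for feasibility and optimality (default
#'   1e-9).
#' @param max_iter pivot limit (default \code{1000 + 50 * (n + m)}).
#' @return list with \code{status} ("optimal", "infeasible" or "unbounded"),
#'   \code{objective} (NA unless optimal) and \code{x} (primal solution).
#' @export
lp_solve <- function(c_obj, A, b, lower, upper, tol = 1e-9,
                     max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(c_obj) == n, length(b) == m,
            length(lower) == n, length(upper) == n)
  if (any(lower > upper + tol))
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  if (is.null(max_iter)) max_iter <- 1000L + 50L * (n + m)

  # initial nonbasic values: finite bound nearest zero
  start_val <- function(l, u) {
    if (is.finite(l) && is.finite(u)) if (abs(l) <= abs(u)) l else u
    else if (is.finite(l)) max(l, min(u, 0))
    else if (is.finite(u)) min(u, max(l, 0))
    else 0
  }
  x <- mapply(start_val, lower, upper)
  at_upper <- is.finite(upper) & (abs(x - upper) < abs(x - lower))

  r <- b - as.vector(A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, nrow = m))
  lo <- c(lower, rep(0, m))
  up <- c(upper, rep(Inf, m))
  nv <- n + m
  basis <- n + seq_len(m)
  xfull <- c(x, abs(r))
  status_up <- c(at_upper, rep(FALSE, m))   # nonbasic-at-upper flags

  run_phase <- function(cc, basis, xfull, status_up, iter_budget) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > iter_budget)
        stop("LP solver: iteration limit exceeded (", iter_budget, ")")
      B <- Afull[, basis, drop = FALSE]
      Binv <- tryCatch(solve(B), error = function(e)
        stop("LP solver: singular basis"))
      nonbasic <- setdiff(seq_len(nv), basis)
      xB <- as.vector(Binv %*% (b - Afull[, nonbasic, drop = FALSE] %*%
                                  xfull[nonbasic]))
      xfull[basis] <- xB
      y <- as.vector(crossprod(Binv, cc[basis]))
      d <- cc[nonbasic] - as.vector(crossprod(Afull[, nonbasic,
                                                    drop = FALSE], y))
      # entering: at lower with positive reduced cost (increase) or at upper
      # with negative (decrease); Bland: smallest variable index
      can_inc <- !status_up[nonbasic] & d > tol &
        (up[nonbasic] - xfull[nonbasic] > tol)
      can_dec <- status_up[nonbasic] & d < -tol &
        (xfull[nonbasic] - lo[nonbasic] > tol)
      cand <- nonbasic[can_inc | can_dec]
      if (!length(cand))
        return(list(basis = basis, xfull = xfull, status_up = status_up,
                    status = "optimal"))
      j <- min(cand)
      sigma <- if (status_up[j]) -1 else 1
      w <- as.vector(Binv %*% Afull[, j])           # xB changes by -sigma*t*w
      # ratio test
      t_own <- up[j] - lo[j]                         # bound-to-bound flip
      t_best <- t_own; leave <- 0L                   # 0 = flip
      for (k in seq_len(m)) {
        wk <- sigma * w[k]
        if (wk > tol) {
          tk <- (xfull[basis[k]] - lo[basis[k]]) / wk
        } else if (wk < -tol) {
          tk <- (up[basis[k]] - xfull[basis[k]]) / (-wk)
        } else next
        if (tk < t_best - tol ||
            (tk < t_best + tol && leave != 0L && basis[k] < basis[leave])) {
          t_best <- tk; leave <- k
        }
      }
      if (!is.finite(t_best))
        return(list(basis = basis, xfull = xfull, status_up = status_up,
                    status = "unbounded"))
      t_best <- max(t_best, 0)
      xfull[j] <- xfull[j] + sigma * t_best
      xfull[basis] <- xfull[basis] - sigma * t_best * w
      if (leave == 0L) {                             # j flips bound
        status_up[j] <- !status_up[j]
      } else {
        lv <- basis[leave]
        wk <- sigma * w[leave]
        status_up[lv] <- wk < 0                      # wk<0: basic rose to its upper bound
        xfull[lv] <- if (status_up[lv]) up[lv] else lo[lv]
        basis[leave] <- j
        status_up[j] <- FALSE                        # basic flag unused
      }
    }
  }

  # phase 1: maximize -sum(artificials)
  c1 <- c(rep(0, n), rep(-1, m))
  p1 <- run_phase(c1, basis, xfull, status_up, max_iter)
  art_sum <- sum(p1$xfull[n + seq_len(m)])
  if (art_sum > 1e-7)
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  # phase 2: pin artificials at zero, optimise the true objective
  up[n + seq_len(m)] <- 0
  xf <- p1$xfull
  xf[n + seq_len(m)] <- pmin(xf[n + seq_len(m)], 0)
  xf[n + seq_len(m)][xf[n + seq_len(m)] < 0] <- 0
  c2 <- c(c_obj, rep(0, m))
  p2 <- run_phase(c2, p1$basis, xf, p1$status_up, max_iter)
  if (p2$status == "unbounded")
    return(list(status = "unbounded", objective = NA_real_,
                x = rep(NA_real_, n)))
  xs <- p2$xfull[seq_len(n)]
  xs <- pmin(pmax(xs, lower), upper)                 # clip roundoff
  list(status = "optimal", objective = sum(c_obj * xs), x = xs)
}
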
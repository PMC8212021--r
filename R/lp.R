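# Linear-programming layer.
#
# All LPs in the package are bounded-variable problems
#   opt  c'v   s.t.  Aeq v = beq,  Ale v <= ble,  lb <= v <= ub
# solved by a dense two-phase primal simplex that handles variable
# bounds natively (no x >= 0 substitution, no explicit bound rows).
# Bland's smallest-index rule guarantees termination on the degenerate
# bases metabolic networks produce routinely. The basis inverse is
# maintained by product-form pivot updates with periodic
# refactorization.

LP_TOL <- 1e-9

#' Solve a bounded-variable linear program
#'
#' Optimizes `c'v` subject to `Aeq v = beq`, optional `Ale v <= ble` and
#' box bounds `lb <= v <= ub`.
#'
#' @param obj Numeric objective coefficients (length `n`).
#' @param Aeq,beq Equality constraints (matrix may be `NULL`).
#' @param lb,ub Variable bounds; infinite lower bounds are capped at
#'   `-big`, infinite upper bounds are allowed.
#' @param direction `"max"` or `"min"`.
#' @param Ale,ble Optional inequality constraints `Ale v <= ble`,
#'   converted internally to equalities with slack variables.
#' @param big Cap substituted for infinite lower bounds (default `1e6`).
#' @param tol Feasibility/optimality tolerance (default `1e-9`).
#'
#' @return List with `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `objective` and `x` (solution on the original
#'   variables; `NULL` unless optimal).
#' @keywords internal
solve_lp <- function(obj, Aeq = NULL, beq = NULL, lb, ub,
                     direction = c("max", "min"),
                     Ale = NULL, ble = NULL, big = 1e6, tol = LP_TOL) {
  direction <- match.arg(direction)
  n0 <- length(obj)
  stopifnot(length(lb) == n0, length(ub) == n0)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  A <- if (is.null(Aeq)) matrix(0, 0, n0) else as.matrix(Aeq)
  b <- if (is.null(beq)) numeric(0) else as.numeric(beq)
  cc <- as.numeric(obj)
  l <- pmax(lb, -big)
  u <- ub
  if (!is.null(Ale)) {
    Ale <- as.matrix(Ale)
    ns <- nrow(Ale)
    A <- rbind(cbind(A, matrix(0, nrow(A), ns)),
               cbind(Ale, diag(ns)))
    b <- c(b, as.numeric(ble))
    cc <- c(cc, rep(0, ns))
    l <- c(l, rep(0, ns))
    u <- c(u, rep(Inf, ns))
  }
  if (direction == "min") cc <- -cc
  res <- simplex_bounded(cc, A, b, l, u, tol = tol)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_, x = NULL))
  }
  x <- res$x[seq_len(n0)]
  list(status = "optimal", objective = sum(obj * x), x = x)
}

# maximize cc'x  s.t.  A x = b,  l <= x <= u  (l finite; u may be +Inf)
simplex_bounded <- function(cc, A, b, l, u, tol = LP_TOL, max_iter = 100000L) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) {
    x <- ifelse(cc > tol, u, l)
    if (any(!is.finite(x))) return(list(status = "unbounded", x = NULL))
    return(list(status = "optimal", x = x))
  }
  # nonbasic start: each variable at its finite bound nearest zero
  start_up <- is.finite(u) & abs(u) < abs(l)
  x0 <- ifelse(start_up, u, l)
  r <- b - as.vector(A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)
  Ae <- cbind(A, diag(sgn, m, m))
  le <- c(l, rep(0, m))
  x <- c(x0, abs(r))
  basis <- n + seq_len(m)
  at_upper <- c(start_up, rep(FALSE, m))

  run_phase <- function(costs, x, basis, at_upper, ue_loc) {
    refac <- function(bs) tryCatch(solve(Ae[, bs, drop = FALSE]),
                                   error = function(e) NULL)
    Binv <- refac(basis)
    if (is.null(Binv)) return(list(status = "singular"))
    since <- 0L
    movable <- (ue_loc - le) > tol
    for (iter in seq_len(max_iter)) {
      if (since >= 60L) {
        Binv <- refac(basis)
        if (is.null(Binv)) return(list(status = "singular"))
        since <- 0L
      }
      y <- as.vector(crossprod(Binv, costs[basis]))
      d <- costs - as.vector(crossprod(Ae, y))
      inb <- logical(length(x)); inb[basis] <- TRUE
      elig <- which(!inb & movable &
                    ((!at_upper & d > tol) | (at_upper & d < -tol)))
      if (!length(elig)) {
        return(list(status = "optimal", x = x, basis = basis,
                    at_upper = at_upper))
      }
      j <- elig[1L]                       # Bland: smallest index
      dir <- if (at_upper[j]) -1 else 1
      wcol <- as.vector(Binv %*% Ae[, j])
      step <- dir * wcol                  # basic change is -step per unit
      best_t <- ue_loc[j] - le[j]         # own bound flip (may be Inf)
      leave <- 0L; leave_to <- "lower"
      dec <- which(step > tol)            # basic vars pushed toward lower
      if (length(dec)) {
        rat <- pmax((x[basis[dec]] - le[basis[dec]]) / step[dec], 0)
        rmin <- min(rat)
        if (rmin < best_t - 1e-12 || (leave == 0L && rmin <= best_t)) {
          cand <- dec[rat <= rmin + 1e-12]
          pick <- cand[which.min(basis[cand])]
          best_t <- rmin; leave <- pick; leave_to <- "lower"
        }
      }
      inc <- which(step < -tol)           # basic vars pushed toward upper
      if (length(inc)) {
        ub_b <- ue_loc[basis[inc]]
        rat <- pmax((ub_b - x[basis[inc]]) / (-step[inc]), 0)
        fin <- is.finite(rat)
        if (any(fin)) {
          rmin <- min(rat[fin])
          if (rmin < best_t - 1e-12 || (leave == 0L && rmin <= best_t)) {
            cand <- inc[fin & rat <= rmin + 1e-12]
            pick <- cand[which.min(basis[cand])]
            best_t <- rmin; leave <- pick; leave_to <- "upper"
          }
        }
      }
      if (!is.finite(best_t)) return(list(status = "unbounded"))
      x[j] <- x[j] + dir * best_t
      if (best_t > 0) x[basis] <- x[basis] - best_t * step
      if (leave == 0L) {                  # bound flip, basis unchanged
        at_upper[j] <- !at_upper[j]
        next
      }
      out_var <- basis[leave]
      x[out_var] <- if (leave_to == "lower") le[out_var] else ue_loc[out_var]
      at_upper[out_var] <- leave_to == "upper"
      basis[leave] <- j
      at_upper[j] <- FALSE
      piv <- wcol[leave]
      if (abs(piv) < 1e-11) {             # numerically unsafe pivot
        Binv <- refac(basis)
        if (is.null(Binv)) return(list(status = "singular"))
        since <- 0L
      } else {
        prow <- Binv[leave, ] / piv
        Binv <- Binv - tcrossprod(wcol, prow)
        Binv[leave, ] <- prow
        since <- since + 1L
      }
    }
    list(status = "maxiter")
  }

  # phase 1: drive the artificial variables to zero
  c1 <- c(rep(0, n), rep(-1, m))
  ue1 <- c(u, rep(Inf, m))
  p1 <- run_phase(c1, x, basis, at_upper, ue1)
  if (!identical(p1$status, "optimal")) {
    return(list(status = if (identical(p1$status, "unbounded")) "infeasible"
                         else p1$status, x = NULL))
  }
  if (sum(p1$x[n + seq_len(m)]) > 1e-7) {
    return(list(status = "infeasible", x = NULL))
  }
  # phase 2: artificials frozen at zero
  ue2 <- c(u, rep(0, m))
  c2 <- c(cc, rep(0, m))
  p2 <- run_phase(c2, p1$x, p1$basis, p1$at_upper, ue2)
  if (!identical(p2$status, "optimal")) return(list(status = p2$status, x = NULL))
  list(status = "optimal", x = p2$x[seq_len(n)])
}
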
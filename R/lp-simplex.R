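#' Solve a bounded-variable linear program
#'
#' Dense two-phase primal simplex for problems of the form
#' maximize (or minimize) \eqn{c'x} subject to \eqn{Ax = b} and
#' \eqn{l \le x \le u}. This is the optimization kernel behind flux balance
#' and flux variability analysis; problem sizes in this package are small
#' (tens of variables), so a dense implementation with Bland's anti-cycling
#' rule is adequate and fully deterministic.
#'
#' @param obj numeric objective coefficients, length `ncol(A)`.
#' @param A equality-constraint matrix.
#' @param rhs right-hand side, length `nrow(A)`.
#' @param lb,ub variable bounds; may contain `-Inf`/`Inf`.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol numerical tolerance for feasibility and optimality tests.
#'
#' @return A list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `objective` and the primal solution `x` (only when
#'   optimal).
#' @keywords internal
lp_solve <- function(obj, A, rhs, lb, ub, maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  if (m == 0L) {
    sense <- if (maximize) 1 else -1
    x <- ifelse(sense * obj >= 0, ub, lb)
    if (any(!is.finite(x) & abs(obj) > tol)) {
      return(list(status = "unbounded", objective = NA_real_, x = NULL))
    }
    x[!is.finite(x)] <- 0
    return(list(status = "optimal", objective = sum(obj * x), x = x))
  }

  cvec <- if (maximize) obj else -obj

  # phase-1 setup: structural variables at a finite bound (0 if none),
  # artificial variables absorb the residual
  start <- ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0))
  resid <- rhs - drop(A %*% start)
  Dart <- diag(ifelse(resid >= 0, 1, -1), nrow = m)
  M <- cbind(A, Dart)
  ntot <- n + m
  free <- c(!is.finite(lb) & !is.finite(ub), rep(FALSE, m))

  state <- list(
    basis = n + seq_len(m),
    # -1 nonbasic at lower, +1 nonbasic at upper, 0 basic
    vstat = c(ifelse(is.finite(lb) | !is.finite(ub), -1L, 1L), rep(0L, m)),
    xval = c(start, abs(resid))
  )

  run_phase <- function(cost, st, lbv, ubv) {
    basis <- st$basis; vstat <- st$vstat; xval <- st$xval
    for (iter in seq_len(20000L)) {
      B <- M[, basis, drop = FALSE]
      y <- tryCatch(drop(solve(t(B), cost[basis])), error = function(e) NULL)
      if (is.null(y)) return(list(status = "singular"))
      d <- cost - drop(crossprod(M, y))
      enter <- 0L; dir <- 1
      for (j in seq_len(ntot)) {  # Bland: smallest improving index enters
        if (vstat[j] == 0L) next
        if (lbv[j] >= ubv[j]) next  # fixed variables cannot move
        if (free[j]) {
          if (abs(d[j]) > tol) { enter <- j; dir <- sign(d[j]); break }
        } else if (vstat[j] == -1L && d[j] > tol) {
          enter <- j; dir <- 1; break
        } else if (vstat[j] == 1L && d[j] < -tol) {
          enter <- j; dir <- -1; break
        }
      }
      if (enter == 0L) {
        return(list(status = "optimal", basis = basis, vstat = vstat,
                    xval = xval))
      }
      w <- drop(solve(B, M[, enter]))
      # entering variable moves by dir * t; basic variables by -dir * w * t
      flip <- if (is.finite(lbv[enter]) && is.finite(ubv[enter])) {
        ubv[enter] - lbv[enter]
      } else Inf
      ratios <- rep(Inf, m)
      for (i in seq_len(m)) {
        bi <- basis[i]
        delta <- -dir * w[i]
        if (delta < -tol && is.finite(lbv[bi])) {
          ratios[i] <- (xval[bi] - lbv[bi]) / (-delta)
        } else if (delta > tol && is.finite(ubv[bi])) {
          ratios[i] <- (ubv[bi] - xval[bi]) / delta
        }
      }
      tstar <- min(flip, ratios)
      if (!is.finite(tstar)) return(list(status = "unbounded"))
      tstar <- max(tstar, 0)
      cand <- which(ratios <= tstar + 1e-9)
      xval[basis] <- xval[basis] - dir * w * tstar
      xval[enter] <- xval[enter] + dir * tstar
      if (length(cand) == 0L) {
        # bound flip: entering variable runs to its opposite bound
        vstat[enter] <- -vstat[enter]
        xval[enter] <- if (vstat[enter] == -1L) lbv[enter] else ubv[enter]
      } else {
        leave <- cand[which.min(basis[cand])]  # Bland tie-break
        out <- basis[leave]
        dlo <- if (is.finite(lbv[out])) abs(xval[out] - lbv[out]) else Inf
        dhi <- if (is.finite(ubv[out])) abs(xval[out] - ubv[out]) else Inf
        vstat[out] <- if (dlo <= dhi) -1L else 1L
        xval[out] <- if (dlo <= dhi) lbv[out] else ubv[out]
        basis[leave] <- enter
        vstat[enter] <- 0L
      }
    }
    list(status = "maxit")
  }

  lb1 <- c(lb, rep(0, m)); ub1 <- c(ub, rep(Inf, m))
  ph1 <- run_phase(c(rep(0, n), rep(-1, m)), state, lb1, ub1)
  if (!identical(ph1$status, "optimal")) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  if (sum(ph1$xval[n + seq_len(m)]) > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  ph1$xval[n + seq_len(m)] <- 0
  ub2 <- c(ub, rep(0, m))  # pin artificials
  ph2 <- run_phase(c(cvec, rep(0, m)), ph1, lb1, ub2)
  if (identical(ph2$status, "unbounded")) {
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  }
  if (!identical(ph2$status, "optimal")) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  x <- ph2$xval[seq_len(n)]
  list(status = "optimal", objective = sum(obj * x), x = x)
}
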
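#' Solve a bounded linear program
#'
#' Dense two-phase simplex for problems of the form
#' optimize \code{obj' v} subject to \code{A v = rhs} and
#' \code{lb <= v <= ub}. This is the linear-programming core behind
#' [fba()]; it handles the moderate problem sizes of enterocyte-scale
#' metabolic networks (a few hundred variables).
#'
#' The implementation is a bounded-variable revised simplex: nonbasic
#' variables rest at a finite bound, the basis inverse is maintained by
#' product-form updates and refactorized periodically, and Bland's rule
#' replaces Dantzig pricing after a fixed iteration count to exclude
#' cycling on degenerate vertices.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A dense constraint matrix (m x n).
#' @param rhs right-hand side (length m).
#' @param lb,ub variable bounds; \code{-Inf}/\code{Inf} allowed.
#' @param sense \code{"max"} or \code{"min"}.
#' @param tol reduced-cost/feasibility tolerance.
#' @param max_iter simplex iteration cap.
#' @return list with \code{status} ("optimal", "infeasible", "unbounded"
#'   or "maxiter"), \code{x} (solution, length n), \code{objval} on the
#'   original sense.
#' @export
lp_solve <- function(obj, A, rhs, lb, ub, sense = c("max", "min"),
                     tol = 1e-9, max_iter = 20000L) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(lb) == n,
            length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objval = NA_real_))
  }
  cmin <- if (sense == "max") -as.numeric(obj) else as.numeric(obj)

  ntot <- n + m
  Ax <- cbind(A, diag(1, m))
  lbx <- c(lb, rep(0, m))
  ubx <- c(ub, rep(Inf, m))

  # start structural variables at a finite bound (0 for free variables)
  x <- numeric(ntot)
  stat <- integer(ntot)            # -1 at lower, +1 at upper, 0 basic
  for (j in seq_len(n)) {
    if (is.finite(lbx[j])) { x[j] <- lbx[j]; stat[j] <- -1L }
    else if (is.finite(ubx[j])) { x[j] <- ubx[j]; stat[j] <- 1L }
    else { x[j] <- 0; stat[j] <- -1L }   # free var treated as at "lower" 0
  }
  r <- rhs - A %*% x[seq_len(n)]
  r <- as.numeric(r)
  sgn <- ifelse(r < 0, -1, 1)
  for (i in seq_len(m)) Ax[i, n + i] <- sgn[i]
  x[n + seq_len(m)] <- abs(r)
  basis <- n + seq_len(m)
  stat[basis] <- 0L
  Binv <- diag(sgn, m)

  run_phase <- function(cvec, x, stat, basis, Binv, phase) {
    iter <- 0L
    bland_after <- 5L * (ntot + m)
    since_refac <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter)
        return(list(status = "maxiter", x = x, stat = stat, basis = basis,
                    Binv = Binv))
      cb <- cvec[basis]
      y <- as.numeric(crossprod(Binv, cb))       # y = Binv' c_B
      nonb <- which(stat != 0L & lbx < ubx)      # fixed vars never enter
      if (length(nonb) == 0L) {
        return(list(status = "optimal", x = x, stat = stat, basis = basis,
                    Binv = Binv))
      }
      d <- cvec[nonb] - as.numeric(y %*% Ax[, nonb, drop = FALSE])
      viol <- ifelse(stat[nonb] == -1L, -d, d)   # positive => improving
      isfree <- !is.finite(lbx[nonb]) & !is.finite(ubx[nonb])
      viol[isfree] <- abs(d[isfree])             # free vars move either way
      cand <- which(viol > tol)
      if (length(cand) == 0L)
        return(list(status = "optimal", x = x, stat = stat, basis = basis,
                    Binv = Binv))
      if (iter > bland_after) {
        q <- min(nonb[cand])
      } else {
        q <- nonb[cand[which.max(viol[cand])]]
      }
      if (!is.finite(lbx[q]) && !is.finite(ubx[q])) {
        dq <- cvec[q] - sum(y * Ax[, q])
        dir <- if (dq < 0) 1 else -1
      } else {
        dir <- if (stat[q] == -1L) 1 else -1
      }
      w <- as.numeric(Binv %*% Ax[, q])

      # ratio test (vectorized over the basis)
      rate <- -dir * w
      lim <- rep(Inf, m)
      ineg <- which(rate < -tol)
      if (length(ineg))
        lim[ineg] <- (x[basis[ineg]] - lbx[basis[ineg]]) / (-rate[ineg])
      ipos <- which(rate > tol)
      if (length(ipos))
        lim[ipos] <- (ubx[basis[ipos]] - x[basis[ipos]]) / rate[ipos]
      delta <- ubx[q] - lbx[q]                  # own-range flip
      leave <- 0L
      ib <- which.min(lim)
      if (length(ib) && lim[ib] < delta - 1e-12) {
        delta <- lim[ib]
        leave <- ib
      }
      if (!is.finite(delta))
        return(list(status = if (phase == 1L) "infeasible" else "unbounded",
                    x = x, stat = stat, basis = basis, Binv = Binv))
      if (delta < 0) delta <- 0

      x[q] <- x[q] + dir * delta
      x[basis] <- x[basis] + rate * delta
      if (leave == 0L) {                        # bound flip, basis unchanged
        stat[q] <- -stat[q]
        next
      }
      p <- basis[leave]
      # leaving variable lands on the bound it ran into
      stat[p] <- if (rate[leave] < 0) -1L else 1L
      x[p] <- if (stat[p] == -1L) lbx[p] else ubx[p]
      basis[leave] <- q
      stat[q] <- 0L
      # product-form update of Binv
      piv <- w[leave]
      if (abs(piv) < 1e-11 || since_refac >= 60L) {
        B <- Ax[, basis, drop = FALSE]
        Binv <- tryCatch(solve(B), error = function(e) NULL)
        if (is.null(Binv))
          return(list(status = "singular", x = x, stat = stat,
                      basis = basis, Binv = diag(m)))
        since_refac <- 0L
      } else {
        Binv[leave, ] <- Binv[leave, ] / piv
        idx <- setdiff(seq_len(m), leave)
        Binv[idx, ] <- Binv[idx, ] - outer(w[idx], Binv[leave, ])
        since_refac <- since_refac + 1L
      }
    }
  }

  c1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(c1, x, stat, basis, Binv, 1L)
  if (ph1$status != "optimal")
    return(list(status = if (ph1$status == "maxiter") "maxiter"
                else "infeasible",
                x = rep(NA_real_, n), objval = NA_real_))
  art_val <- sum(ph1$x[n + seq_len(m)])
  if (art_val > 1e-7)
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objval = NA_real_))
  # pin artificials at zero for phase 2
  ubx[n + seq_len(m)] <- 0
  ph1$x[n + seq_len(m)] <- 0
  c2 <- c(cmin, rep(0, m))
  ph2 <- run_phase(c2, ph1$x, ph1$stat, ph1$basis, ph1$Binv, 2L)
  if (!ph2$status %in% c("optimal"))
    return(list(status = ph2$status, x = rep(NA_real_, n),
                objval = NA_real_))
  xs <- ph2$x[seq_len(n)]
  # clean tiny violations
  xs <- pmin(pmax(xs, lb), ub)
  obj_min <- sum(cmin * xs)
  list(status = "optimal", x = xs,
       objval = if (sense == "max") -obj_min else obj_min)
}
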
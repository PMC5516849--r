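#' Flux balance analysis
#'
#' Solves the steady-state LP `max/min c'v` subject to `S v = 0`,
#' reaction bounds, and the network's linear coupling constraints.
#' Degenerate alternate optima are resolved lexicographically: the
#' objective value is fixed and the total absolute flux is minimized,
#' so returned flux vectors are deterministic.
#'
#' @param net a `stoich_network`.
#' @param objective reaction id; defaults to the network objective.
#' @param sense `"max"` (default) or `"min"`.
#' @param extra_bounds named list of `c(lb, ub)` overrides applied for
#'   this solve only.
#' @param extra_couplings list of additional coupling constraints
#'   (`coef`, `rhs`, `sense` in `"eq"`/`"le"`), e.g. carrier-capacity
#'   allocations.
#' @param minimize_total if `TRUE` (default) apply the secondary
#'   total-flux minimization.
#' @return `flux_solution`: list with `status`, `objective` (value,
#'   mmol/gDW/h), `fluxes` (named vector). On infeasibility, `status`
#'   is `"infeasible"` and a `diagnostic` field lists the reactions
#'   whose bounds force nonzero flux.
#' @export
fba <- function(net, objective = NULL, sense = c("max", "min"),
                extra_bounds = NULL, extra_couplings = NULL,
                minimize_total = TRUE) {
  sense <- match.arg(sense)
  objective <- objective %||% net$objective
  if (is.null(objective) || !objective %in% net$rxns$id)
    stop("objective reaction '", objective, "' not in network",
         call. = FALSE)
  rx <- net$rxns
  if (!is.null(extra_bounds)) {
    for (id in names(extra_bounds)) {
      j <- match(id, rx$id)
      if (is.na(j)) stop("unknown reaction in extra_bounds: ", id,
                         call. = FALSE)
      rx$lb[j] <- extra_bounds[[id]][1]
      rx$ub[j] <- extra_bounds[[id]][2]
    }
  }
  if (any(rx$lb > rx$ub)) {
    bad <- rx$id[rx$lb > rx$ub]
    return(structure(list(status = "infeasible", objective = NA_real_,
                          fluxes = NULL,
                          diagnostic = paste("inconsistent bounds:",
                                             paste(bad, collapse = ", "))),
                     class = "flux_solution"))
  }
  n <- nrow(rx)
  coup <- c(net$couplings, extra_couplings %||% list())
  A <- net$S
  rhs <- rep(0, nrow(A))
  lb <- rx$lb; ub <- rx$ub
  nslack <- sum(vapply(coup, function(cp) identical(cp$sense, "le"), TRUE))
  if (length(coup)) {
    extra <- matrix(0, length(coup), n)
    slack_cols <- matrix(0, nrow(A) + length(coup), nslack)
    si <- 0
    for (i in seq_along(coup)) {
      cp <- coup[[i]]
      extra[i, match(names(cp$coef), rx$id)] <- cp$coef
      rhs <- c(rhs, cp$rhs)
    }
    A <- rbind(A, extra)
    if (nslack > 0) {
      si <- 0
      for (i in seq_along(coup)) {
        if (identical(coup[[i]]$sense, "le")) {
          si <- si + 1
          slack_cols[nrow(net$S) + i, si] <- 1
        }
      }
      A <- cbind(A, slack_cols)
      lb <- c(lb, rep(0, nslack))
      ub <- c(ub, rep(Inf, nslack))
    }
  }
  obj <- numeric(ncol(A))
  jobj <- match(objective, rx$id)
  obj[jobj] <- 1
  sol <- lp_solve(obj, A, rhs, lb, ub, sense)
  if (sol$status != "optimal") {
    diag <- if (sol$status == "infeasible") {
      forced <- rx$id[rx$lb > 0 | rx$ub < 0]
      paste("binding candidates (bounds forcing nonzero flux):",
            paste(forced, collapse = ", "))
    } else sol$status
    return(structure(list(status = sol$status, objective = NA_real_,
                          fluxes = NULL, diagnostic = diag),
                     class = "flux_solution"))
  }
  v <- sol$x
  if (minimize_total) {
    # lexicographic stage: fix the objective, minimize sum |v| via a
    # positive/negative split of sign-free variables
    nv <- ncol(A)
    neg <- which(lb < 0)
    nneg <- length(neg)
    A2 <- cbind(A, -A[, neg, drop = FALSE])
    lb2 <- c(pmax(lb, 0), pmax(-ub[neg], 0))
    ub2 <- c(pmax(ub, 0), pmax(-lb[neg], 0))
    # objective-fixing row
    orow <- numeric(nv + nneg)
    orow[jobj] <- 1
    A2 <- rbind(A2, orow)
    rhs2 <- c(rhs, sol$objval)
    c2 <- c(rep(1, n), rep(0, nv - n), rep(1, sum(neg <= n)),
            rep(0, sum(neg > n)))
    sol2 <- lp_solve(c2, A2, rhs2, lb2, ub2, "min")
    if (sol2$status == "optimal") {
      v <- sol2$x[seq_len(nv)]
      v[neg] <- v[neg] - sol2$x[nv + seq_len(nneg)]
    }
  }
  fluxes <- stats::setNames(v[seq_len(n)], rx$id)
  resid <- max(abs(net$S %*% fluxes))
  if (resid > 1e-6)
    warning("steady-state residual ", signif(resid, 3), call. = FALSE)
  structure(list(status = "optimal", objective = sol$objval,
                 fluxes = fluxes), class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution:", x$status)
  if (x$status == "optimal") cat(", objective =", x$objective)
  cat("\n")
  if (!is.null(x$diagnostic)) cat(x$diagnostic, "\n")
  invisible(x)
}

#' Carrier-allocation bounds for the luminal carrier
#'
#' Allocates the shared luminal-carrier capacity `v_t` across levodopa
#' and the competing luminal amino acids by affinity-weighted shares,
#' and returns the resulting constraint set: the summed luminal
#' antiport flux (levodopa uptake through the carrier) is capped at
#' levodopa's share of `v_t`, and per-substrate antiport reactions are
#' capped by the co-substrate's availability.
#'
#' @param net a `stoich_network` with the levodopa module.
#' @param luminal_aa_amounts named vector, mmol per species in the
#'   segment lumen.
#' @param levodopa_lumen levodopa amount in the segment lumen, mmol.
#' @param catalog a [transporter_catalog()].
#' @param v_t carrier capacity, mmol/gDW/h.
#' @return list with `share` (levodopa share), `bounds` (named list)
#'   and `couplings` (capacity allocation as a `le` constraint), ready
#'   to pass to [fba()].
#' @export
apply_competition_bounds <- function(net, luminal_aa_amounts = numeric(),
                                     levodopa_lumen = 1,
                                     catalog = transporter_catalog(),
                                     v_t = 15) {
  share <- competition_share(levodopa_lumen, luminal_aa_amounts,
                             catalog$luminal_antiporter,
                             catalog$luminal_levodopa_rank)
  anti <- paste0("LDOPA_lum_anti_", names(catalog$luminal_antiporter))
  anti <- intersect(anti, net$rxns$id)
  if (!length(anti))
    stop("network lacks the luminal antiporter module", call. = FALSE)
  cp <- list(coef = stats::setNames(rep(1, length(anti)), anti),
             rhs = share * v_t, sense = "le")
  list(share = share, bounds = list(), couplings = list(cp))
}
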
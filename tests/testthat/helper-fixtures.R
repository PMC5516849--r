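# shared fixtures: parameter sets, networks, and independent oracles

default_phys <- function(...) physiology_parameters(...)
default_kin <- function(...) kinetic_parameters(...)

reduced_with_levodopa <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- add_levodopa_module(build_reduced_siec())
    cache
  }
})

siec_star <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- extend_brain_kidney(reduced_with_levodopa())
    cache
  }
})

# Independent LP oracle: exhaustive vertex enumeration for
# max c'v s.t. S v = 0, lb <= v <= ub (small n only). A vertex fixes
# n - rank(S) variables at a bound and solves for the rest.
bf_lp_max <- function(obj, S, lb, ub, tol = 1e-9) {
  n <- ncol(S)
  qrS <- qr(S)
  r <- qrS$rank
  nf <- n - r
  best <- -Inf
  if (nf == 0) {
    v <- rep(0, n)
    if (all(abs(S %*% v) < tol) && all(v >= lb - tol) &&
        all(v <= ub + tol))
      best <- sum(obj * v)
    return(best)
  }
  for (fixed in utils::combn(n, nf, simplify = FALSE)) {
    freei <- setdiff(seq_len(n), fixed)
    Sb <- S[, freei, drop = FALSE]
    if (qr(Sb)$rank < length(freei)) next
    for (mask in 0:(2^nf - 1)) {
      vals <- ifelse(bitwAnd(mask, 2^(seq_len(nf) - 1)) > 0,
                     ub[fixed], lb[fixed])
      if (any(!is.finite(vals))) next
      rhs <- -S[, fixed, drop = FALSE] %*% vals
      vb <- tryCatch(qr.solve(Sb, rhs), error = function(e) NULL)
      if (is.null(vb)) next
      v <- numeric(n); v[fixed] <- vals; v[freei] <- vb
      if (all(v >= lb - tol) && all(v <= ub + tol) &&
          all(abs(S %*% v) < 1e-7))
        best <- max(best, sum(obj * v))
    }
  }
  best
}

# random small flux network with a feasible interior (zero flux)
random_small_net <- function(n_rxn, n_met, seed) {
  set.seed(seed)
  S <- matrix(sample(-1:1, n_met * n_rxn, replace = TRUE,
                     prob = c(0.3, 0.3, 0.4)), n_met, n_rxn)
  lb <- round(stats::runif(n_rxn, -4, 0), 1)
  ub <- lb + round(stats::runif(n_rxn, 0.5, 5), 1)
  list(S = S, lb = lb, ub = ub,
       obj = round(stats::runif(n_rxn, -2, 2), 1))
}
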
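FITTABLE_KINETICS <- c("hepatic_clearance", "renal_clearance",
                       "k_deg_stomach", "k_deg_lumen",
                       "dissolution_coefficient", "ka_fallback",
                       "k_secretion", "colon_elimination_rate")

# Applies a named parameter vector onto (physiology, kinetics).
# "ger" and "si_transit_rate" address physiology, everything else the
# scalar kinetic fields.
apply_free_params <- function(physiology, kinetics, values) {
  for (nmp in names(values)) {
    if (nmp %in% c("ger", "si_transit_rate")) {
      physiology[[nmp]] <- values[[nmp]]
    } else if (nmp %in% FITTABLE_KINETICS) {
      kinetics[[nmp]] <- values[[nmp]]
    } else {
      stop("unknown free parameter: ", nmp, call. = FALSE)
    }
  }
  list(physiology = physiology, kinetics = kinetics)
}

#' Generate synthetic plasma concentration observations
#'
#' Simulates the whole-body model and samples the plasma concentration
#' on a schedule, optionally applying multiplicative lognormal noise
#' with a given coefficient of variation (mean-one noise factors, so
#' the expectation equals the model prediction).
#'
#' @param physiology,kinetics parameter objects defining the truth.
#' @param regimen a [dose_regimen()].
#' @param times sampling schedule, h.
#' @param noise `"none"` or `"lognormal"`.
#' @param cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed (required for noisy observations).
#' @return `observation_set`: data.frame with `time`, `conc` (mg/l) and
#'   `weight`, carrying the regimen as an attribute.
#' @export
generate_observations <- function(physiology, kinetics, regimen,
                                  times = seq(0.25, 6, by = 0.25),
                                  noise = c("none", "lognormal"),
                                  cv = 0.05, seed = NULL) {
  noise <- match.arg(noise)
  model <- build_wb_acat(physiology, kinetics)
  tc <- simulate_wb(model, regimen, max(times), dt_out = 0.05)
  conc <- stats::approx(tc$time, tc$plasma_conc, xout = times)$y
  if (noise == "lognormal") {
    if (is.null(seed)) stop("seed required for noisy observations",
                            call. = FALSE)
    sdlog <- sqrt(log(1 + cv^2))
    set.seed(seed)
    conc <- conc * exp(stats::rnorm(length(conc), -sdlog^2 / 2, sdlog))
  }
  obs <- data.frame(time = times, conc = conc, weight = 1)
  attr(obs, "regimen") <- regimen
  attr(obs, "noise") <- noise
  class(obs) <- c("observation_set", "data.frame")
  obs
}

#' Fit kinetic parameters to plasma observations
#'
#' Global multistart constrained least squares: starting points are a
#' seeded Latin-hypercube sample of the box constraints, each polished
#' with bounded Levenberg-Marquardt (`minpack.lm::nls.lm`); the best
#' converged start is returned. The objective is the weighted sum of
#' squared concentration residuals with weights
#' `1 / max(observed, weight_floor)`.
#'
#' @param obs an `observation_set`.
#' @param physiology,kinetics base parameter objects; free parameters
#'   are overridden per start.
#' @param free named list of `c(lower, upper)` bounds for each free
#'   parameter (names from `ger`, `si_transit_rate`, or the scalar
#'   kinetic fields).
#' @param n_starts number of multistarts.
#' @param seed integer seed controlling the start sample.
#' @param weight_floor floor of the weighting denominator, mg/l.
#' @return `fit_result`: list with `par` (best values), `residual_norm`
#'   (weighted SSE), `starts` (per-start log), `goodness` (KS p-value
#'   and Pearson r of the best fit), `bounds`, `seed`.
#' @export
fit_model <- function(obs, physiology, kinetics, free, n_starts = 16,
                      seed = 1, weight_floor = 0.1) {
  stopifnot(inherits(obs, "observation_set") || is.data.frame(obs))
  if (n_starts < 1) stop("n_starts must be >= 1", call. = FALSE)
  pnames <- names(free)
  lower <- vapply(free, `[`, 0, 1)
  upper <- vapply(free, `[`, 0, 2)
  if (any(lower > upper)) stop("invalid bounds", call. = FALSE)
  regimen <- attr(obs, "regimen")
  if (is.null(regimen)) stop("observation set lacks a dose regimen",
                             call. = FALSE)
  tmax <- max(obs$time)
  w <- obs$weight / pmax(obs$conc, weight_floor)

  predict_conc <- function(values) {
    pk <- apply_free_params(physiology, kinetics, values)
    model <- build_wb_acat(pk$physiology, pk$kinetics)
    tc <- simulate_wb(model, regimen, tmax, dt_out = 0.05)
    stats::approx(tc$time, tc$plasma_conc, xout = obs$time)$y
  }
  resid_fn <- function(par) {
    (predict_conc(stats::setNames(par, pnames)) - obs$conc) * w
  }

  set.seed(seed)
  k <- length(pnames)
  grid <- lhs::randomLHS(n_starts, k)
  starts <- sweep(sweep(grid, 2, upper - lower, `*`), 2, lower, `+`)
  log_rows <- vector("list", n_starts)
  best <- NULL
  for (i in seq_len(n_starts)) {
    p0 <- pmin(pmax(starts[i, ], lower), upper)
    fitted <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 100, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) e)
    if (inherits(fitted, "error")) {
      log_rows[[i]] <- data.frame(start = i, converged = FALSE,
                                  sse = NA_real_,
                                  message = conditionMessage(fitted))
      next
    }
    sse <- sum(resid_fn(fitted$par)^2)
    log_rows[[i]] <- data.frame(start = i, converged = TRUE, sse = sse,
                                message = fitted$message)
    if (is.null(best) || sse < best$sse)
      best <- list(par = fitted$par, sse = sse)
  }
  if (is.null(best))
    stop("all multistarts failed", call. = FALSE)
  par <- stats::setNames(best$par, pnames)
  pred <- predict_conc(par)
  structure(list(par = par, residual_norm = best$sse,
                 starts = do.call(rbind, log_rows),
                 goodness = goodness_of_fit(pred, obs$conc),
                 bounds = cbind(lower = lower, upper = upper),
                 seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result: weighted SSE", signif(x$residual_norm, 5), "\n")
  print(signif(x$par, 5))
  cat("KS p =", signif(x$goodness$ks_pvalue, 4), " Pearson r =",
      signif(x$goodness$pearson_r, 4), "\n")
  invisible(x)
}

#' Sequential two-occasion gastric-emptying fit
#'
#' Stage 1 (fasted occasion): the gastric-emptying rate is pinned at
#' its literature fasted value and the requested kinetic parameters are
#' fitted on the fasted observations. Stage 2 (fed occasion): all
#' kinetic parameters are frozen at their stage-1 estimates and the
#' gastric-emptying rate alone is fitted on the fed observations. The
#' food-induced delay is thereby isolated in a single parameter.
#'
#' @param fasted_obs,fed_obs `observation_set`s for the two occasions.
#' @param physiology,kinetics base parameter objects (fasted-state
#'   physiology; its `ger` is reset to the literature fasted value).
#' @param free_kinetics named bounds list for the stage-1 kinetic fit.
#' @param ger_bounds bounds for the stage-2 gastric-emptying fit, 1/h.
#' @param n_starts,seed multistart controls, as in [fit_model()].
#' @param fed_physiology if `TRUE` (default) stage 2 runs under the
#'   fed-state values of the non-emptying prandial parameters (they
#'   are literature values, not estimates); set `FALSE` to leave the
#'   stage-1 physiology untouched so the occasions differ only in the
#'   gastric-emptying rate.
#' @return list with `stage1`, `stage2` (both `fit_result`), `ger`
#'   (fed-state estimate) and `kinetics` (stage-1 kinetic estimates).
#' @export
sequential_two_occasion_fit <- function(fasted_obs, fed_obs, physiology,
                                        kinetics, free_kinetics,
                                        ger_bounds = c(0.05, 6),
                                        n_starts = 8, seed = 1,
                                        fed_physiology = TRUE) {
  phys1 <- physiology
  phys1$ger <- PRANDIAL_TABLE$fasted$ger
  stage1 <- fit_model(fasted_obs, phys1, kinetics, free_kinetics,
                      n_starts = n_starts, seed = seed)
  pk <- apply_free_params(phys1, kinetics, stage1$par)
  # the non-emptying prandial parameters (volumes, transit, pH) are
  # literature values, not estimates: the fed occasion runs under fed
  # physiology with the gastric-emptying rate as the only unknown
  phys2 <- if (fed_physiology)
    set_prandial_state(pk$physiology, "fed") else pk$physiology
  stage2 <- fit_model(fed_obs, phys2, pk$kinetics,
                      free = list(ger = ger_bounds),
                      n_starts = n_starts, seed = seed + 1)
  list(stage1 = stage1, stage2 = stage2,
       ger = unname(stage2$par[["ger"]]),
       kinetics = stage1$par)
}

#' Goodness of fit between predicted and observed series
#'
#' Two-sample Kolmogorov-Smirnov p-value between the predicted and
#' observed concentration samples, and the Pearson correlation of the
#' paired values. A constant series leaves the correlation undefined;
#' it is reported as `NA`.
#'
#' @param pred,obs equal-length numeric vectors (n >= 3).
#' @return list `ks_pvalue`, `pearson_r`.
#' @export
goodness_of_fit <- function(pred, obs) {
  if (length(pred) != length(obs) || length(obs) < 3)
    stop("need equal-length paired series with n >= 3", call. = FALSE)
  ks <- suppressWarnings(stats::ks.test(pred, obs))
  r <- if (stats::sd(pred) == 0 || stats::sd(obs) == 0) NA_real_ else
    stats::cor(pred, obs)
  list(ks_pvalue = unname(ks$p.value), pearson_r = r)
}

GI_PARAMETERS <- c("ger", "stomach_volume", "colon_volume",
                   "si_transit_rate", "gastric_ph", "k_deg_stomach",
                   "k_deg_lumen", "dissolution_coefficient",
                   "ka_fallback", "k_secretion",
                   "colon_elimination_rate")

# get/set a scalar parameter by dotted path, e.g.
# "kinetics.organ_blood_flows.muscle" or "physiology.ger"
param_get <- function(physiology, kinetics, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  root <- if (parts[1] == "physiology") physiology else kinetics
  if (length(parts) == 2) root[[parts[2]]] else root[[parts[2]]][[parts[3]]]
}

param_set <- function(physiology, kinetics, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (parts[1] == "physiology") {
    if (length(parts) == 2) physiology[[parts[2]]] <- value
    else physiology[[parts[2]]][[parts[3]]] <- value
  } else {
    if (length(parts) == 2) kinetics[[parts[2]]] <- value
    else kinetics[[parts[2]]][[parts[3]]] <- value
  }
  list(physiology = physiology, kinetics = kinetics)
}

#' Default parameter census for the sensitivity ranking
#'
#' Dotted paths of all scalar whole-body parameters: the
#' gastrointestinal set (emptying, transit, volumes, pH, dissolution,
#' degradation, absorption) plus every organ blood flow, organ volume
#' and partition coefficient, and the two clearances.
#'
#' @return character vector of parameter paths.
#' @export
sensitivity_census <- function() {
  c(paste0("physiology.", c("ger", "stomach_volume", "colon_volume",
                            "si_transit_rate", "gastric_ph")),
    paste0("kinetics.", FITTABLE_KINETICS),
    paste0("kinetics.organ_blood_flows.",
           c(PBPK_ORGANS[!PBPK_ORGANS %in% "liver"], "gut",
             "hepatic_artery")),
    paste0("kinetics.organ_volumes.",
           c(PBPK_ORGANS, "lung", "venous", "arterial", "portal")),
    paste0("kinetics.partition_coefficients.", c(PBPK_ORGANS, "lung")))
}

#' Sensitivity score of a single parameter
#'
#' Central finite-difference approximation of the time-dependent
#' derivative of a model curve with respect to one parameter, scored
#' by the trapezoidal integral of its absolute value.
#'
#' @param curve_fn function of a scalar parameter returning the curve
#'   evaluated on `t_grid`.
#' @param p0 nominal parameter value.
#' @param t_grid time grid, h.
#' @param rel_step relative finite-difference step.
#' @return nonnegative score (curve units x h per parameter unit).
#' @export
sensitivity_score <- function(curve_fn, p0, t_grid, rel_step = 1e-4) {
  h <- rel_step * if (abs(p0) > 0) abs(p0) else 1
  sens <- (curve_fn(p0 + h) - curve_fn(p0 - h)) / (2 * h)
  if (any(!is.finite(sens)))
    stop("non-finite sensitivity", call. = FALSE)
  pracma::trapz(t_grid, abs(sens))
}

#' Time-dependent local parameter sensitivity ranking
#'
#' For each parameter, the non-normalized time-dependent derivative of
#' the plasma concentration, `dC(t)/dp`, is approximated by central
#' finite differences (relative step 1e-4) and scored by the
#' trapezoidal integral of its absolute value over the time grid;
#' parameters are ranked by descending score. Parameters with
#' non-finite derivatives are flagged and excluded.
#'
#' @param physiology,kinetics parameter objects at the nominal point.
#' @param regimen a [dose_regimen()].
#' @param params parameter paths (see [sensitivity_census()]).
#' @param t_grid time grid for the sensitivity integral, h.
#' @param rel_step relative finite-difference step.
#' @return data.frame (`parameter`, `score`, `gi`) sorted by
#'   descending score; attribute `excluded` lists flagged parameters.
#' @export
sensitivity_ranking <- function(physiology, kinetics, regimen,
                                params = sensitivity_census(),
                                t_grid = seq(0, 6, by = 0.1),
                                rel_step = 1e-4) {
  duration <- max(t_grid)
  base_conc <- function(phys, kin) {
    model <- build_wb_acat(phys, kin)
    tc <- simulate_wb(model, regimen, duration, dt_out = 0.05)
    stats::approx(tc$time, tc$plasma_conc, xout = t_grid)$y
  }
  # flow perturbations must preserve flow conservation: perturbing a
  # flow adjusts lung (cardiac output) and liver totals accordingly
  rebalance <- function(kin) {
    q <- kin$organ_blood_flows
    q[["liver"]] <- q[["hepatic_artery"]] + q[["gut"]] + q[["spleen"]] +
      q[["pancreas"]]
    q[["lung"]] <- sum(q[c("heart", "brain", "muscle", "adipose", "skin",
                           "bone", "kidney", "rest_of_body")]) +
      q[["liver"]]
    kin$organ_blood_flows <- q
    kin
  }
  scores <- numeric(length(params))
  ok <- logical(length(params))
  for (i in seq_along(params)) {
    p0 <- param_get(physiology, kinetics, params[i])
    curve_fn <- function(pv) {
      s <- param_set(physiology, kinetics, params[i], pv)
      base_conc(s$physiology, rebalance(s$kinetics))
    }
    sc <- tryCatch(sensitivity_score(curve_fn, p0, t_grid, rel_step),
                   error = function(e) NULL)
    if (is.null(sc)) {
      scores[i] <- NA_real_
      ok[i] <- FALSE
    } else {
      scores[i] <- sc
      ok[i] <- TRUE
    }
  }
  leaf <- vapply(strsplit(params, ".", fixed = TRUE),
                 function(x) x[2], "")
  res <- data.frame(parameter = params[ok], score = scores[ok],
                    gi = leaf[ok] %in% GI_PARAMETERS)
  res <- res[order(-res$score), ]
  rownames(res) <- NULL
  attr(res, "excluded") <- params[!ok]
  res
}
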
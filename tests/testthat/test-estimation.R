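test_that("synthetic observations are exact without noise,
           reproducible with a seed, and carry the requested
           coefficient of variation", {
  phys <- default_phys(); kin <- default_kin()
  reg <- dose_regimen(0, 200, 6)
  obs <- generate_observations(phys, kin, reg)
  mod <- build_wb_acat(phys, kin)
  tc <- simulate_wb(mod, reg, 6, dt_out = 0.05)
  expect_equal(obs$conc,
               approx(tc$time, tc$plasma_conc, xout = obs$time)$y)
  o1 <- generate_observations(phys, kin, reg, noise = "lognormal",
                              cv = 0.05, seed = 123)
  o2 <- generate_observations(phys, kin, reg, noise = "lognormal",
                              cv = 0.05, seed = 123)
  expect_identical(o1, o2)
  expect_error(generate_observations(phys, kin, reg,
                                     noise = "lognormal"), "seed")
  # Monte-Carlo check of the noise model: pooled noise factors across
  # seeds have cv 0.05 and mean 1
  ratios <- unlist(lapply(1:50, function(s) {
    on <- generate_observations(phys, kin, reg, noise = "lognormal",
                                cv = 0.05, seed = s)
    on$conc / obs$conc
  }))
  expect_equal(sd(ratios) / mean(ratios), 0.05, tolerance = 0.1)
  expect_equal(mean(ratios), 1, tolerance = 0.01)
})

test_that("noiseless synthetic data recover the generating parameters
           within 1 percent", {
  phys <- default_phys(); kin <- default_kin()
  reg <- dose_regimen(0, 200, 6)
  obs <- generate_observations(phys, kin, reg)
  fr <- fit_model(obs, phys, kin,
                  free = list(hepatic_clearance = c(3, 60),
                              k_deg_lumen = c(0.05, 2)),
                  n_starts = 8, seed = 42)
  truth <- c(hepatic_clearance = 15, k_deg_lumen = 0.5)
  expect_lt(max(abs(fr$par - truth) / truth), 0.01)
  expect_equal(fr$goodness$pearson_r, 1, tolerance = 1e-6)
})

test_that("5 percent multiplicative noise keeps recovery within 15
           percent and the multistart log is monotone", {
  phys <- default_phys(); kin <- default_kin()
  reg <- dose_regimen(0, 200, 6)
  obs <- generate_observations(phys, kin, reg, noise = "lognormal",
                               cv = 0.05, seed = 7)
  fr <- fit_model(obs, phys, kin,
                  free = list(hepatic_clearance = c(3, 60),
                              k_deg_lumen = c(0.05, 2)),
                  n_starts = 8, seed = 42)
  truth <- c(hepatic_clearance = 15, k_deg_lumen = 0.5)
  expect_lt(max(abs(fr$par - truth) / truth), 0.15)
  # best-so-far objective never increases as starts accumulate
  sse <- fr$starts$sse[fr$starts$converged]
  expect_true(all(diff(cummin(sse)) <= 0))
  expect_lte(fr$residual_norm, min(sse))
})

test_that("point bounds pin the fit to the forward model", {
  phys <- default_phys(); kin <- default_kin()
  reg <- dose_regimen(0, 200, 4)
  obs <- generate_observations(phys, kin, reg,
                               times = seq(0.5, 4, 0.5))
  fr <- fit_model(obs, phys, kin,
                  free = list(hepatic_clearance = c(20, 20)),
                  n_starts = 2, seed = 1)
  expect_equal(unname(fr$par[["hepatic_clearance"]]), 20)
  expect_gt(fr$residual_norm, 0)   # wrong clearance leaves residuals
})

test_that("the sequential two-occasion procedure recovers the fed
           gastric-emptying rate and freezes stage-1 kinetics", {
  phys <- default_phys(); kin <- default_kin()
  reg <- dose_regimen(0, 200, 6)
  fasted_obs <- generate_observations(phys, kin, reg)
  fed_truth <- set_prandial_state(phys, "fed")
  fed_obs <- generate_observations(fed_truth, kin, reg,
                                   times = seq(0.5, 10, 0.5))
  sq <- sequential_two_occasion_fit(
    fasted_obs, fed_obs, phys, kin,
    free_kinetics = list(hepatic_clearance = c(3, 60)),
    n_starts = 4, seed = 1)
  expect_equal(sq$ger, 0.33, tolerance = 0.01)
  # stage 2 exposes only the emptying rate; stage-1 kinetics unchanged
  expect_identical(names(sq$stage2$par), "ger")
  expect_identical(sq$kinetics, sq$stage1$par)
  # occasions differing only in the emptying rate: identical data
  # recover the fasted value (no food effect)
  sq0 <- sequential_two_occasion_fit(
    fasted_obs, fasted_obs, phys, kin,
    free_kinetics = list(hepatic_clearance = c(3, 60)),
    n_starts = 4, seed = 1, fed_physiology = FALSE)
  expect_equal(sq0$ger, 3.96, tolerance = 0.05)
})

test_that("goodness of fit reproduces textbook values on worked
           examples", {
  x <- c(1, 2, 3, 4, 5)
  g <- goodness_of_fit(x, x)
  expect_equal(g$pearson_r, 1)
  expect_equal(g$ks_pvalue, 1)
  xc <- x - mean(x)
  expect_equal(goodness_of_fit(-xc, xc)$pearson_r, -1)
  # hand-computed pair set: r via the product-moment formula and the
  # two-sample KS statistic via direct ecdf comparison
  p <- c(0.5, 1.1, 2.3, 3.0, 4.2)
  o <- c(0.7, 1.0, 2.0, 3.5, 4.0)
  g2 <- goodness_of_fit(p, o)
  r_hand <- sum((p - mean(p)) * (o - mean(o))) /
    sqrt(sum((p - mean(p))^2) * sum((o - mean(o))^2))
  expect_equal(g2$pearson_r, r_hand)
  d_hand <- max(abs(ecdf(p)(sort(c(p, o))) - ecdf(o)(sort(c(p, o)))))
  expect_equal(suppressWarnings(ks.test(p, o))$statistic[["D"]], d_hand)
  expect_equal(g2$ks_pvalue,
               suppressWarnings(ks.test(p, o))$p.value)
  # constant series: correlation undefined
  expect_true(is.na(goodness_of_fit(rep(1, 5), x)$pearson_r))
  expect_error(goodness_of_fit(1:2, 1:2), "n >= 3")
})

test_that("sensitivity scoring matches the closed-form one-compartment
           oracle and vanishes for non-influential parameters", {
  # C(t) = C0 exp(-k t): dC/dk = -t C, and the absolute time integral
  # has the closed form C0 (1/k^2 - exp(-kT) (T/k + 1/k^2))
  c0 <- 2; k <- 0.8; tg <- seq(0, 6, 0.05)
  score <- sensitivity_score(function(p) c0 * exp(-p * tg), k, tg)
  closed <- c0 * (1 / k^2 - exp(-k * 6) * (6 / k + 1 / k^2))
  expect_equal(score, closed, tolerance = 0.01)
  # grid refinement changes the score by less than 1 percent
  tg2 <- seq(0, 6, 0.025)
  score2 <- sensitivity_score(function(p) c0 * exp(-p * tg2), k, tg2)
  expect_lt(abs(score2 - score) / score, 0.01)
  # colonic parameters have no influence before drug reaches the colon
  phys <- default_phys(); kin <- default_kin()
  reg <- dose_regimen(0, 200, 2)
  rk <- sensitivity_ranking(phys, kin, reg,
                            params = c("physiology.colon_volume",
                                       "kinetics.hepatic_clearance"),
                            t_grid = seq(0, 1, 0.1))
  expect_lt(rk$score[rk$parameter == "physiology.colon_volume"], 1e-6)
  expect_gt(rk$score[rk$parameter == "kinetics.hepatic_clearance"], 0)
})

test_that("under impaired (fed) gastric emptying the emptying rate
           dominates the whole-body sensitivity ranking", {
  fed <- set_prandial_state(default_phys(), "fed")
  rk <- sensitivity_ranking(fed, default_kin(), dose_regimen(0, 200, 6),
                            t_grid = seq(0, 6, 0.25))
  expect_equal(rk$parameter[1], "physiology.ger")
  expect_gte(sum(rk$gi[1:5]), 3)
})
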
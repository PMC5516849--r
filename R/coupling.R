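#' Coupling configuration
#'
#' Settings of the dynamic flux-balance coupling loop: the simulation is
#' discretized into fixed steps; at every step each segment's enterocyte
#' model is re-solved under bounds derived from the current luminal and
#' plasma state (static optimization approach).
#'
#' @param step coupling step, h.
#' @param duration total simulated time, h; must be an integer multiple
#'   of `step`.
#' @param v_t shared luminal-carrier capacity per segment, mmol/gDW/h.
#' @param molecular_weight levodopa molecular weight, mg/mmol.
#' @param eps_lum luminal amino-acid threshold (mmol) below which the
#'   competitor set is treated as empty.
#' @param ka_aa first-order amino-acid absorption rate in the proximal
#'   jejunum (segments jejunum1/jejunum2 only), 1/h.
#' @param k_plasma_aa first-order return rate of the plasma amino-acid
#'   pool toward its fasting baseline, 1/h.
#' @param plasma_baseline named fasting plasma amino-acid amounts, mmol
#'   (all species).
#' @param bl_base basal basolateral amino-acid availability for the
#'   antiporter, mmol/gDW/h, added on top of the plasma-proportional
#'   term.
#' @param bl_per_mmol basolateral amino-acid availability per mmol of
#'   plasma amino acid, mmol/gDW/h per mmol; the plasma pool drives the
#'   exchangeable amino-acid supply of the basolateral antiporter
#'   (trans-stimulation).
#' @return object of class `coupling_config`.
#' @export
coupling_config <- function(step = 0.1, duration = 18, v_t = 15,
                            molecular_weight = LEVODOPA_MW,
                            eps_lum = 1e-6, ka_aa = 2,
                            k_plasma_aa = 0.3,
                            plasma_baseline =
                              stats::setNames(rep(1, length(AA_SPECIES)),
                                              AA_SPECIES),
                            bl_base = 0, bl_per_mmol = 0.2) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  nstep <- duration / step
  if (abs(nstep - round(nstep)) > 1e-9)
    stop("duration must be an integer number of steps", call. = FALSE)
  structure(list(step = step, duration = duration, v_t = v_t,
                 molecular_weight = molecular_weight, eps_lum = eps_lum,
                 ka_aa = ka_aa, k_plasma_aa = k_plasma_aa,
                 plasma_baseline = plasma_baseline, bl_base = bl_base,
                 bl_per_mmol = bl_per_mmol),
            class = "coupling_config")
}

#' Select the carrier interaction mode of a segment
#'
#' Competition mode applies whenever luminal amino acids are present
#' above `eps_lum`; trans-stimulation applies when the lumen is free of
#' amino acids but the plasma pool is elevated above its fasting
#' baseline; otherwise plain uptake is treated as competition with an
#' empty competitor set.
#'
#' @param segment segment exchange state: list with `lum_aa` (named
#'   mmol), `plasma_aa` (named mmol) and `baseline` (named mmol).
#' @param config a [coupling_config()].
#' @return `"competition"` or `"trans_stimulation"`.
#' @export
select_mode <- function(segment, config = coupling_config()) {
  lum <- sum(segment$lum_aa %||% 0)
  if (lum > config$eps_lum) return("competition")
  pl <- sum(segment$plasma_aa %||% 0)
  base <- sum(segment$baseline %||% config$plasma_baseline)
  if (pl > base * (1 + 1e-9)) return("trans_stimulation")
  "competition"
}

#' Derive per-reaction bounds for a segment's flux solve
#'
#' Converts the segment's luminal amounts into flux bounds on the
#' enterocyte model: the levodopa luminal exchange is limited by the
#' amount available over one step (`amount / (MW * gDW * step)`), the
#' shared-carrier allocation caps the summed luminal antiport flux at
#' levodopa's affinity share of `v_t`, luminal amino-acid exchanges are
#' limited by their own amounts, and basolateral amino-acid
#' availability scales with the plasma pool (the trans-stimulation
#' route).
#'
#' @param segment list with `lum_ld_mg` (levodopa, mg), `lum_aa` (named
#'   mmol), `plasma_aa` (named mmol), `gdw` (g dry weight).
#' @param step step length, h.
#' @param config a [coupling_config()].
#' @param catalog a [transporter_catalog()].
#' @param net the segment's `stoich_network` (levodopa module applied).
#' @return list with `bounds`, `couplings` and `share`, for [fba()].
#' @export
derive_bounds <- function(segment, step, config = coupling_config(),
                          catalog = transporter_catalog(), net) {
  if (segment$gdw <= 0) stop("segment dry weight must be positive",
                             call. = FALSE)
  mw <- config$molecular_weight
  gdw <- segment$gdw
  lum_mmol <- max(segment$lum_ld_mg, 0) / mw
  q_rate <- lum_mmol / (step * gdw)          # amount-limited, mmol/gDW/h
  comp <- apply_competition_bounds(net, segment$lum_aa %||% numeric(),
                                   lum_mmol, catalog, config$v_t)
  bounds <- list(EX_levodopa_l = c(-q_rate, 0))
  for (sp in AA_SPECIES) {
    ex <- paste0("EX_", sp, "_l")
    if (!ex %in% net$rxns$id) next
    amt <- segment$lum_aa[sp]
    amt <- if (is.na(amt) || is.null(amt)) 0 else amt
    bounds[[ex]] <- c(-max(amt, 0) / (step * gdw), 1000)
  }
  # trans-side availability limits the basolateral antiporter turnover:
  # the summed antiport flux is capped by the exchangeable plasma
  # amino-acid supply (capping only the blood-side exchanges would be
  # bypassed by cytosol-to-blood recycling of the co-substrate)
  blsub <- names(catalog$basolateral_antiporter)
  pl <- segment$plasma_aa[blsub]
  pl[is.na(pl)] <- 0
  avail <- config$bl_base + config$bl_per_mmol * sum(pmax(pl, 0))
  anti <- intersect(paste0("LDOPA_bl_anti_", blsub), net$rxns$id)
  cp_bl <- list(coef = stats::setNames(rep(1, length(anti)), anti),
                rhs = avail, sense = "le")
  list(bounds = bounds,
       couplings = c(comp$couplings, list(cp_bl)),
       share = comp$share)
}

#' Convert a flux solution to whole-body derivative terms
#'
#' Scales segment fluxes (mmol/gDW/h) to mass rates (mg/h) with the
#' segment dry weight and the levodopa molecular weight: the luminal
#' uptake rate debits the segment lumen and the basolateral secretion
#' rate credits the portal vein over the next coupling step.
#'
#' @param sol an optimal `flux_solution`.
#' @param gdw segment dry weight, g.
#' @param config a [coupling_config()].
#' @return list `uptake_mg_h`, `secretion_mg_h`.
#' @export
fluxes_to_derivatives <- function(sol, gdw, config = coupling_config()) {
  if (!inherits(sol, "flux_solution") || sol$status != "optimal")
    stop("flux solution is not optimal", call. = FALSE)
  mw <- config$molecular_weight
  uptake <- -sol$fluxes[["EX_levodopa_l"]]
  secretion <- sol$fluxes[["EX_levodopa_b"]]
  list(uptake_mg_h = uptake * gdw * mw,
       secretion_mg_h = secretion * gdw * mw)
}

# amino-acid side model: 9 luminal compartments + 1 plasma pool per
# species, first-order transit mirroring the drug chain; absorption
# confined to the proximal jejunum; plasma relaxes to baseline
aa_rhs <- function(t, y, parms) {
  nsp <- parms$nsp
  Y <- matrix(y, nrow = nsp)       # rows species, cols compartments
  D <- matrix(0, nsp, 10)
  ger <- parms$ger; kt <- parms$kt
  D[, 1] <- -ger * Y[, 1]
  infl <- ger * Y[, 1]
  for (i in 1:7) {
    abs_rate <- if (i %in% c(2, 3)) parms$ka_aa else 0
    D[, 1 + i] <- infl - kt * Y[, 1 + i] - abs_rate * Y[, 1 + i]
    infl <- kt * Y[, 1 + i]
  }
  D[, 9] <- infl - parms$kel * Y[, 9]
  absorbed <- parms$ka_aa * (Y[, 3] + Y[, 4])
  D[, 10] <- absorbed - parms$k_plasma_aa * (Y[, 10] - parms$baseline)
  list(as.numeric(D))
}

#' Run the coupled multiscale simulation
#'
#' The static-optimization-approach loop: the simulated time is divided
#' into `duration/step` steps; in each step the whole-body model is
#' integrated with the current per-segment uptake and secretion rates,
#' the segment states are read, the interaction mode is selected, flux
#' bounds are derived, one flux-balance problem is solved per segment
#' (objective: luminal uptake in competition mode, basolateral
#' secretion in trans-stimulation mode), and the resulting fluxes set
#' the rates of the next step.
#'
#' Dietary amino acids follow a parallel luminal transit chain with
#' absorption confined to the proximal jejunum and a single well-mixed
#' plasma pool that relaxes to the fasting baseline; these states are
#' additional to the 42 drug states. Segments whose lumen and
#' enterocyte are levodopa-free are resolved to zero flux without a
#' solver call.
#'
#' @param model a [build_wb_acat()] model.
#' @param networks list of 7 `stoich_network`s (one per segment), each
#'   with the levodopa module applied.
#' @param regimen a [dose_regimen()].
#' @param diet optional diet schedule: list with `meals` (data.frame
#'   `time`, `species`, `mmol`: luminal amino-acid loads),
#'   `plasma_init` (named mmol, initial plasma pool; defaults to the
#'   fasting baseline) and `plasma_events` (data.frame `time`,
#'   `species`, `mmol`: direct additions to the plasma pool).
#' @param config a [coupling_config()].
#' @param catalog a [transporter_catalog()].
#' @return object of class `coupled_run`: list with `tc` (the
#'   `time_course`), `flux_log` (data.frame: step, time, segment, mode,
#'   share, uptake and secretion in mg/h), `aa` (plasma and luminal
#'   amino-acid trajectories), `n_steps`.
#' @export
run_coupled <- function(model, networks, regimen, diet = NULL,
                        config = coupling_config(),
                        catalog = transporter_catalog()) {
  if (length(networks) != 7L)
    stop("exactly 7 segment networks are required", call. = FALSE)
  for (nw in networks)
    if (!"levodopa" %in% nw$modules)
      stop("all segment networks need the levodopa module", call. = FALSE)
  nstep <- round(config$duration / config$step)
  p <- model$physiology
  gdw <- p$segment_dry_weight

  baseline <- config$plasma_baseline
  meals <- diet$meals %||% data.frame(time = numeric(),
                                      species = character(),
                                      mmol = numeric())
  pl_events <- diet$plasma_events %||% data.frame(time = numeric(),
                                                  species = character(),
                                                  mmol = numeric())
  species <- sort(unique(c(meals$species, pl_events$species,
                           names(diet$plasma_init %||% c()))))
  unknown <- setdiff(species, AA_SPECIES)
  if (length(unknown))
    stop("unknown amino-acid species in diet: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  nsp <- length(species)
  aa_y <- matrix(0, nsp, 10,
                 dimnames = list(species, c("stomach", SI_SEGMENTS,
                                            "colon", "plasma")))
  aa_y[, "plasma"] <- baseline[species]
  if (!is.null(diet$plasma_init))
    aa_y[names(diet$plasma_init), "plasma"] <- diet$plasma_init
  plasma_full <- baseline
  aa_parms <- list(nsp = nsp, ger = p$ger, kt = p$si_transit_rate,
                   ka_aa = config$ka_aa, kel = model$kinetics$colon_elimination_rate,
                   k_plasma_aa = config$k_plasma_aa,
                   baseline = unname(baseline[species]))

  nm <- model$state_names
  y <- stats::setNames(numeric(length(nm)), nm)
  uptake <- numeric(7); secretion <- numeric(7)
  i_dis <- match(paste0(SI_SEGMENTS, "_dissolved"), nm)
  i_ent <- match(paste0("enterocyte_", SI_SEGMENTS), nm)

  tc_rows <- vector("list", nstep)
  log_rows <- vector("list", nstep)
  aa_rows <- vector("list", nstep)
  compiled <- wb_has_compiled()

  for (s in seq_len(nstep)) {
    t0 <- (s - 1) * config$step
    t1 <- s * config$step
    # events at the start of this step
    hit <- which(abs(regimen$times - t0) < 1e-9)
    if (length(hit)) y["stomach_solid"] <- y["stomach_solid"] +
        sum(regimen$amounts[hit])
    mhit <- which(abs(meals$time - t0) < 1e-9)
    for (i in mhit) aa_y[meals$species[i], "stomach"] <-
        aa_y[meals$species[i], "stomach"] + meals$mmol[i]
    phit <- which(abs(pl_events$time - t0) < 1e-9)
    for (i in phit) aa_y[pl_events$species[i], "plasma"] <-
        aa_y[pl_events$species[i], "plasma"] + pl_events$mmol[i]

    # per-segment flux solves
    if (nsp) plasma_full[species] <- aa_y[, "plasma"]
    seg_mode <- character(7); seg_share <- numeric(7)
    for (g in seq_len(7)) {
      lum_ld <- y[i_dis[g]]
      ent_ld <- y[i_ent[g]]
      lum_aa <- if (nsp) aa_y[, 1 + g] else
        stats::setNames(numeric(0), character(0))
      if (nsp) names(lum_aa) <- species
      seg <- list(lum_ld_mg = lum_ld, lum_aa = lum_aa,
                  plasma_aa = plasma_full, baseline = baseline,
                  gdw = gdw[g])
      mode <- select_mode(seg, config)
      seg_mode[g] <- mode
      if (lum_ld < 1e-9 && ent_ld < 1e-9) {
        uptake[g] <- 0; secretion[g] <- 0; seg_share[g] <- NA_real_
        next
      }
      db <- derive_bounds(seg, config$step, config, catalog,
                          networks[[g]])
      seg_share[g] <- db$share
      obj <- if (mode == "trans_stimulation") "EX_levodopa_b" else
        "EX_levodopa_l"
      sense <- if (mode == "trans_stimulation") "max" else "min"
      sol <- fba(networks[[g]], objective = obj, sense = sense,
                 extra_bounds = db$bounds,
                 extra_couplings = db$couplings,
                 minimize_total = FALSE)
      if (sol$status != "optimal")
        stop("segment LP ", sol$status, " at step ", s, ", segment ",
             SI_SEGMENTS[g], call. = FALSE)
      rr <- fluxes_to_derivatives(sol, gdw[g], config)
      uptake[g] <- rr$uptake_mg_h
      secretion[g] <- rr$secretion_mg_h
    }
    log_rows[[s]] <- data.frame(step = s, time = t0,
                                segment = SI_SEGMENTS, mode = seg_mode,
                                share = seg_share, uptake_mg_h = uptake,
                                secretion_mg_h = secretion)

    # integrate both scales over the step
    times <- c(t0, t1)
    if (compiled) {
      pv <- wb_parms_vector(p, model$kinetics, uptake, secretion)
      sol_ode <- deSolve::lsoda(y, times, func = "wb_acat_derivs",
                                parms = pv, dllname = "levogut",
                                initfunc = "wb_acat_init",
                                rtol = 1e-8, atol = 1e-10)
    } else {
      sol_ode <- deSolve::lsoda(y, times, function(t, yy, pp)
        list(model$rhs(t, yy, uptake, secretion)), parms = NULL,
        rtol = 1e-8, atol = 1e-10)
    }
    y <- sol_ode[nrow(sol_ode), -1]
    if (nsp) {
      sol_aa <- deSolve::lsoda(as.numeric(aa_y), times, aa_rhs,
                               parms = aa_parms, rtol = 1e-8,
                               atol = 1e-10)
      aa_y[] <- matrix(sol_aa[nrow(sol_aa), -1], nrow = nsp)
      aa_y[aa_y < 0] <- 0
    }
    tc_rows[[s]] <- c(time = t1, y)
    aa_rows[[s]] <- c(time = t1, as.numeric(aa_y))
  }

  tc <- as.data.frame(do.call(rbind, tc_rows))
  names(tc) <- c("time", nm)
  tc$plasma_conc <- tc$venous / model$kinetics$organ_volumes[["venous"]]
  class(tc) <- c("time_course", "data.frame")
  aa <- if (nsp) {
    a <- as.data.frame(do.call(rbind, aa_rows))
    names(a) <- c("time", as.vector(outer(species,
                                          colnames(aa_y), paste,
                                          sep = ".")))
    a
  } else NULL
  structure(list(tc = tc, flux_log = do.call(rbind, log_rows), aa = aa,
                 n_steps = nstep), class = "coupled_run")
}
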
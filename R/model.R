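wb_state_names <- function() {
  c(as.vector(t(outer(LUMINAL_COMPARTMENTS, c("solid", "dissolved"),
                      paste, sep = "_"))),
    paste0("enterocyte_", SI_SEGMENTS),
    "venous", "arterial", "portal", "lung", "heart", "brain", "muscle",
    "adipose", "skin", "bone", "kidney", "liver", "spleen", "pancreas",
    "rest_of_body", "urine_cum", "degraded_cum")
}

#' Oral dose regimen
#'
#' @param times dosing times, h; nonnegative, strictly increasing.
#' @param amounts dose amounts, mg; positive. Recycled to the length of
#'   `times` if scalar.
#' @param horizon simulation horizon the regimen is intended for, h.
#' @return object of class `dose_regimen`.
#' @export
dose_regimen <- function(times, amounts, horizon = 18) {
  amounts <- rep_len(amounts, length(times))
  if (length(times) && (any(times < 0) || is.unsorted(times,
                                                      strictly = TRUE)))
    stop("dose times must be nonnegative and strictly increasing",
         call. = FALSE)
  if (any(amounts <= 0))
    stop("dose amounts must be positive", call. = FALSE)
  if (horizon <= 0) stop("horizon must be positive", call. = FALSE)
  structure(list(times = as.numeric(times), amounts = as.numeric(amounts),
                 horizon = horizon), class = "dose_regimen")
}

#' Build the whole-body oral-absorption model
#'
#' Assembles the 42-state whole-body model: nine luminal compartments
#' (stomach, seven small-intestinal segments, colon), each with a solid
#' and a dissolved drug state; seven enterocyte amounts (one per
#' small-intestinal segment; none for stomach or colon, where no
#' absorption takes place); and seventeen systemic states (venous,
#' arterial, portal blood, lung, eleven perfused organs, cumulative
#' urine and a cumulative degraded + fecal sink).
#'
#' Absorption runs either uncoupled (first-order `ka_fallback` per
#' segment, identical across segments) or with externally supplied
#' per-segment uptake and secretion rates, as produced each step by the
#' enterocyte flux-balance coupling ([run_coupled()]).
#'
#' @param physiology a [physiology_parameters()] object.
#' @param kinetics a [kinetic_parameters()] object.
#' @return object of class `wb_acat_model` with elements `state_names`
#'   (42 labels), `rhs` (derivative function), `physiology`, `kinetics`.
#' @export
build_wb_acat <- function(physiology, kinetics) {
  validate_physiology(physiology)
  validate_kinetics(kinetics)
  nm <- wb_state_names()
  idx <- as.list(stats::setNames(seq_along(nm), nm))
  model <- list(state_names = nm, index = idx, physiology = physiology,
                kinetics = kinetics)
  model$rhs <- wb_rhs_compiled(physiology, kinetics)
  class(model) <- "wb_acat_model"
  model
}

# Precompiles state indices and parameter constants into a closure so the
# derivative evaluation involves no name lookups; lsoda calls it many
# thousand times per run.
wb_rhs_compiled <- function(p, k) {
  nm <- wb_state_names()
  ix <- function(x) match(x, nm)
  i_ssol <- ix("stomach_solid"); i_sdis <- ix("stomach_dissolved")
  i_sol <- ix(paste0(SI_SEGMENTS, "_solid"))
  i_dis <- ix(paste0(SI_SEGMENTS, "_dissolved"))
  i_ent <- ix(paste0("enterocyte_", SI_SEGMENTS))
  i_csol <- ix("colon_solid"); i_cdis <- ix("colon_dissolved")
  plain <- c("heart", "brain", "muscle", "adipose", "skin", "bone",
             "rest_of_body")
  i_plain <- ix(plain)
  i_ven <- ix("venous"); i_art <- ix("arterial"); i_por <- ix("portal")
  i_lun <- ix("lung"); i_kid <- ix("kidney"); i_liv <- ix("liver")
  i_spl <- ix("spleen"); i_pan <- ix("pancreas")
  i_ur <- ix("urine_cum"); i_dg <- ix("degraded_cum")

  q <- k$organ_blood_flows; v <- k$organ_volumes
  kp <- k$partition_coefficients
  q_plain <- unname(q[plain])
  vk_plain <- unname(v[plain] * kp[plain])
  q_kid <- q[["kidney"]]; vk_kid <- v[["kidney"]] * kp[["kidney"]]
  q_spl <- q[["spleen"]]; vk_spl <- v[["spleen"]] * kp[["spleen"]]
  q_pan <- q[["pancreas"]]; vk_pan <- v[["pancreas"]] * kp[["pancreas"]]
  q_gut <- q[["gut"]]; q_ha <- q[["hepatic_artery"]]
  vk_liv <- v[["liver"]] * kp[["liver"]]
  vk_lun <- v[["lung"]] * kp[["lung"]]
  q_lun <- q[["lung"]]
  qpv <- q_gut + q_spl + q_pan
  qliv <- q_ha + qpv
  q_art_off <- sum(q_plain) + q_kid + q_ha + q_gut + q_spl + q_pan
  v_ven <- v[["venous"]]; v_art <- v[["arterial"]]; v_por <- v[["portal"]]
  csat_si <- solubility_at_ph(p$si_ph_profile, k)
  csat_st <- solubility_at_ph(p$gastric_ph, k)
  csat_co <- solubility_at_ph(p$colon_ph, k)
  kd <- k$dissolution_coefficient
  kt <- p$si_transit_rate
  vol_si <- p$segment_volumes
  n42 <- length(nm)

  function(t, s, uptake = NULL, secretion = NULL) {
    d <- numeric(n42)
    ss <- s[i_ssol]; sd <- s[i_sdis]
    jst <- max(0, kd * max(ss, 0)^(2 / 3) *
                 (csat_st - max(sd, 0) / p$stomach_volume))
    d[i_ssol] <- -p$ger * ss - jst
    d[i_sdis] <- jst - p$ger * sd - k$k_deg_stomach * sd
    deg <- k$k_deg_stomach * sd

    sol <- s[i_sol]; dis <- s[i_dis]; ent <- s[i_ent]
    jd <- pmax(0, kd * pmax(sol, 0)^(2 / 3) *
                 (csat_si - pmax(dis, 0) / vol_si))
    up <- if (is.null(uptake)) k$ka_fallback * dis else
      uptake * soft_gate(dis)
    sec <- if (is.null(secretion)) k$k_secretion * ent else
      secretion * soft_gate(ent)
    in_sol <- c(p$ger * ss, kt * sol[-7])
    in_dis <- c(p$ger * sd, kt * dis[-7])
    d[i_sol] <- in_sol - kt * sol - jd
    d[i_dis] <- in_dis + jd - kt * dis - k$k_deg_lumen * dis - up
    d[i_ent] <- up - sec
    deg <- deg + k$k_deg_lumen * sum(dis)
    sec_total <- sum(sec)

    csol <- s[i_csol]; cdis <- s[i_cdis]
    jc <- max(0, kd * max(csol, 0)^(2 / 3) *
                (csat_co - max(cdis, 0) / p$colon_volume))
    kel <- k$colon_elimination_rate
    d[i_csol] <- kt * sol[7] - jc - kel * csol
    d[i_cdis] <- kt * dis[7] + jc - kel * cdis - k$k_deg_lumen * cdis
    deg <- deg + k$k_deg_lumen * cdis
    fecal <- kel * (csol + cdis)

    cart <- s[i_art] / v_art
    cven <- s[i_ven] / v_ven
    cpor <- s[i_por] / v_por
    co_plain <- s[i_plain] / vk_plain
    d[i_plain] <- q_plain * (cart - co_plain)
    ven_in <- sum(q_plain * co_plain)
    ck <- s[i_kid] / vk_kid
    d[i_kid] <- q_kid * (cart - ck) - k$renal_clearance * ck
    ven_in <- ven_in + q_kid * ck
    csp <- s[i_spl] / vk_spl; cpa <- s[i_pan] / vk_pan
    d[i_spl] <- q_spl * (cart - csp)
    d[i_pan] <- q_pan * (cart - cpa)
    d[i_por] <- q_gut * cart + q_spl * csp + q_pan * cpa + sec_total -
      qpv * cpor
    cli <- s[i_liv] / vk_liv
    d[i_liv] <- q_ha * cart + qpv * cpor - qliv * cli -
      k$hepatic_clearance * cli
    ven_in <- ven_in + qliv * cli
    clung <- s[i_lun] / vk_lun
    d[i_lun] <- q_lun * (cven - clung)
    d[i_ven] <- ven_in - q_lun * cven
    d[i_art] <- q_lun * clung - q_art_off * cart
    d[i_ur] <- k$renal_clearance * ck
    d[i_dg] <- deg + fecal + k$hepatic_clearance * cli
    d
  }
}

# Smooth positivity guard: scales an outgoing rate down as the source
# state approaches zero, so externally imposed (zero-order) rates cannot
# drive a state negative.
soft_gate <- function(amount, eps = 1e-6) {
  a <- pmax(amount, 0)
  a / (a + eps)
}

# Flattens physiology + kinetics (+ per-segment rates) into the numeric
# parameter vector consumed by the compiled derivative (src/wbacat.c);
# layout documented there.
wb_parms_vector <- function(p, k, uptake = NULL, secretion = NULL) {
  plain <- c("heart", "brain", "muscle", "adipose", "skin", "bone",
             "rest_of_body")
  q <- k$organ_blood_flows; v <- k$organ_volumes
  kp <- k$partition_coefficients
  qpv <- q[["gut"]] + q[["spleen"]] + q[["pancreas"]]
  use_rates <- !is.null(uptake)
  if (use_rates && is.null(secretion)) secretion <- numeric(7)
  c(p$ger, p$stomach_volume, solubility_at_ph(p$gastric_ph, k),
    k$k_deg_stomach, p$si_transit_rate, k$dissolution_coefficient,
    k$k_deg_lumen, k$ka_fallback, k$k_secretion,
    k$colon_elimination_rate, p$colon_volume,
    solubility_at_ph(p$colon_ph, k), k$hepatic_clearance,
    k$renal_clearance,
    p$segment_volumes, solubility_at_ph(p$si_ph_profile, k),
    as.numeric(use_rates),
    if (use_rates) uptake else numeric(7),
    if (use_rates) secretion else numeric(7),
    unname(q[plain]), unname(v[plain] * kp[plain]),
    q[["kidney"]], v[["kidney"]] * kp[["kidney"]],
    q[["spleen"]], v[["spleen"]] * kp[["spleen"]],
    q[["pancreas"]], v[["pancreas"]] * kp[["pancreas"]],
    q[["gut"]], q[["hepatic_artery"]],
    v[["liver"]] * kp[["liver"]], v[["lung"]] * kp[["lung"]],
    q[["lung"]], qpv, q[["hepatic_artery"]] + qpv,
    sum(q[plain]) + q[["kidney"]] + q[["hepatic_artery"]] + qpv,
    v[["venous"]], v[["arterial"]], v[["portal"]])
}

wb_has_compiled <- function() {
  is.loaded("wb_acat_derivs", PACKAGE = "levogut")
}

#' Simulate the whole-body model
#'
#' Integrates the 42-state system with a stiff-capable adaptive solver
#' (`deSolve::lsoda`, relative tolerance 1e-8, absolute tolerance
#' 1e-10). Dose events are applied as discontinuous additions to the
#' stomach solid state with a stop-and-restart of the integrator.
#'
#' @param model a [build_wb_acat()] model.
#' @param regimen a [dose_regimen()].
#' @param duration simulated time, h.
#' @param dt_out output grid spacing, h.
#' @param uptake,secretion optional per-segment rates, mg/h (length 7),
#'   held constant over the run; used by the coupling loop, which calls
#'   this stepwise.
#' @param init optional initial state (named, length 42).
#' @return a `time_course` object: data.frame of times, the 42 state
#'   trajectories, and derived plasma concentration `plasma_conc`
#'   (venous amount / venous volume, mg/l).
#' @export
simulate_wb <- function(model, regimen, duration, dt_out = 0.05,
                        uptake = NULL, secretion = NULL, init = NULL) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  nm <- model$state_names
  y <- stats::setNames(numeric(length(nm)), nm)
  if (!is.null(init)) {
    stopifnot(length(init) == length(nm))
    y[] <- init
  }
  ev_times <- regimen$times[regimen$times <= duration + 1e-12]
  ev_amts <- regimen$amounts[regimen$times <= duration + 1e-12]
  breaks <- sort(unique(c(0, ev_times, duration)))
  out_list <- list()
  compiled <- wb_has_compiled()
  if (compiled) {
    pv <- wb_parms_vector(model$physiology, model$kinetics, uptake,
                          secretion)
  } else {
    func <- function(t, y, parms) {
      list(model$rhs(t, y, uptake, secretion))
    }
  }
  for (b in seq_len(length(breaks) - 1)) {
    t0 <- breaks[b]; t1 <- breaks[b + 1]
    hit <- which(abs(ev_times - t0) < 1e-12)
    if (length(hit)) y["stomach_solid"] <- y["stomach_solid"] +
        sum(ev_amts[hit])
    times <- unique(c(seq(t0, t1, by = dt_out), t1))
    sol <- if (compiled) {
      deSolve::lsoda(y, times, func = "wb_acat_derivs", parms = pv,
                     dllname = "levogut", initfunc = "wb_acat_init",
                     rtol = 1e-8, atol = 1e-10)
    } else {
      deSolve::lsoda(y, times, func, parms = NULL,
                     rtol = 1e-8, atol = 1e-10)
    }
    if (attr(sol, "istate")[1] < 0)
      stop("integrator failure; last valid time ",
           max(sol[, 1][stats::complete.cases(sol)]), call. = FALSE)
    y <- sol[nrow(sol), -1]
    out_list[[b]] <- sol[if (b > 1) -1 else TRUE, , drop = FALSE]
  }
  out <- do.call(rbind, out_list)
  tc <- as.data.frame(out)
  names(tc) <- c("time", nm)
  tc$plasma_conc <- tc$venous / model$kinetics$organ_volumes[["venous"]]
  class(tc) <- c("time_course", "data.frame")
  tc
}

#' Total drug accounting of a trajectory
#'
#' Sum over all drug-containing states plus the cumulative urine and
#' degraded + fecal sinks at each output time; between and after dose
#' events this quantity is conserved.
#'
#' @param tc a `time_course` from [simulate_wb()].
#' @return numeric vector, mg.
#' @export
total_drug <- function(tc) {
  rowSums(tc[, wb_state_names(), drop = FALSE])
}
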
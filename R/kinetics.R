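#' Drug-specific kinetic parameters
#'
#' Rate, clearance, partition and dissolution parameters of the
#' whole-body disposition model. The defaults are a physiologically
#' plausible levodopa-like parameterization (benserazide
#' co-administration is absorbed into the peripheral clearances rather
#' than modeled explicitly); fitted values are normally supplied through
#' the configuration layer or [fit_model()].
#'
#' @param organ_blood_flows named vector, l/h. Must contain every organ
#'   in `PBPK_ORGANS` plus `gut` (mesenteric flow feeding the portal
#'   vein), `hepatic_artery` and `lung` (total pulmonary = cardiac
#'   output). The liver is perfused by hepatic artery + portal vein;
#'   `organ_blood_flows["liver"]` is therefore derived and must equal
#'   hepatic_artery + gut + spleen + pancreas.
#' @param organ_volumes named vector, l; organs plus `venous`,
#'   `arterial`, `portal`, `lung`.
#' @param partition_coefficients named vector, tissue:plasma, for all
#'   perfused organs and `lung`.
#' @param hepatic_clearance intrinsic hepatic elimination, l/h.
#' @param renal_clearance renal elimination from the kidney compartment
#'   into cumulative urine, l/h.
#' @param k_deg_stomach first-order degradation of dissolved drug in the
#'   stomach, 1/h.
#' @param k_deg_lumen first-order luminal degradation in intestine and
#'   colon (enzymatic + microbial + chemical, lumped), 1/h.
#' @param dissolution_coefficient Noyes-Whitney coefficient `kd`,
#'   ml^(1)/(mg^(2/3) h) scale: flux mg/h = kd * m_solid^(2/3) *
#'   (Csat(pH) - C) with concentrations in mg/ml.
#' @param solubility_by_ph two-column matrix (pH, mg/ml) defining a
#'   piecewise-linear saturation solubility profile.
#' @param ka_fallback first-order absorption rate per small-intestinal
#'   segment, 1/h; used only when the model runs uncoupled from the
#'   enterocyte networks.
#' @param k_secretion first-order enterocyte-to-portal secretion rate,
#'   1/h (uncoupled mode).
#' @param colon_elimination_rate first-order fecal elimination from the
#'   colon, 1/h.
#' @return object of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(
    organ_blood_flows = c(heart = 15, brain = 46, muscle = 66,
                          adipose = 19, skin = 23, bone = 19, kidney = 74,
                          spleen = 11, pancreas = 6, rest_of_body = 50,
                          gut = 38, hepatic_artery = 23, liver = 78,
                          lung = 390),
    organ_volumes = c(heart = 0.33, brain = 1.45, muscle = 29,
                      adipose = 14.5, skin = 3.4, bone = 10,
                      kidney = 0.31, liver = 1.8, spleen = 0.18,
                      pancreas = 0.1, rest_of_body = 4.0, lung = 0.5,
                      venous = 3.4, arterial = 1.8, portal = 0.25),
    partition_coefficients = c(heart = 0.7, brain = 0.3, muscle = 0.7,
                               adipose = 0.15, skin = 0.6, bone = 0.4,
                               kidney = 1.6, liver = 1.2, spleen = 0.8,
                               pancreas = 0.8, rest_of_body = 0.7,
                               lung = 0.6),
    hepatic_clearance = 15,
    renal_clearance = 5,
    k_deg_stomach = 0.3,
    k_deg_lumen = 0.5,
    dissolution_coefficient = 2,
    solubility_by_ph = cbind(ph = c(1, 2, 5, 7.4, 9),
                             csat = c(20, 12, 5, 3.3, 3.3)),
    ka_fallback = 3,
    k_secretion = 20,
    colon_elimination_rate = 0.2) {
  k <- list(organ_blood_flows = organ_blood_flows,
            organ_volumes = organ_volumes,
            partition_coefficients = partition_coefficients,
            hepatic_clearance = hepatic_clearance,
            renal_clearance = renal_clearance,
            k_deg_stomach = k_deg_stomach,
            k_deg_lumen = k_deg_lumen,
            dissolution_coefficient = dissolution_coefficient,
            solubility_by_ph = solubility_by_ph,
            ka_fallback = ka_fallback,
            k_secretion = k_secretion,
            colon_elimination_rate = colon_elimination_rate)
  class(k) <- "kinetic_parameters"
  validate_kinetics(k)
  k
}

validate_kinetics <- function(k) {
  need_flow <- c(PBPK_ORGANS[PBPK_ORGANS != "liver"], "gut",
                 "hepatic_artery", "liver", "lung")
  if (!all(need_flow %in% names(k$organ_blood_flows)))
    stop("kinetics field 'organ_blood_flows' is missing: ",
         paste(setdiff(need_flow, names(k$organ_blood_flows)),
               collapse = ", "), call. = FALSE)
  need_vol <- c(PBPK_ORGANS, "lung", "venous", "arterial", "portal")
  if (!all(need_vol %in% names(k$organ_volumes)))
    stop("kinetics field 'organ_volumes' is missing: ",
         paste(setdiff(need_vol, names(k$organ_volumes)), collapse = ", "),
         call. = FALSE)
  need_kp <- c(PBPK_ORGANS, "lung")
  if (!all(need_kp %in% names(k$partition_coefficients)))
    stop("kinetics field 'partition_coefficients' is missing: ",
         paste(setdiff(need_kp, names(k$partition_coefficients)),
               collapse = ", "), call. = FALSE)
  scalars <- c("hepatic_clearance", "renal_clearance", "k_deg_stomach",
               "k_deg_lumen", "dissolution_coefficient", "ka_fallback",
               "k_secretion", "colon_elimination_rate")
  for (f in scalars) {
    v <- k[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("kinetics field '", f, "' must be a single nonnegative number",
           call. = FALSE)
  }
  if (any(k$organ_blood_flows < 0) || any(k$organ_volumes <= 0))
    stop("kinetics field 'organ_blood_flows'/'organ_volumes' must be ",
         "nonnegative/positive", call. = FALSE)
  if (any(k$partition_coefficients <= 0))
    stop("kinetics field 'partition_coefficients' must be strictly ",
         "positive", call. = FALSE)
  q <- k$organ_blood_flows
  qliv <- q[["hepatic_artery"]] + q[["gut"]] + q[["spleen"]] +
    q[["pancreas"]]
  if (abs(q[["liver"]] - qliv) > 1e-6 * max(1, qliv))
    stop("kinetics field 'organ_blood_flows': liver flow must equal ",
         "hepatic_artery + gut + spleen + pancreas (flow conservation)",
         call. = FALSE)
  venous_return <- sum(q[c("heart", "brain", "muscle", "adipose", "skin",
                           "bone", "kidney", "rest_of_body")]) + qliv
  if (abs(q[["lung"]] - venous_return) > 1e-6 * max(1, venous_return))
    stop("kinetics field 'organ_blood_flows': lung (cardiac output) flow ",
         "must equal the venous return (flow conservation)",
         call. = FALSE)
  sp <- k$solubility_by_ph
  if (!is.matrix(sp) || ncol(sp) != 2L || nrow(sp) < 2L ||
      any(!is.finite(sp)) || any(sp[, 2] <= 0) || is.unsorted(sp[, 1]))
    stop("kinetics field 'solubility_by_ph' must be a two-column ",
         "(pH, mg/ml) matrix with increasing pH and positive solubility",
         call. = FALSE)
  invisible(k)
}

#' Saturation solubility at a given pH
#'
#' Piecewise-linear interpolation of the configured solubility profile;
#' constant extrapolation outside the tabulated pH range.
#'
#' @param ph pH value(s).
#' @param kinetics a [kinetic_parameters()] object.
#' @return solubility, mg/ml.
#' @export
solubility_at_ph <- function(ph, kinetics) {
  sp <- kinetics$solubility_by_ph
  stats::approx(sp[, 1], sp[, 2], xout = ph, rule = 2)$y
}

#' Noyes-Whitney dissolution rate
#'
#' Surface-area-scaled dissolution of the remaining solid:
#' `kd * m^(2/3) * (Csat(pH) - C)`, floored at zero (no
#' re-precipitation is modeled).
#'
#' @param solid_mass undissolved drug mass, mg.
#' @param dissolved_conc local dissolved concentration, mg/ml.
#' @param ph luminal pH of the compartment.
#' @param volume luminal fluid volume, ml (unused directly; the caller
#'   computes `dissolved_conc` from it, it is accepted for interface
#'   completeness and validated).
#' @param kinetics a [kinetic_parameters()] object.
#' @return dissolution flux, mg/h.
#' @export
dissolution_flux <- function(solid_mass, dissolved_conc, ph, volume,
                             kinetics) {
  if (any(solid_mass < 0) || any(volume < 0) || any(dissolved_conc < 0))
    stop("dissolution_flux: negative input", call. = FALSE)
  csat <- solubility_at_ph(ph, kinetics)
  pmax(0, kinetics$dissolution_coefficient * solid_mass^(2 / 3) *
         (csat - dissolved_conc))
}
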
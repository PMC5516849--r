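#' Gastrointestinal and whole-body physiology parameters
#'
#' Constructs the physiological parameter set of the oral-absorption
#' (compartmental transit) part of the model: gastric emptying,
#' intestinal transit, luminal volumes and pH, and the mucosal dry
#' weights that normalize enterocyte fluxes. Defaults are the fasted
#' state; [set_prandial_state()] switches the five food-sensitive
#' parameters between fasted and fed values.
#'
#' @param ger gastric-emptying rate, 1/h (first-order stomach-to-duodenum).
#' @param stomach_volume gastric fluid volume, ml.
#' @param colon_volume colonic fluid volume, ml.
#' @param si_transit_rate per-segment small-intestinal transit rate, 1/h.
#'   Interpreted as the first-order rate of each of the seven segments.
#' @param gastric_ph gastric pH.
#' @param si_ph_profile luminal pH of the seven small-intestinal segments
#'   (duodenum to terminal ileum).
#' @param colon_ph colonic luminal pH.
#' @param segment_volumes luminal fluid volume of each small-intestinal
#'   segment, ml.
#' @param segment_dry_weight mucosal dry weight of each small-intestinal
#'   segment, g; normalization basis of the enterocyte fluxes
#'   (mmol/gDW/h).
#' @param body_weight body weight, kg.
#' @return object of class `physiology_parameters` (a validated list).
#' @export
physiology_parameters <- function(ger = 3.96,
                                  stomach_volume = 50,
                                  colon_volume = 1000,
                                  si_transit_rate = 2.1,
                                  gastric_ph = 2,
                                  si_ph_profile = c(6.0, 6.2, 6.4,
                                                    6.6, 6.8, 7.0, 7.2),
                                  colon_ph = 6.8,
                                  segment_volumes = c(40, 80, 80,
                                                      60, 60, 60, 60),
                                  segment_dry_weight = rep(0.05, 7),
                                  body_weight = 70) {
  p <- list(ger = ger, stomach_volume = stomach_volume,
            colon_volume = colon_volume, si_transit_rate = si_transit_rate,
            gastric_ph = gastric_ph, si_ph_profile = si_ph_profile,
            colon_ph = colon_ph, segment_volumes = segment_volumes,
            segment_dry_weight = segment_dry_weight,
            body_weight = body_weight)
  class(p) <- "physiology_parameters"
  validate_physiology(p)
  p
}

validate_physiology <- function(p) {
  scalar_pos <- c("ger", "stomach_volume", "colon_volume",
                  "si_transit_rate", "body_weight")
  for (f in scalar_pos) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("physiology field '", f, "' must be a single positive number",
           call. = FALSE)
  }
  for (f in c("gastric_ph", "colon_ph")) {
    if (any(p[[f]] < 1 | p[[f]] > 9))
      stop("physiology field '", f, "' must lie in [1, 9]", call. = FALSE)
  }
  for (f in c("si_ph_profile", "segment_volumes", "segment_dry_weight")) {
    if (length(p[[f]]) != 7L)
      stop("physiology field '", f, "' must have exactly 7 entries ",
           "(one per small-intestinal segment)", call. = FALSE)
  }
  if (any(p$si_ph_profile < 1 | p$si_ph_profile > 9))
    stop("physiology field 'si_ph_profile' must lie in [1, 9]",
         call. = FALSE)
  if (any(p$segment_volumes <= 0))
    stop("physiology field 'segment_volumes' must be strictly positive",
         call. = FALSE)
  if (any(p$segment_dry_weight <= 0))
    stop("physiology field 'segment_dry_weight' must be strictly positive",
         call. = FALSE)
  invisible(p)
}

# Fed vs fasted values of the five food-sensitive parameters.
PRANDIAL_TABLE <- list(
  fasted = list(ger = 3.96, stomach_volume = 50, colon_volume = 1000,
                si_transit_rate = 2.1, gastric_ph = 2),
  fed = list(ger = 0.33, stomach_volume = 1000, colon_volume = 7000,
             si_transit_rate = 0.57, gastric_ph = 5)
)

#' Switch physiology between fasted and fed state
#'
#' Sets the five prandial-state-dependent parameters (gastric-emptying
#' rate, stomach volume, colon volume, small-intestinal transit rate and
#' gastric pH) to their fasted or fed values; all other fields are left
#' untouched.
#'
#' @param physiology a [physiology_parameters()] object.
#' @param state `"fasted"` or `"fed"`.
#' @return modified copy of `physiology`.
#' @export
set_prandial_state <- function(physiology, state = c("fasted", "fed")) {
  if (!inherits(physiology, "physiology_parameters"))
    stop("'physiology' must be a physiology_parameters object",
         call. = FALSE)
  if (length(state) != 1L || !state %in% names(PRANDIAL_TABLE))
    stop("unknown prandial state; use \"fasted\" or \"fed\"",
         call. = FALSE)
  tab <- PRANDIAL_TABLE[[state]]
  physiology[names(tab)] <- tab
  validate_physiology(physiology)
  physiology
}
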
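#' Default configuration tree
#'
#' Full configuration with prandial-state physiology (fasted and fed
#' columns pre-filled), kinetics, dose regimen, solver, coupling and
#' efficacy-threshold sections. [load_config()] validates user files
#' against this tree and injects defaults for omitted keys.
#'
#' @return nested list.
#' @export
default_config <- function() {
  phys_f <- unclass(physiology_parameters())
  phys_fed <- unclass(set_prandial_state(physiology_parameters(), "fed"))
  kin <- unclass(kinetic_parameters())
  kin$organ_blood_flows <- as.list(kin$organ_blood_flows)
  kin$organ_volumes <- as.list(kin$organ_volumes)
  kin$partition_coefficients <- as.list(kin$partition_coefficients)
  kin$solubility_by_ph <- list(ph = unname(kin$solubility_by_ph[, 1]),
                               csat = unname(kin$solubility_by_ph[, 2]))
  cc <- unclass(coupling_config())
  cc$plasma_baseline <- as.list(cc$plasma_baseline)
  list(
    physiology = list(fasted = phys_f, fed = phys_fed),
    kinetics = kin,
    regimen = list(times = c(0, 6, 12), amounts = 100, horizon = 18),
    solver = list(rtol = 1e-8, atol = 1e-10, dt_out = 0.05),
    coupling = cc,
    thresholds = list(HY1 = 0.5, HY2 = 0.9, HY3 = 1.4, HY4 = 2.0),
    scenario = list(protein_g_per_kg = 0.8, prd_multiplier = 3,
                    serine_g = 5)
  )
}

check_unknown_keys <- function(user, ref, path = "") {
  if (!is.list(user) || !is.list(ref) || is.null(names(user)))
    return(invisible())
  extra <- setdiff(names(user), names(ref))
  if (length(extra))
    stop("unknown configuration key", if (length(extra) > 1) "s",
         ": ", paste0(path, extra, collapse = ", "), call. = FALSE)
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(ref[[nm]]) &&
        !is.null(names(ref[[nm]])) &&
        !nm %in% c("plasma_baseline", "organ_blood_flows",
                   "organ_volumes", "partition_coefficients"))
      check_unknown_keys(user[[nm]], ref[[nm]],
                         paste0(path, nm, "."))
  }
  invisible()
}

#' Load and validate a configuration file
#'
#' Reads YAML (or JSON, which YAML subsumes), rejects unknown keys
#' with a path-qualified message, and merges the defaults for any key
#' left out, so an empty file yields the full default tree.
#'
#' @param path file path, or `NULL` for the pure defaults.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL) {
  ref <- default_config()
  if (is.null(path)) return(ref)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  check_unknown_keys(user, ref)
  utils::modifyList(ref, user)
}

#' Materialize parameter objects from a configuration
#'
#' @param config a configuration list from [load_config()].
#' @param prandial `"fasted"` or `"fed"`.
#' @return list with `physiology`, `kinetics`, `regimen`, `coupling`,
#'   `thresholds`.
#' @export
config_objects <- function(config, prandial = "fasted") {
  ph <- config$physiology[[prandial]]
  if (is.null(ph)) stop("unknown prandial state: ", prandial,
                        call. = FALSE)
  physiology <- do.call(physiology_parameters,
                        ph[names(ph) %in%
                             names(formals(physiology_parameters))])
  kin <- config$kinetics
  kinetics <- kinetic_parameters(
    organ_blood_flows = unlist(kin$organ_blood_flows),
    organ_volumes = unlist(kin$organ_volumes),
    partition_coefficients = unlist(kin$partition_coefficients),
    hepatic_clearance = kin$hepatic_clearance,
    renal_clearance = kin$renal_clearance,
    k_deg_stomach = kin$k_deg_stomach,
    k_deg_lumen = kin$k_deg_lumen,
    dissolution_coefficient = kin$dissolution_coefficient,
    solubility_by_ph = cbind(ph = unlist(kin$solubility_by_ph$ph),
                             csat = unlist(kin$solubility_by_ph$csat)),
    ka_fallback = kin$ka_fallback,
    k_secretion = kin$k_secretion,
    colon_elimination_rate = kin$colon_elimination_rate)
  regimen <- dose_regimen(unlist(config$regimen$times),
                          unlist(config$regimen$amounts),
                          config$regimen$horizon)
  cc <- config$coupling
  coupling <- coupling_config(
    step = cc$step, duration = cc$duration, v_t = cc$v_t,
    molecular_weight = cc$molecular_weight, eps_lum = cc$eps_lum,
    ka_aa = cc$ka_aa, k_plasma_aa = cc$k_plasma_aa,
    plasma_baseline = unlist(cc$plasma_baseline),
    bl_base = cc$bl_base, bl_per_mmol = cc$bl_per_mmol)
  list(physiology = physiology, kinetics = kinetics, regimen = regimen,
       coupling = coupling,
       thresholds = hy_thresholds(unlist(config$thresholds)))
}

#' Tidy export of a time course
#'
#' @param tc a `time_course`.
#' @return data.frame in long form (`time`, `state`, `value`).
#' @export
tidy_time_course <- function(tc) {
  states <- setdiff(names(tc), "time")
  data.frame(
    time = rep(tc$time, length(states)),
    state = rep(states, each = nrow(tc)),
    value = unlist(tc[states], use.names = FALSE))
}
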
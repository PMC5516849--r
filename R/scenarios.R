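#' Efficacy thresholds by disease stage
#'
#' Plasma efficacy threshold per Hoehn and Yahr stage: the more
#' advanced the stage, the higher the levodopa concentration required
#' for symptom control. The numeric values are configuration inputs
#' with documented placeholder defaults; all threshold-relative results
#' are reported per stage so conclusions are auditable under
#' user-supplied values.
#'
#' @param thresholds named increasing vector, mg/l.
#' @return object of class `hy_thresholds`.
#' @export
hy_thresholds <- function(thresholds = c(HY1 = 0.5, HY2 = 0.9,
                                         HY3 = 1.4, HY4 = 2.0)) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must increase strictly with stage", call. = FALSE)
  structure(as.list(thresholds), class = "hy_thresholds")
}

equimolar_meal <- function(total_g, species = AA_SPECIES) {
  per_g <- total_g / length(species)
  stats::setNames(1000 * per_g / AA_MW[species], species)
}

#' Build a named diet scenario
#'
#' Encodes the standard dietary experiments:
#' \describe{
#'   \item{ac}{ante cibum reference: 100 mg every 6 h, fasted
#'     physiology, no amino acids.}
#'   \item{fed_aproteic}{same dosing with fed physiology, protein-free
#'     meal.}
#'   \item{fed_proteic}{fed physiology plus an amino-acid load at each
#'     dose time.}
#'   \item{lpd}{low-protein diet: 200 mg t.i.d. every 6 h with
#'     0.8 g/kg body weight of amino acids per meal; the dose precedes
#'     the meal, so fasted physiology applies.}
#'   \item{prd}{protein redistribution: daily protein moved to the
#'     last (evening) meal, so the simulated day has no luminal amino
#'     acids but an elevated plasma amino-acid pool at the first dose.}
#'   \item{serine_rich}{ante cibum dosing with serine added to the
#'     plasma pool one hour after each dose (a serine-rich post-dose
#'     meal).}
#' }
#'
#' @param name scenario name (see above) or `"custom"`.
#' @param physiology a [physiology_parameters()]; provides body weight
#'   and the fasted-state base.
#' @param species amino-acid species of the meals; default equimolar
#'   over the full catalog. Single-species variants (e.g. cystine-only
#'   low-protein meals) are obtained by passing one name.
#' @param protein_g_per_kg amino-acid load per meal, g per kg body
#'   weight (low-protein limit 0.8).
#' @param prd_multiplier plasma amino-acid elevation at the start of a
#'   protein-redistribution day, relative to the fasting baseline.
#' @param serine_g serine added to the plasma pool per post-dose meal,
#'   g.
#' @param config a [coupling_config()]; supplies the plasma baseline
#'   and horizon.
#' @param custom for `name = "custom"`: a list with `regimen`,
#'   `prandial`, `diet`.
#' @return object of class `diet_scenario`: list with `name`,
#'   `regimen`, `prandial` (`"fasted"`/`"fed"`) and `diet` (as consumed
#'   by [run_coupled()]).
#' @export
build_scenario <- function(name, physiology = physiology_parameters(),
                           species = AA_SPECIES,
                           protein_g_per_kg = 0.8,
                           prd_multiplier = 3, serine_g = 5,
                           config = coupling_config(),
                           custom = NULL) {
  valid <- c("ac", "fed_aproteic", "fed_proteic", "lpd", "prd",
             "serine_rich", "custom")
  if (!name %in% valid)
    stop("unknown scenario '", name, "'; valid names: ",
         paste(valid, collapse = ", "), call. = FALSE)
  horizon <- config$duration
  q6 <- seq(0, horizon - 1e-9, by = 6)
  meal_mmol <- equimolar_meal(protein_g_per_kg * physiology$body_weight,
                              species)
  meal_df <- function(times) {
    do.call(rbind, lapply(times, function(tt)
      data.frame(time = tt, species = names(meal_mmol),
                 mmol = unname(meal_mmol))))
  }
  sc <- switch(
    name,
    ac = list(regimen = dose_regimen(q6, 100, horizon),
              prandial = "fasted", diet = NULL),
    fed_aproteic = list(regimen = dose_regimen(q6, 100, horizon),
                        prandial = "fed", diet = NULL),
    fed_proteic = list(regimen = dose_regimen(q6, 100, horizon),
                       prandial = "fed",
                       diet = list(meals = meal_df(q6))),
    lpd = list(regimen = dose_regimen(q6, 200, horizon),
               prandial = "fasted",
               diet = list(meals = meal_df(q6))),
    prd = list(regimen = dose_regimen(q6, 100, horizon),
               prandial = "fasted",
               diet = list(plasma_init = prd_multiplier *
                             config$plasma_baseline)),
    serine_rich = list(
      regimen = dose_regimen(q6, 100, horizon),
      prandial = "fasted",
      diet = list(plasma_events = data.frame(
        time = q6 + 1, species = "ser",
        mmol = 1000 * serine_g / AA_MW[["ser"]]))),
    custom = custom)
  if (is.null(sc))
    stop("custom scenario requires the 'custom' argument", call. = FALSE)
  structure(c(list(name = name), sc), class = "diet_scenario")
}

#' Run scenarios and compare threshold-scored exposure
#'
#' Runs every scenario through the coupled simulation and scores each
#' by the area under the plasma curve above every efficacy threshold,
#' plus peak metrics. Relative changes are reported against the first
#' scenario (the reference, typically the ante cibum fasted state), as
#' `100 * (AUC_s - AUC_ref) / AUC_ref` per threshold.
#'
#' @param scenarios list of `diet_scenario`s (first = reference).
#' @param thresholds a [hy_thresholds()].
#' @param physiology,kinetics base parameter objects.
#' @param networks list of 7 segment networks (levodopa module
#'   applied).
#' @param config a [coupling_config()].
#' @param catalog a [transporter_catalog()].
#' @return `scenario_report`: list with `metrics` (data.frame), and
#'   `runs` (named list of `coupled_run`s).
#' @export
run_and_compare <- function(scenarios, thresholds = hy_thresholds(),
                            physiology = physiology_parameters(),
                            kinetics = kinetic_parameters(),
                            networks = NULL,
                            config = coupling_config(),
                            catalog = transporter_catalog()) {
  if (!length(scenarios)) stop("no scenarios given", call. = FALSE)
  if (is.null(networks)) {
    net <- add_levodopa_module(build_reduced_siec(), catalog)
    networks <- rep(list(net), 7)
  }
  runs <- list(); rows <- list()
  for (sc in scenarios) {
    phys <- set_prandial_state(physiology, sc$prandial)
    model <- build_wb_acat(phys, kinetics)
    run <- run_coupled(model, networks, sc$regimen, sc$diet, config,
                       catalog)
    runs[[sc$name]] <- run
    pk <- cmax_tmax(run$tc)
    row <- data.frame(scenario = sc$name, cmax = pk$cmax,
                      tmax = pk$tmax,
                      auc = auc_above_threshold(run$tc, 0))
    for (st in names(thresholds))
      row[[paste0("auc_", st)]] <-
        auc_above_threshold(run$tc, thresholds[[st]])
    rows[[sc$name]] <- row
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  ref <- metrics[1, ]
  for (col in grep("^auc", names(metrics), value = TRUE)) {
    metrics[[paste0("rel_", col, "_pct")]] <-
      if (ref[[col]] > 0) 100 * (metrics[[col]] - ref[[col]]) / ref[[col]]
      else NA_real_
  }
  structure(list(metrics = metrics, runs = runs,
                 reference = metrics$scenario[1]),
            class = "scenario_report")
}

# Fasting-state constraint set of the extended (kidney/brain) model:
# fixed luminal influx, affinity-share carrier allocations, and the
# flux-ratio constraints tying systemic delivery to uptake and renal
# elimination to systemic delivery.
fasting_constraints <- function(net, influx = 15, coadmin = NULL,
                                catalog = transporter_catalog(),
                                systemic_fraction = 0.66,
                                renal_fraction = 0.30,
                                brain_capacity = 0.7 * influx) {
  q_co <- if (is.null(coadmin)) numeric() else
    stats::setNames(1, coadmin)
  share_lum <- competition_share(1, q_co, catalog$luminal_antiporter,
                                 catalog$luminal_levodopa_rank)
  share_renal <- competition_share(1, q_co, catalog$renal_carrier,
                                   catalog$renal_levodopa_rank)
  share_brain <- competition_share(1, q_co, catalog$brain_carrier,
                                   catalog$brain_levodopa_rank)
  anti <- intersect(paste0("LDOPA_lum_anti_",
                           names(catalog$luminal_antiporter)),
                    net$rxns$id)
  couplings <- list(
    list(coef = stats::setNames(rep(1, length(anti)), anti),
         rhs = share_lum * influx, sense = "le"),
    list(coef = stats::setNames(
      c(1, rep(-systemic_fraction, length(anti))),
      c("LDOPA_systemic", anti)), rhs = 0, sense = "eq"),
    list(coef = c(LDOPA_renal = 1,
                  LDOPA_systemic = -renal_fraction * share_renal),
         rhs = 0, sense = "eq"))
  bounds <- list(EX_levodopa_l = c(-influx, 0),
                 LDOPA_brain = c(0, share_brain * brain_capacity))
  list(bounds = bounds, couplings = couplings,
       shares = c(luminal = share_lum, renal = share_renal,
                  brain = share_brain))
}

#' Fasting-state reference flux solution of the extended model
#'
#' Fixes the luminal levodopa influx, applies the fasting flux-ratio
#' constraints (systemic delivery as a fraction of uptake; renal
#' elimination as a fraction of systemic delivery, both
#' affinity-share-scaled under co-administration), and maximizes the
#' brain delivery reaction.
#'
#' @param net an extended network from [extend_brain_kidney()].
#' @param influx luminal levodopa influx, mmol/gDW/h.
#' @param coadmin optional single amino-acid species co-administered
#'   with levodopa (present on all shared carriers at matched amount).
#' @param catalog a [transporter_catalog()].
#' @param systemic_fraction fraction of absorbed levodopa reaching the
#'   systemic circulation in the fasting state.
#' @param renal_fraction fraction of systemic levodopa eliminated by
#'   the kidney in the fasting state.
#' @param brain_capacity blood-brain-barrier carrier capacity,
#'   mmol/gDW/h; scales with the reference influx.
#' @return list with `solution` (a `flux_solution`), `uptake`,
#'   `systemic`, `renal`, `brain`, `residual` fluxes (mmol/gDW/h), and
#'   `systemic_pct` / `renal_pct` (percent of influx / of absorbed).
#' @export
fasting_reference_fba <- function(net, influx = 15, coadmin = NULL,
                                  catalog = transporter_catalog(),
                                  systemic_fraction = 0.66,
                                  renal_fraction = 0.30,
                                  brain_capacity = 0.7 * influx) {
  if (!"brain_kidney" %in% net$modules)
    stop("network lacks the kidney/brain extension", call. = FALSE)
  fc <- fasting_constraints(net, influx, coadmin, catalog,
                            systemic_fraction, renal_fraction,
                            brain_capacity)
  sol <- fba(net, objective = "LDOPA_brain", sense = "max",
             extra_bounds = fc$bounds, extra_couplings = fc$couplings)
  if (sol$status != "optimal")
    return(list(solution = sol, uptake = NA_real_, systemic = NA_real_,
                renal = NA_real_, brain = NA_real_,
                residual = NA_real_, systemic_pct = NA_real_,
                renal_pct = NA_real_))
  v <- sol$fluxes
  uptake <- -v[["EX_levodopa_l"]]
  systemic <- v[["LDOPA_systemic"]]
  renal <- v[["LDOPA_renal"]]
  brain <- v[["LDOPA_brain"]]
  list(solution = sol, uptake = uptake, systemic = systemic,
       renal = renal, brain = brain,
       residual = v[["LDOPA_systemic_residual"]],
       systemic_pct = 100 * systemic / influx,
       renal_pct = 100 * renal / systemic)
}

#' Rank amino acids by their effect on brain levodopa delivery
#'
#' For every amino acid, simulates co-administration with levodopa on
#' the extended enterocyte-kidney-brain model under the fasting
#' reference constraints and records the maximal brain levodopa flux.
#' Amino acids partition into three classes relative to the no-amino-
#' acid reference: `improving` (higher brain delivery; renal-carrier
#' competitors that spare levodopa from urinary loss and trans-
#' stimulate basolateral secretion), `neutral` (no shared carrier;
#' delivery identical to the fasted reference) and `competing` (luminal
#' or blood-brain-barrier competition dominates).
#'
#' @inheritParams fasting_reference_fba
#' @return data.frame (`species`, `brain_flux`, `class`) in descending
#'   order of brain delivery; the reference flux is attached as
#'   attribute `reference`.
#' @export
rank_amino_acids <- function(net, influx = 15,
                             catalog = transporter_catalog(),
                             systemic_fraction = 0.66,
                             renal_fraction = 0.30,
                             brain_capacity = 0.7 * influx) {
  ref <- fasting_reference_fba(net, influx, NULL, catalog,
                               systemic_fraction, renal_fraction,
                               brain_capacity)
  if (ref$solution$status != "optimal")
    stop("reference flux solve failed: ", ref$solution$status,
         call. = FALSE)
  rows <- lapply(AA_SPECIES, function(sp) {
    r <- fasting_reference_fba(net, influx, sp, catalog,
                               systemic_fraction, renal_fraction,
                               brain_capacity)
    if (r$solution$status != "optimal")
      return(data.frame(species = sp, brain_flux = NA_real_,
                        class = paste0("infeasible: ",
                                       r$solution$status)))
    cls <- if (r$brain > ref$brain + 1e-6) "improving"
    else if (r$brain < ref$brain - 1e-6) "competing"
    else "neutral"
    data.frame(species = sp, brain_flux = r$brain, class = cls)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$brain_flux), ]
  rownames(out) <- NULL
  attr(out, "reference") <- ref$brain
  out
}
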
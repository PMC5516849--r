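#' Stoichiometric network container
#'
#' A lightweight constraint-based model: metabolites with compartments,
#' reactions with bounds (mmol/gDW/h), a dense stoichiometric matrix,
#' an objective reaction, and optional linear coupling constraints
#' (rows beyond steady state, e.g. the fixed uniporter/antiporter split
#' of basolateral levodopa efflux).
#'
#' @param mets data.frame with columns `id`, `compartment`.
#' @param rxns data.frame with columns `id`, `lb`, `ub`, `gene`.
#' @param S dense stoichiometric matrix, rows = metabolites, columns =
#'   reactions.
#' @param objective id of the objective reaction.
#' @param couplings list of extra linear constraints, each a list with
#'   `coef` (named numeric over reaction ids), `rhs`, and `sense`
#'   (`"eq"` or `"le"`).
#' @param modules character tags of applied modules.
#' @return object of class `stoich_network`.
#' @export
stoich_network <- function(mets, rxns, S, objective = NULL,
                           couplings = list(), modules = character()) {
  net <- structure(list(mets = mets, rxns = rxns, S = S,
                        objective = objective, couplings = couplings,
                        modules = modules),
                   class = "stoich_network")
  validate_network(net)
  net
}

validate_network <- function(net) {
  stopifnot(is.data.frame(net$mets), is.data.frame(net$rxns))
  if (nrow(net$S) != nrow(net$mets) || ncol(net$S) != nrow(net$rxns))
    stop("stoichiometric matrix dimensions do not match metabolite/",
         "reaction tables", call. = FALSE)
  if (anyDuplicated(net$mets$id) || anyDuplicated(net$rxns$id))
    stop("duplicate metabolite or reaction ids", call. = FALSE)
  if (any(net$rxns$lb > net$rxns$ub))
    stop("reaction bounds must satisfy lb <= ub", call. = FALSE)
  if (!is.null(net$objective) && !net$objective %in% net$rxns$id)
    stop("objective reaction '", net$objective, "' not in network",
         call. = FALSE)
  for (cp in net$couplings) {
    if (!all(names(cp$coef) %in% net$rxns$id))
      stop("coupling constraint references unknown reactions",
           call. = FALSE)
  }
  invisible(net)
}

#' @export
print.stoich_network <- function(x, ...) {
  cat("stoich_network:", nrow(x$mets), "metabolites,", nrow(x$rxns),
      "reactions,", length(x$couplings), "coupling constraint(s)\n")
  if (length(x$modules)) cat("modules:", paste(x$modules,
                                               collapse = ", "), "\n")
  invisible(x)
}

#' Number of reactions / metabolites
#' @param net a `stoich_network`.
#' @return integer count.
#' @export
n_reactions <- function(net) nrow(net$rxns)

#' @rdname n_reactions
#' @export
n_metabolites <- function(net) nrow(net$mets)

# internal builder kept in a plain environment for speed/clarity
net_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$mets <- list()
  env$rxns <- list()
  env$stoich <- list()
  env
}

nb_add_met <- function(env, id, compartment) {
  if (!id %in% names(env$mets)) env$mets[[id]] <- compartment
  invisible(env)
}

nb_add_rxn <- function(env, id, stoich, lb, ub, gene = "") {
  if (id %in% names(env$rxns))
    stop("duplicate reaction id: ", id, call. = FALSE)
  env$rxns[[id]] <- c(lb = lb, ub = ub)
  env$stoich[[id]] <- stoich
  attr(env$rxns[[id]], "gene") <- gene
  invisible(env)
}

nb_build <- function(env, objective = NULL, couplings = list(),
                     modules = character()) {
  met_ids <- names(env$mets)
  rxn_ids <- names(env$rxns)
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (r in rxn_ids) {
    st <- env$stoich[[r]]
    missing_met <- setdiff(names(st), met_ids)
    if (length(missing_met))
      stop("reaction ", r, " references unknown metabolite(s): ",
           paste(missing_met, collapse = ", "), call. = FALSE)
    S[names(st), r] <- st
  }
  mets <- data.frame(id = met_ids,
                     compartment = unlist(env$mets, use.names = FALSE),
                     stringsAsFactors = FALSE)
  bnds <- do.call(rbind, env$rxns)
  rxns <- data.frame(id = rxn_ids, lb = bnds[, "lb"], ub = bnds[, "ub"],
                     gene = vapply(env$rxns, function(x)
                       attr(x, "gene") %||% "", ""),
                     stringsAsFactors = FALSE, row.names = NULL)
  stoich_network(mets, rxns, S, objective, couplings, modules)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the reduced enterocyte network
#'
#' Deterministic desk-scale stand-in for a genome-scale enterocyte
#' reconstruction: the 20 proteinogenic amino acids plus cystine and
#' ornithine, each with a luminal exchange, an apical transport, a
#' basolateral transport and a basolateral (blood-side) exchange; a
#' lumped biomass demand on the proteinogenic amino acids; and three
#' reversible interconversions (serine/glycine, glutamate/glutamine,
#' aspartate/asparagine). Compartments: `lumen`, `cytosol`, `blood`.
#' All three levodopa carrier scaffolds operate on these species once
#' [add_levodopa_module()] is applied.
#'
#' Exchange convention: positive exchange flux exports out of the
#' system; uptake is negative.
#'
#' @return a `stoich_network` with 92 reactions and 66 metabolites;
#'   objective is the biomass demand.
#' @export
build_reduced_siec <- function() {
  b <- net_builder()
  for (sp in AA_SPECIES) {
    for (cmp in c("l", "c", "b")) {
      nb_add_met(b, paste0(sp, "[", cmp, "]"),
                 switch(cmp, l = "lumen", c = "cytosol", b = "blood"))
    }
    lmet <- paste0(sp, "[l]"); cmet <- paste0(sp, "[c]")
    bmet <- paste0(sp, "[b]")
    nb_add_rxn(b, paste0("EX_", sp, "_l"), stats::setNames(-1, lmet),
               -1000, 1000)
    nb_add_rxn(b, paste0("T_", sp, "_apical"),
               stats::setNames(c(-1, 1), c(lmet, cmet)), -1000, 1000)
    nb_add_rxn(b, paste0("T_", sp, "_baso"),
               stats::setNames(c(-1, 1), c(cmet, bmet)), -1000, 1000)
    nb_add_rxn(b, paste0("EX_", sp, "_b"), stats::setNames(-1, bmet),
               -1000, 1000)
  }
  proteinogenic <- setdiff(AA_SPECIES, c("cystine", "ornithine"))
  nb_add_rxn(b, "biomass",
             stats::setNames(rep(-0.1, length(proteinogenic)),
                             paste0(proteinogenic, "[c]")), 0, 1000)
  nb_add_rxn(b, "SER_GLY_c",
             stats::setNames(c(-1, 1), c("ser[c]", "gly[c]")),
             -1000, 1000)
  nb_add_rxn(b, "GLU_GLN_c",
             stats::setNames(c(-1, 1), c("glu[c]", "gln[c]")),
             -1000, 1000)
  nb_add_rxn(b, "ASP_ASN_c",
             stats::setNames(c(-1, 1), c("asp[c]", "asn[c]")),
             -1000, 1000)
  nb_build(b, objective = "biomass", modules = "reduced_siec")
}

#' Add the levodopa transport module
#'
#' Adds levodopa species in lumen, cytosol and blood, and exactly 36
#' reactions describing carrier-mediated levodopa transport with its
#' amino-acid co-substrates:
#' \itemize{
#'   \item 20 luminal antiport reactions (levodopa in / amino acid out),
#'     one per dibasic or neutral substrate of the luminal carrier;
#'   \item 13 basolateral antiport reactions (levodopa out / neutral
#'     amino acid in) -- the trans-stimulation route;
#'   \item 1 basolateral uniporter reaction;
#'   \item 1 luminal and 1 basolateral levodopa exchange.
#' }
#' All antiport reactions are strict 1:1 exchanges. A linear coupling
#' constraint fixes the uniporter share of basolateral levodopa efflux
#' to `split_fraction_uniporter` (4/5 by default) in every flux
#' solution.
#'
#' @param net a `stoich_network` without levodopa species.
#' @param catalog a [transporter_catalog()].
#' @return extended `stoich_network` (module tag `levodopa`).
#' @export
add_levodopa_module <- function(net, catalog = transporter_catalog()) {
  if ("levodopa" %in% net$modules)
    stop("levodopa module already applied", call. = FALSE)
  missing_sub <- setdiff(c(names(catalog$luminal_antiporter),
                           names(catalog$basolateral_antiporter)),
                         sub("\\[.*", "", net$mets$id))
  if (length(missing_sub))
    stop("network lacks carrier substrates: ",
         paste(unique(missing_sub), collapse = ", "), call. = FALSE)
  b <- net_builder()
  # re-register existing content
  for (i in seq_len(nrow(net$mets)))
    nb_add_met(b, net$mets$id[i], net$mets$compartment[i])
  for (j in seq_len(nrow(net$rxns))) {
    st <- net$S[, j]
    nb_add_rxn(b, net$rxns$id[j], st[st != 0], net$rxns$lb[j],
               net$rxns$ub[j], net$rxns$gene[j])
  }
  nb_add_met(b, "levodopa[l]", "lumen")
  nb_add_met(b, "levodopa[c]", "cytosol")
  nb_add_met(b, "levodopa[b]", "blood")
  for (sp in names(catalog$luminal_antiporter)) {
    nb_add_rxn(b, paste0("LDOPA_lum_anti_", sp),
               stats::setNames(c(-1, -1, 1, 1),
                               c("levodopa[l]", paste0(sp, "[c]"),
                                 "levodopa[c]", paste0(sp, "[l]"))),
               0, 1000, gene = catalog$genes[["luminal_antiporter"]])
  }
  for (sp in names(catalog$basolateral_antiporter)) {
    nb_add_rxn(b, paste0("LDOPA_bl_anti_", sp),
               stats::setNames(c(-1, -1, 1, 1),
                               c("levodopa[c]", paste0(sp, "[b]"),
                                 "levodopa[b]", paste0(sp, "[c]"))),
               0, 1000, gene = catalog$genes[["basolateral_antiporter"]])
  }
  nb_add_rxn(b, "LDOPA_bl_uni",
             stats::setNames(c(-1, 1), c("levodopa[c]", "levodopa[b]")),
             0, 1000, gene = catalog$genes[["basolateral_uniporter"]])
  nb_add_rxn(b, "EX_levodopa_l", stats::setNames(-1, "levodopa[l]"),
             -1000, 1000)
  nb_add_rxn(b, "EX_levodopa_b", stats::setNames(-1, "levodopa[b]"),
             0, 1000)
  # uniporter carries split/(1-split) times the antiporter total
  f <- catalog$split_fraction_uniporter
  anti <- paste0("LDOPA_bl_anti_", names(catalog$basolateral_antiporter))
  cp <- list(coef = stats::setNames(
    c(1 - f, rep(-f, length(anti))), c("LDOPA_bl_uni", anti)),
    rhs = 0, sense = "eq")
  nb_build(b, objective = net$objective,
           couplings = c(net$couplings, list(cp)),
           modules = c(net$modules, "levodopa"))
}

#' Extend the enterocyte model with kidney and brain compartments
#'
#' Builds the extended network (the starred model): basolateral
#' levodopa is routed into a systemic pool from which three fates
#' compete -- transport across the blood-brain barrier, renal
#' elimination into urine, and a residual systemic sink (peripheral
#' tissues and metabolism). A cytosolic loss reaction (enterocyte
#' decarboxylation) provides the pre-systemic loss route. Shared-carrier
#' amino-acid transport reactions are added for the substrates of the
#' renal and brain carriers; competition at those carriers is imposed
#' through affinity-share bounds (see [fasting_reference_fba()]).
#'
#' The plain basolateral levodopa exchange is closed; all absorbed
#' levodopa passes through the systemic pool.
#'
#' @param net a `stoich_network` with the levodopa module applied.
#' @param catalog a [transporter_catalog()].
#' @return extended `stoich_network` (module tag `brain_kidney`).
#' @export
extend_brain_kidney <- function(net, catalog = transporter_catalog()) {
  if (!"levodopa" %in% net$modules)
    stop("levodopa module missing; apply add_levodopa_module() first",
         call. = FALSE)
  if ("brain_kidney" %in% net$modules)
    stop("brain/kidney extension already applied", call. = FALSE)
  b <- net_builder()
  for (i in seq_len(nrow(net$mets)))
    nb_add_met(b, net$mets$id[i], net$mets$compartment[i])
  for (j in seq_len(nrow(net$rxns))) {
    st <- net$S[, j]
    lb <- net$rxns$lb[j]; ub <- net$rxns$ub[j]
    if (net$rxns$id[j] == "EX_levodopa_b") { lb <- 0; ub <- 0 }
    nb_add_rxn(b, net$rxns$id[j], st[st != 0], lb, ub, net$rxns$gene[j])
  }
  nb_add_met(b, "levodopa[s]", "systemic")
  nb_add_met(b, "levodopa[brain]", "brain")
  nb_add_met(b, "levodopa[u]", "kidney-urine")
  nb_add_rxn(b, "LDOPA_systemic",
             stats::setNames(c(-1, 1), c("levodopa[b]", "levodopa[s]")),
             0, 1000)
  nb_add_rxn(b, "LDOPA_gut_loss", stats::setNames(-1, "levodopa[c]"),
             0, 1000)
  nb_add_rxn(b, "LDOPA_brain",
             stats::setNames(c(-1, 1),
                             c("levodopa[s]", "levodopa[brain]")),
             0, 1000)
  nb_add_rxn(b, "DM_levodopa_brain", stats::setNames(-1,
                                                     "levodopa[brain]"),
             0, 1000)
  nb_add_rxn(b, "LDOPA_renal",
             stats::setNames(c(-1, 1), c("levodopa[s]", "levodopa[u]")),
             0, 1000)
  nb_add_rxn(b, "DM_levodopa_urine", stats::setNames(-1, "levodopa[u]"),
             0, 1000)
  nb_add_rxn(b, "LDOPA_systemic_residual",
             stats::setNames(-1, "levodopa[s]"), 0, 1000)
  for (sp in names(catalog$brain_carrier))
    nb_add_rxn(b, paste0("BRAIN_", sp),
               stats::setNames(-1, paste0(sp, "[b]")), 0, 1000)
  for (sp in names(catalog$renal_carrier))
    nb_add_rxn(b, paste0("RENAL_", sp),
               stats::setNames(-1, paste0(sp, "[b]")), 0, 1000)
  nb_build(b, objective = "LDOPA_brain",
           couplings = net$couplings,
           modules = c(net$modules, "brain_kidney"))
}

#' Set reaction bounds
#'
#' @param net a `stoich_network`.
#' @param bounds named list; each element `c(lb, ub)` for a reaction id.
#' @return modified network.
#' @export
set_bounds <- function(net, bounds) {
  for (id in names(bounds)) {
    j <- match(id, net$rxns$id)
    if (is.na(j)) stop("unknown reaction: ", id, call. = FALSE)
    net$rxns$lb[j] <- bounds[[id]][1]
    net$rxns$ub[j] <- bounds[[id]][2]
  }
  validate_network(net)
  net
}
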
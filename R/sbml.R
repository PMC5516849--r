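# SBML (level 3 + flux-bound parameters) serialization of
# stoich_network objects, built directly on xml2. Metabolite ids like
# "ala[l]" are sanitized to SBML SIds ("M_ala_l"); the original id
# travels in the species name attribute so a round trip is lossless.
# Coupling constraints are not part of SBML; they are re-derived from
# the transporter catalog after loading.

sbml_id <- function(x, prefix) {
  paste0(prefix, "_", gsub("[^A-Za-z0-9_]", "_", x))
}

#' Write a network to SBML
#'
#' @param net a `stoich_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  ns_core <- "http://www.sbml.org/sbml/level3/version1/core"
  doc <- xml2::xml_new_root("sbml", xmlns = ns_core, level = "3",
                            version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = "levogut_network")
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cmp in unique(net$mets$compartment))
    xml2::xml_add_child(lc, "compartment",
                        id = sbml_id(cmp, "C"), constant = "true")
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(net$mets)))
    xml2::xml_add_child(ls, "species",
                        id = sbml_id(net$mets$id[i], "M"),
                        name = net$mets$id[i],
                        compartment = sbml_id(net$mets$compartment[i],
                                              "C"),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_len(nrow(net$rxns))) {
    st <- net$S[, j]
    rx <- xml2::xml_add_child(lr, "reaction",
                              id = sbml_id(net$rxns$id[j], "R"),
                              name = net$rxns$id[j],
                              reversible = if (net$rxns$lb[j] < 0)
                                "true" else "false",
                              fast = "false")
    # bounds carried as plain numeric attributes understood by
    # load_network
    xml2::xml_set_attr(rx, "lowerFluxBound",
                       format(net$rxns$lb[j], digits = 17))
    xml2::xml_set_attr(rx, "upperFluxBound",
                       format(net$rxns$ub[j], digits = 17))
    if (nzchar(net$rxns$gene[j]))
      xml2::xml_set_attr(rx, "geneAssociation", net$rxns$gene[j])
    neg <- which(st < 0); pos <- which(st > 0)
    if (length(neg)) {
      lrt <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in neg)
        xml2::xml_add_child(lrt, "speciesReference",
                            species = sbml_id(net$mets$id[i], "M"),
                            stoichiometry = format(-st[i], digits = 17),
                            constant = "true")
    }
    if (length(pos)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in pos)
        xml2::xml_add_child(lpr, "speciesReference",
                            species = sbml_id(net$mets$id[i], "M"),
                            stoichiometry = format(st[i], digits = 17),
                            constant = "true")
    }
  }
  if (!is.null(net$objective))
    xml2::xml_set_attr(mdl, "objectiveReaction",
                       sbml_id(net$objective, "R"))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Load a network from SBML
#'
#' Reads the subset of SBML written by [write_network()] (level 3
#' species/reactions with flux-bound attributes); a
#' write-then-load round trip preserves stoichiometry and bounds
#' exactly. Coupling constraints and module tags are not represented
#' in SBML and come back empty.
#'
#' @param path SBML file path.
#' @return a `stoich_network`.
#' @export
load_network <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse error in '", path, "': ", conditionMessage(e),
         call. = FALSE))
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing"))
    stop("SBML parse error: no <model> element in '", path, "'",
         call. = FALSE)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(sp_nodes))
    stop("SBML parse error: no species in '", path, "'", call. = FALSE)
  sid <- xml2::xml_attr(sp_nodes, "id")
  sname <- xml2::xml_attr(sp_nodes, "name")
  sname[is.na(sname)] <- sid[is.na(sname)]
  scomp <- xml2::xml_attr(sp_nodes, "compartment")
  comp_nodes <- xml2::xml_find_all(doc, ".//listOfCompartments/compartment")
  comp_map <- stats::setNames(
    sub("^C_", "", xml2::xml_attr(comp_nodes, "id")),
    xml2::xml_attr(comp_nodes, "id"))
  mets <- data.frame(id = sname,
                     compartment = unname(comp_map[scomp]),
                     stringsAsFactors = FALSE)
  id2name <- stats::setNames(sname, sid)

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  nrx <- length(rx_nodes)
  rid <- xml2::xml_attr(rx_nodes, "name")
  rid[is.na(rid)] <- xml2::xml_attr(rx_nodes, "id")[is.na(rid)]
  lb <- as.numeric(xml2::xml_attr(rx_nodes, "lowerFluxBound"))
  ub <- as.numeric(xml2::xml_attr(rx_nodes, "upperFluxBound"))
  lb[is.na(lb)] <- -1000; ub[is.na(ub)] <- 1000
  gene <- xml2::xml_attr(rx_nodes, "geneAssociation")
  gene[is.na(gene)] <- ""
  S <- matrix(0, nrow(mets), nrx,
              dimnames = list(mets$id, rid))
  for (j in seq_len(nrx)) {
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rx_nodes[[j]],
                                 paste0("./", side, "/speciesReference"))
      if (!length(refs)) next
      sp <- id2name[xml2::xml_attr(refs, "species")]
      if (any(is.na(sp)))
        stop("SBML parse error: reaction '", rid[j],
             "' references unknown species", call. = FALSE)
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      sgn <- if (side == "listOfReactants") -1 else 1
      S[sp, j] <- S[sp, j] + sgn * coef
    }
  }
  obj <- xml2::xml_attr(mdl, "objectiveReaction")
  objective <- if (!is.na(obj)) {
    hit <- which(sbml_id(rid, "R") == obj)
    if (length(hit)) rid[hit[1]] else NULL
  } else NULL
  stoich_network(mets,
                 data.frame(id = rid, lb = lb, ub = ub, gene = gene,
                            stringsAsFactors = FALSE),
                 S, objective = objective)
}
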
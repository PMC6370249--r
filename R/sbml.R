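#' Write a community model as SBML Level 3
#'
#' Minimal SBML L3v1 serialization: compartments (the shared extracellular
#' compartment plus one per species), species (metabolites), global
#' parameters holding flux bounds referenced by fbc-style
#' `lowerFluxBound`/`upperFluxBound` attributes, and reactions with
#' stoichiometric reactant/product lists. Subsystem, species tag, nutrient
#' class and role (biomass / ATP synthase, with biomass priority order)
#' travel in COBRA-style notes (`<p>KEY: value</p>`), so a written model can
#' be read back with no side channel.
#'
#' @param model A [community_model()].
#' @param path Output `.xml` file.
#' @return `path`, invisibly.
#' @seealso [read_sbml_community()]
#' @export
write_sbml_community <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "gut_community")

  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in unique(model$metabolites$compartment))
    xml2::xml_add_child(comps, "compartment", id = cid, constant = "true")

  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites)))
    xml2::xml_add_child(sps, "species",
                        id = model$metabolites$id[i],
                        compartment = model$metabolites$compartment[i],
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")

  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  rx <- model$reactions
  for (i in seq_len(nrow(rx))) {
    xml2::xml_add_child(pars, "parameter", id = paste0("lb_", rx$id[i]),
                        value = format(rx$lb[i], digits = 17),
                        constant = "true")
    xml2::xml_add_child(pars, "parameter", id = paste0("ub_", rx$id[i]),
                        value = format(rx$ub[i], digits = 17),
                        constant = "true")
  }

  cls_of <- rep(NA_character_, nrow(rx))
  for (cls in names(model$exchange_groups))
    cls_of[rx$id %in% model$exchange_groups[[cls]]] <- cls
  prio <- match(rx$id, model$biomass_objectives)

  rxs <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(rx))) {
    rnode <- xml2::xml_add_child(rxs, "reaction", id = rx$id[i],
                                 reversible = tolower(rx$lb[i] < 0),
                                 fast = "false",
                                 "fbc:lowerFluxBound" = paste0("lb_", rx$id[i]),
                                 "fbc:upperFluxBound" = paste0("ub_", rx$id[i]))
    notes <- xml2::xml_add_child(rnode, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    note <- function(key, val)
      xml2::xml_add_child(body, "p", paste0(key, ": ", val))
    note("SUBSYSTEM", rx$subsystem[i])
    if (!is.na(rx$species[i])) note("SPECIES", rx$species[i])
    if (!is.na(cls_of[i])) note("NUTRIENT_CLASS", cls_of[i])
    if (rx$id[i] %in% model$atp_synthase_ids) note("ROLE", "atp_synthase")
    if (!is.na(prio[i])) note("ROLE", paste0("biomass:", prio[i]))
    s <- model$stoich[, rx$id[i]]
    re <- which(s < 0); pr <- which(s > 0)
    if (length(re)) {
      ln <- xml2::xml_add_child(rnode, "listOfReactants")
      for (m in re)
        xml2::xml_add_child(ln, "speciesReference",
                            species = rownames(model$stoich)[m],
                            stoichiometry = format(-s[m], digits = 17),
                            constant = "true")
    }
    if (length(pr)) {
      ln <- xml2::xml_add_child(rnode, "listOfProducts")
      for (m in pr)
        xml2::xml_add_child(ln, "speciesReference",
                            species = rownames(model$stoich)[m],
                            stoichiometry = format(s[m], digits = 17),
                            constant = "true")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a community model from SBML
#'
#' Reads the SBML subset written by [write_sbml_community()] (and plain
#' SBML L3 core with fbc flux-bound parameters). Subsystems default to
#' `"unassigned"` when a reaction carries no subsystem note; species tags
#' default to `NA` (shared reaction); exchange reactions without a nutrient
#' class note are left ungrouped.
#'
#' @param path SBML file.
#' @param objective_order Ordered character vector of biomass reaction ids
#'   (priority order). `NULL` uses the `biomass:<k>` role notes stored by the
#'   writer. An id absent from the model is an error that lists candidates.
#' @return A [community_model()].
#' @export
read_sbml_community <- function(path, objective_order = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  met_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- data.frame(
    id = xml2::xml_attr(met_nodes, "id"),
    compartment = xml2::xml_attr(met_nodes, "compartment"))

  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                            xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  n <- length(rx_nodes)
  ids <- xml2::xml_attr(rx_nodes, "id")
  lb <- ub <- numeric(n)
  subsystem <- rep("unassigned", n)
  species <- rep(NA_character_, n)
  nutrient <- rep(NA_character_, n)
  atp_ids <- character(0)
  bio <- data.frame(id = character(0), prio = integer(0))
  S <- matrix(0, nrow(mets), n, dimnames = list(mets$id, ids))

  for (i in seq_len(n)) {
    node <- rx_nodes[[i]]
    lb[i] <- parval[[xml2::xml_attr(node, "lowerFluxBound")]]
    ub[i] <- parval[[xml2::xml_attr(node, "upperFluxBound")]]
    for (p in xml2::xml_find_all(node, "./notes/body/p")) {
      txt <- xml2::xml_text(p)
      kv <- regmatches(txt, regexec("^([A-Z_]+): (.*)$", txt))[[1]]
      if (length(kv) != 3) next
      switch(kv[2],
             SUBSYSTEM = { subsystem[i] <- kv[3] },
             SPECIES = { species[i] <- kv[3] },
             NUTRIENT_CLASS = { nutrient[i] <- kv[3] },
             ROLE = {
               if (kv[3] == "atp_synthase") atp_ids <- c(atp_ids, ids[i])
               if (startsWith(kv[3], "biomass:"))
                 bio <- rbind(bio, data.frame(
                   id = ids[i],
                   prio = as.integer(sub("biomass:", "", kv[3]))))
             })
    }
    for (sr in xml2::xml_find_all(node, "./listOfReactants/speciesReference"))
      S[xml2::xml_attr(sr, "species"), i] <-
        S[xml2::xml_attr(sr, "species"), i] -
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    for (sr in xml2::xml_find_all(node, "./listOfProducts/speciesReference"))
      S[xml2::xml_attr(sr, "species"), i] <-
        S[xml2::xml_attr(sr, "species"), i] +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
  }

  if (is.null(objective_order)) {
    if (nrow(bio) == 0)
      stop("no biomass objectives stored in file; supply objective_order",
           call. = FALSE)
    objective_order <- bio$id[order(bio$prio)]
  }
  missing <- setdiff(objective_order, ids)
  if (length(missing))
    stop("objective id(s) not in model: ", paste(missing, collapse = ", "),
         "\n  candidates: ",
         paste(grep("bio", ids, ignore.case = TRUE, value = TRUE),
               collapse = ", "), call. = FALSE)

  sp_order <- unique(species[match(objective_order, ids)])
  sp_order <- sp_order[!is.na(sp_order)]
  if (length(sp_order) == 0) sp_order <- unique(stats::na.omit(species))
  names(atp_ids) <- species[match(atp_ids, ids)]

  # the extracellular compartment: the one exchange-note reactions touch,
  # else the compartment named "e"
  ex_ids <- ids[!is.na(nutrient)]
  ext_comp <- if (length(ex_ids)) {
    unique(mets$compartment[rowSums(abs(S[, ex_ids, drop = FALSE])) > 0])
  } else "e"
  mets$external <- mets$compartment %in% ext_comp

  groups <- split(ids[!is.na(nutrient)], nutrient[!is.na(nutrient)])

  community_model(
    species = sp_order,
    metabolites = mets,
    reactions = data.frame(id = ids, species = species,
                           subsystem = subsystem, lb = lb, ub = ub),
    stoich = S,
    biomass_objectives = objective_order,
    atp_synthase_ids = atp_ids,
    exchange_groups = groups)
}
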
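#' Community metabolic model container
#'
#' Validating constructor for the multi-species community model used by
#' [lexicographic_fba()]. Most users will obtain one from
#' [generate_toy_community()] or [read_sbml_community()].
#'
#' @param species Ordered character vector of species labels.
#' @param metabolites data.frame with columns `id`, `compartment`,
#'   `external` (logical: lives in the shared extracellular compartment).
#' @param reactions data.frame with columns `id`, `species` (NA for shared
#'   exchange reactions), `subsystem`, `lb`, `ub`.
#' @param stoich Metabolites x reactions stoichiometric matrix, dimnames
#'   matching the id columns.
#' @param biomass_objectives Ordered reaction ids: priority order of the
#'   per-species biomass objectives (`c_1` first).
#' @param atp_synthase_ids Named (by species) reaction ids of the
#'   ATP-synthase-like reactions.
#' @param exchange_groups Named list (`sugar`, `fiber`, `fat`, `protein`) of
#'   exchange reaction ids.
#' @return Object of class `community_model`.
#' @export
community_model <- function(species, metabolites, reactions, stoich,
                            biomass_objectives, atp_synthase_ids,
                            exchange_groups) {
  stopifnot(is.data.frame(metabolites), is.data.frame(reactions))
  if (ncol(stoich) != nrow(reactions))
    stop("stoich column count must equal reaction count", call. = FALSE)
  if (nrow(stoich) != nrow(metabolites))
    stop("stoich row count must equal metabolite count", call. = FALSE)
  if (!all(biomass_objectives %in% reactions$id))
    stop("every biomass objective must be a reaction id", call. = FALSE)
  ex_ids <- unlist(exchange_groups, use.names = FALSE)
  for (rid in ex_ids) {
    touched <- metabolites$id[stoich[, rid] != 0]
    if (!all(metabolites$external[match(touched, metabolites$id)]))
      stop("exchange reactions must touch only external metabolites",
           call. = FALSE)
  }
  dimnames(stoich) <- list(metabolites$id, reactions$id)
  structure(list(species = species, metabolites = metabolites,
                 reactions = reactions, stoich = stoich,
                 biomass_objectives = biomass_objectives,
                 atp_synthase_ids = atp_synthase_ids,
                 exchange_groups = exchange_groups),
            class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat("Gut community model:", length(x$species), "species,",
      nrow(x$metabolites), "metabolites,", nrow(x$reactions), "reactions\n")
  cat("  biomass priorities:", paste(x$biomass_objectives, collapse = " > "),
      "\n")
  cat("  exchange classes:",
      paste(names(x$exchange_groups), collapse = ", "), "\n")
  invisible(x)
}

# fixed subsystem vocabulary of the toy template
TOY_SUBSYSTEMS <- c(
  sugar = "Sugar transport", fiber = "Fiber degradation",
  fat = "Lipid metabolism", protein = "Protein degradation",
  atps = "Oxidative phosphorylation", glyc = "Glycolysis",
  aa = "Amino acid metabolism", bio = "Biomass",
  mnt = "Energy maintenance", ex = "Exchange")

#' Generate a toy gut-community model
#'
#' Builds a small, always-solvable community model emulating the structure of
#' a genome-scale gut reconstruction: several species share an extracellular
#' compartment with sugar, fiber, fat and protein exchange metabolites; each
#' species carries uptake reactions for every nutrient class, an
#' ATP-synthase-like reaction, amino-acid interconversion, an ATP-maintenance
#' sink and a biomass reaction, all with randomized (but
#' feasibility-guaranteed) yields and subsystem labels from a fixed
#' vocabulary. Every species can reach a biomass flux of at least 0.01 under
#' the 50/30/20 reference diet; this is checked by a lexicographic FBA solve
#' at generation time, regenerating (bounded retries) on the rare infeasible
#' draw.
#'
#' @param n_species Number of species (>= 1). The community of the motivating
#'   study has 12 ordered biomass objectives.
#' @param reactions_per_species Reactions per species; the template minimum
#'   is 8, larger values add alternative glycolytic ATP routes.
#' @param seed Optional integer seed.
#' @param species_labels Optional labels (default `sp1`, `sp2`, ...).
#' @return A [community_model()] with exchange lower bounds preset to the
#'   reference diet.
#' @examples
#' mod <- generate_toy_community(3, seed = 1)
#' mod
#' @export
generate_toy_community <- function(n_species = 12, reactions_per_species = 8,
                                   seed = NULL, species_labels = NULL) {
  if (n_species < 1) stop("n_species must be >= 1", call. = FALSE)
  if (reactions_per_species < 8)
    stop("the toy template needs >= 8 reactions per species", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  for (try in 1:20) {
    mod <- toy_community_draw(n_species, reactions_per_species, species_labels)
    ok <- tryCatch({
      prof <- lexicographic_fba(apply_diet(mod, diet_spec(50, 30, 20)))
      all(prof$objective_values >= 0.01 - 1e-9)
    }, error = function(e) FALSE)
    if (ok) return(mod)
  }
  stop("could not draw a feasible toy community in 20 attempts", call. = FALSE)
}

toy_community_draw <- function(n_species, reactions_per_species,
                               species_labels) {
  sp <- species_labels %||% paste0("sp", seq_len(n_species))
  classes <- c("sugar", "fiber", "fat", "protein")
  ext <- paste0(classes, "_e")
  mets <- data.frame(id = ext, compartment = "e", external = TRUE)
  rxns <- data.frame(id = paste0("EX_", classes), species = NA_character_,
                     subsystem = TOY_SUBSYSTEMS[["ex"]], lb = 0, ub = 1000)
  cols <- list()
  for (k in seq_along(classes))
    cols[[rxns$id[k]]] <- stats::setNames(-1, ext[k])

  bio_ids <- character(n_species)
  atps_ids <- stats::setNames(character(n_species), sp)
  for (s in seq_len(n_species)) {
    lab <- sp[s]
    m_int <- paste0(c("c_", "aa_", "atp_"), lab)
    mets <- rbind(mets, data.frame(id = m_int, compartment = lab,
                                   external = FALSE))
    cmet <- m_int[1]; amet <- m_int[2]; atp <- m_int[3]

    add <- function(id, subsystem, stoichs, lb = 0, ub = 1000) {
      rxns <<- rbind(rxns, data.frame(id = id, species = lab,
                                      subsystem = subsystem, lb = lb, ub = ub))
      cols[[id]] <<- stoichs
    }
    add(paste0("UPT_sugar_", lab), TOY_SUBSYSTEMS[["sugar"]],
        stats::setNames(c(-1, stats::runif(1, .8, 1.2)), c("sugar_e", cmet)))
    add(paste0("UPT_fiber_", lab), TOY_SUBSYSTEMS[["fiber"]],
        stats::setNames(c(-1, stats::runif(1, .3, .7)), c("fiber_e", cmet)))
    add(paste0("UPT_fat_", lab), TOY_SUBSYSTEMS[["fat"]],
        stats::setNames(c(-1, stats::runif(1, 1.5, 2.5)), c("fat_e", cmet)))
    add(paste0("UPT_protein_", lab), TOY_SUBSYSTEMS[["protein"]],
        stats::setNames(c(-1, stats::runif(1, .8, 1.2)), c("protein_e", amet)))
    atps_ids[lab] <- paste0("ATPS_", lab)
    y_atp <- stats::runif(1, 1.5, 3)
    add(atps_ids[lab], TOY_SUBSYSTEMS[["atps"]],
        stats::setNames(c(-1, y_atp), c(cmet, atp)))
    # reversible interconversion so any macronutrient mix can feed growth
    add(paste0("AAS_", lab), TOY_SUBSYSTEMS[["aa"]],
        stats::setNames(c(-1, stats::runif(1, .4, .8)), c(cmet, amet)),
        lb = -1000)
    add(paste0("MNT_", lab), TOY_SUBSYSTEMS[["mnt"]],
        stats::setNames(-1, atp))
    # biomass: carbon + amino acids + ATP drained in randomized proportions
    w <- stats::runif(3, .8, 1.2) * c(1, .5, 2)
    bio_ids[s] <- paste0("BIO_", lab)
    add(bio_ids[s], TOY_SUBSYSTEMS[["bio"]],
        stats::setNames(-w, c(cmet, amet, atp)))
    # optional extra low-yield glycolytic ATP routes
    n_extra <- reactions_per_species - 8L
    if (n_extra > 0) for (k in seq_len(n_extra))
      add(paste0("GLY", k, "_", lab), TOY_SUBSYSTEMS[["glyc"]],
          stats::setNames(c(-1, stats::runif(1, .5, min(1.4, y_atp))),
                          c(cmet, atp)))
  }

  S <- matrix(0, nrow(mets), nrow(rxns),
              dimnames = list(mets$id, rxns$id))
  for (rid in names(cols)) S[names(cols[[rid]]), rid] <- cols[[rid]]

  mod <- community_model(sp, mets, rxns, S, bio_ids, atps_ids,
                         exchange_groups = list(
                           sugar = "EX_sugar", fiber = "EX_fiber",
                           fat = "EX_fat", protein = "EX_protein"))
  apply_diet(mod, diet_spec(50, 30, 20))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
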
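#' Diet specification
#'
#' A diet is a macronutrient composition (percentages of carbohydrate, fat
#' and protein summing to 100), the share of carbohydrate taken as simple
#' sugars vs fiber, and per-class basal uptake rates `B` (the reference
#' uptake of one metabolite of that class at 100% intake; the default of 1
#' for every class is a deliberate neutral choice, survey-derived values can
#' be plugged in per class).
#'
#' @param carb_pct,fat_pct,protein_pct Percentages summing to 100.
#' @param sugar_fraction Share of carbohydrate that is sugar, in `[0, 1]`;
#'   0.5 for all diets except the Western preset (0.9436).
#' @param basal_rates Named numeric (`sugar`, `fiber`, `fat`, `protein`) or a
#'   single positive scalar recycled to all classes.
#' @return Object of class `diet_spec`.
#' @examples
#' diet_spec(34, 44, 22)
#' diet_presets()$western
#' @export
diet_spec <- function(carb_pct, fat_pct, protein_pct, sugar_fraction = 0.5,
                      basal_rates = 1) {
  p <- c(carb_pct, fat_pct, protein_pct)
  if (any(p < 0)) stop("percentages must be >= 0", call. = FALSE)
  if (abs(sum(p) - 100) > 1e-9)
    stop("percentages must sum to 100", call. = FALSE)
  if (sugar_fraction < 0 || sugar_fraction > 1)
    stop("sugar_fraction must be in [0,1]", call. = FALSE)
  cls <- c("sugar", "fiber", "fat", "protein")
  if (length(basal_rates) == 1L && is.null(names(basal_rates)))
    basal_rates <- stats::setNames(rep(basal_rates, 4), cls)
  if (!all(cls %in% names(basal_rates)) || any(basal_rates <= 0))
    stop("basal_rates must be positive and named sugar/fiber/fat/protein",
         call. = FALSE)
  structure(list(carb_pct = carb_pct, fat_pct = fat_pct,
                 protein_pct = protein_pct, sugar_fraction = sugar_fraction,
                 basal_rates = basal_rates[cls]),
            class = "diet_spec")
}

#' @export
print.diet_spec <- function(x, ...) {
  cat(sprintf("Diet: %g%% carbohydrate (%g%% sugar / %g%% fiber), %g%% fat, %g%% protein\n",
              x$carb_pct, 100 * x$sugar_fraction, 100 * (1 - x$sugar_fraction),
              x$fat_pct, x$protein_pct))
  invisible(x)
}

#' Diet presets
#'
#' The four extreme diets used to seed the population: a Western diet
#' (carbohydrate heavily skewed to sugars, 94.36% sugars / 5.64% fiber),
#' high-fat (20/60/20), high-carbohydrate (70/15/15) and high-protein
#' (20/20/60). The Western macronutrient split (50/35/15) and the other
#' preset compositions are package choices representative of each pattern.
#'
#' @param basal_rates Passed to every preset.
#' @return Named list of [diet_spec()] objects.
#' @export
diet_presets <- function(basal_rates = 1) {
  list(western = diet_spec(50, 35, 15, sugar_fraction = 0.9436,
                           basal_rates = basal_rates),
       high_fat = diet_spec(20, 60, 20, basal_rates = basal_rates),
       high_carb = diet_spec(70, 15, 15, basal_rates = basal_rates),
       high_protein = diet_spec(20, 20, 60, basal_rates = basal_rates))
}

#' Translate a diet into uptake rates
#'
#' Per-metabolite uptake rates: with macronutrient fractions `f_C`, `f_F`,
#' `f_P` (percent / 100), carbohydrate uptake is `2 f_C B` split between
#' sugar (`sugar_fraction`) and fiber, while fats and proteins are
#' `2 f_F B` and `2 f_P B` (the doubling re-scales them against the
#' sugar/fiber split of the carbohydrates). At the default 50/50 split each
#' carbohydrate metabolite therefore receives `f_C * B`. Uptake enters the
#' model as a negative exchange flux, so exchange lower bounds are set to
#' `-A_u`.
#'
#' @param diet A [diet_spec()].
#' @return List with `uptake` (named vector: sugar, fiber, fat, protein) and
#'   `exchange_lb` (its negative).
#' @examples
#' diet_uptake_bounds(diet_spec(34, 44, 22))$uptake  # 0.34 0.34 0.88 0.44
#' @export
diet_uptake_bounds <- function(diet) {
  stopifnot(inherits(diet, "diet_spec"))
  B <- diet$basal_rates
  fC <- diet$carb_pct / 100; fF <- diet$fat_pct / 100
  fP <- diet$protein_pct / 100
  u <- c(sugar = 2 * fC * B[["sugar"]] * diet$sugar_fraction,
         fiber = 2 * fC * B[["fiber"]] * (1 - diet$sugar_fraction),
         fat = 2 * fF * B[["fat"]],
         protein = 2 * fP * B[["protein"]])
  list(uptake = u, exchange_lb = -u)
}

#' Apply a diet to a community model
#'
#' Sets the lower bounds of the exchange reactions of each nutrient class to
#' the negated uptake rates from [diet_uptake_bounds()].
#'
#' @param model A [community_model()].
#' @param diet A [diet_spec()].
#' @return The model with updated exchange bounds.
#' @export
apply_diet <- function(model, diet) {
  bl <- diet_uptake_bounds(diet)
  for (cls in names(model$exchange_groups)) {
    ids <- model$exchange_groups[[cls]]
    model$reactions$lb[model$reactions$id %in% ids] <- bl$exchange_lb[[cls]]
  }
  model
}

# Bounded LP front end: max/min obj'v s.t. S v = 0, extra_A v >= extra_b,
# lb <= v <= ub, dispatched to the package's two-phase simplex (see lp.R).
solve_lp <- function(obj, S, lb, ub, extra_A = NULL, extra_b = NULL,
                     maximize = TRUE) {
  if (!is.null(extra_A)) extra_A <- matrix(extra_A, ncol = length(obj))
  simplex_lp(obj, Aeq = S, beq = rep(0, nrow(S)),
             Age = extra_A, bge = extra_b,
             lb = lb, ub = ub, maximize = maximize)
}

#' Lexicographic (multi-level) flux balance analysis
#'
#' Solves the ordered sequence of biomass objectives `c_1, ..., c_S`: each
#' level maximizes one species' biomass flux subject to steady state
#' (`Lambda v = 0` on internal metabolites), flux bounds, a minimal growth
#' constraint (biomass lower bounds raised to `min_biomass`), and all
#' earlier optima preserved within `tolerance` (`c_k . v >= opt_k - tol`,
#' an equality-with-tolerance that is kinder to the solver than a hard fix).
#' Earlier priorities therefore pre-empt shared substrates; later species
#' optimize over the residual.
#'
#' @param model A [community_model()] with exchange bounds already set
#'   (see [apply_diet()]).
#' @param tolerance Slack allowed on earlier optima (default 1e-6).
#' @param min_biomass Minimal growth enforced on every biomass reaction
#'   (default 0.01).
#' @return Object of class `flux_profile`: `flux` (named per-reaction
#'   vector from the final level) and `objective_values` (named per-priority
#'   optima).
#' @examples
#' mod <- generate_toy_community(2, seed = 1)
#' lexicographic_fba(mod)
#' @export
lexicographic_fba <- function(model, tolerance = 1e-6, min_biomass = 0.01) {
  rx <- model$reactions
  lb <- rx$lb; ub <- rx$ub
  is_bio <- rx$id %in% model$biomass_objectives
  lb[is_bio] <- pmax(lb[is_bio], min_biomass)
  # every compartment metabolite is balanced; the exchange reactions are the
  # boundary, so the truly external pools (free xdot) stay outside the matrix
  S_all <- model$stoich
  n <- nrow(rx)
  opts <- numeric(0)
  extra_A <- NULL; extra_b <- NULL
  x <- NULL
  for (k in seq_along(model$biomass_objectives)) {
    obj <- as.numeric(rx$id == model$biomass_objectives[k])
    sol <- solve_lp(obj, S_all, lb, ub, extra_A, extra_b, maximize = TRUE)
    if (sol$status != "optimal")
      stop(structure(class = c("gutplex_infeasible", "error", "condition"),
                     list(message = sprintf(
                       "lexicographic FBA infeasible at priority %d (%s)",
                       k, model$biomass_objectives[k]),
                       call = NULL, priority = k,
                       objective = model$biomass_objectives[k])))
    opts[k] <- sol$value
    x <- sol$x
    extra_A <- rbind(extra_A, obj)
    extra_b <- c(extra_b, sol$value - tolerance)
  }
  structure(list(flux = stats::setNames(x, rx$id),
                 objective_values = stats::setNames(
                   opts, model$biomass_objectives)),
            class = "flux_profile")
}

#' @export
print.flux_profile <- function(x, ...) {
  cat("Flux profile:", length(x$flux), "reactions\n")
  cat("  priority optima:\n")
  print(round(x$objective_values, 6))
  invisible(x)
}

#' Steady-state residual of a flux profile
#'
#' Maximum absolute net production over internal metabolites; should be at
#' solver tolerance for any returned profile.
#'
#' @param model A [community_model()].
#' @param profile A [lexicographic_fba()] result.
#' @return Scalar residual.
#' @export
steady_state_residual <- function(model, profile) {
  S_int <- model$stoich[!model$metabolites$external, , drop = FALSE]
  max(abs(S_int %*% profile$flux[colnames(S_int)]))
}

#' Write flux profiles as CSV
#'
#' Columns: reaction, species, subsystem, flux.
#'
#' @param profile A `flux_profile`.
#' @param model The model it was solved on.
#' @param path Output file.
#' @export
write_flux_csv <- function(profile, model, path) {
  utils::write.csv(data.frame(reaction = model$reactions$id,
                              species = model$reactions$species,
                              subsystem = model$reactions$subsystem,
                              flux = as.numeric(profile$flux)),
                   path, row.names = FALSE)
  invisible(path)
}
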
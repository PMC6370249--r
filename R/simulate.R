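#' Simulation configuration
#'
#' Collects every tunable of the coupled simulation with the study's default
#' conditions: 100 nodes on 2 scale-free layers, snowdrift payoffs
#' `b = 1, c = 0.8`, selection intensity `K = 0.1`, estimator floors 0.1,
#' similarity floors 0.05, 100 Monte Carlo sweeps per epoch and 4 feedback
#' rounds after the baseline epoch, a 12-species toy community, unit basal
#' uptake rates and a 50/50 sugar/fiber split outside the Western preset.
#'
#' @param n_nodes,n_layers,attachment,coupling_weight Network structure; see
#'   [build_multiplex()].
#' @param homophily_mean,homophily_sigma Attribute distribution; see
#'   [assign_homophily()].
#' @param delta_floor,delta_scale Homophily coupling; see [delta_matrix()].
#' @param b,c,K,eta_max,eta_min,psi_max,psi_min Game constants; see
#'   [game_params()].
#' @param init_coop_fraction Initial cooperator probability.
#' @param use_eta,use_psi,use_theta,use_delta Estimator/similarity switches
#'   (all on by default; turning one off fixes its factor at 1 for
#'   well-mixed control runs).
#' @param gamma_th,n_rounds_per_epoch,n_feedback_rounds,gamma_mode Feedback
#'   loop; see [feedback_params()].
#' @param n_species,reactions_per_species Toy community size; see
#'   [generate_toy_community()].
#' @param theta_floor Gut-similarity floor; see [flux_distance_matrix()].
#' @param basal_rates,sugar_fraction Diet construction; see [diet_spec()].
#' @param n_preset_nodes How many nodes start on the four extreme diet
#'   presets (cycled); the rest draw uniform random compositions on the
#'   integer simplex.
#' @param fba_tolerance,min_biomass See [lexicographic_fba()].
#' @param model Optional pre-built [community_model()] (e.g. from
#'   [read_sbml_community()]); overrides the toy generator.
#' @param seed Master seed; the whole trajectory is a pure function of the
#'   configuration and this seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_nodes = 100, n_layers = 2, attachment = 2,
                       coupling_weight = 1,
                       homophily_mean = 5, homophily_sigma = 1,
                       delta_floor = 0.05, delta_scale = NULL,
                       b = 1, c = 0.8, K = 0.1,
                       eta_max = 1, eta_min = 0.1,
                       psi_max = 1, psi_min = 0.1,
                       init_coop_fraction = 0.5,
                       use_eta = TRUE, use_psi = TRUE,
                       use_theta = TRUE, use_delta = TRUE,
                       gamma_th = 0.5, n_rounds_per_epoch = 100,
                       n_feedback_rounds = 4,
                       gamma_mode = "behavioral",
                       n_species = 12, reactions_per_species = 8,
                       theta_floor = 0.05,
                       basal_rates = 1, sugar_fraction = 0.5,
                       n_preset_nodes = 4,
                       fba_tolerance = 1e-6, min_biomass = 0.01,
                       model = NULL, seed = 1) {
  cfg <- as.list(environment())
  cfg$game <- game_params(b, c, K, eta_max, eta_min, psi_max, psi_min)
  cfg$feedback <- feedback_params(gamma_th, n_rounds_per_epoch,
                                  n_feedback_rounds, gamma_mode)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_nodes, "nodes x", x$n_layers, "layers;",
      x$n_species, "species;", x$feedback$n_rounds_per_epoch,
      "rounds/epoch;", x$feedback$n_feedback_rounds, "feedback rounds\n")
  invisible(x)
}

uniform_simplex_diet <- function(sugar_fraction, basal_rates) {
  d <- sort(sample.int(102L, 2L))          # stars and bars over 100 units
  diet_spec(d[1] - 1L, d[2] - d[1] - 1L, 102L - d[2],
            sugar_fraction = sugar_fraction, basal_rates = basal_rates)
}

diet_key <- function(diet)
  paste(diet$carb_pct, diet$fat_pct, diet$protein_pct, diet$sugar_fraction,
        sep = "_")

solve_diets <- function(model, diets, cache, tolerance, min_biomass) {
  profiles <- NULL
  for (i in seq_along(diets)) {
    key <- diet_key(diets[[i]])
    if (is.null(cache[[key]])) {
      pr <- lexicographic_fba(apply_diet(model, diets[[i]]),
                              tolerance = tolerance,
                              min_biomass = min_biomass)
      cache[[key]] <- pr$flux
    }
    if (is.null(profiles))
      profiles <- matrix(0, length(diets), length(cache[[key]]),
                         dimnames = list(NULL, names(cache[[key]])))
    profiles[i, ] <- cache[[key]]
  }
  profiles
}

#' Initialize the coupled simulation
#'
#' Builds the multiplex and its communicability, draws homophily attributes
#' and diets (presets plus random compositions), solves the community model
#' per distinct diet, computes the gut similarity and the initial Ward
#' clustering, and starts every node with happiness 0 and empty MA/MI
#' counters.
#'
#' @param config A [sim_config()].
#' @return A simulation state list (see [run_simulation()]).
#' @export
initialize_simulation <- function(config) {
  set.seed(config$seed)
  mx <- build_multiplex(config$n_nodes, config$n_layers, config$attachment,
                        config$coupling_weight)
  mx <- assign_homophily(mx, config$homophily_mean, config$homophily_sigma)
  G <- if (config$use_eta) communicability(mx) else NULL
  delta <- if (config$use_delta)
    delta_matrix(mx$homophily, config$delta_floor, config$delta_scale)
  else NULL

  model <- config$model %||%
    generate_toy_community(config$n_species, config$reactions_per_species)

  presets <- diet_presets(config$basal_rates)
  diets <- vector("list", config$n_nodes)
  for (i in seq_len(config$n_nodes)) {
    diets[[i]] <- if (i <= config$n_preset_nodes)
      presets[[(i - 1L) %% length(presets) + 1L]]
    else uniform_simplex_diet(config$sugar_fraction, config$basal_rates)
  }

  cache <- new.env(parent = emptyenv())
  profiles <- solve_diets(model, diets, cache,
                          config$fba_tolerance, config$min_biomass)
  gd <- flux_distance_matrix(profiles, floor = config$theta_floor)
  dendro <- ward_clustering(gd)
  state <- list(
    config = config, multiplex = mx, G = G, delta = delta, model = model,
    diets = diets, profiles = profiles,
    theta = if (config$use_theta) gd$theta else NULL,
    dendro = dendro, labels = cut_clusters(dendro),
    game = game_state(config$n_nodes, config$init_coop_fraction),
    gamma = numeric(config$n_nodes),
    fba_cache = cache)
  state
}

node_flux_score <- function(state) {
  ids <- c(state$model$biomass_objectives,
           unname(state$model$atp_synthase_ids))
  rowSums(state$profiles[, ids, drop = FALSE])
}

#' Run the coupled social-metabolic simulation
#'
#' Executes the full procedure: a baseline epoch of `N_r` Monte Carlo sweeps
#' of the iterated snowdrift game, then `n_feedback_rounds` feedback rounds,
#' each of which (i) turns every node's cooperation record into a happiness
#' index, (ii) amplifies its MA or MI counters by the gut bias, (iii)
#' perturbs its diet within `(1 - gamma) * 10` percentage points, (iv)
#' re-solves the community model per distinct diet, and (v) recomputes the
#' gut similarity and the Ward clustering, before the next epoch of play.
#'
#' @param config A [sim_config()], or a state from
#'   [initialize_simulation()].
#' @return Object of class `gutplex_sim`: list with `epochs` (one record per
#'   epoch: `rho_series`, `gamma`, `cluster_labels`, `diets` matrix,
#'   `profiles`, `dendro`), the final `state` and the `config`.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_nodes = 20, n_species = 2, n_rounds_per_epoch = 20,
#'                   n_feedback_rounds = 2, seed = 1)
#' sim <- run_simulation(cfg)
#' sim
#' }
#' @export
run_simulation <- function(config) {
  state <- if (inherits(config, "sim_config"))
    initialize_simulation(config) else config
  config <- state$config
  fp <- config$feedback
  n_epochs <- fp$n_feedback_rounds + 1L
  epochs <- vector("list", n_epochs)

  for (e in seq_len(n_epochs)) {
    state$game$coop_history <-
      matrix(numeric(0), 0, config$n_nodes)       # fresh epoch record
    rho <- numeric(fp$n_rounds_per_epoch)
    for (t in seq_len(fp$n_rounds_per_epoch)) {
      state$game <- monte_carlo_step(
        state$game, state$multiplex, state$G, config$game,
        theta = state$theta, delta = state$delta,
        use_eta = config$use_eta, use_psi = config$use_psi)
      rho[t] <- record_density(state$game)
    }
    state$gamma <- happiness_index(state$game$coop_history)

    epochs[[e]] <- list(
      epoch = e - 1L,
      rho_series = rho,
      gamma = state$gamma,
      cluster_labels = state$labels,
      diets = t(vapply(state$diets, function(d)
        c(carb = d$carb_pct, fat = d$fat_pct, protein = d$protein_pct),
        numeric(3))),
      profiles = state$profiles,
      dendro = state$dendro)

    if (e < n_epochs) {
      out <- feedback_outcome(state$gamma, state$game$ma, state$game$mi,
                              fp, flux_score = if (fp$gamma_mode == "blended")
                                node_flux_score(state) else NULL)
      amp <- apply_gut_feedback(out, state$game$ma, state$game$mi)
      state$game$ma <- amp$ma; state$game$mi <- amp$mi
      state$diets <- lapply(seq_along(state$diets), function(i)
        perturb_diet(state$diets[[i]], out$gamma[i]))
      state$profiles <- solve_diets(state$model, state$diets,
                                    state$fba_cache, config$fba_tolerance,
                                    config$min_biomass)
      gd <- flux_distance_matrix(state$profiles,
                                 floor = config$theta_floor)
      if (config$use_theta) state$theta <- gd$theta
      state$dendro <- ward_clustering(gd)
      state$labels <- cut_clusters(state$dendro)
      epochs[[e]]$feedback <- out
    }
  }
  structure(list(epochs = epochs, state = state, config = config),
            class = "gutplex_sim")
}

#' @export
print.gutplex_sim <- function(x, ...) {
  cat("Coupled social-metabolic simulation:", length(x$epochs), "epochs",
      sprintf("(baseline + %d feedback rounds)\n",
              x$config$feedback$n_feedback_rounds))
  for (ep in x$epochs)
    cat(sprintf(
      "  epoch %d: mean rho %.3f (final %.3f), mean gamma %.3f, %d clusters\n",
      ep$epoch, mean(ep$rho_series), ep$rho_series[length(ep$rho_series)],
      mean(ep$gamma), length(unique(ep$cluster_labels))))
  invisible(x)
}

#' @export
summary.gutplex_sim <- function(object, steady_window = 0.2, ...) {
  df <- do.call(rbind, lapply(object$epochs, function(ep) {
    n <- length(ep$rho_series)
    w <- seq.int(ceiling(n * (1 - steady_window)) + 1L, n)
    data.frame(epoch = ep$epoch,
               mean_rho = mean(ep$rho_series),
               steady_rho = mean(ep$rho_series[w]),
               mean_gamma = mean(ep$gamma),
               n_clusters = length(unique(ep$cluster_labels)))
  }))
  class(df) <- c("summary.gutplex_sim", "data.frame")
  df
}

#' @export
plot.gutplex_sim <- function(x, ...) {
  ne <- length(x$epochs)
  oldpar <- graphics::par(mfrow = c(1, ne), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  for (ep in x$epochs) {
    plot(ep$rho_series, type = "l", ylim = c(0, 1),
         xlab = "round", ylab = expression(rho),
         main = if (ep$epoch == 0) "baseline"
         else paste("feedback round", ep$epoch), ...)
    graphics::abline(h = mean(ep$rho_series), lty = 3)
  }
  invisible(x)
}

#' Write per-epoch feedback reports
#'
#' One CSV row per node and feedback round: happiness, gut bias, branch
#' sign, and the diet before and after the perturbation.
#'
#' @param sim A [run_simulation()] result.
#' @param path Output CSV.
#' @export
write_feedback_report <- function(sim, path) {
  eps <- sim$epochs
  rows <- do.call(rbind, lapply(seq_len(length(eps) - 1L), function(e) {
    out <- eps[[e]]$feedback
    data.frame(epoch = eps[[e]]$epoch, node = seq_along(out$gamma),
               gamma = out$gamma, epsilon = out$epsilon, sign = out$sign,
               old_carb = eps[[e]]$diets[, "carb"],
               old_fat = eps[[e]]$diets[, "fat"],
               old_protein = eps[[e]]$diets[, "protein"],
               new_carb = eps[[e + 1]]$diets[, "carb"],
               new_fat = eps[[e + 1]]$diets[, "fat"],
               new_protein = eps[[e + 1]]$diets[, "protein"])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write simulation outputs to a directory
#'
#' Emits `rho_series.csv` (epoch, round, rho), `gamma.csv`, `clusters.csv`,
#' `diets.csv` (per epoch and node), one `fluxes/epoch_<k>.csv` per epoch,
#' one Newick dendrogram per epoch and, when the `yaml` package is
#' installed, `resolved_config.yaml`.
#'
#' @param sim A [run_simulation()] result.
#' @param dir Output directory (created if needed).
#' @export
write_simulation_outputs <- function(sim, dir) {
  dir.create(file.path(dir, "fluxes"), recursive = TRUE, showWarnings = FALSE)
  rho <- do.call(rbind, lapply(sim$epochs, function(ep)
    data.frame(epoch = ep$epoch, round = seq_along(ep$rho_series),
               rho = ep$rho_series)))
  utils::write.csv(rho, file.path(dir, "rho_series.csv"), row.names = FALSE)
  per_node <- function(field) do.call(rbind, lapply(sim$epochs, function(ep)
    data.frame(epoch = ep$epoch, node = seq_along(ep[[field]]),
               value = ep[[field]])))
  g <- per_node("gamma"); names(g)[3] <- "gamma"
  utils::write.csv(g, file.path(dir, "gamma.csv"), row.names = FALSE)
  cl <- per_node("cluster_labels"); names(cl)[3] <- "cluster"
  utils::write.csv(cl, file.path(dir, "clusters.csv"), row.names = FALSE)
  diets <- do.call(rbind, lapply(sim$epochs, function(ep)
    data.frame(epoch = ep$epoch, node = seq_len(nrow(ep$diets)), ep$diets)))
  utils::write.csv(diets, file.path(dir, "diets.csv"), row.names = FALSE)
  for (ep in sim$epochs) {
    utils::write.csv(
      data.frame(node = rep(seq_len(nrow(ep$profiles)), ncol(ep$profiles)),
                 reaction = rep(colnames(ep$profiles),
                                each = nrow(ep$profiles)),
                 flux = as.numeric(ep$profiles)),
      file.path(dir, "fluxes", sprintf("epoch_%d.csv", ep$epoch)),
      row.names = FALSE)
    write_newick(ep$dendro,
                 file.path(dir, sprintf("dendrogram_epoch_%d.nwk", ep$epoch)))
  }
  if (length(sim$epochs) > 1L)
    write_feedback_report(sim, file.path(dir, "feedback_report.csv"))
  if (requireNamespace("yaml", quietly = TRUE)) {
    cfg <- sim$config
    cfg$model <- NULL; cfg$game <- NULL; cfg$feedback <- NULL
    yaml::write_yaml(cfg, file.path(dir, "resolved_config.yaml"))
  }
  invisible(dir)
}
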
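small_cfg <- function(seed = 1, ...)
  sim_config(n_nodes = 16, n_species = 2, n_rounds_per_epoch = 12,
             n_feedback_rounds = 2, attachment = 2, seed = seed, ...)

test_that("initialization follows the opening procedure", {
  state <- initialize_simulation(small_cfg())
  expect_equal(state$multiplex$n_nodes, 16L)
  expect_equal(state$multiplex$n_layers, 2L)
  # happiness starts at zero, counters empty
  expect_equal(state$gamma, rep(0, 16))
  expect_equal(state$game$ma, rep(0, 16))
  expect_equal(state$game$mi, rep(0, 16))
  # per-node diets with presets on the first nodes
  expect_length(state$diets, 16)
  expect_equal(state$diets[[1]]$sugar_fraction, 0.9436)   # Western preset
  sums <- vapply(state$diets, function(d)
    d$carb_pct + d$fat_pct + d$protein_pct, numeric(1))
  expect_true(all(sums == 100))
  # initial FBA, similarity and clustering are in place
  expect_equal(nrow(state$profiles), 16)
  expect_true(all(diag(state$theta) == 1))
  expect_length(state$labels, 16)
})

test_that("identical diets give full similarity and one cluster", {
  cfg <- small_cfg(n_preset_nodes = 0)
  state <- initialize_simulation(cfg)
  same <- diet_spec(50, 30, 20)
  state$diets <- rep(list(same), 16)
  state$profiles <- gutplex:::solve_diets(state$model, state$diets,
                                          state$fba_cache, 1e-6, 0.01)
  gd <- flux_distance_matrix(state$profiles)
  expect_true(all(gd$theta == 1))
  expect_equal(length(unique(cut_clusters(ward_clustering(gd)))), 1)
})

test_that("a full run records every epoch and is a pure function of the seed", {
  cfg <- small_cfg(seed = 5)
  sim <- run_simulation(cfg)
  expect_s3_class(sim, "gutplex_sim")
  expect_length(sim$epochs, 3)     # baseline + 2 feedback rounds
  for (ep in sim$epochs) {
    expect_length(ep$rho_series, 12)
    expect_true(all(ep$rho_series >= 0 & ep$rho_series <= 1))
    expect_length(ep$gamma, 16)
    expect_true(all(ep$gamma >= 0 & ep$gamma <= 1))
    expect_true(all(rowSums(ep$diets) == 100))   # conservation
    expect_equal(nrow(ep$profiles), 16)
  }
  sim2 <- run_simulation(cfg)
  expect_identical(lapply(sim$epochs, `[[`, "rho_series"),
                   lapply(sim2$epochs, `[[`, "rho_series"))
  expect_identical(sim$state$game$strategies, sim2$state$game$strategies)
  # node count never changes
  expect_equal(unique(vapply(sim$epochs, function(e) nrow(e$diets),
                             numeric(1))), 16)
})

test_that("cooperation density is the cooperator fraction", {
  expect_equal(record_density(rep(1, 10)), 1)
  expect_equal(record_density(rep(0, 10)), 0)
  expect_equal(record_density(c(rep(1, 33), rep(0, 67))), 0.33)
  expect_equal(record_density(list(strategies = c(1, 0))), 0.5)
})

test_that("feedback rounds amplify counters and perturb diets coherently", {
  cfg <- small_cfg(seed = 9)
  sim <- run_simulation(cfg)
  out <- sim$epochs[[1]]$feedback
  expect_s3_class(out, "feedback_outcome")
  expect_true(all((out$sign == "positive") == (out$gamma >= 0.5)))
  expect_true(all(out$epsilon >= 0))
  # diets moved within the allowed half-width between epochs 0 and 1
  w <- (1 - out$gamma) * 10
  d0 <- sim$epochs[[1]]$diets; d1 <- sim$epochs[[2]]$diets
  expect_true(all(abs(d1 - d0) <= w + 1e-9))
})

test_that("degenerate well-mixed runs approach the snowdrift equilibrium", {
  # complete graph, all similarity and bias factors disabled
  rho_star <- 1 - 0.8 / (2 - 0.8)
  p <- game_params(b = 1, c = 0.8, K = 0.05)
  res <- vapply(1:4, function(s) {
    set.seed(s)
    mx <- complete_multiplex(40)
    st <- game_state(40, 0.5)
    rho <- numeric(80)
    for (t in 1:80) {
      st <- monte_carlo_step(st, mx, NULL, p,
                             use_eta = FALSE, use_psi = FALSE)
      rho[t] <- record_density(st)
    }
    mean(rho[61:80])
  }, numeric(1))
  expect_equal(mean(res), rho_star, tolerance = 0.1)
})

test_that("simulation outputs serialize to the documented files", {
  sim <- run_simulation(small_cfg(seed = 2))
  dir <- withr::local_tempdir()
  write_simulation_outputs(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "rho_series.csv", "gamma.csv", "clusters.csv", "diets.csv",
    "dendrogram_epoch_0.nwk", "fluxes/epoch_0.csv")))))
  rho <- utils::read.csv(file.path(dir, "rho_series.csv"))
  expect_equal(nrow(rho), 3 * 12)
  expect_true(all(rho$rho >= 0 & rho$rho <= 1))
})

test_that("game traces and feedback reports serialize with the documented columns", {
  mx <- build_multiplex(12, 2, seed = 3)
  G <- communicability(mx)
  set.seed(1)
  st <- game_state(12, 0.5)
  traces <- list()
  for (r in 1:3) {
    st <- monte_carlo_step(st, mx, G, game_params(), trace = TRUE)
    traces[[r]] <- st$trace
  }
  f <- withr::local_tempfile(fileext = ".tsv")
  write_game_log(traces, f)
  log <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_setequal(names(log), c("round", "node", "strategy", "payoff",
                                "ma", "mi", "eta", "psi"))
  expect_true(all(log$eta >= 0.1 - 1e-9 & log$eta <= 1 + 1e-9))
  expect_true(all(log$psi >= 0.1 - 1e-9 & log$psi <= 1 + 1e-9))
  # tracing does not perturb the trajectory
  set.seed(1)
  st2 <- game_state(12, 0.5)
  for (r in 1:3) st2 <- monte_carlo_step(st2, mx, G, game_params())
  expect_identical(st$strategies, st2$strategies)

  sim <- run_simulation(small_cfg(seed = 4))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_feedback_report(sim, f2)
  rep <- utils::read.csv(f2)
  expect_equal(nrow(rep), 2 * 16)      # one row per node and feedback round
  expect_true(all(rep$sign %in% c("positive", "negative")))
  expect_true(all(rep$new_carb + rep$new_fat + rep$new_protein == 100))
})
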
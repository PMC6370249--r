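test_that("diet specs validate composition and presets carry the sugar split", {
  expect_error(diet_spec(50, 30, 30), "sum to 100")
  expect_error(diet_spec(-10, 60, 50), ">= 0")
  expect_error(diet_spec(50, 30, 20, sugar_fraction = 1.2), "sugar_fraction")
  w <- diet_presets()$western
  expect_equal(w$sugar_fraction, 0.9436)
  d <- diet_spec(34, 44, 22)
  expect_equal(d$carb_pct + d$fat_pct + d$protein_pct, 100)
})

test_that("diet uptake bounds follow the macronutrient scaling rule", {
  # 34/44/22 with unit basal rates: per-metabolite uptakes 0.34 / 0.88 / 0.44
  u <- diet_uptake_bounds(diet_spec(34, 44, 22))$uptake
  expect_equal(unname(u["sugar"]), 0.34)
  expect_equal(unname(u["fiber"]), 0.34)
  expect_equal(unname(u["fat"]), 0.88)
  expect_equal(unname(u["protein"]), 0.44)
  # fats and proteins carry the doubling factor relative to carbohydrates
  expect_equal(unname(u["fat"] / 0.44), 2)
  expect_equal(unname(u["protein"] / 0.22), 2)

  # Western preset: carbohydrate split 94.36% sugars / 5.64% fiber
  uw <- diet_uptake_bounds(diet_presets()$western)$uptake
  expect_equal(unname(uw["sugar"] / (uw["sugar"] + uw["fiber"])), 0.9436)
  expect_equal(unname(uw["fiber"] / (uw["sugar"] + uw["fiber"])), 0.0564)

  # pure-carbohydrate diet: fat and protein uptakes vanish
  u0 <- diet_uptake_bounds(diet_spec(100, 0, 0))$uptake
  expect_equal(unname(u0[c("fat", "protein")]), c(0, 0))

  # uptake enters as a negative exchange lower bound
  mod <- single_route_model()
  mod2 <- apply_diet(mod, diet_spec(100, 0, 0))
  expect_equal(mod2$reactions$lb[mod2$reactions$id == "EX_sugar"], -1)
})

test_that("single linear route optimum equals yield times uptake", {
  for (u in c(0.5, 2)) for (y in c(0.25, 0.8)) {
    mod <- single_route_model(u = u, y = y)
    pr <- lexicographic_fba(mod, min_biomass = 0)
    expect_equal(unname(pr$objective_values), y * u, tolerance = 1e-8)
    expect_lte(steady_state_residual(mod, pr), 1e-6)
  }
})

test_that("priority order pre-empts a shared substrate", {
  mod <- two_species_competition(u = 1, y1 = 1, y2 = 0.8)
  pr <- lexicographic_fba(mod, min_biomass = 0)
  # priority 1 takes the whole substrate; priority 2 gets the residual
  expect_equal(unname(pr$objective_values["BIO_sp1"]), 1, tolerance = 1e-6)
  expect_equal(unname(pr$objective_values["BIO_sp2"]), 0, tolerance = 1e-5)
  # with a minimal growth floor, priority 2 is held at the floor
  pr2 <- lexicographic_fba(mod)
  expect_equal(unname(pr2$objective_values["BIO_sp2"]), 0.01,
               tolerance = 1e-3)   # held at the floor up to the level slack
  expect_true(all(pr2$objective_values >= 0.01 - 1e-9))
})

test_that("lexicographic optima match the vertex-enumeration oracle", {
  # fixed tiny instances
  for (mod in list(single_route_model(2, 0.5),
                   two_species_competition(1, 1, 0.8))) {
    expect_equal(unname(lexicographic_fba(mod)$objective_values),
                 unname(enum_lex_fba(mod)), tolerance = 1e-6)
  }
  # randomized 1-2 species toy draws (<= 10 reactions within each check)
  for (seed in 1:3) {
    mod <- two_species_competition(u = stats::runif(1, 0.5, 2),
                                   y1 = stats::runif(1, 0.5, 1.5),
                                   y2 = stats::runif(1, 0.5, 1.5))
    expect_equal(unname(lexicographic_fba(mod)$objective_values),
                 unname(enum_lex_fba(mod)), tolerance = 1e-6)
  }
})

test_that("relaxing the inter-level tolerance never lowers later optima", {
  mod <- two_species_competition(u = 1, y1 = 1, y2 = 0.8)
  tight <- lexicographic_fba(mod, tolerance = 1e-8)
  loose <- lexicographic_fba(mod, tolerance = 1e-3)
  expect_gte(loose$objective_values[["BIO_sp2"]],
             tight$objective_values[["BIO_sp2"]] - 1e-9)
})

test_that("toy community draws are feasible, labeled and solvable at any seed", {
  for (seed in c(1, 7, 99)) {
    mod <- generate_toy_community(3, seed = seed)
    pr <- lexicographic_fba(mod)
    expect_true(all(pr$objective_values >= 0.01 - 1e-9))
    expect_lte(steady_state_residual(mod, pr), 1e-6)
    expect_true(all(mod$reactions$subsystem %in% gutplex:::TOY_SUBSYSTEMS))
    # lexicographic consistency: re-optimizing level k with earlier levels
    # fixed reproduces its optimum
    pr2 <- lexicographic_fba(mod)
    expect_equal(pr$objective_values, pr2$objective_values, tolerance = 1e-6)
  }
  # community of the reference size
  mod12 <- generate_toy_community(12, seed = 3)
  expect_length(mod12$species, 12)
  expect_length(mod12$biomass_objectives, 12)
  expect_error(generate_toy_community(0), "n_species")

  # the smallest instance is a hand-checkable single-species model
  mod1 <- generate_toy_community(1, seed = 2)
  pr1 <- lexicographic_fba(mod1)
  expect_length(pr1$objective_values, 1)
  expect_gte(pr1$objective_values[[1]], 0.01)
})

test_that("raising carbohydrate never hurts a sugar-limited priority-1 species", {
  # minimal instance: biomass consumes only sugar-derived carbon
  mod <- single_route_model(u = 1, y = 0.5)
  prev <- -Inf
  for (carb in c(20, 40, 60, 80)) {
    m <- apply_diet(mod, diet_spec(carb, (100 - carb) / 2, (100 - carb) / 2))
    val <- lexicographic_fba(m, min_biomass = 0)$objective_values[[1]]
    expect_gte(val, prev - 1e-9)
    prev <- val
  }
})

test_that("infeasible models produce a structured diagnosis", {
  mod <- two_species_competition(u = 1e-4, y1 = 1, y2 = 0.8)
  err <- tryCatch(lexicographic_fba(mod), error = function(e) e)
  expect_s3_class(err, "gutplex_infeasible")
  expect_match(conditionMessage(err), "priority 1")
})
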
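decay_model <- function(rate = -1) {
  terms <- esindy:::ode_term_set(1, 1, FALSE, "x")
  sparse_model(matrix(c(0, rate), 2, 1), terms, "x")
}

test_that("simulate_model matches closed forms and handles empty models", {
  U <- simulate_model(decay_model(), x0 = 1, t_grid = c(0, 1))
  expect_equal(unname(U[2, 1]), exp(-1), tolerance = 1e-6)

  empty <- decay_model(rate = 0)
  empty$Xi[] <- 0
  empty <- sparse_model(empty$Xi, empty$terms, "x")
  U2 <- simulate_model(empty, x0 = 3, t_grid = seq(0, 2, 0.5))
  expect_true(all(U2 == 3))
})

test_that("explosive models are truncated and flagged divergent", {
  terms <- esindy:::ode_term_set(1, 3, FALSE, "x")
  grow <- sparse_model(matrix(c(0, 0, 0, 5), 4, 1), terms, "x")  # dx/dt = 5 x^3
  U <- simulate_model(grow, x0 = 10, t_grid = seq(0, 5, 0.1))
  expect_true(attr(U, "divergent"))
  expect_true(anyNA(U))
})

test_that("recovered clean-Lorenz model shadows the truth over a short horizon", {
  fit <- stridge(lorenz_library(), regression_config(lambda1 = 0.1))
  tgrid <- seq(0, 0.5, by = 0.01)
  sim_fit <- simulate_model(fit, x0 = c(-8, 8, 27), t_grid = tgrid)
  sim_true <- simulate_model(true_model(lorenz_spec()), x0 = c(-8, 8, 27),
                             t_grid = tgrid)
  expect_lt(max(abs(sim_fit - sim_true)), 0.1)
})

test_that("degenerate ensembles give zero-width bands; bands are ordered", {
  terms <- esindy:::ode_term_set(1, 1, FALSE, "x")
  Xi <- matrix(c(0, -0.5), 2, 1)
  em <- esindy:::new_ensemble_model(
    members = replicate(8, Xi, simplify = FALSE),
    availability = matrix(TRUE, 8, 2), inclusion = (Mod(Xi) > 0) * 1,
    aggregate = sparse_model(Xi, terms, "x"), terms = terms, names = "x",
    econf = ensemble_config(q = 8L))
  band <- ensemble_forecast(em, x0 = 2, t_grid = seq(0, 1, 0.1),
                            n_realizations = 50, models_per_draw = 3,
                            seed = 1)
  expect_equal(band$lower, band$upper, tolerance = 1e-12)
  expect_true(all(band$lower <= band$median & band$median <= band$upper))
  expect_equal(band$median[, 1], 2 * exp(-0.5 * band$t), tolerance = 1e-3)
})

test_that("95% ensemble bands cover most of a clean trajectory on noisy LV fits", {
  spec <- system_spec("lotka_volterra")
  clean <- simulate_system(spec, m = 400)
  noisy <- add_noise(clean, 0.02, seed = 21)
  lib <- build_ode_library(noisy, 2, deriv_method = "smoothed")
  em <- fit_ensemble(lib, ensemble_config(q = 60L, seed = 22),
                     regression_config(lambda1 = 0.05))
  horizon <- seq(0, 10, by = 0.25)
  band <- ensemble_forecast(em, x0 = clean$U[1, ], t_grid = horizon,
                            n_realizations = 300, models_per_draw = 5,
                            level = 0.95, seed = 23)
  truth_path <- simulate_model(true_model(spec, poly_order = 2),
                               x0 = clean$U[1, ], t_grid = horizon)
  inside <- truth_path >= band$lower & truth_path <= band$upper
  expect_gte(mean(inside), 0.75)
})

test_that("coefficient error is the relative Frobenius deviation", {
  A <- matrix(c(3, 4), 1)
  expect_equal(coefficient_error(A, A), 0)
  expect_equal(coefficient_error(0 * A, A), 1)
  expect_equal(coefficient_error(matrix(c(3, 0), 1), A), 0.8)
  expect_equal(coefficient_error(2 * A, 2 * A), 0)
  expect_equal(coefficient_error(5 * matrix(c(3, 0), 1), 5 * A), 0.8)
  expect_error(coefficient_error(A, 0 * A), "zero")
  expect_error(coefficient_error(matrix(1, 2, 2), A), "shape")
})

test_that("success rate counts exact support matches (and per-term optionally)", {
  truth <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
  model_of <- function(mask) {
    terms <- esindy:::ode_term_set(2, 1, FALSE)
    sparse_model(matrix(as.numeric(mask), 2) * 1.5,
                 esindy:::subset_terms(terms, 1:2), c("a", "b"))
  }
  good <- model_of(truth)
  bad <- model_of(matrix(c(TRUE, TRUE, TRUE, FALSE), 2))
  expect_equal(success_rate(list(good, good, good), truth), 1)
  expect_equal(success_rate(list(good, good, good, bad), truth), 0.75)
  expect_equal(success_rate(list(bad), truth, per_term = TRUE), 0.75)
  # permutation invariance over realizations
  expect_equal(success_rate(list(bad, good), truth),
               success_rate(list(good, bad), truth))
})

test_that("ensembles on mildly noisy Lorenz data keep a high success rate", {
  spec <- lorenz_spec()
  truth <- true_model(spec)
  clean <- lorenz_clean()
  fits <- lapply(1:20, function(s) {
    noisy <- add_noise(clean, 0.001, seed = 500 + s)
    lib <- build_ode_library(noisy, 3, deriv_method = "smoothed")
    suppressWarnings(fit_ensemble(lib, ensemble_config(q = 20L, seed = s),
                                  regression_config(lambda1 = 0.1)))$aggregate
  })
  expect_gte(success_rate(fits, truth$support), 0.9)
})
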
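test_that("zero forcing reproduces the autonomous Lorenz trajectory", {
  forced <- simulate_forced_lorenz(c(-8, 8, 27), function(t) 0, m = 200)
  free <- simulate_system(lorenz_spec(), m = 200)
  expect_equal(forced$U, free$U, tolerance = 1e-7)
  expect_true(all(forced$u_ctrl == 0))
})

test_that("a constant input shifts the first state derivative additively", {
  fp <- c(sqrt(72), sqrt(72), 27)
  dt <- 1e-3
  shifted <- simulate_forced_lorenz(fp, function(t) 5, dt = dt, m = 2)
  # at the equilibrium the unforced derivative is zero, so dx/dt = u
  expect_equal(unname(shifted$U[2, 1] - fp[1]) / dt, 5, tolerance = 1e-2)
})

test_that("the unstable equilibrium holds for a short unforced horizon", {
  fp <- c(sqrt(72), sqrt(72), 27)
  s <- simulate_forced_lorenz(fp, function(t) 0, dt = 0.01, m = 11)
  expect_lt(max(abs(sweep(s$U, 2, fp))), 1e-3)
})

test_that("clean forced data identifies the Lorenz terms plus the input channel", {
  tr <- mpc_training_series(m = 600, noise_level = 0, seed = 1)
  em <- suppressWarnings(fit_control_ensemble(
    tr, econf = ensemble_config(q = 30L, seed = 2)))
  truth_terms <- list(x = c("x", "y", "u"), y = c("x", "y", "x*z"),
                      z = c("z", "x*y"))
  for (i in seq_along(truth_terms)) {
    idx <- match(truth_terms[[i]], rownames(em$inclusion))
    expect_true(all(em$inclusion[idx, i] >= 0.9))
  }
  expect_gte(em$inclusion["u", 1], 0.9)
})

test_that("zero actuation is flagged and leaves the input term unidentifiable", {
  tr <- simulate_forced_lorenz(c(-8, 8, 27), function(t) 0, m = 300,
                               noise_level = 0.01, seed = 3)
  expect_warning(em <- fit_control_ensemble(
    tr, econf = ensemble_config(q = 20L, seed = 4)), "excitation")
  expect_lt(em$inclusion["u", 1], 0.2)
})

test_that("single-member identity-resampled ensemble equals the plain fit", {
  tr <- mpc_training_series(m = 200, noise_level = 0, seed = 5)
  lib <- esindy:::control_library(tr, 2)
  rconf <- regression_config(lambda1 = 0.1, lambda2 = 0.01,
                             normalize_columns = TRUE)
  em <- fit_ensemble(lib, ensemble_config(q = 1L, inclusion_tol = 0.5),
                     rconf, resample_fn = seq_len)
  expect_equal(em$aggregate$Xi, stridge(lib, rconf)$Xi, tolerance = 1e-13)
})

test_that("the rollout cost matches an R-side reference computation", {
  terms <- esindy:::ode_term_set(2, 1, FALSE, c("a", "b"))
  Xi <- matrix(c(0, -1, 0, 0, 0, -2), 3, 2)  # da/dt = -a, db/dt = -2b
  Expo <- cbind(terms$expo, 0L)  # exponents over (a, b, u); u unused
  storage.mode(Expo) <- "integer"
  u <- c(0.5, -0.25)
  ref <- {
    x <- c(1, 2); dtt <- 0.1; cost <- 0; up <- 0
    rhs <- function(x, uu) c(-x[1], -2 * x[2])
    for (k in 1:2) {
      k1 <- rhs(x); k2 <- rhs(x + dtt / 2 * k1); k3 <- rhs(x + dtt / 2 * k2)
      k4 <- rhs(x + dtt * k3)
      x <- x + dtt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      cost <- cost + sum((x - c(0, 0))^2) + 0.01 * u[k]^2 +
        0.02 * (u[k] - up)^2
      up <- u[k]
    }
    cost
  }
  got <- esindy:::mpc_rollout_cost(u, c(1, 2), Xi, Expo, 0.1, c(1, 1),
                                   0.01, 0.02, c(0, 0), 0)
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("MPC with the true model stabilizes the unstable fixed point", {
  tm <- true_model(lorenz_spec(), poly_order = 2)
  # extend to the (states, u) term set with the input entering dx/dt
  terms <- esindy:::ode_term_set(4, 2, FALSE, c("x", "y", "z", "u"))
  terms <- esindy:::subset_terms(terms, which(terms$expo[, 4] <= 1))
  Xi <- matrix(0, length(terms$kind), 3)
  rownames(Xi) <- terms$label
  for (i in 1:3) Xi[rownames(tm$Xi)[tm$support[, i]], i] <-
    tm$Xi[tm$support[, i], i]
  Xi["u", 1] <- 1
  model <- sparse_model(Xi, terms, c("x", "y", "z"))
  res <- run_mpc(model, mpc_config(episode_steps = 350),
                 x0 = c(7, 7, 25))
  expect_lt(res$terminal_distance, 0.5)
  expect_equal(res$J_bar, mean(res$stage_costs))
  expect_true(all(abs(res$inputs) <= 50))
})

test_that("a huge input weight drives the inputs toward zero", {
  terms <- esindy:::ode_term_set(4, 2, FALSE, c("x", "y", "z", "u"))
  terms <- esindy:::subset_terms(terms, which(terms$expo[, 4] <= 1))
  tm <- true_model(lorenz_spec(), poly_order = 2)
  Xi <- matrix(0, length(terms$kind), 3)
  rownames(Xi) <- terms$label
  for (i in 1:3) Xi[rownames(tm$Xi)[tm$support[, i]], i] <-
    tm$Xi[tm$support[, i], i]
  Xi["u", 1] <- 1
  model <- sparse_model(Xi, terms, c("x", "y", "z"))
  fp <- c(sqrt(72), sqrt(72), 27)
  res <- run_mpc(model, mpc_config(episode_steps = 30, r = 1e7, x_ref = fp),
                 x0 = fp)
  expect_lt(max(abs(res$inputs)), 0.05)
})
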
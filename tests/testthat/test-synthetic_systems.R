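test_that("Lorenz equilibria satisfy the classical closed form to 1e-10", {
  fp <- lorenz_fixed_points()
  expect_equal(fp[1, 3], 27, tolerance = 1e-10)
  expect_equal(fp[1, 1]^2, 72, tolerance = 1e-10)
  expect_equal(fp[1, 2]^2, 72, tolerance = 1e-10)
  expect_equal(fp[2, 1], -fp[1, 1], tolerance = 1e-10)
  # residual of the vector field at the roots
  s <- fp[1, ]
  expect_lt(max(abs(c(10 * (s[2] - s[1]),
                      s[1] * (28 - s[3]) - s[2],
                      s[1] * s[2] - 8 / 3 * s[3]))), 1e-9)
})

test_that("Lotka-Volterra conserves its first integral along the trajectory", {
  spec <- system_spec("lotka_volterra")
  tr <- simulate_system(spec)
  p <- spec$params
  V <- p$d * tr$U[, 1] - p$c * log(tr$U[, 1]) +
    p$b * tr$U[, 2] - p$a * log(tr$U[, 2])
  expect_lt(diff(range(V)), 1e-6 * abs(mean(V)))
  expect_gt(diff(range(tr$U[, 1])), 1)  # genuinely oscillating
})

test_that("true models embed the generating coefficients on the declared library", {
  tm <- true_model(lorenz_spec())
  expect_equal(sum(tm$support), 7)
  expect_equal(unname(tm$Xi["x*y", "z"]), 1)
  expect_equal(unname(tm$Xi["x", "y"]), 28)
  kdv <- true_model(system_spec("kdv"))
  expect_equal(unname(kdv$Xi["u*u_x", 1]), -6)
  expect_error(true_model(system_spec("lorenz"), poly_order = 1),
               "library too small")
})

test_that("Burgers refuses horizons past the shock and stays smooth before it", {
  spec <- system_spec("burgers_inviscid")
  expect_error(simulate_system(spec, t_end = 2), "safe")
  f <- burgers_clean()
  expect_true(all(is.finite(f$u)))
  expect_lt(max(abs(f$u)), 1.2)
})

test_that("KdV solitons propagate with near-conserved mass and energy", {
  f <- kdv_clean()
  dx <- f$x[2] - f$x[1]
  mass <- colSums(f$u[, , 1]) * dx
  energy <- colSums(f$u[, , 1]^2) * dx
  expect_lt(diff(range(mass)) / abs(mean(mass)), 1e-6)
  expect_lt(diff(range(energy)) / mean(energy), 1e-4)
})

test_that("the Schroedinger breather conserves power and stays complex", {
  spec <- system_spec("nls")
  f <- simulate_system(spec, m = 65L)
  expect_true(is.complex(f$u))
  power <- colSums(Mod(f$u[, , 1])^2)
  expect_lt(diff(range(power)) / mean(power), 1e-8)
  # 2-soliton breather: amplitude oscillates, envelope bounded
  expect_lt(max(Mod(f$u)), 4.5)
  expect_gt(max(Mod(f$u)), 2)
})

test_that("Kuramoto-Sivashinsky stays bounded and non-decaying on its attractor", {
  f <- simulate_system(system_spec("kuramoto_sivashinsky"))
  rms_t <- sqrt(colMeans(f$u[, , 1]^2))
  late <- rms_t[f$t > 50]
  expect_lt(max(abs(f$u)), 30)
  expect_gt(min(late), 0.5)
})

test_that("reaction-diffusion settles onto the unit-amplitude oscillation", {
  f <- simulate_system(system_spec("reaction_diffusion"))
  A <- sqrt(f$u[, , 1]^2 + f$u[, , 2]^2)
  expect_lt(max(abs(A[, dim(A)[2]] - 1)), 0.05)
})

test_that("simulated PDE fields satisfy their own equations in the weak sense", {
  for (name in c("burgers_inviscid", "kdv", "kuramoto_sivashinsky")) {
    spec <- system_spec(name)
    f <- switch(name, burgers_inviscid = burgers_clean(), kdv = kdv_clean(),
                simulate_system(spec))
    ws <- assemble_weak_system(f, spec$poly_order, spec$max_deriv, seed = 31)
    truth <- true_model(spec)
    resid <- ws$q0[, 1] - ws$Q %*% truth$Xi[, 1]
    expect_lt(sqrt(mean(Mod(resid)^2)) / sqrt(mean(Mod(ws$q0[, 1])^2)), 1e-2)
  }
})

test_that("noise is scaled to the per-state RMS and is seed-deterministic", {
  set.seed(1)
  m <- 1e5
  s <- sindy_series(cbind(x = rnorm(m), y = 5 * rnorm(m)), t = seq_len(m))
  noisy <- add_noise(s, 0.1, seed = 7)
  sd_x <- sd(noisy$U[, 1] - s$U[, 1])
  sd_y <- sd(noisy$U[, 2] - s$U[, 2])
  rms_x <- sqrt(mean(s$U[, 1]^2))
  expect_gt(sd_x, 0.095 * rms_x)
  expect_lt(sd_x, 0.105 * rms_x)
  expect_gt(sd_y / sd_x, 4.5)
  expect_identical(add_noise(s, 0.1, seed = 7)$U, noisy$U)
  expect_identical(add_noise(s, 0)$U, s$U)
})

test_that("initial-condition sampling is uniform in the box and reproducible", {
  box <- rbind(c(-2, 2), c(0, 10))
  X <- sample_initial_condition(box, n = 1e4, seed = 3)
  expect_true(all(X[, 1] >= -2 & X[, 1] <= 2))
  se <- apply(X, 2, sd) / sqrt(1e4)
  expect_lt(abs(mean(X[, 1]) - 0), 3 * se[1])
  expect_lt(abs(mean(X[, 2]) - 5), 3 * se[2])
  expect_identical(sample_initial_condition(box, n = 5, seed = 9),
                   sample_initial_condition(box, n = 5, seed = 9))
  # degenerate box collapses to the point
  expect_equal(sample_initial_condition(rbind(c(1, 1), c(2, 2)), seed = 1),
               c(1, 2))
})

test_that("trajectories converge under time-step refinement", {
  spec <- system_spec("lotka_volterra")
  a <- simulate_system(spec, m = 101)
  spec2 <- system_spec("lotka_volterra", dt = 0.025)
  b <- simulate_system(spec2, m = 201)
  expect_equal(a$U[101, ], b$U[201, ], tolerance = 1e-6)
})
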
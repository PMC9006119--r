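make_field <- function(fun, nx = 128, m = 128, Lx = 2 * pi, Tt = 1) {
  x <- Lx * (0:(nx - 1)) / nx
  t <- seq(0, Tt, length.out = m)
  sindy_field(outer(x, t, fun), x, t)
}

test_that("domain placement is deterministic, interior, and capacity-checked", {
  f <- make_field(function(x, t) sin(x) * cos(t), nx = 100, m = 100)
  d1 <- make_domains(f, K = 12, seed = 4)
  d2 <- make_domains(f, K = 12, seed = 4)
  expect_identical(d1, d2)
  expect_true(all(d1$ix - d1$hx_pts >= 2) && all(d1$ix + d1$hx_pts <= 99))
  expect_gte(min(2 * d1$hx_pts + 1, 2 * d1$ht_pts + 1), 9)
  expect_error(make_domains(f, K = 1e6), "admissible")
})

test_that("weak assembly annihilates constants and needs smooth enough weights", {
  f <- make_field(function(x, t) rep(3.7, length(x)))
  ws <- assemble_weak_system(f, poly_order = 2, max_deriv = 2, seed = 1)
  expect_lt(max(abs(ws$q0)), 1e-12)
  expect_error(
    assemble_weak_system(f, poly_order = 1, max_deriv = 3,
                         tf = test_function_spec(p_x = 2, p_t = 3)),
    "boundary")
})

test_that("manufactured travelling wave satisfies q0 = Q xi for u_t = -u_x", {
  f <- make_field(function(x, t) sin(x - t), nx = 256, m = 256)
  ws <- assemble_weak_system(f, poly_order = 1, max_deriv = 1, seed = 2)
  i_ux <- match("u_x", ws$terms$label)
  resid <- ws$q0[, 1] - (-1) * ws$Q[, i_ux]
  expect_lt(max(abs(resid)) / max(abs(ws$q0)), 1e-4)
})

test_that("quadrature error shrinks at second order under grid refinement", {
  err_at <- function(nx) {
    f <- make_field(function(x, t) sin(x - t), nx = nx, m = nx)
    d <- make_domains(f, K = 20, h_x = 0.2, h_t = 0.2, seed = 3)
    ws <- assemble_weak_system(f, poly_order = 1, max_deriv = 1,
                               domains = d)
    i_ux <- match("u_x", ws$terms$label)
    sqrt(mean((ws$q0[, 1] + ws$Q[, i_ux])^2))
  }
  expect_gt(err_at(64) / err_at(128), 3.5)
})

test_that("integration by parts agrees with direct differentiation on smooth fields", {
  f <- make_field(function(x, t) sin(2 * x) * exp(-t), nx = 256, m = 128)
  ws <- assemble_weak_system(f, poly_order = 0, max_deriv = 2, seed = 5)
  # recompute u_xx column by direct spectral differentiation + quadrature
  fx <- f
  fx$u[, , 1] <- esindy:::spectral_deriv(f$u[, , 1], 2 * pi, 2)
  ws_direct <- assemble_weak_system(fx, poly_order = 1, max_deriv = 0,
                                    domains = ws$domains, tf = ws$tf)
  i_uxx <- match("u_xx", ws$terms$label)
  i_u <- match("u", ws_direct$terms$label)
  expect_equal(ws$Q[, i_uxx], ws_direct$Q[, i_u], tolerance = 1e-3)
})

test_that("weak fits recover Burgers and KdV exactly from clean fields", {
  bspec <- system_spec("burgers_inviscid")
  ws <- assemble_weak_system(burgers_clean(), bspec$poly_order,
                             bspec$max_deriv, seed = 11)
  fit <- weak_fit(ws)
  truth <- true_model(bspec)
  expect_identical(fit$support, truth$support)
  expect_lt(abs(fit$Xi["u*u_x", 1] + 1), 0.05)

  kspec <- system_spec("kdv")
  ws2 <- assemble_weak_system(kdv_clean(), kspec$poly_order, kspec$max_deriv,
                              seed = 12)
  fit2 <- weak_fit(ws2)
  truth2 <- true_model(kspec)
  expect_identical(fit2$support, truth2$support)
  expect_lt(abs(fit2$Xi["u*u_x", 1] + 6) / 6, 0.05)
  expect_lt(abs(fit2$Xi["u_xxx", 1] + 1), 0.05)
})

test_that("an all-zero integrated target gives an empty model", {
  f <- make_field(function(x, t) rep(1.5, length(x)))
  ws <- assemble_weak_system(f, poly_order = 1, max_deriv = 1, seed = 6)
  expect_warning(fit <- weak_fit(ws), "empty")
  expect_equal(sum(fit$support), 0)
})

test_that("relative weak-integral noise shrinks as domains grow on white noise", {
  set.seed(8)
  nx <- 200
  x <- seq(0, 1, length.out = nx + 1)[1:nx]
  t <- seq(0, 1, length.out = nx + 1)[1:nx]
  noise <- sindy_field(matrix(rnorm(nx * nx), nx), x, t, periodic = FALSE)
  ramp <- sindy_field(matrix(rep(t, each = nx), nx), x, t, periodic = FALSE)
  rel_var <- function(h) {
    d <- make_domains(noise, 60, h_x = h, h_t = h, seed = 1)
    v <- var(assemble_weak_system(noise, 0, 0, domains = d)$q0[, 1])
    # deterministic scale of the same integral: u = t gives q0 = +int w > 0
    s <- mean(assemble_weak_system(ramp, 0, 0, domains = d)$q0[, 1])
    v / s^2
  }
  # quadrupling the half-width multiplies the points per domain by ~16;
  # the noise-to-scale variance ratio should drop by at least that order
  expect_gt(rel_var(0.05) / rel_var(0.2), 10)
})
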
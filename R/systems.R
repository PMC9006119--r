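# Synthetic benchmark systems. Each spec carries its governing parameters,
# grid, initial condition and the ground-truth coefficients on a declared
# library, so simulate-then-recover tests know the answer by construction.

.system_names <- c("lorenz", "lotka_volterra", "burgers_inviscid", "kdv",
                   "nls", "kuramoto_sivashinsky", "reaction_diffusion")

#' Benchmark system specification
#'
#' Builds a fully specified synthetic system: governing parameters, default
#' simulation grid, initial condition, and the true sparse coefficients on a
#' declared candidate library. Any field can be overridden.
#'
#' Defaults (grids chosen so a full single-system discovery runs in seconds):
#' * `lorenz`: sigma 10, rho 28, beta 8/3; dt 0.01, m 2500, x0 (-8, 8, 27).
#' * `lotka_volterra`: a 1, b 0.1, c 1.5, d 0.075 (prey growth/predation,
#'   predator death/conversion); dt 0.05, m 1000, x0 (30, 5).
#' * `burgers_inviscid`: Gaussian pulse on a periodic domain, integrated
#'   before shock formation.
#' * `kdv`: two-soliton initial condition, `u_t = -6 u u_x - u_xxx`.
#' * `nls`: focusing Schroedinger `i u_t + u_xx/2 + |u|^2 u = 0`, 2-soliton
#'   breather `u0 = 2 sech(x)`.
#' * `kuramoto_sivashinsky`: `u_t = -u u_x - u_xx - u_xxxx` on `L = 32 pi`
#'   (chaotic attractor).
#' * `reaction_diffusion`: two-component lambda-omega system on a periodic
#'   1-d grid (diffusion 0.1, rotation beta 1).
#'
#' @param name one of `lorenz`, `lotka_volterra`, `burgers_inviscid`, `kdv`,
#'   `nls`, `kuramoto_sivashinsky`, `reaction_diffusion`.
#' @param ... overrides for the defaults (`params`, `dt`, `m`, `n_x`, `L`,
#'   `x0`, `t_end`, ...).
#' @return A `system_spec` list.
#' @export
system_spec <- function(name = .system_names, ...) {
  name <- match.arg(name)
  base <- switch(name,
    lorenz = list(
      params = list(sigma = 10, rho = 28, beta = 8 / 3),
      dt = 0.01, m = 2500L, x0 = c(-8, 8, 27), vars = c("x", "y", "z"),
      kind = "ode", poly_order = 3L,
      region = rbind(c(-20, 20), c(-20, 20), c(0, 40))),
    lotka_volterra = list(
      params = list(a = 1, b = 0.1, c = 1.5, d = 0.075),
      dt = 0.05, m = 1000L, x0 = c(30, 5), vars = c("x", "y"),
      kind = "ode", poly_order = 3L,
      region = rbind(c(5, 50), c(2, 30))),
    burgers_inviscid = list(
      params = list(), L = 10, n_x = 256L, m = 256L, t_end = 0.8,
      u0 = function(x) exp(-(x - 5)^2), vars = "u",
      kind = "pde", poly_order = 2L, max_deriv = 3L),
    kdv = list(
      params = list(), L = 20, n_x = 256L, m = 256L, t_end = 1,
      u0 = function(x) {
        sol <- function(c, x0) c / 2 / cosh(sqrt(c) / 2 * (x - x0))^2
        sol(4, -6) + sol(1, -2)
      }, vars = "u",
      kind = "pde", poly_order = 2L, max_deriv = 3L),
    nls = list(
      params = list(), L = 20, n_x = 256L, m = 256L, t_end = 1,
      u0 = function(x) 2 / cosh(x) + 0i, vars = "u",
      kind = "pde", poly_order = 3L, max_deriv = 2L),
    kuramoto_sivashinsky = list(
      params = list(), L = 32 * pi, n_x = 256L, m = 401L, t_end = 100,
      u0 = function(x) cos(x / 16) * (1 + sin(x / 16)), vars = "u",
      kind = "pde", poly_order = 2L, max_deriv = 4L),
    reaction_diffusion = list(
      params = list(d = 0.1, beta = 1), L = 20, n_x = 256L, m = 201L,
      t_end = 10,
      u0 = function(x) cbind(cos(2 * pi * x / 20), sin(2 * pi * x / 20)),
      vars = c("u", "v"), kind = "pde", poly_order = 3L, max_deriv = 2L))
  spec <- modifyList(base, list(...))
  spec$name <- name
  structure(spec, class = "system_spec")
}

# Named true coefficients per state, labels matching the declared library.
true_coefficients <- function(spec) {
  p <- spec$params
  switch(spec$name,
    lorenz = list(
      x = c("x" = -p$sigma, "y" = p$sigma),
      y = c("x" = p$rho, "y" = -1, "x*z" = -1),
      z = c("z" = -p$beta, "x*y" = 1)),
    lotka_volterra = list(
      x = c("x" = p$a, "x*y" = -p$b),
      y = c("y" = -p$c, "x*y" = p$d)),
    burgers_inviscid = list(u = c("u*u_x" = -1)),
    kdv = list(u = c("u*u_x" = -6, "u_xxx" = -1)),
    nls = list(u = c("u_xx" = 0.5i, "|u|^2*u" = 1i)),
    kuramoto_sivashinsky = list(
      u = c("u*u_x" = -1, "u_xx" = -1, "u_xxxx" = -1)),
    reaction_diffusion = list(
      u = c("u" = 1, "u^3" = -1, "u*v^2" = -1, "u^2*v" = p$beta,
            "v^3" = p$beta, "u_xx" = p$d),
      v = c("v" = 1, "u^3" = -p$beta, "u*v^2" = -p$beta, "u^2*v" = -1,
            "v^3" = -1, "v_xx" = p$d)))
}

#' Ground-truth sparse model of a benchmark system
#'
#' Returns the generating equations as a `sparse_model` on the declared
#' candidate library, for simulate-then-recover oracles and scoring.
#'
#' @param spec a [system_spec()].
#' @param poly_order,max_deriv,include_trig library declaration; defaults
#'   follow the spec.
#' @return A `sparse_model` whose nonzero pattern is the true support.
#' @export
true_model <- function(spec, poly_order = spec$poly_order,
                       max_deriv = spec$max_deriv, include_trig = FALSE) {
  coefs <- true_coefficients(spec)
  cplx <- spec$name == "nls"
  terms <- if (spec$kind == "ode")
    ode_term_set(length(spec$vars), poly_order, include_trig, spec$vars)
  else pde_term_set(length(spec$vars), poly_order, max_deriv, spec$vars,
                    include_modsq = cplx)
  Xi <- matrix(if (cplx) 0 + 0i else 0, n_terms(terms), length(coefs))
  for (i in seq_along(coefs)) {
    idx <- match(names(coefs[[i]]), terms$label)
    if (anyNA(idx))
      stop("library too small for the true terms of ", spec$name, ": missing ",
           paste(names(coefs[[i]])[is.na(idx)], collapse = ", "))
    Xi[idx, i] <- coefs[[i]]
  }
  sparse_model(Xi, terms, names(coefs))
}

ode_rhs_factory <- function(spec) {
  p <- spec$params
  switch(spec$name,
    lorenz = function(t, s, parms) list(c(
      p$sigma * (s[2] - s[1]),
      s[1] * (p$rho - s[3]) - s[2],
      s[1] * s[2] - p$beta * s[3])),
    lotka_volterra = function(t, s, parms) list(c(
      p$a * s[1] - p$b * s[1] * s[2],
      -p$c * s[2] + p$d * s[1] * s[2])))
}

#' Simulate a benchmark system
#'
#' ODE systems are integrated with adaptive Dormand-Prince Runge-Kutta
#' (tolerances `1e-10`/`1e-12`). Periodic PDEs use Fourier pseudo-spectral
#' discretization: fourth-order exponential time differencing (ETDRK4) for
#' the stiff Korteweg-de Vries, Kuramoto-Sivashinsky and reaction-diffusion
#' systems, split-step Fourier for the Schroedinger equation, and
#' method-of-lines Runge-Kutta for inviscid Burgers stopped before shock
#' formation.
#'
#' @param spec a [system_spec()].
#' @param x0 optional override of the initial state (ODE systems).
#' @param m,t_end optional overrides of the sample count / horizon.
#' @return A [sindy_series()] (ODE) or [sindy_field()] (PDE) of clean data;
#'   the generating `spec` is attached as attribute `"spec"`.
#' @export
simulate_system <- function(spec, x0 = NULL, m = NULL, t_end = NULL) {
  stopifnot(inherits(spec, "system_spec"))
  log_stage("simulate_system", system = spec$name)
  if (spec$kind == "ode") {
    m <- m %||% spec$m
    times <- spec$dt * (0:(m - 1))
    out <- deSolve::ode(y = as.numeric(x0 %||% spec$x0), times = times,
                        func = ode_rhs_factory(spec), parms = NULL,
                        method = "ode45", rtol = 1e-10, atol = 1e-12)
    res <- sindy_series(unname(out[, -1, drop = FALSE]), times,
                        names = spec$vars)
  } else {
    res <- simulate_pde(spec, m = m %||% spec$m, t_end = t_end %||% spec$t_end)
  }
  attr(res, "spec") <- spec
  res
}

simulate_pde <- function(spec, m, t_end) {
  nx <- spec$n_x
  x <- spec$L * (0:(nx - 1)) / nx + switch(spec$name, kdv = -10, nls = -10, 0)
  t_save <- seq(0, t_end, length.out = m)
  neg <- nx - nx %/% 2 - 1
  k <- 2 * pi / spec$L * c(0:(nx %/% 2), if (neg > 0) -(neg:1))
  switch(spec$name,
    burgers_inviscid = {
      u0 <- spec$u0(x)
      du0 <- Re(spectral_deriv(matrix(u0), spec$L, 1))
      t_shock <- -1 / min(du0)
      if (t_end > 0.9 * t_shock)
        stop("horizon ", t_end, " exceeds safe pre-shock window; latest safe ",
             "horizon is ", signif(0.9 * t_shock, 4))
      rhs <- function(u) {
        ux <- drop(spectral_deriv(matrix(u), spec$L, 1))
        -u * ux
      }
      U <- rk4_grid(u0, rhs, t_save, dt_int = 1e-3)
      sindy_field(U, x, t_save, names = spec$vars)
    },
    kdv = {
      Lhat <- 1i * k^3
      Nfun <- function(u) {
        ux <- drop(spectral_deriv(matrix(u + 0i), spec$L, 1))
        -6 * u * ux
      }
      U <- etdrk4(spec$u0(x), Lhat, Nfun, t_save, dt_int = 1e-3, real = TRUE)
      sindy_field(U, x, t_save, names = spec$vars)
    },
    kuramoto_sivashinsky = {
      Lhat <- k^2 - k^4
      Nfun <- function(u) {
        ux <- drop(spectral_deriv(matrix(u + 0i), spec$L, 1))
        -u * ux
      }
      U <- etdrk4(spec$u0(x), Lhat, Nfun, t_save, dt_int = 0.05, real = TRUE)
      sindy_field(U, x, t_save, names = spec$vars)
    },
    nls = {
      U <- splitstep_nls(spec$u0(x), k, t_save, dt_int = 5e-4)
      sindy_field(U, x, t_save, names = spec$vars)
    },
    reaction_diffusion = {
      d <- spec$params$d; beta <- spec$params$beta
      Lhat <- cbind(-d * k^2 + 1, -d * k^2 + 1)
      Nfun <- function(uv) {
        A2 <- uv[, 1]^2 + uv[, 2]^2
        cbind(-A2 * uv[, 1] + beta * A2 * uv[, 2],
              -beta * A2 * uv[, 1] - A2 * uv[, 2])
      }
      U <- etdrk4(spec$u0(x), Lhat, Nfun, t_save, dt_int = 0.01, real = TRUE)
      sindy_field(U, x, t_save, names = spec$vars)
    })
}

# Fixed-step RK4 for method-of-lines systems; saves at t_save (assumed
# uniform), sub-stepping at ~dt_int.
rk4_grid <- function(u0, rhs, t_save, dt_int) {
  u <- u0
  m <- length(t_save)
  out <- matrix(NA_real_, length(u0), m)
  out[, 1] <- u
  dt_save <- t_save[2] - t_save[1]
  nsub <- max(1L, ceiling(dt_save / dt_int))
  h <- dt_save / nsub
  for (j in 2:m) {
    for (s in seq_len(nsub)) {
      k1 <- rhs(u); k2 <- rhs(u + h / 2 * k1)
      k3 <- rhs(u + h / 2 * k2); k4 <- rhs(u + h * k3)
      u <- u + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[, j] <- u
  }
  out
}

# Fourth-order exponential time differencing (Kassam-Trefethen contour
# quadrature for the phi-functions). u0: n_x vector or n_x x n_c matrix;
# Lhat: matching Fourier multipliers; Nfun: physical-space nonlinearity.
etdrk4 <- function(u0, Lhat, Nfun, t_save, dt_int, real = TRUE) {
  u0 <- cbind(u0); Lhat <- cbind(Lhat)
  nx <- nrow(u0); ncmp <- ncol(u0)
  m <- length(t_save)
  dt_save <- t_save[2] - t_save[1]
  nsub <- max(1L, ceiling(dt_save / dt_int))
  h <- dt_save / nsub
  E <- exp(h * Lhat); E2 <- exp(h * Lhat / 2)
  M <- 32
  r <- exp(1i * pi * ((1:M) - 0.5) / M)
  LR <- h * matrix(as.vector(Lhat), nx * ncmp, M) +
    matrix(r, nx * ncmp, M, byrow = TRUE)
  # contour means are real only when the linear symbol is real (KS, RD); for
  # dispersive symbols (KdV: i k^3) they stay complex
  fix <- if (all(Im(Lhat) == 0)) function(z) Re(z) else function(z) z
  reshape <- function(v) matrix(v, nx, ncmp)
  Qc <- reshape(h * fix(rowMeans((exp(LR / 2) - 1) / LR)))
  f1 <- reshape(h * fix(rowMeans((-4 - LR + exp(LR) * (4 - 3 * LR + LR^2)) / LR^3)))
  f2 <- reshape(h * fix(rowMeans((2 + LR + exp(LR) * (-2 + LR)) / LR^3)))
  f3 <- reshape(h * fix(rowMeans((-4 - 3 * LR - LR^2 + exp(LR) * (4 - LR)) / LR^3)))
  to_phys <- function(V) {
    u <- mvfft(V, inverse = TRUE) / nx
    if (real) Re(u) else u
  }
  to_four <- function(u) mvfft(u + 0i)
  V <- to_four(u0)
  Nhat <- function(V) to_four(Nfun(to_phys(V)))
  out <- array(if (real) NA_real_ else NA_complex_, dim = c(nx, m, ncmp))
  out[, 1, ] <- to_phys(V)
  for (j in 2:m) {
    for (s in seq_len(nsub)) {
      Nv <- Nhat(V)
      a <- E2 * V + Qc * Nv; Na <- Nhat(a)
      b <- E2 * V + Qc * Na; Nb <- Nhat(b)
      cc <- E2 * a + Qc * (2 * Nb - Nv); Nc <- Nhat(cc)
      V <- E * V + f1 * Nv + 2 * f2 * (Na + Nb) + f3 * Nc
    }
    out[, j, ] <- to_phys(V)
  }
  if (ncmp == 1) out[, , 1] else out
}

# Strang-split Fourier integrator for i u_t + u_xx/2 + |u|^2 u = 0.
splitstep_nls <- function(u0, k, t_save, dt_int) {
  nx <- length(u0)
  m <- length(t_save)
  dt_save <- t_save[2] - t_save[1]
  nsub <- max(1L, ceiling(dt_save / dt_int))
  h <- dt_save / nsub
  lin <- exp(-1i * k^2 * h / 2)
  u <- u0 + 0i
  out <- matrix(NA_complex_, nx, m)
  out[, 1] <- u
  for (j in 2:m) {
    for (s in seq_len(nsub)) {
      u <- u * exp(1i * Mod(u)^2 * h / 2)
      u <- fft(fft(u) * lin, inverse = TRUE) / nx
      u <- u * exp(1i * Mod(u)^2 * h / 2)
    }
    out[, j] <- u
  }
  out
}

#' Add scaled measurement noise
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation
#' `level x RMS(clean signal)`, per state variable (per field component; for
#' complex fields, circularly symmetric complex noise scaled to the RMS
#' modulus). Deterministic for a given seed.
#'
#' @param data a [sindy_series()] or [sindy_field()].
#' @param level dimensionless noise fraction (>= 0).
#' @param seed optional RNG seed.
#' @return Object of the same class with noise added.
#' @export
add_noise <- function(data, level, seed = NULL) {
  stopifnot(level >= 0)
  if (level == 0) return(data)
  with_seed(seed, {
    if (inherits(data, "sindy_series")) {
      for (j in seq_len(n_states(data))) {
        s <- level * rms(data$U[, j])
        data$U[, j] <- data$U[, j] + rnorm(nrow(data$U), sd = s)
      }
    } else if (inherits(data, "sindy_field")) {
      dims <- dim(data$u)
      for (i in seq_len(dims[3])) {
        s <- level * rms(data$u[, , i])
        eps <- if (is.complex(data$u))
          (rnorm(dims[1] * dims[2]) + 1i * rnorm(dims[1] * dims[2])) / sqrt(2) * s
        else rnorm(dims[1] * dims[2], sd = s)
        data$u[, , i] <- data$u[, , i] + eps
      }
    } else stop("unsupported data type")
    data
  })
}

#' Uniform random initial condition in a box
#'
#' @param spec a [system_spec()] (its default phase-space box is used) or a
#'   `d x 2` matrix of bounds.
#' @param n number of draws.
#' @param seed optional RNG seed.
#' @return `n x d` matrix of states (a vector if `n = 1`).
#' @export
sample_initial_condition <- function(spec, n = 1L, seed = NULL) {
  box <- if (inherits(spec, "system_spec")) {
    if (is.null(spec$region)) stop("no default sampling box for ", spec$name)
    spec$region
  } else as.matrix(spec)
  stopifnot(ncol(box) == 2)
  d <- nrow(box)
  out <- with_seed(seed, matrix(runif(n * d, rep(box[, 1], each = n),
                                      rep(box[, 2], each = n)), n, d))
  if (n == 1) drop(out) else out
}

#' Non-origin equilibria of the Lorenz system
#'
#' Newton root-solve of the Lorenz vector field from symmetric starting
#' guesses; with the classical parameters the two non-origin fixed points are
#' `(+-sqrt(beta (rho - 1)), +-sqrt(beta (rho - 1)), rho - 1)`.
#'
#' @param sigma,rho,beta Lorenz parameters.
#' @return `2 x 3` matrix, one fixed point per row.
#' @export
lorenz_fixed_points <- function(sigma = 10, rho = 28, beta = 8 / 3) {
  f <- function(s) c(sigma * (s[2] - s[1]),
                     s[1] * (rho - s[3]) - s[2],
                     s[1] * s[2] - beta * s[3])
  jac <- function(s) rbind(c(-sigma, sigma, 0),
                           c(rho - s[3], -1, -s[1]),
                           c(s[2], s[1], -beta))
  solve_from <- function(s) {
    for (i in 1:100) {
      step <- solve(jac(s), f(s))
      s <- s - step
      if (max(abs(step)) < 1e-14) break
    }
    s
  }
  guess <- sqrt(max(beta * (rho - 1), 1))
  rbind(solve_from(c(guess * 1.1, guess * 0.9, rho)),
        solve_from(-c(guess * 1.1, guess * 0.9, -rho)))
}
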
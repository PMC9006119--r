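# Shared fixtures, built once per session and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

lorenz_spec <- function() system_spec("lorenz")

lorenz_clean <- function() cached("lorenz_clean",
                                  simulate_system(lorenz_spec()))

lorenz_library <- function() cached("lorenz_lib",
                                    build_ode_library(lorenz_clean(), 3))

burgers_clean <- function() cached("burgers_clean",
                                   simulate_system(system_spec("burgers_inviscid")))

kdv_clean <- function() cached("kdv_clean", simulate_system(system_spec("kdv")))

# tiny deterministic series: two decoupled exponentials
toy_series <- function(m = 50, dt = 0.05) {
  t <- dt * (0:(m - 1))
  sindy_series(cbind(x = exp(-t), y = 2 * exp(-0.5 * t)), t)
}

# library whose target is an exact linear combination of named columns
rigged_library <- function(m = 40) {
  t <- seq(0, 2, length.out = m)
  U <- cbind(x = sin(t) + 0.2 * t, y = cos(2 * t))
  s <- sindy_series(U, t)
  lib <- build_ode_library(s, 2)
  lib$target <- cbind(2 * lib$Theta[, "x"] - 0.7 * lib$Theta[, "x*y"])
  colnames(lib$target) <- "x"
  lib$names <- "x"
  lib
}
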
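#' Integrate a sparse ODE model
#'
#' Simulates `dx/dt = Theta(x) Xi` with an adaptive Dormand-Prince 4(5)
#' Runge-Kutta scheme (relative/absolute tolerances `1e-8`/`1e-10`). If the
#' state magnitude exceeds `1e6` the trajectory is truncated there and flagged
#' divergent rather than raising an error (ensemble members are allowed to be
#' unstable).
#'
#' @param model a `sparse_model` with ODE terms (no spatial derivatives).
#' @param x0 initial state (length `n`).
#' @param t_grid times at which to report the state (first entry is the
#'   initial time).
#' @param rtol,atol integration tolerances.
#' @return `length(t_grid) x n` state matrix; rows after a divergence are
#'   `NA` and the attribute `divergent` is `TRUE`.
#' @export
simulate_model <- function(model, x0, t_grid, rtol = 1e-8, atol = 1e-10) {
  if (any(model$terms$deriv > 0, na.rm = TRUE))
    stop("model contains spatial-derivative terms; only ODE models can be ",
         "integrated")
  Xi <- Re(model$Xi)
  terms <- model$terms
  n <- ncol(Xi)
  rhs <- function(t, x, parms) {
    if (any(!is.finite(x)) || max(abs(x)) > 1e6) return(list(rep(0, n)))
    list(drop(eval_ode_terms(terms, matrix(x, 1)) %*% Xi))
  }
  out <- suppressWarnings(
    deSolve::ode(y = as.numeric(x0), times = t_grid, func = rhs, parms = NULL,
                 method = "ode45", rtol = rtol, atol = atol))
  U <- matrix(NA_real_, length(t_grid), n)
  got <- seq_len(min(nrow(out), length(t_grid)))
  U[got, ] <- unname(out[got, -1, drop = FALSE])
  bad <- which(!is.finite(rowSums(U)) | apply(abs(U), 1, max) > 1e6)
  divergent <- length(bad) > 0
  if (divergent) U[min(bad):nrow(U), ] <- NA_real_
  colnames(U) <- model$names
  attr(U, "divergent") <- divergent
  U
}

#' Probabilistic ensemble forecast
#'
#' Draws `models_per_draw` member coefficient matrices uniformly with
#' replacement, averages them, and integrates the averaged model from `x0`;
#' repeated for `n_realizations` draws. The band is the pointwise empirical
#' `(1 - level)/2` and `(1 + level)/2` quantile envelope (median likewise)
#' over the non-divergent realizations.
#'
#' @param em an `ensemble_model` (ODE terms).
#' @param x0 initial state.
#' @param t_grid forecast time grid.
#' @param n_realizations number of coefficient draws (default 1000).
#' @param models_per_draw members averaged per draw (default 5).
#' @param level nominal band coverage (default 0.95).
#' @param seed optional RNG seed.
#' @return A `forecast_band`: `t`, `median`, `lower`, `upper` (`m x n` each),
#'   plus the divergent-realization count.
#' @export
ensemble_forecast <- function(em, x0, t_grid, n_realizations = 1000L,
                              models_per_draw = 5L, level = 0.95,
                              seed = NULL) {
  q <- ensemble_size(em)
  if (q < models_per_draw)
    stop("ensemble has ", q, " members; models_per_draw = ", models_per_draw)
  terms <- em$terms
  m <- length(t_grid); n <- ncol(em$inclusion)
  log_stage("ensemble_forecast", realizations = n_realizations,
            models_per_draw = models_per_draw)
  draws <- with_seed(seed, replicate(n_realizations,
    sample.int(q, models_per_draw, replace = TRUE), simplify = FALSE))
  arr <- array(NA_real_, dim = c(m, n, n_realizations))
  n_div <- 0L
  # purely polynomial models integrate through the compiled fixed-step path
  # (fine substepping); anything else goes through the adaptive integrator
  fast <- all(terms$kind == "poly")
  if (fast) {
    Expo <- cbind(terms$expo, 0L)
    storage.mode(Expo) <- "integer"
  }
  for (r in seq_len(n_realizations)) {
    Xi <- Reduce(`+`, em$members[draws[[r]]]) / models_per_draw
    if (fast) {
      path <- poly_path(as.numeric(x0), Re(Xi), Expo, t_grid, 25L)
      if (isTRUE(path$divergent)) n_div <- n_div + 1L
      else arr[, , r] <- path$states
    } else {
      U <- simulate_model(sparse_model(Xi, terms, em$names), x0, t_grid)
      if (isTRUE(attr(U, "divergent"))) n_div <- n_div + 1L else arr[, , r] <- U
    }
  }
  if (n_div > 0) log_stage("ensemble_forecast", divergent = n_div)
  if (n_div == n_realizations)
    stop("every forecast realization diverged; cannot form a band")
  probs <- c((1 - level) / 2, 0.5, (1 + level) / 2)
  qs <- apply(arr, c(1, 2), quantile, probs = probs, na.rm = TRUE)
  layer <- function(i) matrix(qs[i, , ], m, n,
                              dimnames = list(NULL, em$names))
  band <- structure(list(t = t_grid, lower = layer(1), median = layer(2),
                         upper = layer(3), level = level,
                         n_realizations = n_realizations,
                         models_per_draw = models_per_draw,
                         n_divergent = n_div),
                    class = "forecast_band")
  stopifnot(all(band$lower <= band$median + 1e-12),
            all(band$median <= band$upper + 1e-12))
  band
}

#' @export
print.forecast_band <- function(x, ...) {
  cat(sprintf(
    "<forecast_band> %d time points, %d%% band from %d realizations x %d models (%d divergent)\n",
    length(x$t), round(100 * x$level), x$n_realizations, x$models_per_draw,
    x$n_divergent))
  invisible(x)
}

#' Relative coefficient error
#'
#' `Ec = ||Xi_true - Xi_hat||_2 / ||Xi_true||_2` with the entrywise
#' (Frobenius) norm over the vectorized coefficient matrices; dimensionless
#' and invariant to scaling both matrices by the same constant.
#'
#' @param Xi_hat,Xi_true coefficient matrices of the same shape.
#' @return Non-negative scalar.
#' @export
coefficient_error <- function(Xi_hat, Xi_true) {
  if (!all(dim(as.matrix(Xi_hat)) == dim(as.matrix(Xi_true))))
    stop("coefficient matrices must have the same shape")
  denom <- sqrt(sum(Mod(Xi_true)^2))
  if (denom == 0) stop("||Xi_true|| is zero; relative error undefined")
  sqrt(sum(Mod(Xi_true - Xi_hat)^2)) / denom
}

#' Support-recovery success rate
#'
#' A realization counts as a success when its identified support matches the
#' true nonzero/zero pattern exactly — every true term present and every
#' non-term absent (`per_term = FALSE`, the default strict reading). With
#' `per_term = TRUE` the per-realization score is instead the fraction of
#' library entries classified correctly.
#'
#' @param models list of `sparse_model`s (or logical support masks).
#' @param true_support logical `D x n` mask of the true support.
#' @param per_term use term-averaged scoring instead of exact match.
#' @return Mean success over realizations, in `[0, 1]`.
#' @export
success_rate <- function(models, true_support, per_term = FALSE) {
  score <- vapply(models, function(mod) {
    supp <- if (inherits(mod, "sparse_model")) mod$support else mod
    if (!all(dim(supp) == dim(true_support)))
      stop("support mask shape mismatch")
    if (per_term) mean(supp == true_support)
    else as.numeric(all(supp == true_support))
  }, numeric(1))
  mean(score)
}
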
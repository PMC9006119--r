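#' Numerical time differentiation of a series
#'
#' Estimates the time derivative of every state variable by second-order
#' centred differences on the interior and second-order one-sided stencils at
#' both endpoints, so all `m` samples stay usable — important in the low-data
#' limit. The `smoothed` method first applies a fixed-window Savitzky-Golay
#' local-polynomial filter (order 3) to each state before differencing, which
#' tames measurement noise at the cost of slight bias.
#'
#' A 2-sample series falls back to the first-order two-point slope for both
#' rows (needed when single-step segments are acquired during active learning).
#'
#' @param series a [sindy_series()] with uniform sampling.
#' @param method `"centered"` (default) or `"smoothed"`.
#' @param window odd Savitzky-Golay window length for `"smoothed"`; default 7
#'   (shrunk automatically for very short series).
#' @return `m x n` matrix of derivative estimates.
#' @examples
#' s <- sindy_series(cbind(x = (0:10)^2), t = 0:10)
#' differentiate_time(s)  # exactly 2*t at interior points
#' @export
differentiate_time <- function(series, method = c("centered", "smoothed"),
                               window = 7L) {
  method <- match.arg(method)
  t <- series$t
  m <- length(t)
  if (!is_uniform(t, rel_tol = 1e-8))
    stop("non-uniform sampling times: centred differencing needs a uniform ",
         "grid; resample the series first")
  dt <- t[2] - t[1]
  U <- series$U
  if (method == "smoothed" && m >= 5) {
    w <- min(window, if (m %% 2 == 1) m else m - 1L)
    if (w %% 2 == 0) w <- w - 1L
    if (w >= 5) U <- apply(U, 2, function(col) signal::sgolayfilt(col, p = 3, n = w))
  }
  if (m == 2) {
    slope <- (U[2, ] - U[1, ]) / dt
    return(matrix(slope, nrow = 2, ncol = ncol(U), byrow = TRUE,
                  dimnames = list(NULL, colnames(U))))
  }
  dU <- matrix(0, m, ncol(U), dimnames = list(NULL, colnames(U)))
  dU[2:(m - 1), ] <- (U[3:m, , drop = FALSE] - U[1:(m - 2), , drop = FALSE]) / (2 * dt)
  dU[1, ] <- (-3 * U[1, ] + 4 * U[2, ] - U[3, ]) / (2 * dt)
  dU[m, ] <- (3 * U[m, ] - 4 * U[m - 1, ] + U[m - 2, ]) / (2 * dt)
  dU
}
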
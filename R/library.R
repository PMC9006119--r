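# Candidate-term bookkeeping. A term_set describes the D columns of the
# feature matrix: multivariate monomials (kind "poly"), trigonometric terms
# ("sin"/"cos"), and PDE product terms monomial * d^d u_c/dx^d, optionally
# carrying a |u|^2 power for complex fields ("pde"). Term order is a
# deterministic function of the specification only (graded lexicographic),
# so term indices are stable across runs and ensemble members.

term_set <- function(kind, expo, deriv, deriv_comp, modsq, trig, vars) {
  expo <- as.matrix(expo)
  D <- length(kind)
  stopifnot(nrow(expo) == D, length(deriv) == D)
  labels <- vapply(seq_len(D), function(i) {
    term_label(kind[i], expo[i, ], deriv[i], deriv_comp[i], modsq[i],
               trig[i], vars)
  }, character(1))
  structure(list(kind = kind, expo = expo, deriv = as.integer(deriv),
                 deriv_comp = as.integer(deriv_comp),
                 modsq = as.integer(modsq), trig = as.integer(trig),
                 label = labels, vars = vars),
            class = "term_set")
}

n_terms <- function(terms) length(terms$kind)

subset_terms <- function(terms, idx) {
  term_set(terms$kind[idx], terms$expo[idx, , drop = FALSE], terms$deriv[idx],
           terms$deriv_comp[idx], terms$modsq[idx], terms$trig[idx],
           terms$vars)
}

#' @export
print.term_set <- function(x, ...) {
  cat("<term_set> D =", n_terms(x), ":", paste(x$label, collapse = ", "), "\n")
  invisible(x)
}

term_label <- function(kind, expo, deriv, deriv_comp, modsq, trig, vars) {
  if (kind %in% c("sin", "cos")) return(paste0(kind, "(", vars[trig], ")"))
  parts <- character(0)
  if (!is.na(modsq) && modsq > 0)
    parts <- c(parts, if (modsq == 1) paste0("|", vars[1], "|^2")
               else paste0("|", vars[1], "|^", 2 * modsq))
  pow <- which(expo > 0)
  parts <- c(parts, vapply(pow, function(j) {
    if (expo[j] == 1) vars[j] else paste0(vars[j], "^", expo[j])
  }, character(1)))
  if (!is.na(deriv) && deriv > 0)
    parts <- c(parts, paste0(vars[deriv_comp], "_",
                             paste(rep("x", deriv), collapse = "")))
  if (!length(parts)) "1" else paste(parts, collapse = "*")
}

# All exponent vectors of total degree <= p over n variables, graded
# lexicographic (degree-major, then lexicographic with the first variable
# highest priority): for n = 2, p = 2 the order is 1, x, y, x^2, x*y, y^2.
monomial_exponents <- function(n, p) {
  per_degree <- function(total, parts) {
    if (parts == 1) return(matrix(total, 1, 1))
    do.call(rbind, lapply(total:0, function(k) {
      rest <- per_degree(total - k, parts - 1)
      cbind(k, rest, deparse.level = 0)
    }))
  }
  do.call(rbind, lapply(0:p, per_degree, parts = n))
}

ode_term_set <- function(n, poly_order, include_trig = FALSE, vars = NULL) {
  stopifnot(poly_order >= 1)
  vars <- vars %||% paste0("x", seq_len(n))
  expo <- monomial_exponents(n, poly_order)
  D <- nrow(expo)
  kind <- rep("poly", D); trig <- rep(NA_integer_, D)
  if (include_trig) {
    kind <- c(kind, rep(c("sin", "cos"), each = n))
    trig <- c(trig, rep(seq_len(n), 2))
    expo <- rbind(expo, matrix(0L, 2 * n, n))
  }
  term_set(kind, expo, deriv = rep(0L, length(kind)),
           deriv_comp = rep(NA_integer_, length(kind)),
           modsq = rep(0L, length(kind)), trig = trig, vars = vars)
}

pde_term_set <- function(nc, poly_order, max_deriv, vars,
                         include_modsq = FALSE) {
  mono <- monomial_exponents(nc, poly_order)
  rows <- list()
  for (i in seq_len(nrow(mono))) {
    # pure monomial (no derivative factor), then each derivative factor
    rows[[length(rows) + 1]] <- list(expo = mono[i, ], d = 0L, c = NA_integer_,
                                     b = 0L)
    for (d in seq_len(max_deriv)) for (cc in seq_len(nc))
      rows[[length(rows) + 1]] <- list(expo = mono[i, ], d = as.integer(d),
                                       c = as.integer(cc), b = 0L)
  }
  if (include_modsq) {
    p <- poly_order
    for (b in seq_len(max(0, p %/% 2))) for (a in 0:(p - 2 * b))
      rows[[length(rows) + 1]] <- list(expo = c(a, rep(0L, nc - 1)),
                                       d = 0L, c = NA_integer_,
                                       b = as.integer(b))
  }
  term_set(rep("pde", length(rows)),
           do.call(rbind, lapply(rows, `[[`, "expo")),
           vapply(rows, `[[`, integer(1), "d"),
           vapply(rows, `[[`, integer(1), "c"),
           vapply(rows, `[[`, integer(1), "b"),
           rep(NA_integer_, length(rows)), vars)
}

# Evaluate ODE terms at a matrix of states (m x n) -> m x D feature matrix.
eval_ode_terms <- function(terms, X) {
  X <- rbind(X)  # keep matrix for single states
  m <- nrow(X)
  D <- n_terms(terms)
  Theta <- matrix(1, m, D)
  for (d in seq_len(D)) {
    if (terms$kind[d] == "poly") {
      col <- rep(1, m)
      e <- terms$expo[d, ]
      for (j in which(e > 0)) col <- col * X[, j]^e[j]
      Theta[, d] <- col
    } else if (terms$kind[d] == "sin") {
      Theta[, d] <- sin(X[, terms$trig[d]])
    } else {
      Theta[, d] <- cos(X[, terms$trig[d]])
    }
  }
  colnames(Theta) <- terms$label
  Theta
}

#' Build the candidate-function library for ODE discovery
#'
#' Assembles the feature matrix whose columns are the constant, all
#' multivariate monomials of total degree up to `poly_order` (graded
#' lexicographic order), and optionally `sin`/`cos` of each state, together
#' with the numerically differentiated regression target. Without trig terms
#' the library has `choose(n + poly_order, poly_order)` columns.
#'
#' @param series a [sindy_series()].
#' @param poly_order maximum total polynomial degree (>= 1).
#' @param include_trig add `sin` and `cos` of each state.
#' @param deriv_method differentiation method, see [differentiate_time()].
#' @param target optional precomputed target matrix (`m x n`); overrides
#'   differentiation (used when resampling keeps derivative stencils intact).
#' @return A `sindy_library`: feature matrix `Theta` (`m x D`), `terms`
#'   descriptors, `target` (`m x n`), and target `names`.
#' @examples
#' s <- sindy_series(cbind(x = sin(seq(0, 5, .1)), y = cos(seq(0, 5, .1))),
#'                   t = seq(0, 5, .1))
#' lib <- build_ode_library(s, poly_order = 2)
#' lib$terms$label  # 1, x, y, x^2, x*y, y^2
#' @export
build_ode_library <- function(series, poly_order, include_trig = FALSE,
                              deriv_method = "centered", target = NULL) {
  terms <- ode_term_set(n_states(series), poly_order, include_trig,
                        vars = series$names)
  Theta <- eval_ode_terms(terms, series$U)
  bad <- which(!apply(is.finite(Theta), 2, all))
  if (length(bad))
    stop("non-finite feature values in term(s): ",
         paste(terms$label[bad], collapse = ", "))
  if (is.null(target)) target <- differentiate_time(series, deriv_method)
  sindy_library(Theta, terms, target, series$names)
}

sindy_library <- function(Theta, terms, target, names) {
  target <- as.matrix(target)
  stopifnot(ncol(Theta) == n_terms(terms), nrow(Theta) == nrow(target))
  if (anyNA(Theta) || anyNA(target)) stop("library contains missing values")
  structure(list(Theta = Theta, terms = terms, target = target, names = names),
            class = "sindy_library")
}

#' @export
print.sindy_library <- function(x, ...) {
  cat(sprintf("<sindy_library> %d rows x %d terms -> %d target(s)\n",
              nrow(x$Theta), n_terms(x$terms), ncol(x$target)))
  cat(" terms:", paste(x$terms$label, collapse = ", "), "\n")
  invisible(x)
}

subset_library <- function(lib, cols) {
  sindy_library(lib$Theta[, cols, drop = FALSE], subset_terms(lib$terms, cols),
                lib$target, lib$names)
}

# Spectral differentiation along the first dimension of an n_x x m matrix on a
# periodic domain of extent L; exact for band-limited fields.
spectral_deriv <- function(mat, L, order) {
  nx <- nrow(mat)
  neg <- nx - nx %/% 2 - 1
  k <- 2 * pi / L * c(0:(nx %/% 2), if (neg > 0) -(neg:1))
  mult <- (1i * k)^order
  if (order %% 2 == 1 && nx %% 2 == 0) mult[nx / 2 + 1] <- 0  # Nyquist
  out <- mvfft(mvfft(mat) * mult, inverse = TRUE) / nx
  if (is.complex(mat)) out else Re(out)
}

# Centred finite differences (one-sided second-order stencils at the ends),
# applied `order` times; fallback for non-periodic fields.
fd_deriv <- function(mat, dx, order) {
  one <- function(v) {
    n <- length(v)
    d <- numeric(n)
    d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dx)
    d[1] <- (-3 * v[1] + 4 * v[2] - v[3]) / (2 * dx)
    d[n] <- (3 * v[n] - 4 * v[n - 1] + v[n - 2]) / (2 * dx)
    d
  }
  for (i in seq_len(order)) mat <- apply(mat, 2, one)
  mat
}

field_deriv <- function(field, comp, order) {
  mat <- field_component(field, comp)
  if (order == 0) return(mat)
  if (field$periodic) {
    dx <- field$x[2] - field$x[1]
    spectral_deriv(mat, L = dx * length(field$x), order)
  } else fd_deriv(mat, field$x[2] - field$x[1], order)
}

# Time derivative of each field component by centred differences (one-sided at
# the ends), returned as an n_x x m x n_c array.
field_time_deriv <- function(field) {
  dt <- field$t[2] - field$t[1]
  m <- length(field$t)
  out <- field$u
  for (i in seq_len(n_components(field))) {
    u <- field$u[, , i]
    d <- u
    d[, 2:(m - 1)] <- (u[, 3:m] - u[, 1:(m - 2)]) / (2 * dt)
    d[, 1] <- (-3 * u[, 1] + 4 * u[, 2] - u[, 3]) / (2 * dt)
    d[, m] <- (3 * u[, m] - 4 * u[, m - 1] + u[, m - 2]) / (2 * dt)
    out[, , i] <- d
  }
  out
}

# Evaluate one PDE term on the full grid -> n_x x m matrix.
eval_pde_term_grid <- function(field, terms, d) {
  nx <- length(field$x); m <- length(field$t)
  col <- matrix(if (is.complex(field$u)) 1 + 0i else 1, nx, m)
  e <- terms$expo[d, ]
  for (j in which(e > 0)) col <- col * field_component(field, j)^e[j]
  if (terms$modsq[d] > 0)
    col <- col * Mod(field_component(field, 1))^(2 * terms$modsq[d])
  if (terms$deriv[d] > 0)
    col <- col * field_deriv(field, terms$deriv_comp[d], terms$deriv[d])
  col
}

#' Build the pointwise candidate library for PDE discovery
#'
#' Columns are products of component monomials (total degree up to
#' `poly_order`) with a single spatial-derivative factor of order up to
#' `max_deriv` (order 0 means a pure monomial; the all-zero term is the
#' constant). Spatial derivatives use spectral differentiation on periodic
#' fields and centred finite differences otherwise; the target is the time
#' derivative by centred differences. Rows are all `(x, t)` grid points,
#' flattened time-major. For complex fields, `|u|^2`-weighted monomial terms
#' (e.g. `|u|^2*u`) are appended, the canonical cubic nonlinearity of
#' Schroedinger-type equations.
#'
#' This pointwise form is noise-fragile (derivatives amplify noise) and is
#' retained as a diagnostic baseline; the weak form
#' ([assemble_weak_system()]) is the robust path.
#'
#' @param field a [sindy_field()].
#' @param max_deriv maximum spatial derivative order (<= 4).
#' @param poly_order maximum monomial total degree.
#' @return A `sindy_library` with `M = n_x * m` rows.
#' @export
build_pde_library <- function(field, max_deriv, poly_order) {
  stopifnot(max_deriv <= 4, poly_order >= 0)
  nx <- length(field$x)
  if (nx < 2 * max_deriv + 1)
    stop("grid too coarse for derivative order ", max_deriv,
         ": need at least ", 2 * max_deriv + 1, " spatial points, have ", nx)
  terms <- pde_term_set(n_components(field), poly_order, max_deriv,
                        vars = field$names,
                        include_modsq = is.complex(field$u))
  D <- n_terms(terms)
  M <- nx * length(field$t)
  Theta <- matrix(if (is.complex(field$u)) NA_complex_ else NA_real_, M, D)
  for (d in seq_len(D))
    Theta[, d] <- as.vector(eval_pde_term_grid(field, terms, d))
  colnames(Theta) <- terms$label
  bad <- which(!apply(is.finite(Theta), 2, all))
  if (length(bad))
    stop("non-finite feature values in term(s): ",
         paste(terms$label[bad], collapse = ", "))
  ut <- field_time_deriv(field)
  target <- sapply(seq_len(n_components(field)), function(i)
    as.vector(ut[, , i]))
  sindy_library(Theta, terms, target, field$names)
}
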
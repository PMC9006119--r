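#' Test-function smoothness specification
#'
#' Separable compactly supported polynomial test functions
#' `w(x, t) = (1 - X^2)^p_x (1 - T^2)^p_t` on each subdomain mapped to
#' `[-1, 1]^2`. The exponents must be large enough that every integration by
#' parts leaves exactly zero boundary terms: `p_x >= max_deriv + 1` and
#' `p_t >= 2`.
#'
#' @param p_x,p_t polynomial smoothness exponents (dimensionless).
#' @return A `test_function_spec`.
#' @export
test_function_spec <- function(p_x, p_t = 3) {
  stopifnot(p_x >= 1, p_t >= 2)
  structure(list(p_x = as.integer(p_x), p_t = as.integer(p_t)),
            class = "test_function_spec")
}

# d-th derivative of (1 - s^2)^p evaluated at points s (|s| <= 1).
phi_deriv <- function(p, s, d = 0) {
  coef <- numeric(2 * p + 1)
  coef[2 * (0:p) + 1] <- choose(p, 0:p) * (-1)^(0:p)  # power s^(2j)
  for (k in seq_len(d)) {
    if (length(coef) == 1) return(rep(0, length(s)))
    coef <- coef[-1] * seq_along(coef[-1])
  }
  out <- rep(coef[length(coef)], length(s))
  for (j in rev(seq_len(length(coef) - 1))) out <- out * s + coef[j]
  out
}

#' Random subdomains for weak-form integration
#'
#' Draws `K` rectangular space-time subdomains `[x_k - h_x, x_k + h_x] x
#' [t_k - h_t, t_k + h_t]` whose centres are sampled uniformly, without
#' replacement, over the admissible interior grid points. Deterministic for a
#' given `seed`.
#'
#' @param field a [sindy_field()].
#' @param K number of domains.
#' @param h_x,h_t half-widths as fractions of the full spatial / temporal
#'   extent, in `(0, 0.5)`.
#' @param seed optional placement seed.
#' @return A `domain_set` with centre indices and half-widths in grid points
#'   (at least 4, so each domain contains at least 9 x 9 points).
#' @export
make_domains <- function(field, K, h_x = 0.1, h_t = 0.1, seed = NULL) {
  stopifnot(h_x > 0, h_x < 0.5, h_t > 0, h_t < 0.5, K >= 1)
  nx <- length(field$x); m <- length(field$t)
  hx_pts <- max(4L, round(h_x * (nx - 1)))
  ht_pts <- max(4L, round(h_t * (m - 1)))
  ix_range <- (hx_pts + 2L):(nx - hx_pts - 1L)  # strictly inside the extent
  it_range <- (ht_pts + 2L):(m - ht_pts - 1L)
  if (length(ix_range) < 1 || length(it_range) < 1)
    stop("field too small for half-widths h_x = ", h_x, ", h_t = ", h_t)
  n_adm <- length(ix_range) * length(it_range)
  if (K > n_adm)
    stop("K = ", K, " exceeds the ", n_adm, " admissible interior centres")
  pick <- with_seed(seed, sample.int(n_adm, K))
  structure(list(
    ix = ix_range[(pick - 1L) %% length(ix_range) + 1L],
    it = it_range[(pick - 1L) %/% length(ix_range) + 1L],
    hx_pts = hx_pts, ht_pts = ht_pts, K = as.integer(K), seed = seed),
    class = "domain_set")
}

#' Assemble the weak-form linear system
#'
#' Integrates the candidate PDE terms against compactly supported test
#' functions over each subdomain, transferring derivatives onto the smooth
#' test function wherever algebraically possible so that noisy data are never
#' differentiated:
#' * the time-derivative side is always moved onto `w`:
#'   `q0_k = -\int\int u w_t`;
#' * pure derivative terms (`d >= 1`, no monomial factor) are integrated with
#'   `d` parts-integrations: `(-1)^d \int\int u w^{(d)}`;
#' * advective powers `u^a u_x` use the conservative form
#'   `-1/(a+1) \int\int u^{a+1} w_x`;
#' * remaining product terms are integrated directly against `w` with a
#'   spectrally differentiated factor.
#'
#' Quadrature is the trapezoidal rule on the native grid points inside each
#' domain (no interpolation).
#'
#' @param field a [sindy_field()].
#' @param poly_order,max_deriv library specification, as in
#'   [build_pde_library()].
#' @param tf a [test_function_spec()]; default `p_x = max_deriv + 2`,
#'   `p_t = 3`.
#' @param domains a [make_domains()] result; default `K = 2 D` domains with
#'   10% half-widths.
#' @param seed placement seed used when `domains` is `NULL`.
#' @return A `weak_system`: `Q` (`K x D`), `q0` (`K x n_c`), `terms`, and the
#'   provenance (`tf`, `domains`).
#' @export
assemble_weak_system <- function(field, poly_order, max_deriv, tf = NULL,
                                 domains = NULL, seed = NULL) {
  tf <- tf %||% test_function_spec(p_x = max_deriv + 2, p_t = 3)
  if (tf$p_x < max_deriv + 1)
    stop("test-function exponent p_x = ", tf$p_x, " too small for derivative ",
         "order ", max_deriv, ": boundary terms would be nonzero")
  terms <- pde_term_set(n_components(field), poly_order, max_deriv,
                        vars = field$names,
                        include_modsq = is.complex(field$u))
  D <- n_terms(terms)
  nc <- n_components(field)
  domains <- domains %||% make_domains(field, K = 2L * D, seed = seed)
  dx <- field$x[2] - field$x[1]
  dtt <- field$t[2] - field$t[1]
  cplx <- is.complex(field$u)

  # integration rule and global integrand grid per term
  rules <- vector("list", D)
  for (d in seq_len(D)) {
    e <- terms$expo[d, ]; dd <- terms$deriv[d]; cc <- terms$deriv_comp[d]
    b <- terms$modsq[d]
    mono <- matrix(if (cplx) 1 + 0i else 1, length(field$x), length(field$t))
    for (j in which(e > 0)) mono <- mono * field_component(field, j)^e[j]
    if (b > 0) mono <- mono * Mod(field_component(field, 1))^(2 * b)
    if (dd == 0) {
      rules[[d]] <- list(type = "direct", G = mono, scale = 1)
    } else if (sum(e) == 0 && b == 0) {
      rules[[d]] <- list(type = "dw", G = field_component(field, cc),
                         order = dd, scale = (-1)^dd)
    } else if (dd == 1 && b == 0 && sum(e) == e[cc]) {
      a <- e[cc]
      rules[[d]] <- list(type = "dw", G = field_component(field, cc)^(a + 1),
                         order = 1L, scale = -1 / (a + 1))
    } else {
      rules[[d]] <- list(type = "direct",
                         G = mono * field_deriv(field, cc, dd), scale = 1)
    }
  }

  hx <- domains$hx_pts; ht <- domains$ht_pts
  sx <- hx * dx; st <- ht * dtt
  Xl <- (-hx:hx) / hx
  Tl <- (-ht:ht) / ht
  wq <- outer(dx * c(0.5, rep(1, 2 * hx - 1), 0.5),
              dtt * c(0.5, rep(1, 2 * ht - 1), 0.5))
  phx0 <- phi_deriv(tf$p_x, Xl, 0)
  pht0 <- phi_deriv(tf$p_t, Tl, 0)
  W0 <- outer(phx0, pht0) * wq
  Wt <- outer(phx0, phi_deriv(tf$p_t, Tl, 1) / st) * wq
  Wx <- lapply(seq_len(max_deriv), function(o)
    outer(phi_deriv(tf$p_x, Xl, o) / sx^o, pht0) * wq)

  K <- domains$K
  Q <- matrix(if (cplx) 0 + 0i else 0, K, D,
              dimnames = list(NULL, terms$label))
  q0 <- matrix(if (cplx) 0 + 0i else 0, K, nc)
  for (k in seq_len(K)) {
    xs <- (domains$ix[k] - hx):(domains$ix[k] + hx)
    ts <- (domains$it[k] - ht):(domains$it[k] + ht)
    for (d in seq_len(D)) {
      r <- rules[[d]]
      W <- if (r$type == "direct") W0 else Wx[[r$order]]
      Q[k, d] <- r$scale * sum(r$G[xs, ts] * W)
    }
    for (i in seq_len(nc))
      q0[k, i] <- -sum(field$u[, , i][xs, ts] * Wt)
  }
  structure(list(Q = Q, q0 = q0, terms = terms, tf = tf, domains = domains,
                 names = field$names),
            class = "weak_system")
}

#' @export
print.weak_system <- function(x, ...) {
  cat(sprintf("<weak_system> K = %d domains x D = %d terms, %d component(s)\n",
              nrow(x$Q), ncol(x$Q), ncol(x$q0)))
  invisible(x)
}

#' Sparse fit of a weak-form system
#'
#' Delegates to [stridge()] with the integrated library `Q` as features and
#' the integrated time-derivative side `q0` as target. Column normalization
#' defaults to on (weak columns are strongly correlated and wildly scaled).
#'
#' @param ws a [assemble_weak_system()] result.
#' @param config a [regression_config()].
#' @return A `sparse_model` on the weak term set.
#' @export
weak_fit <- function(ws, config = regression_config(normalize_columns = TRUE)) {
  if (nrow(ws$Q) < ncol(ws$Q))
    warning("fewer domains (", nrow(ws$Q), ") than library terms (",
            ncol(ws$Q), "); the weak least squares is underdetermined")
  lib <- list(Theta = ws$Q, terms = ws$terms, target = ws$q0,
              names = ws$names)
  stridge(lib, config)
}
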
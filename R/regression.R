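#' Regression hyperparameters for sequential thresholding
#'
#' @param lambda1 hard threshold on coefficient magnitude (same units as the
#'   coefficients; compared in normalized space when `normalize_columns` is
#'   on). Must be positive.
#' @param lambda2 ridge weight (>= 0); `0` gives sequentially thresholded
#'   least squares (STLS).
#' @param max_iter maximum threshold/refit sweeps (default 10).
#' @param normalize_columns scale library columns to unit l2 norm before
#'   thresholding (coefficients are rescaled on exit). Recommended for weak /
#'   PDE libraries whose columns are highly correlated and wildly scaled;
#'   off by default for ODE polynomial libraries.
#' @return A `regression_config` list.
#' @export
regression_config <- function(lambda1 = 0.1, lambda2 = 0, max_iter = 10L,
                              normalize_columns = FALSE) {
  stopifnot(lambda1 > 0, lambda2 >= 0, max_iter >= 1)
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 max_iter = as.integer(max_iter),
                 normalize_columns = isTRUE(normalize_columns)),
            class = "regression_config")
}

#' Ridge (Tikhonov) least squares
#'
#' Minimizes `||y - Theta xi||^2 + lambda2 ||xi||^2`. With `lambda2 = 0` the
#' minimum-norm least-squares solution is returned via a rank-revealing SVD.
#' Complex systems are supported (conjugate-transpose normal equations).
#'
#' @param Theta `M x D` feature matrix (real or complex).
#' @param y length-`M` response.
#' @param lambda2 ridge weight (>= 0).
#' @return Length-`D` coefficient vector.
#' @export
ridge_solve <- function(Theta, y, lambda2 = 0) {
  Theta <- as.matrix(Theta)
  if (lambda2 == 0) {
    sv <- svd(Theta)
    dvals <- sv$d
    tol <- max(dim(Theta)) * .Machine$double.eps * max(dvals, 0)
    pos <- dvals > tol
    if (!any(pos)) return(rep(if (is.complex(Theta)) 0 + 0i else 0, ncol(Theta)))
    coef_v <- Conj(t(sv$u[, pos, drop = FALSE])) %*% y / dvals[pos]
    out <- sv$v[, pos, drop = FALSE] %*% coef_v
  } else {
    A <- Conj(t(Theta)) %*% Theta
    diag(A) <- diag(A) + lambda2
    out <- solve(A, Conj(t(Theta)) %*% y)
  }
  drop(out)
}

#' Sparse regression by sequential thresholding (STLS / STRidge)
#'
#' For each target column: fit ridge regression on the active terms, zero all
#' coefficients with magnitude strictly below `lambda1`, refit on the
#' survivors, and repeat until the support is unchanged (or `max_iter` sweeps).
#' A final unregularized least-squares pass on the converged support removes
#' ridge shrinkage from the reported coefficients. With `lambda2 = 0` this is
#' exactly sequentially thresholded least squares.
#'
#' @param library a `sindy_library` (see [build_ode_library()]) or any list
#'   with `Theta`, `terms`, `target`, `names`.
#' @param config a [regression_config()].
#' @return A `sparse_model`: coefficient matrix `Xi` (`D x n`), `terms`, and
#'   logical `support` mask. If every coefficient of a target is thresholded
#'   away an empty-support model is returned with a warning.
#' @export
stridge <- function(library, config = regression_config()) {
  Theta <- library$Theta
  Y <- as.matrix(library$target)
  D <- ncol(Theta); n <- ncol(Y)
  cplx <- is.complex(Theta) || is.complex(Y)
  norms <- sqrt(colSums(Mod(Theta)^2))
  norms[norms == 0] <- 1
  Thn <- if (config$normalize_columns) sweep(Theta, 2, norms, "/") else Theta
  Xi <- matrix(if (cplx) 0 + 0i else 0, D, n,
               dimnames = list(library$terms$label, library$names))
  for (i in seq_len(n)) {
    y <- Y[, i]
    ynorm <- sqrt(sum(Mod(y)^2))
    # a target that is zero to rounding has nothing to explain
    if (ynorm <= 1e-12 * max(sqrt(colSums(Mod(Theta)^2)), 1)) {
      warning("target '", library$names[i], "' is numerically zero; ",
              "returning empty support")
      next
    }
    # with column normalization the response is normalized too, making the
    # threshold dimensionless (relative contribution per unit-norm column)
    if (config$normalize_columns) y <- y / ynorm
    active <- seq_len(D)
    for (it in seq_len(config$max_iter)) {
      xi <- ridge_solve(Thn[, active, drop = FALSE], y, config$lambda2)
      keep <- Mod(xi) >= config$lambda1  # strict inequality for removal
      new_active <- active[keep]
      if (identical(new_active, active)) break
      active <- new_active
      if (!length(active)) break
    }
    if (!length(active)) {
      warning("all terms thresholded away for target '", library$names[i],
              "'; returning empty support")
      next
    }
    # final unregularized refit on the original (unnormalized) columns
    Xi[active, i] <- ridge_solve(Theta[, active, drop = FALSE], Y[, i], 0)
  }
  sparse_model(Xi, library$terms, library$names)
}

#' Sparse dynamical model
#'
#' A `D x n` coefficient matrix over a declared term set; column `i` gives the
#' right-hand side of state `i` as a linear combination of the library terms.
#'
#' @param Xi coefficient matrix (`D x n`), real or complex.
#' @param terms the `term_set` the rows refer to.
#' @param names state / component labels (length `n`).
#' @return A `sparse_model` with a `support` mask (`Xi` is zero exactly where
#'   `support` is `FALSE`).
#' @export
sparse_model <- function(Xi, terms, names = colnames(Xi)) {
  Xi <- as.matrix(Xi)
  stopifnot(nrow(Xi) == n_terms(terms))
  support <- Mod(Xi) > 0
  dimnames(Xi) <- list(terms$label, names)
  dimnames(support) <- dimnames(Xi)
  structure(list(Xi = Xi, terms = terms, support = support, names = names),
            class = "sparse_model")
}

#' @export
print.sparse_model <- function(x, digits = 4, ...) {
  cat(sprintf("<sparse_model> %d terms -> %d state(s), %d active coefficients\n",
              nrow(x$Xi), ncol(x$Xi), sum(x$support)))
  for (i in seq_len(ncol(x$Xi))) {
    act <- which(x$support[, i])
    rhs <- if (!length(act)) "0" else paste(
      sprintf("%s %s*%s", ifelse(sign(Re(x$Xi[act, i])) < 0, "-", "+"),
              format(abs(x$Xi[act, i]), digits = digits),
              x$terms$label[act]), collapse = " ")
    cat(sprintf("  d%s/dt = %s\n", x$names[i] %||% paste0("x", i), rhs))
  }
  invisible(x)
}

model_support_size <- function(model) sum(model$support)
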
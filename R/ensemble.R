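#' Bootstrap resampling indices
#'
#' Draws `m` indices i.i.d. uniformly on `1..m` with replacement (a data
#' bootstrap). For large `m` the expected fraction of distinct indices
#' approaches `1 - exp(-1) ~ 0.632`.
#'
#' @param m number of rows.
#' @return Integer vector of length `m`.
#' @export
bootstrap_indices <- function(m) {
  stopifnot(m >= 1)
  sample.int(m, m, replace = TRUE)
}

#' Ensemble configuration
#'
#' @param q ensemble size (number of member models). Defaults: 100 for
#'   b(r)agging, 200 for library bagging.
#' @param mode `"bagging"` (mean aggregation), `"bragging"` (median, robust to
#'   outlier members), or `"library"` (term subsampling).
#' @param l library subsample size for `"library"` mode (defaults to
#'   `ceiling(D / 2)` at fit time).
#' @param inclusion_tol inclusion-probability threshold in `[0, 1]` applied to
#'   the aggregate (default 0.65).
#' @param resample_rows also bootstrap data rows inside each library-bagging
#'   member (off by default: library bagging samples terms instead of data).
#' @param seed optional RNG seed for the resampling.
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(q = 100L, mode = c("bagging", "bragging", "library"),
                            l = NULL, inclusion_tol = 0.65,
                            resample_rows = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(q >= 1, inclusion_tol >= 0, inclusion_tol <= 1)
  structure(list(q = as.integer(q), mode = mode, l = l,
                 inclusion_tol = inclusion_tol,
                 resample_rows = isTRUE(resample_rows), seed = seed),
            class = "ensemble_config")
}

new_ensemble_model <- function(members, availability, inclusion, aggregate,
                               terms, names, econf) {
  structure(list(members = members, availability = availability,
                 inclusion = inclusion, aggregate = aggregate, terms = terms,
                 names = names, econf = econf),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> q = %d members (%s), %d terms -> %d state(s)\n",
              length(x$members), x$econf$mode, n_terms(x$terms),
              ncol(x$inclusion)))
  cat(" aggregate support:", sum(x$aggregate$support), "coefficients\n")
  invisible(x)
}

ensemble_size <- function(em) length(em$members)

# zero-matrix member used when a fit fails
empty_member <- function(D, n, cplx = FALSE) {
  matrix(if (cplx) 0 + 0i else 0, D, n)
}

aggregate_members <- function(members, inclusion, mode, availability = NULL) {
  D <- nrow(members[[1]]); n <- ncol(members[[1]])
  arr <- array(unlist(members), dim = c(D, n, length(members)))
  agg <- if (mode == "bragging") apply(arr, c(1, 2), median)
  else if (is.null(availability)) apply(arr, c(1, 2), mean)
  else {
    # library mode: mean over the members the term was offered to
    offered <- colSums(availability)
    out <- apply(arr, c(1, 2), sum)
    sweep(out, 1, pmax(offered, 1), "/")
  }
  agg
}

#' Bagging / bragging ensemble of sparse models
#'
#' Fits `q` member models on joint row bootstraps of the feature matrix and
#' target (resampling regression rows, never raw snapshots, so derivative
#' stencils are intact), records per-term inclusion probabilities (the
#' fraction of members in which a coefficient is nonzero), and aggregates by
#' the elementwise mean (`bagging`) or median (`bragging`), zeroing every
#' coefficient whose inclusion probability falls below
#' `econf$inclusion_tol`.
#'
#' @param library a `sindy_library` (or weak-system pseudo-library).
#' @param econf an [ensemble_config()].
#' @param rconf a [regression_config()].
#' @param resample_fn resampling hook mapping `m` to row indices; defaults to
#'   [bootstrap_indices()]. Supplying `seq_len` makes every member see the
#'   full data (useful for degenerate checks).
#' @return An `ensemble_model` with members, inclusion matrix (`D x n`) and a
#'   thresholded aggregate `sparse_model`.
#' @export
fit_ensemble <- function(library, econf = ensemble_config(),
                         rconf = regression_config(),
                         resample_fn = bootstrap_indices) {
  M <- nrow(library$Theta)
  D <- ncol(library$Theta)
  n <- ncol(as.matrix(library$target))
  cplx <- is.complex(library$Theta)
  log_stage("fit_ensemble", q = econf$q, mode = econf$mode, rows = M, D = D)
  members <- with_seed(econf$seed, lapply(seq_len(econf$q), function(j) {
    idx <- resample_fn(M)
    sub <- list(Theta = library$Theta[idx, , drop = FALSE],
                terms = library$terms,
                target = as.matrix(library$target)[idx, , drop = FALSE],
                names = library$names)
    fit <- tryCatch(suppressWarnings(stridge(sub, rconf)),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning("member ", j, " fit failed; recorded as empty model")
      empty_member(D, n, cplx)
    } else fit$Xi
  }))
  availability <- matrix(TRUE, econf$q, D)
  inclusion <- Reduce(`+`, lapply(members, function(Xi) Mod(Xi) > 0)) / econf$q
  mode <- if (econf$mode == "library") "bagging" else econf$mode
  agg <- aggregate_members(members, inclusion, mode)
  agg[inclusion < econf$inclusion_tol] <- 0
  dimnames(inclusion) <- list(library$terms$label, library$names)
  new_ensemble_model(members, availability, inclusion,
                     sparse_model(agg, library$terms, library$names),
                     library$terms, library$names, econf)
}

#' Library-bagging ensemble
#'
#' Each member sees a random subset of `l` of the `D` library terms (drawn
#' uniformly without replacement) and all data rows; member coefficient
#' matrices are zero-padded back to the full library. Inclusion probabilities
#' are normalized by the number of members each term was offered to; the
#' aggregate is the mean over offering members, thresholded at
#' `econf$inclusion_tol`. Set `econf$resample_rows = TRUE` to additionally
#' bootstrap rows within each member.
#'
#' @inheritParams fit_ensemble
#' @return An `ensemble_model`; its `availability` matrix (`q x D`) records
#'   which terms were offered to each member.
#' @export
fit_library_ensemble <- function(library, econf = ensemble_config(q = 200L,
                                                                  mode = "library"),
                                 rconf = regression_config()) {
  M <- nrow(library$Theta)
  D <- ncol(library$Theta)
  n <- ncol(as.matrix(library$target))
  cplx <- is.complex(library$Theta)
  l <- econf$l %||% ceiling(D / 2)
  if (l > D) stop("library subsample size l = ", l, " exceeds D = ", D)
  log_stage("fit_library_ensemble", q = econf$q, l = l, rows = M, D = D)
  availability <- matrix(FALSE, econf$q, D)
  members <- with_seed(econf$seed, lapply(seq_len(econf$q), function(j) {
    cols <- sort(sample.int(D, l))
    availability[j, cols] <<- TRUE
    idx <- if (econf$resample_rows) bootstrap_indices(M) else seq_len(M)
    sub <- list(Theta = library$Theta[idx, cols, drop = FALSE],
                terms = subset_terms(library$terms, cols),
                target = as.matrix(library$target)[idx, , drop = FALSE],
                names = library$names)
    Xi <- empty_member(D, n, cplx)
    fit <- tryCatch(suppressWarnings(stridge(sub, rconf)),
                    error = function(e) NULL)
    if (is.null(fit)) warning("member ", j, " fit failed; recorded as empty")
    else Xi[cols, ] <- fit$Xi
    Xi
  }))
  offered <- colSums(availability)
  if (any(offered == 0))
    warning(sum(offered == 0), " term(s) never offered to any member; ",
            "their inclusion is set to 0 (increase q or l)")
  counts <- Reduce(`+`, lapply(members, function(Xi) Mod(Xi) > 0))
  inclusion <- sweep(counts, 1, pmax(offered, 1), "/")
  agg <- aggregate_members(members, inclusion, "library-mean", availability)
  agg[inclusion < econf$inclusion_tol] <- 0
  dimnames(inclusion) <- list(library$terms$label, library$names)
  new_ensemble_model(members, availability, inclusion,
                     sparse_model(agg, library$terms, library$names),
                     library$terms, library$names, econf)
}

#' Re-aggregate an ensemble with an alternative statistic
#'
#' The default aggregate computes the mean (bagging) or median (bragging)
#' over all members, zeros included, then thresholds by inclusion
#' probability. Whether member zeros should enter the location statistic is
#' a genuinely open choice; this helper exposes the conditional variant
#' (statistic over the members in which the term is active), which debiases
#' coefficients whose inclusion sits between the threshold and 1 — useful
#' when the aggregate is simulated or used as a control model.
#'
#' @param em an `ensemble_model`.
#' @param stat `"mean"` or `"median"`.
#' @param zeros `"include"` (the default aggregation) or `"exclude"`
#'   (conditional on the term being active in a member).
#' @param inclusion_tol threshold applied afterwards; defaults to the
#'   ensemble's configured tolerance.
#' @return A `sparse_model`.
#' @export
ensemble_aggregate <- function(em, stat = c("mean", "median"),
                               zeros = c("include", "exclude"),
                               inclusion_tol = em$econf$inclusion_tol) {
  stat <- match.arg(stat)
  zeros <- match.arg(zeros)
  fun <- if (stat == "mean") mean else median
  arr <- array(unlist(em$members),
               dim = c(dim(em$members[[1]]), length(em$members)))
  agg <- apply(arr, c(1, 2), function(v) {
    if (zeros == "exclude") v <- v[Mod(v) > 0]
    if (!length(v)) 0 else fun(v)
  })
  agg[em$inclusion < inclusion_tol] <- 0
  sparse_model(agg, em$terms, em$names)
}

#' Prescreen a library by inclusion probability
#'
#' Keeps the sub-library of terms whose maximum inclusion probability over
#' states reaches `keep_tol` — the library-bagging screening step before a
#' final b(r)agging fit on the reduced library. The threshold needs to be
#' selected carefully: too high removes relevant terms.
#'
#' @param library the `sindy_library` the ensemble was built on.
#' @param em an `ensemble_model` fitted on `library`.
#' @param keep_tol probability threshold in `[0, 1]`.
#' @return The reduced `sindy_library` (term descriptors preserved).
#' @export
prescreen_library <- function(library, em, keep_tol) {
  if (n_terms(em$terms) != ncol(library$Theta))
    stop("ensemble was not built on this library (term count mismatch)")
  keep <- apply(em$inclusion, 1, max) >= keep_tol
  if (!any(keep))
    stop("no term reaches inclusion ", keep_tol,
         "; lower keep_tol (max observed inclusion is ",
         round(max(em$inclusion), 3), ")")
  subset_library(library, which(keep))
}
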
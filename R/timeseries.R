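#' Multivariate time series container
#'
#' Holds an `m x n` snapshot matrix of `n` state variables sampled at `m`
#' strictly increasing times. This is the basic data object for ODE discovery.
#'
#' @param U numeric matrix, `m` samples by `n` state variables.
#' @param t numeric vector of length `m`, strictly increasing sample times.
#' @param names optional character vector of `n` state labels; defaults to
#'   column names of `U` or `x1..xn`.
#' @return An object of class `sindy_series` with fields `U`, `t`, `names`.
#' @examples
#' s <- sindy_series(cbind(sin(0:10), cos(0:10)), t = 0:10, names = c("x", "y"))
#' n_samples(s)
#' @export
sindy_series <- function(U, t, names = NULL) {
  U <- as.matrix(U)
  storage.mode(U) <- "double"
  t <- as.numeric(t)
  if (nrow(U) != length(t))
    stop("rows of U (", nrow(U), ") must align with t (", length(t), ")")
  if (nrow(U) < 2) stop("need at least 2 samples, got ", nrow(U))
  if (anyNA(U) || anyNA(t)) stop("missing values are not allowed")
  dt <- diff(t)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1L
    stop("non-monotone time at row ", bad, " (t = ", t[bad], ")")
  }
  if (is.null(names)) names <- colnames(U) %||% paste0("x", seq_len(ncol(U)))
  colnames(U) <- names
  structure(list(U = U, t = t, names = names), class = "sindy_series")
}

#' @rdname sindy_series
#' @param x a `sindy_series`.
#' @export
n_samples <- function(x) nrow(x$U)

#' @rdname sindy_series
#' @export
n_states <- function(x) ncol(x$U)

#' @export
print.sindy_series <- function(x, ...) {
  cat(sprintf("<sindy_series> %d samples x %d states (%s), t in [%g, %g]\n",
              n_samples(x), n_states(x), paste(x$names, collapse = ", "),
              x$t[1], x$t[length(x$t)]))
  invisible(x)
}

#' Time series with an actuation channel
#'
#' Extends [sindy_series()] with a control input sampled on the same time base,
#' as used for identification of forced systems.
#'
#' @inheritParams sindy_series
#' @param u_ctrl numeric vector of length `m`, the actuation signal.
#' @return An object of class `controlled_series` (also a `sindy_series`).
#' @export
controlled_series <- function(U, t, u_ctrl, names = NULL) {
  s <- sindy_series(U, t, names)
  u_ctrl <- as.numeric(u_ctrl)
  if (length(u_ctrl) != n_samples(s))
    stop("actuation length (", length(u_ctrl), ") must match samples (",
         n_samples(s), ")")
  if (anyNA(u_ctrl)) stop("missing values in actuation are not allowed")
  s$u_ctrl <- u_ctrl
  class(s) <- c("controlled_series", "sindy_series")
  s
}

#' Read a delimited time-series file
#'
#' Reads a delimited text file with a header row into a [sindy_series()].
#' Comma and tab separators are auto-detected from the extension
#' (`.tsv`/`.tab` means tab, anything else comma).
#'
#' @param path file path.
#' @param time_column name of the time column (default `"t"`).
#' @return A `sindy_series`.
#' @export
read_timeseries <- function(path, time_column = "t") {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE)
  if (!time_column %in% names(df))
    stop("time column '", time_column, "' not found in ", path)
  t <- as.numeric(df[[time_column]])
  U <- as.matrix(df[setdiff(names(df), time_column)])
  if (anyNA(t) || anyNA(U)) stop("missing values in ", path)
  sindy_series(U, t)
}

#' Write a time series as delimited text
#'
#' @param series a [sindy_series()].
#' @param path output path; `.tsv` writes tab-separated, otherwise CSV.
#' @param time_column column name for the time axis.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path, time_column = "t") {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(series$t, series$U, check.names = FALSE)
  names(df) <- c(time_column, series$names)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Yearly lynx-hare pelt counts, 1900-1920
#'
#' Loads the bundled 21-sample, two-species fixture of yearly pelt counts
#' (thousands) emulating the Hudson Bay Company records commonly used in
#' predator-prey studies. The exact table is the widely reproduced published
#' version, shipped as a stand-in since provenance of the archival records
#' varies between secondary sources.
#'
#' @return A `sindy_series` with `m = 21`, states `hare` and `lynx`,
#'   `t = 1900..1920`.
#' @export
load_lynx_hare_fixture <- function() {
  path <- system.file("extdata", "lynx_hare_1900_1920.csv", package = "esindy",
                      mustWork = TRUE)
  read_timeseries(path, time_column = "year")
}

#' Spatio-temporal field container
#'
#' Holds one or more real or complex field components `u(x, t)` on a uniform
#' space-time grid, the data object for PDE discovery.
#'
#' @param u matrix (`n_x` by `m`) or 3-d array (`n_x` by `m` by `n_c`) of field
#'   values; may be complex.
#' @param x uniform spatial grid (length `n_x`).
#' @param t uniform time grid (length `m`).
#' @param names optional component labels (default `u`, `v`, ...).
#' @param periodic logical; whether the spatial domain is periodic (affects
#'   differentiation). Default `TRUE`.
#' @return An object of class `sindy_field`.
#' @export
sindy_field <- function(u, x, t, names = NULL, periodic = TRUE) {
  if (is.matrix(u)) u <- array(u, dim = c(dim(u), 1L))
  if (length(dim(u)) != 3)
    stop("u must be a matrix or a 3-d array (n_x x m x n_c)")
  x <- as.numeric(x); t <- as.numeric(t)
  if (dim(u)[1] != length(x) || dim(u)[2] != length(t))
    stop("dim(u) = ", paste(dim(u), collapse = "x"),
         " inconsistent with length(x) = ", length(x),
         ", length(t) = ", length(t))
  if (!is_uniform(x)) stop("x grid is not uniform (tolerance 1e-10 relative)")
  if (!is_uniform(t)) stop("t grid is not uniform (tolerance 1e-10 relative)")
  if (anyNA(u)) stop("missing values are not allowed")
  nc <- dim(u)[3]
  if (is.null(names)) names <- c("u", "v", "w")[seq_len(nc)] %||% paste0("u", seq_len(nc))
  structure(list(u = u, x = x, t = t, names = names, periodic = periodic),
            class = "sindy_field")
}

#' @export
print.sindy_field <- function(x, ...) {
  cat(sprintf(
    "<sindy_field> %d x-points x %d t-points, %d component(s) (%s)%s%s\n",
    length(x$x), length(x$t), dim(x$u)[3], paste(x$names, collapse = ", "),
    if (is.complex(x$u)) ", complex" else "",
    if (x$periodic) ", periodic" else ""))
  invisible(x)
}

n_components <- function(field) dim(field$u)[3]

field_component <- function(field, i = 1L) field$u[, , i]

#' Write / read a field as a self-describing text container
#'
#' Fields are stored as schema-versioned JSON with full double precision
#' (datasets `x`, `t`, and per-component real/imaginary parts), so round trips
#' are lossless and the files remain diffable.
#'
#' @param field a [sindy_field()].
#' @param path file path.
#' @return `write_field` returns `path` invisibly; `read_field` a `sindy_field`.
#' @export
write_field <- function(field, path) {
  payload <- list(
    schema = "esindy-field-1",
    x = field$x, t = field$t, names = field$names,
    periodic = field$periodic,
    complex = is.complex(field$u),
    u_re = lapply(seq_len(n_components(field)), function(i) Re(field$u[, , i])),
    u_im = if (is.complex(field$u))
      lapply(seq_len(n_components(field)), function(i) Im(field$u[, , i]))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                          simplifyDataFrame = FALSE),
                      error = function(e) stop("not a valid field file: ",
                                               conditionMessage(e)))
  if (!identical(payload$schema, "esindy-field-1"))
    stop("unsupported field schema: ", payload$schema %||% "<missing>")
  nc <- length(payload$names)
  nx <- length(payload$x); m <- length(payload$t)
  u <- array(if (isTRUE(payload$complex)) NA_complex_ else NA_real_,
             dim = c(nx, m, nc))
  split_components <- function(z) {
    if (is.null(z)) return(NULL)
    # one component may come back as a matrix, several as a 3-d array
    if (is.array(z) && length(dim(z)) == 3)
      z <- lapply(seq_len(dim(z)[1]), function(i) z[i, , ])
    if (!is.list(z)) z <- list(z)
    z
  }
  ure <- split_components(payload$u_re)
  uim <- split_components(payload$u_im)
  for (i in seq_len(nc)) {
    re <- ure[[i]]
    if (!all(dim(re) == c(nx, m))) stop("truncated or corrupt field file")
    if (isTRUE(payload$complex)) u[, , i] <- re + 1i * uim[[i]]
    else u[, , i] <- re
  }
  sindy_field(u, payload$x, payload$t, names = payload$names,
              periodic = isTRUE(payload$periodic))
}
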
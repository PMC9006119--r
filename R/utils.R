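#' @keywords internal
"_PACKAGE"

#' @importFrom stats median quantile rnorm runif sd var setNames optim
#' @importFrom utils head tail read.csv write.csv modifyList
#' @importFrom Rcpp sourceCpp
#' @useDynLib esindy, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the global
# RNG stream is restored afterwards so seeded helpers do not perturb callers.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Structured per-stage log line; silent unless options(esindy.verbose = TRUE).
log_stage <- function(stage, ...) {
  if (!isTRUE(getOption("esindy.verbose", FALSE))) return(invisible(NULL))
  info <- list(...)
  kv <- if (length(info))
    paste(names(info), vapply(info, function(v) paste(format(v), collapse = ","),
                              character(1)), sep = "=", collapse = " ")
  else ""
  message(sprintf("[esindy] stage=%s %s", stage, kv))
  invisible(NULL)
}

rms <- function(x) sqrt(mean(Mod(x)^2))

is_uniform <- function(x, rel_tol = 1e-10) {
  if (length(x) < 2) return(TRUE)
  d <- diff(x)
  max(abs(d - d[1])) <= rel_tol * max(abs(d[1]), .Machine$double.eps)
}
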
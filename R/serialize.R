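# Model persistence: a single self-describing, schema-versioned JSON text
# container holding term descriptors plus full-precision numeric arrays —
# inspectable and diffable, and byte-identical across runs with the same
# configuration and seed.

.model_schema <- "esindy-model-1"

terms_payload <- function(terms) {
  list(kind = terms$kind, expo = terms$expo, deriv = terms$deriv,
       deriv_comp = terms$deriv_comp, modsq = terms$modsq, trig = terms$trig,
       vars = terms$vars)
}

terms_restore <- function(p) {
  term_set(p$kind, matrix(as.integer(p$expo), nrow = length(p$kind)),
           as.integer(p$deriv), as.integer(p$deriv_comp),
           as.integer(p$modsq), as.integer(p$trig), p$vars)
}

matrix_payload <- function(M) {
  if (is.complex(M)) list(re = Re(M), im = Im(M)) else list(re = M, im = NULL)
}

matrix_restore <- function(p, nrow) {
  re <- matrix(as.numeric(unlist(p$re)), nrow = nrow)
  if (is.null(p$im)) re else re + 1i * matrix(as.numeric(unlist(p$im)),
                                              nrow = nrow)
}

#' Save / load a model as schema-versioned JSON
#'
#' Lossless (double precision) round trip of coefficients, term descriptors,
#' ensemble members and inclusion probabilities. Files from a different
#' schema version, or truncated files, raise an explicit error.
#'
#' @param model a `sparse_model` or `ensemble_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` the restored
#'   object.
#' @export
save_model <- function(model, path) {
  payload <- if (inherits(model, "sparse_model")) {
    list(schema = .model_schema, type = "sparse",
         terms = terms_payload(model$terms), names = model$names,
         xi = matrix_payload(model$Xi))
  } else if (inherits(model, "ensemble_model")) {
    list(schema = .model_schema, type = "ensemble",
         terms = terms_payload(model$terms), names = model$names,
         mode = model$econf$mode, inclusion_tol = model$econf$inclusion_tol,
         inclusion = model$inclusion, availability = model$availability,
         members = lapply(model$members, matrix_payload),
         aggregate = matrix_payload(model$aggregate$Xi))
  } else stop("cannot serialize objects of class ", class(model)[1])
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                    simplifyDataFrame = FALSE),
                error = function(e)
                  stop("not a valid model file (truncated or corrupt): ",
                       conditionMessage(e)))
  if (!identical(p$schema, .model_schema))
    stop("unsupported model schema '", p$schema %||% "<missing>",
         "'; this build reads ", .model_schema)
  terms <- terms_restore(p$terms)
  D <- n_terms(terms)
  if (identical(p$type, "sparse")) {
    sparse_model(matrix_restore(p$xi, D), terms, p$names)
  } else if (identical(p$type, "ensemble")) {
    members <- lapply(p$members, function(mp) {
      M <- matrix_restore(mp, nrow = D)
      dimnames(M) <- list(terms$label, p$names)
      M
    })
    econf <- ensemble_config(q = length(members),
                             mode = if (identical(p$mode, "library"))
                               "library" else p$mode,
                             inclusion_tol = p$inclusion_tol)
    inclusion <- matrix(as.numeric(p$inclusion), D)
    dimnames(inclusion) <- list(terms$label, p$names)
    new_ensemble_model(members, matrix(as.logical(p$availability),
                                       length(members)),
                       inclusion,
                       sparse_model(matrix_restore(p$aggregate, D), terms,
                                    p$names),
                       terms, p$names, econf)
  } else stop("unknown model type '", p$type, "'")
}

#' Read a YAML run configuration
#'
#' A run configuration bundles the seed with named parameter groups
#' (`regression`, `ensemble`, `weak`, `noise`, `forecast`); identical
#' configurations yield identical outputs. Missing groups fall back to the
#' package defaults.
#'
#' @param path YAML file path.
#' @return A `run_config` list with members `seed`, `regression` (a
#'   [regression_config()]), `ensemble` (an [ensemble_config()]), `weak`,
#'   `noise` and `forecast` lists.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("run config must set a seed")
  as_run_config(raw)
}

#' @rdname read_run_config
#' @param raw a named list with the same structure as the YAML file.
#' @export
as_run_config <- function(raw) {
  structure(list(
    seed = as.integer(raw$seed),
    regression = do.call(regression_config, raw$regression %||% list()),
    ensemble = do.call(ensemble_config, raw$ensemble %||% list()),
    weak = modifyList(list(K = NULL, h_x = 0.1, h_t = 0.1, p_x = NULL,
                           p_t = 3), raw$weak %||% list()),
    noise = modifyList(list(level = 0), raw$noise %||% list()),
    forecast = modifyList(list(n_realizations = 1000L, models_per_draw = 5L,
                               level = 0.95), raw$forecast %||% list())),
    class = "run_config")
}
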
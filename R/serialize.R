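#' Write model parameters to JSON
#'
#' @param params A [tnfm_params()] or [tpfm_params()].
#' @param path Output path; `NULL` returns the JSON string.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_params <- function(params, path = NULL) {
  family <- if (inherits(params, "tnfm_params")) "tnfm"
    else if (inherits(params, "tpfm_params")) "tpfm"
    else stop("params must be tnfm_params or tpfm_params", call. = FALSE)
  obj <- list(family = family, params = as.list(unclass(params)))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}

#' Read model parameters from JSON
#'
#' @param path Path to a JSON file as written by [write_params()].
#' @return A [tnfm_params()] or [tpfm_params()].
#' @export
read_params <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$family) || is.null(obj$params)) {
    stop("parameter JSON must contain 'family' and 'params'", call. = FALSE)
  }
  ctor <- switch(obj$family, tnfm = tnfm_params, tpfm = tpfm_params,
                 stop("unknown model family: ", obj$family, call. = FALSE))
  do.call(ctor, as.list(obj$params))
}
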
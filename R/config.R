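#' Load array / medium parameters from a YAML configuration file
#'
#' The file may contain an `array:` block (fields of [ring_array_spec()]) and
#' a `medium:` block (fields of [medium()]); missing fields keep their
#' defaults. Requires the `yaml` package.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return list with `spec` and `medium`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path))
    return(list(spec = ring_array_spec(), medium = medium()))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading configuration files requires the 'yaml' package")
  cfg <- yaml::read_yaml(path)
  spec <- do.call(ring_array_spec, as.list(cfg$array %||% list()))
  med <- do.call(medium, as.list(cfg$medium %||% list()))
  list(spec = spec, medium = med)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
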
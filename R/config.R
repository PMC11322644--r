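#' Read and write configuration blocks as YAML
#'
#' Model and preprocessing configurations round-trip through YAML blocks
#' whose keys mirror the constructor argument names exactly, so a run can
#' be specified in a plain config file.
#'
#' @param params an [epileptor_params()] object.
#' @param cfg a [preprocess_config()] object.
#' @param path YAML file path.
#' @return The written path (writers, invisibly) or the reconstructed
#'   object (readers).
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_epileptor_config(epileptor_params(x0 = -2.20), f)
#' read_epileptor_config(f)$x0
#' @name config-io
NULL

#' @rdname config-io
#' @export
write_epileptor_config <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname config-io
#' @export
read_epileptor_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(epileptor_params, v[setdiff(names(v), character(0))])
}

#' @rdname config-io
#' @export
write_preprocess_config <- function(cfg, path) {
  v <- unclass(cfg)
  v$resample_hz <- if (is.na(cfg$resample_hz)) NULL else cfg$resample_hz
  yaml::write_yaml(v, path)
  invisible(path)
}

#' @rdname config-io
#' @export
read_preprocess_config <- function(path) {
  v <- yaml::read_yaml(path)
  if (is.null(v$resample_hz)) v$resample_hz <- NA
  do.call(preprocess_config, v)
}
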
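# Run configuration and structured logging for scripted / CLI use.

#' Load a run configuration
#'
#' One scenario per YAML (or JSON) file: a `seed`, a `scenario` name and a
#' nested parameter tree for the modules involved. Defaults are filled in
#' and the complete configuration is echoed into the output directory when
#' a run starts, so every artifact is reproducible from the echo + seed.
#'
#' @param path YAML or JSON file.
#' @return object of class `run_config` (a named list).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the yaml package", call. = FALSE)
    yaml::read_yaml(path)
  }
  defaults <- list(seed = 1L, scenario = "jar", out = "hiptomo_out",
                   verbose = FALSE, params = list())
  cfg <- utils::modifyList(defaults, cfg)
  structure(cfg, class = "run_config")
}

#' Echo a configuration into an output directory
#'
#' @param cfg a `run_config`.
#' @param out_dir output directory (created if needed).
#' @return path to the written echo file, invisibly.
#' @export
echo_config <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(out_dir, "config_echo.json")
  jsonlite::write_json(unclass(cfg), p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(p)
}

hip_log <- function(verbose, stage, t0 = NULL, ...) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  msg <- paste0(...)
  el <- if (is.null(t0)) ""
        else sprintf(" [%.2fs]", as.numeric(Sys.time()) - as.numeric(t0))
  message(sprintf("[hiptomo] %-12s %s%s", stage, msg, el))
}
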
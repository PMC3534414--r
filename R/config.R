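# Run configuration: TOML-style key/value file with optional [section]
# headers. All CLI flags override config values; unknown keys are errors.

run_config_defaults <- function() {
  list(kgml_dir = NULL, network = NULL, profiles = NULL, ec_map = NULL,
       dest_counts = NULL, name_map = NULL, pool_list = NULL,
       fusion_table = NULL, out = ".",
       peak = 10, fdr = 0.2, t = 1, pseudocount = 1,
       solver = "exact", time_limit = Inf, seed = 1, top_k = 1,
       clamp = NA_real_)
}

#' Read a run-configuration file
#'
#' Simple TOML-style format: \code{key = value} lines, optional
#' \code{[section]} headers (sections are flattened), \code{#} comments.
#' Unknown keys are an error; numeric and logical values are coerced.
#'
#' @param path configuration file.
#' @return Named list of parameters merged over the defaults.
#' @export
read_run_config <- function(path) {
  defaults <- run_config_defaults()
  if (is.null(path)) return(defaults)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[.*\\]$", lines)]
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop_usage("config line is not 'key = value': ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    if (!key %in% names(defaults))
      stop_usage("unknown config key: ", key)
    old <- defaults[[key]]
    defaults[[key]] <- if (is.numeric(old) || is.null(old)) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num) && !is.null(old) && is.numeric(old)) {
        stop_usage("config key ", key, " must be numeric, got: ", val)
      }
      if (is.na(num)) val else num
    } else val
  }
  defaults
}

#' Serialize a run configuration next to the outputs
#'
#' @param config named list.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, if (is.null(v)) "" else format(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
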
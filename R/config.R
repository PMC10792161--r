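#' Read a pipeline configuration file
#'
#' Plain `key = value` text configuration for the quantification defaults:
#' `ssi_min`, `scan_width_mm`, `roi_radius_mm`, `global_method`
#' (`otsu`/`mean`), and the Phansalkar parameters `phansalkar_window_radius_px`,
#' `phansalkar_k`, `phansalkar_r`, `phansalkar_p`, `phansalkar_q`. Lines
#' starting with `#` and blank lines are ignored; unknown keys raise an
#' error so typos do not silently fall back to defaults.
#'
#' @param path Path to the config file, or `NULL` for pure defaults.
#' @return A named list of settings.
#' @export
read_octa_config <- function(path = NULL) {
  defaults <- list(
    ssi_min = 8,
    scan_width_mm = 3,
    roi_radius_mm = 1.5,
    global_method = "otsu",
    phansalkar_window_radius_px = 15,
    phansalkar_k = 0.25,
    phansalkar_r = 0.5,
    phansalkar_p = 2,
    phansalkar_q = 10
  )
  if (is.null(path)) return(defaults)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) abort(sprintf("Malformed config line: '%s'", ln))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(defaults)) abort(sprintf("Unknown config key: '%s'", key))
    defaults[[key]] <- if (key == "global_method") {
      match.arg(val, c("otsu", "mean"))
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) abort(sprintf("Config key '%s' needs a number, got '%s'.", key, val))
      num
    }
  }
  defaults
}
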
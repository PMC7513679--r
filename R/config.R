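#' Read a sectioned key/value configuration file
#'
#' Minimal, dependency-free run configuration: one `key = value` pair per
#' line, optional `[section]` headers prefixing subsequent keys as
#' `section.key`, `#` comments, blank lines ignored. Values are parsed as
#' numeric when possible (comma-separated values become numeric vectors),
#' as logical for `true`/`false`, and as strings otherwise. Command-line
#' flags are expected to override file values; the file mirrors the
#' [analysis_grid()] and [scenario_config()] defaults.
#'
#' @param path configuration file
#' @return named list of values (names like `grid.win_ms`,
#'   `scenario.n_trials`)
#' @examples
#' p <- tempfile()
#' writeLines(c("[grid]", "win_ms = 80", "[scenario]",
#'              "coupling_freqs = 22, 27.5", "n_trials = 16"), p)
#' read_config(p)$scenario.n_trials
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  section <- ""
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    parsed <- if (!anyNA(num)) num
      else if (length(parts) == 1 && tolower(parts) %in% c("true", "false"))
        as.logical(toupper(parts))
      else if (length(parts) > 1) parts else val
    out[[if (nzchar(section)) paste(section, key, sep = ".") else key]] <- parsed
  }
  out
}

#' Build an analysis grid and scenario from a configuration list
#'
#' Applies `grid.*` entries as [analysis_grid()] arguments and `scenario.*`
#' entries as [scenario_config()] arguments; `overrides` (e.g. parsed
#' command-line flags) take precedence over the file.
#'
#' @param config list from [read_config()], or NULL
#' @param overrides named list of scenario overrides
#' @return list with `grid` and `scenario`
#' @export
configure_run <- function(config = NULL, overrides = list()) {
  config <- config %||% list()
  nms <- names(config) %||% character(0)
  pick <- function(prefix) {
    keys <- nms[startsWith(nms, paste0(prefix, "."))]
    stats::setNames(config[keys], sub(paste0("^", prefix, "\\."), "", keys))
  }
  gargs <- pick("grid")
  sargs <- pick("scenario")
  sargs[names(overrides)] <- overrides
  list(grid = do.call(analysis_grid, gargs),
       scenario = do.call(scenario_config, sargs))
}
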
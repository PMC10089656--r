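#' Read a tidy trial table
#'
#' Column dictionary (version 1): `observer` (id string), `condition`
#' (`HM` / `VM` / `M-scale` or custom), `angle` (`HM`/`LVM`/`UVM`),
#' `ecc` (degrees), `scaled` (logical), `sf` (cpd), `log10_contrast`,
#' `response` (0/1), `trial` (presentation index, optional). A `cell`
#' column is derived if absent.
#'
#' @param path Path to a comma-delimited text file.
#' @return Validated trial data frame. Malformed rows abort with their
#'   line numbers; an empty file returns an empty table with a warning.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) {
    warning("empty trial file: ", path)
    return(empty_trials())
  }
  required <- c("observer", "angle", "ecc", "scaled", "sf",
                "log10_contrast", "response")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stopf("missing required column(s): %s", paste(missing, collapse = ", "))
  }
  if (!"condition" %in% names(raw)) raw$condition <- NA_character_
  raw$scaled <- as.logical(raw$scaled)
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1
  bad <- !(raw$response %in% c(0, 1)) |
    !raw$angle %in% c("HM", "LVM", "UVM") |
    !is.finite(raw$sf) | raw$sf <= 0 |
    !is.finite(raw$log10_contrast) |
    !is.finite(raw$ecc) | raw$ecc < 0 | is.na(raw$scaled)
  if (any(bad)) {
    stopf("malformed trial row(s) at line(s): %s",
          paste(utils::head(line_no[bad], 10), collapse = ", "))
  }
  raw$response <- as.integer(raw$response)
  if (!"cell" %in% names(raw)) raw$cell <- cell_id(raw$angle, raw$ecc, raw$scaled)
  if (!"trial" %in% names(raw)) raw$trial <- seq_len(nrow(raw))
  raw
}

empty_trials <- function() {
  data.frame(observer = character(0), condition = character(0),
             angle = character(0), ecc = numeric(0), scaled = logical(0),
             cell = character(0), sf = numeric(0),
             log10_contrast = numeric(0), response = integer(0),
             trial = integer(0), stringsAsFactors = FALSE)
}

#' Write a tidy trial table
#'
#' @param trials Trial data frame.
#' @param path Output path (comma-delimited text).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  check_trials(trials, allow_empty = TRUE)
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

check_trials <- function(trials, allow_empty = FALSE) {
  required <- c("cell", "sf", "log10_contrast", "response")
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0) {
    stopf("trial table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  if (!allow_empty && nrow(trials) == 0) stopf("trial table is empty")
  if (nrow(trials) > 0 && !all(trials$response %in% c(0L, 1L))) {
    stopf("responses must be 0/1")
  }
  invisible(trials)
}

#' Read a pipeline configuration file
#'
#' Accepts JSON (preferred; parsed with jsonlite) or a flat
#' `key: value` text format for simple scalar options. The configuration
#' round-trips losslessly through [jsonlite::write_json()].
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("no such config file: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (grepl("^\\s*\\{", txt)) {
    return(jsonlite::fromJSON(txt, simplifyVector = TRUE))
  }
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([^:]+)\\s*:\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3
  if (any(bad)) stopf("unparseable config line(s): %s",
                      paste(lines[bad], collapse = "; "))
  vals <- lapply(kv, function(m) {
    v <- trimws(m[3])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num
    else if (v %in% c("true", "TRUE", "yes")) TRUE
    else if (v %in% c("false", "FALSE", "no")) FALSE
    else v
  })
  setNames(vals, vapply(kv, function(m) trimws(m[2]), character(1)))
}
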
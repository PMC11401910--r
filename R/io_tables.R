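# TSV is the single tabular dialect of the package: tab-separated, '.'
# decimal, header row, optional leading '#'-comment header lines carrying
# the serialised run configuration.

#' Write a TSV table
#'
#' @param df Data frame.
#' @param path Output path.
#' @param header Optional character vector written as leading `#` comment
#'   lines (e.g. a serialised [run_config()]).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV table written by [write_tsv()]
#'
#' @param path Input path.
#' @return Data frame (leading `#` comment lines are skipped).
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

peak_table_columns <- c("residue", "residue_type", "wH_ppm", "wC_ppm",
                        "intensity", "noise_floor", "domain", "flags")

#' Read an NMR peak table
#'
#' Expects a TSV with columns `residue`, `residue_type`, `wH_ppm`,
#' `wC_ppm`, `intensity`, `noise_floor`, `domain`, `flags`. The `flags`
#' column holds semicolon-separated labels from
#' `{overlapped, broadened_below_noise, excluded}` (empty for a clean peak).
#'
#' @param path Path to the TSV file.
#' @return Validated data frame of peaks (one row per assigned methyl).
#' @export
read_peak_table <- function(path) {
  df <- read_tsv(path)
  validate_peak_table(df, source = path)
}

#' Validate an in-memory peak table
#'
#' @param df Data frame with the [read_peak_table()] columns.
#' @param source Label used in error messages.
#' @return The validated data frame (with `flags` normalised to character).
#' @export
validate_peak_table <- function(df, source = "peak table") {
  miss <- setdiff(peak_table_columns, names(df))
  if (length(miss))
    stop(source, ": missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$residue)) {
    dup <- unique(df$residue[duplicated(df$residue)])
    stop(source, ": duplicate residue id(s): ", paste(dup, collapse = ", "))
  }
  if (any(df$intensity < 0))
    stop(source, ": negative intensities")
  if (any(df$noise_floor <= 0))
    stop(source, ": noise_floor must be > 0")
  df$flags <- as.character(df$flags)
  df$flags[is.na(df$flags)] <- ""
  known <- c("", "overlapped", "broadened_below_noise", "excluded")
  toks <- unlist(strsplit(df$flags, ";", fixed = TRUE))
  bad <- setdiff(unique(toks), known)
  if (length(bad))
    stop(source, ": unknown flag(s): ", paste(bad, collapse = ", "))
  df
}

# TRUE where the peak carries the given flag
has_flag <- function(flags, what) {
  vapply(strsplit(as.character(flags), ";", fixed = TRUE),
         function(x) what %in% x, logical(1))
}

#' Read a titration table
#'
#' @param path TSV with columns `concentration_uM` and `signal`.
#' @return Validated data frame.
#' @export
read_titration_table <- function(path) {
  df <- read_tsv(path)
  if (!all(c("concentration_uM", "signal") %in% names(df)))
    stop(path, ": needs columns concentration_uM, signal")
  if (any(df$concentration_uM <= 0))
    stop(path, ": concentrations must be > 0")
  df
}
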
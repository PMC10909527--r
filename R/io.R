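# Reading and writing the long-format trial table.

.required_trial_cols <- c("participant_id", "stimulus_id", .affect_vars)

#' Read a trial table from CSV
#'
#' Expects a comma-separated file with a header row, decimal points, and at
#' least the identifier and feature columns; extra columns are preserved as
#' passthrough metadata. Validates types and key uniqueness with informative
#' errors.
#'
#' @param path file path.
#' @return A trial-table data.frame.
#' @export
read_trial_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.required_trial_cols, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("trial table %s is missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (v in .affect_vars) {
    if (!is.numeric(tab[[v]])) {
      suppressWarnings(num <- as.numeric(tab[[v]]))
      bad <- which(is.na(num) & !is.na(tab[[v]]) & nzchar(tab[[v]]))
      if (length(bad)) {
        stop(sprintf("column %s has unparseable numeric value(s) at row(s): %s",
                     v, paste(utils::head(bad, 5L), collapse = ", ")),
             call. = FALSE)
      }
      tab[[v]] <- num
    }
  }
  key <- paste(tab$participant_id, tab$stimulus_id)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop(sprintf("duplicated (participant, stimulus) key(s): %s",
                 paste(utils::head(dups, 5L), collapse = "; ")),
         call. = FALSE)
  }
  for (cc in c("valence_category", "arousal_category")) {
    if (cc %in% names(tab)) tab[[cc]] <- factor(tab[[cc]])
  }
  tab
}

#' Write a trial table to CSV
#'
#' UTF-8 comma-separated values with a header row, full precision.
#'
#' @param table trial table.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Compact JSON writer used for reports and manifests.
.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
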
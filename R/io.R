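# Plain-CSV interchange with provenance headers.  Every table written by
# the pipeline starts with '#'-prefixed key: value lines (stage, parameters,
# seed) so each stage can be re-run standalone; readers skip those lines.
# Numeric columns are written with full precision so tables round-trip
# losslessly.

#' Write a data.frame as CSV with provenance header lines
#'
#' @param x data.frame.
#' @param path Output file.
#' @param provenance Named character/list written as `# key: value` lines.
#' @export
write_table_csv <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance)) {
    writeLines(sprintf("# %s: %s", names(provenance),
                       vapply(provenance, as.character, character(1))), con)
  }
  y <- x
  for (i in seq_along(y)) {
    if (is.numeric(y[[i]]) && !is.integer(y[[i]])) {
      y[[i]] <- ifelse(is.na(y[[i]]), "NA", sprintf("%.17g", y[[i]]))
    }
    if (inherits(x[[i]], "Date")) y[[i]] <- format(x[[i]])
  }
  utils::write.csv(y, con, row.names = FALSE, quote = FALSE)
}

#' Read a CSV written by [write_table_csv()]
#'
#' @param path File path.
#' @param date_cols Columns to parse as `Date`.
#' @return data.frame (provenance lines skipped; available as the
#'   `provenance` attribute).
#' @export
read_table_csv <- function(path, date_cols = "date") {
  lines <- readLines(path)
  prov <- grep("^#", lines, value = TRUE)
  x <- utils::read.csv(text = lines[!grepl("^#", lines)],
                       stringsAsFactors = FALSE)
  for (dc in intersect(date_cols, names(x))) x[[dc]] <- as.Date(x[[dc]])
  attr(x, "provenance") <- sub("^# ", "", prov)
  x
}

STUDY_TABLES <- c("titration_table", "standardization_table",
                  "scintillation_table", "gran_table", "station_table",
                  "covariate_table")

#' Write a simulated study to a directory of CSV tables
#'
#' One CSV per table plus `truth.json` holding the generating parameters
#' and per-date expected rates.
#'
#' @param study A `simulated_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(stage = "simulate", seed = study$truth$config$seed,
            n_dates = study$truth$config$n_dates)
  for (tb in STUDY_TABLES) {
    write_table_csv(study[[tb]], file.path(dir, paste0(tb, ".csv")), prov)
  }
  if (!is.null(study$count_table)) {
    ct <- data.frame(sample = rownames(study$count_table),
                     study$count_table, check.names = FALSE)
    write_table_csv(ct, file.path(dir, "count_table.csv"), prov)
    cc <- data.frame(sample = rownames(study$community_covariates),
                     study$community_covariates)
    write_table_csv(cc, file.path(dir, "community_covariates.csv"), prov)
  }
  truth <- study$truth
  truth$config <- unclass(truth$config)
  truth$rates$date <- format(truth$rates$date)
  truth$carbonate$date <- format(truth$carbonate$date)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Directory path.
#' @return A `simulated_study` (without the reconstructed config class).
#' @export
read_study <- function(dir) {
  out <- lapply(STUDY_TABLES, function(tb) {
    read_table_csv(file.path(dir, paste0(tb, ".csv")))
  })
  names(out) <- STUDY_TABLES
  ct_path <- file.path(dir, "count_table.csv")
  if (file.exists(ct_path)) {
    ct <- read_table_csv(ct_path)
    m <- as.matrix(ct[, -1, drop = FALSE])
    rownames(m) <- ct$sample
    out$count_table <- m
    cc <- read_table_csv(file.path(dir, "community_covariates.csv"))
    rownames(cc) <- cc$sample
    out$community_covariates <- cc[, -1, drop = FALSE]
  }
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    out$truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  }
  structure(out, class = "simulated_study")
}
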
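assay_schemas <- list(
  titration = c("ligand_total_uM", "intensity_au"),
  proteolysis = c("protease_uM", "time_min", "intact_fraction"),
  thermal = c("temp_C", "signal_au"),
  itc = c("injection_index", "volume_uL", "heat_ucal")
)

#' Read an assay CSV with schema validation
#'
#' Reads one of the four assay CSV schemas, checking the header and every
#' cell. Non-numeric cells (including locale decimal-comma numbers such as
#' `"1,5"`) raise an explicit error naming the offending row and column
#' rather than being silently coerced.
#'
#' @param path Path to the CSV file.
#' @param kind One of `"titration"`, `"proteolysis"`, `"thermal"`, `"itc"`.
#' @return A tibble with the schema's numeric columns.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_assay_csv(simulate_titration(variant_truth("WT")), p)
#' read_assay_csv(p, "titration")
#' @export
read_assay_csv <- function(path, kind = names(assay_schemas)) {
  kind <- match.arg(kind)
  cols <- assay_schemas[[kind]]
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(cols, names(raw))
  if (length(missing) > 0) {
    stop(sprintf("malformed %s file '%s': expected columns %s; missing %s",
                 kind, path, paste(cols, collapse = ", "),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- raw[cols]
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(out[[cl]]))
    bad <- which(is.na(v) & !is.na(out[[cl]]))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' in column '%s', row %d of '%s'",
                   out[[cl]][bad[1]], cl, bad[1], path), call. = FALSE)
    }
    out[[cl]] <- v
  }
  tibble::as_tibble(out)
}

#' Write an assay table as CSV
#'
#' Full-precision CSV writer for the simulated or measured assay tables;
#' a write-then-read round trip is lossless well beyond 9 significant
#' digits.
#'
#' @param data Assay tibble (as produced by the `simulate_*` functions).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Write the ground-truth panel as JSON for provenance
#'
#' @param truth A `variant_truth` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a pipeline report to disk
#'
#' Emits the report tibbles as TSV files plus a JSON file holding the
#' scores, regression block and provenance, under a single directory.
#'
#' @param report A `variant_report` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "variant_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in c("traits", "derived", "codes", "scores")) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(report[[nm]], f, progress = FALSE)
    files <- c(files, f)
  }
  j <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(scores = report$scores, regression = report$regression,
         published = report$published, provenance = report$provenance),
    j, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, j)
  invisible(files)
}
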
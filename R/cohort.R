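# Measurement cohorts: one row per saline bolus. Repeated boluses in the
# same patient are separate rows, exactly as the validation study treated
# them. CSV is the interchange format; JSON export is provided for
# programmatic use.

COHORT_COLUMNS <- c(
  "record_id", "sex", "age_y", "weight_kg", "tbw_l",
  "infusate_volume_l", "infusate_percent_nacl",
  "na_initial_mmol_l", "na_final_mmol_l", "urine_osm_mosm_l",
  "causative_condition"
)

NA_PLAUSIBLE <- c(80, 200)  # mmol/L band; out-of-band values warn, not fail

#' Construct a measurement cohort
#'
#' Validates a data frame of saline-response measurements and wraps it as a
#' `"cohort"`. Numeric fields must be positive; plasma sodium values
#' outside 80-200 mmol/L are flagged with a warning but kept (severe
#' hyponatremia is clinically extreme yet real); duplicate `record_id`s are
#' an error.
#'
#' @param records data frame with columns `record_id`, `sex`, `age_y`,
#'   `weight_kg`, `tbw_l`, `infusate_volume_l`, `infusate_percent_nacl`,
#'   `na_initial_mmol_l`, `na_final_mmol_l`, `urine_osm_mosm_l` and
#'   optionally `causative_condition`.
#' @param provenance free-text description of where the records came from.
#' @return Object of class `"cohort"`: list with elements `records` and
#'   `provenance`.
#' @seealso [load_cohort()], [siadh_cohort()], [generate_cohort()]
#' @export
cohort <- function(records, provenance = "user-supplied") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"causative_condition" %in% names(records)) {
    records$causative_condition <- NA_character_
  }
  missing_cols <- setdiff(COHORT_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop_parse(sprintf("cohort is missing column(s): %s",
                       paste(missing_cols, collapse = ", ")))
  }
  records <- records[COHORT_COLUMNS]
  if (nrow(records)) {
    num_cols <- setdiff(COHORT_COLUMNS, c("sex", "causative_condition"))
    for (col in num_cols) {
      v <- suppressWarnings(as.numeric(records[[col]]))
      bad <- which(!is.finite(v) | v <= 0)
      if (length(bad)) {
        stop_parse(sprintf("column %s, row %d: value %s is not a positive number",
                           dQuote(col), bad[1L],
                           dQuote(as.character(records[[col]][bad[1L]]))))
      }
      records[[col]] <- v
    }
    if (anyDuplicated(records$record_id)) {
      stop_parse(sprintf("duplicate record_id: %s",
                         paste(unique(records$record_id[
                           duplicated(records$record_id)]), collapse = ", ")))
    }
    records$sex <- normalize_sex(records$sex)
    for (col in c("na_initial_mmol_l", "na_final_mmol_l")) {
      out <- which(records[[col]] < NA_PLAUSIBLE[1L] |
                     records[[col]] > NA_PLAUSIBLE[2L])
      if (length(out)) {
        warning(sprintf("%s outside the %d-%d mmol/L plausibility band in row(s) %s",
                        col, NA_PLAUSIBLE[1L], NA_PLAUSIBLE[2L],
                        paste(out, collapse = ", ")), call. = FALSE)
      }
    }
  }
  structure(list(records = records, provenance = provenance),
            class = "cohort")
}

#' Read a cohort from CSV
#'
#' @param path path to a CSV file following the cohort schema (decimal
#'   point, UTF-8, header required; see [cohort()] for the column list).
#' @param provenance provenance string stored on the result; defaults to
#'   the file path.
#' @return A [cohort()].
#' @export
load_cohort <- function(path, provenance = path) {
  if (!file.exists(path)) stop_parse(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  cohort(df, provenance = provenance)
}

#' Write a cohort to CSV
#'
#' Inverse of [load_cohort()]: `load_cohort(write_cohort(x, f))` restores
#' `x`'s records exactly.
#'
#' @param x a [cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  utils::write.csv(x$records, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Export a cohort as JSON
#'
#' @param x a [cohort()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
cohort_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "cohort"))
  js <- jsonlite::toJSON(
    list(provenance = x$provenance, records = x$records),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
  )
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' The bundled SIADH validation cohort
#'
#' The published 15-measurement cohort of plasma sodium responses to saline
#' infusate in twelve SIADH patients (three patients contributed repeated
#' boluses, recorded as separate measurements). Volumes span 0.10-1.5 L,
#' NaCl strengths are 0.9% and 2.5%, urine osmolality 336-890 mOsmol/L.
#' SIADH was diagnosed by the Bartter-Schwartz criteria with urine
#' osmolality above plasma osmolality; the `causative_condition` column is
#' metadata only.
#'
#' @return A [cohort()] with 15 records.
#' @examples
#' siadh_cohort()$records[1, c("tbw_l", "na_initial_mmol_l")]
#' @export
siadh_cohort <- function() {
  path <- system.file("extdata", "siadh_cohort.csv", package = "natremia",
                      mustWork = TRUE)
  load_cohort(path,
              provenance = "published 15-measurement SIADH saline-response validation cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d record(s) - %s\n", nrow(x$records), x$provenance))
  if (nrow(x$records)) print(utils::head(x$records, 6L))
  invisible(x)
}

#' @export
as.data.frame.cohort <- function(x, ...) x$records
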
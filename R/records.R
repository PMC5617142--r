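#' @importFrom rlang .data %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# Column order of the on-disk record format. `value` is empty for nondetects.
RECORD_COLUMNS <- c(
  "site_id", "sample_id", "date", "matrix", "chemical_id",
  "value", "detect_status", "reporting_limit"
)

MATRIX_LEVELS <- c("water", "sediment")
DETECT_LEVELS <- c("quantified", "estimated", "nondetect")

#' Units used for concentrations in a sampling matrix
#'
#' Water concentrations are expressed in micrograms per liter, sediment
#' concentrations in micrograms per kilogram (dry weight).
#'
#' @param matrix `"water"` or `"sediment"`.
#' @return A unit string.
#' @export
matrix_units <- function(matrix) {
  matrix <- match.arg(matrix, MATRIX_LEVELS)
  if (matrix == "water") "ug/L" else "ug/kg"
}

#' Validate a table of concentration records
#'
#' Checks the structural invariants of censored concentration reporting:
#' a numeric value is present if and only if the result is not a nondetect;
#' values are non-negative and reporting limits strictly positive;
#' `estimated` results lie below their reporting limit and `quantified`
#' results at or above it (the laboratory reporting-limit convention under
#' which quantifiable detections below the reporting limit are flagged as
#' estimated).
#'
#' @param records A data frame with columns
#'   `site_id, sample_id, date, matrix, chemical_id, value, detect_status,
#'   reporting_limit`.
#' @return The records, invisibly, as a tibble with normalized column types.
#'   Errors (mentioning offending row indices) if any invariant is violated.
#' @export
validate_records <- function(records) {
  missing <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing) > 0) {
    stop("record table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  records <- as_tibble(records)[RECORD_COLUMNS]
  records$value <- as.numeric(records$value)
  records$reporting_limit <- as.numeric(records$reporting_limit)
  records$date <- as.Date(records$date)

  bad_matrix <- which(!records$matrix %in% MATRIX_LEVELS)
  if (length(bad_matrix) > 0) {
    stop("unknown matrix label in row(s) ", row_str(bad_matrix),
         " (expected 'water' or 'sediment')", call. = FALSE)
  }
  bad_status <- which(!records$detect_status %in% DETECT_LEVELS)
  if (length(bad_status) > 0) {
    stop("unknown detect_status in row(s) ", row_str(bad_status), call. = FALSE)
  }

  nondetect <- records$detect_status == "nondetect"
  bad <- which(nondetect & !is.na(records$value))
  if (length(bad) > 0) {
    stop("nondetect row(s) ", row_str(bad), " carry a numeric value; ",
         "left-censored results must have an empty value", call. = FALSE)
  }
  bad <- which(!nondetect & is.na(records$value))
  if (length(bad) > 0) {
    stop("detected row(s) ", row_str(bad), " have no numeric value",
         call. = FALSE)
  }
  bad <- which(!is.na(records$value) & records$value < 0)
  if (length(bad) > 0) {
    stop("negative concentration value in row(s) ", row_str(bad),
         call. = FALSE)
  }
  bad <- which(is.na(records$reporting_limit) | records$reporting_limit <= 0)
  if (length(bad) > 0) {
    stop("reporting_limit must be > 0; offending row(s) ", row_str(bad),
         call. = FALSE)
  }
  est <- records$detect_status == "estimated"
  bad <- which(est & records$value >= records$reporting_limit)
  if (length(bad) > 0) {
    stop("estimated result at or above its reporting limit in row(s) ",
         row_str(bad), call. = FALSE)
  }
  quant <- records$detect_status == "quantified"
  bad <- which(quant & records$value < records$reporting_limit)
  if (length(bad) > 0) {
    stop("quantified result below its reporting limit in row(s) ",
         row_str(bad), call. = FALSE)
  }
  invisible(records)
}

row_str <- function(idx, max_show = 5L) {
  shown <- paste(utils::head(idx, max_show), collapse = ", ")
  if (length(idx) > max_show) shown <- paste0(shown, ", ...")
  shown
}

#' Read concentration records from a delimited text file
#'
#' Expects a comma-delimited UTF-8 file with header
#' `site_id,sample_id,date,matrix,chemical_id,value,detect_status,reporting_limit`
#' and an empty `value` field for nondetects. Every row is validated against
#' the censoring invariants (see [validate_records()]); row order is
#' preserved.
#'
#' @param path Path to the file.
#' @return A tibble of validated records.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      site_id = readr::col_character(),
      sample_id = readr::col_character(),
      date = readr::col_date(),
      matrix = readr::col_character(),
      chemical_id = readr::col_character(),
      value = readr::col_double(),
      detect_status = readr::col_character(),
      reporting_limit = readr::col_double()
    ),
    progress = FALSE
  )
  missing <- setdiff(RECORD_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop("record file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_records(raw)
  as_tibble(raw)[RECORD_COLUMNS]
}

#' Write concentration records to a delimited text file
#'
#' Inverse of [read_records()]: writing and re-reading reproduces the record
#' collection exactly (nondetect values are serialized as empty fields,
#' dates as ISO-8601).
#'
#' @param records Validated record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records <- validate_records(records)
  readr::write_csv(records, path, na = "", progress = FALSE)
  invisible(path)
}

#' Cross-check records against the chemical and site registries
#'
#' Produces a report of referential problems rather than erroring: chemical
#' ids absent from the chemical registry, site ids absent from the site
#' registry, and matrix inconsistencies (a result reported in a matrix the
#' chemical is not analyzed in). An empty report means the dataset is
#' consistent with its registries.
#'
#' @param records Validated record tibble.
#' @param chemicals Chemical registry (see [read_chemicals()]).
#' @param sites Site registry (see [read_sites()]).
#' @return A tibble with columns `kind` (`orphan_chemical`, `orphan_site`,
#'   `matrix_mismatch`), `id`, and `detail`; zero rows when consistent.
#' @export
validate_against_registries <- function(records, chemicals, sites) {
  records <- validate_records(records)
  report <- list()

  orphan_chem <- sort(setdiff(unique(records$chemical_id),
                              chemicals$chemical_id))
  if (length(orphan_chem) > 0) {
    report$chem <- tibble(
      kind = "orphan_chemical", id = orphan_chem,
      detail = "chemical_id not present in chemical registry"
    )
  }
  orphan_site <- sort(setdiff(unique(records$site_id), sites$site_id))
  if (length(orphan_site) > 0) {
    report$site <- tibble(
      kind = "orphan_site", id = orphan_site,
      detail = "site_id not present in site registry"
    )
  }

  if ("analyzed_in" %in% names(chemicals)) {
    seen <- dplyr::distinct(records, .data$chemical_id, .data$matrix)
    seen <- dplyr::inner_join(seen, chemicals[c("chemical_id", "analyzed_in")],
                              by = "chemical_id")
    bad <- seen[!mapply(grepl, seen$matrix, seen$analyzed_in, fixed = TRUE), ]
    if (nrow(bad) > 0) {
      report$mat <- tibble(
        kind = "matrix_mismatch", id = bad$chemical_id,
        detail = paste0("result reported in ", bad$matrix,
                        " but analyzed_in is '", bad$analyzed_in, "'")
      )
    }
  }

  if (length(report) == 0) {
    tibble(kind = character(), id = character(), detail = character())
  } else {
    dplyr::bind_rows(report)
  }
}
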
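#' Recode left-censored results as zeroes
#'
#' Nondetect rows receive a numeric value of 0; quantified and estimated
#' rows keep their reported value unchanged. Zero-recoding keeps the
#' rank-transformations and summary statistics downstream well defined
#' without imposing a distributional model on the censored tail.
#'
#' @param records Validated record tibble.
#' @return The records with a numeric `value` in every row.
#' @export
recode_censored <- function(records) {
  records <- validate_records(records)
  records$value[records$detect_status == "nondetect"] <- 0
  records
}

#' Per-chemical detection frequency, median, and maximum
#'
#' For each chemical analyzed in the given matrix: the number of analyzed
#' samples, the number of detections (quantified or estimated — results
#' reported below the reporting limit still count as detections), the
#' detection frequency in percent, and the median and maximum over the
#' censored-recoded values (zeroes included). The denominator is the
#' per-chemical analyzed count, which may differ between chemicals.
#'
#' @param records Censored-recoded record tibble (see [recode_censored()]).
#' @param matrix `"water"` or `"sediment"`.
#' @return A frequency tibble with columns `chemical_id`, `n_analyzed`,
#'   `n_detected`, `detection_frequency`, `median`, `maximum`.
#' @export
chemical_summary <- function(records, matrix = c("water", "sediment")) {
  matrix <- match.arg(matrix)
  if (anyNA(records$value)) {
    stop("records must be censored-recoded first (recode_censored)",
         call. = FALSE)
  }
  records |>
    dplyr::filter(.data$matrix == !!matrix) |>
    dplyr::group_by(.data$chemical_id) |>
    dplyr::summarise(
      n_analyzed = dplyr::n(),
      n_detected = sum(.data$detect_status != "nondetect"),
      detection_frequency = 100 * .data$n_detected / .data$n_analyzed,
      median = stats::median(.data$value),
      maximum = max(.data$value),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$detection_frequency),
                   dplyr::desc(.data$maximum), .data$chemical_id)
}

#' Retain chemicals detected in at least a given percentage of samples
#'
#' The ubiquity filter: chemicals whose basin-wide detection frequency is
#' greater than or equal to `threshold_percent` (inclusive boundary) are
#' retained, ordered by descending detection frequency with ties broken by
#' descending maximum and then by id. The filter is antitone in the
#' threshold: raising it can only shrink the panel.
#'
#' @param freq_table Output of [chemical_summary()] (or any table with
#'   `chemical_id`, `detection_frequency`, `maximum`).
#' @param threshold_percent Detection-frequency threshold in \[0, 100\];
#'   default 30, retaining chemicals that are fairly ubiquitous across a
#'   basin-wide survey.
#' @return Character vector of chemical ids (the panel).
#' @export
ubiquity_filter <- function(freq_table, threshold_percent = 30) {
  stopifnot(is.numeric(threshold_percent), length(threshold_percent) == 1,
            threshold_percent >= 0, threshold_percent <= 100)
  kept <- freq_table[freq_table$detection_frequency >= threshold_percent, ]
  kept <- kept[order(-kept$detection_frequency, -kept$maximum,
                     kept$chemical_id), ]
  kept$chemical_id
}

#' Reduce records to one observation per site: the maximum concentration
#'
#' For each site and chemical in the matrix, the maximum censored-recoded
#' concentration over all that site's samples; sites where a chemical was
#' never detected get 0. Maxima are used as the site statistic because, for
#' a screening survey, they are the condition of greatest toxicological
#' concern, and sparse revisit counts with heavy censoring preclude
#' distribution-based mean estimation.
#'
#' @param records Censored-recoded record tibble.
#' @param matrix `"water"` or `"sediment"`.
#' @return A `site_max_matrix`: numeric matrix (sites x chemicals) with
#'   attributes `matrix` and `units`.
#' @export
site_maxima <- function(records, matrix = c("water", "sediment")) {
  matrix <- match.arg(matrix)
  if (anyNA(records$value)) {
    stop("records must be censored-recoded first (recode_censored)",
         call. = FALSE)
  }
  sub <- records[records$matrix == matrix, ]
  if (nrow(sub) == 0) stop("no records in matrix '", matrix, "'",
                           call. = FALSE)
  sites <- sort(unique(sub$site_id))
  chems <- sort(unique(sub$chemical_id))
  m <- matrix(0, nrow = length(sites), ncol = length(chems),
              dimnames = list(sites, chems))
  agg <- stats::aggregate(value ~ site_id + chemical_id, data = sub, FUN = max)
  m[cbind(agg$site_id, agg$chemical_id)] <- agg$value
  structure(m, class = c("site_max_matrix", "matrix", "array"),
            matrix = matrix, units = matrix_units(matrix))
}

#' @export
print.site_max_matrix <- function(x, ...) {
  cat("Site-maximum concentration matrix (", attr(x, "matrix"), ", ",
      attr(x, "units"), "): ", nrow(x), " sites x ", ncol(x),
      " chemicals\n", sep = "")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))),
                   drop = FALSE], ...)
  invisible(x)
}

#' Restrict a site-maximum matrix to a chemical panel
#'
#' @param site_max A `site_max_matrix`.
#' @param panel Character vector of chemical ids (see [ubiquity_filter()]).
#' @return The restricted `site_max_matrix` (panel order preserved).
#' @export
restrict_to_panel <- function(site_max, panel) {
  missing <- setdiff(panel, colnames(site_max))
  if (length(missing) > 0) {
    stop("panel chemical(s) absent from site-maximum matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- site_max[, panel, drop = FALSE]
  structure(out, class = class(site_max), matrix = attr(site_max, "matrix"),
            units = attr(site_max, "units"))
}

#' Total chemical-class and total site concentrations
#'
#' Sums the per-site maximum concentrations over all chemicals of each
#' class, and over all classes, per site. Because the summands are maxima
#' taken over multiple samples, the totals may be biased high; they are a
#' screening statistic, not an exposure average. Conservation holds
#' exactly: the site total equals the sum of its class totals.
#'
#' @param site_max A `site_max_matrix`.
#' @param chemicals Chemical registry covering every column of `site_max`.
#' @return A list with `class_totals` (tibble: `site_id`, `chemical_class`,
#'   `class_total`) and `site_totals` (tibble: `site_id`, `site_total`).
#' @export
class_totals <- function(site_max, chemicals) {
  unregistered <- setdiff(colnames(site_max), chemicals$chemical_id)
  if (length(unregistered) > 0) {
    stop("unregistered chemical(s) in site-maximum matrix: ",
         paste(unregistered, collapse = ", "), call. = FALSE)
  }
  cls <- chemicals$chemical_class[match(colnames(site_max),
                                        chemicals$chemical_id)]
  per_class <- t(rowsum(t(unclass(site_max)), group = cls))
  ct <- tibble::as_tibble(as.data.frame.table(per_class,
                                              stringsAsFactors = FALSE))
  names(ct) <- c("site_id", "chemical_class", "class_total")
  st <- tibble(site_id = rownames(site_max),
               site_total = unname(rowSums(unclass(site_max))))
  list(class_totals = tibble::as_tibble(ct), site_totals = st)
}

#' Chemicals frequently detected in both matrices
#'
#' @param panel_water,panel_sediment Chemical-id vectors (ubiquity-filtered
#'   panels for the two matrices).
#' @return A list: `shared` (sorted intersection), `n_shared`, `n_water`,
#'   `n_sediment`, and `n_entries` (the two panel sizes summed, i.e. the
#'   number of frequently detected chemical-by-matrix entries).
#' @export
matrix_overlap <- function(panel_water, panel_sediment) {
  shared <- sort(intersect(panel_water, panel_sediment))
  list(
    shared = shared,
    n_shared = length(shared),
    n_water = length(panel_water),
    n_sediment = length(panel_sediment),
    n_entries = length(panel_water) + length(panel_sediment)
  )
}
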
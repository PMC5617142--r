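CHEMICAL_CLASSES <- c(
  "Pharmaceutical", "Pesticide", "Sterol", "Hormone", "PAH",
  "Flame retardant", "Fragrance", "Industrial", "Fecal indicator",
  "Alkylphenol", "Phenolic", "Plasticizer", "Insect repellant", "Other"
)

ARCHETYPES <- c("urban_wwtp", "agricultural", "reference", "mixed")

#' Read the chemical registry
#'
#' Columns: `chemical_id`, `name` (optional, defaults to the id),
#' `chemical_class`, `log_kow` (may be empty), `analyzed_in`
#' (`water`, `sediment`, or `water|sediment`), `eeq_factor` (estrogenic
#' potency relative to 17beta-estradiol; empty for chemicals with no
#' published potency). Chemicals with no natural class should be registered
#' as `Other`.
#'
#' @param path CSV path.
#' @return Chemical registry tibble.
#' @export
read_chemicals <- function(path) {
  chem <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  validate_chemicals(chem)
}

#' @rdname read_chemicals
#' @param chemicals A data frame to validate/normalize in place of a file.
#' @export
validate_chemicals <- function(chemicals) {
  need <- c("chemical_id", "chemical_class")
  missing <- setdiff(need, names(chemicals))
  if (length(missing) > 0) {
    stop("chemical registry missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  chemicals <- tibble::as_tibble(chemicals)
  if (anyDuplicated(chemicals$chemical_id)) {
    dup <- unique(chemicals$chemical_id[duplicated(chemicals$chemical_id)])
    stop("duplicate chemical_id in registry: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!"name" %in% names(chemicals)) chemicals$name <- chemicals$chemical_id
  if (!"log_kow" %in% names(chemicals)) chemicals$log_kow <- NA_real_
  if (!"analyzed_in" %in% names(chemicals)) {
    chemicals$analyzed_in <- "water|sediment"
  }
  if (!"eeq_factor" %in% names(chemicals)) chemicals$eeq_factor <- NA_real_
  chemicals$log_kow <- as.numeric(chemicals$log_kow)
  chemicals$eeq_factor <- as.numeric(chemicals$eeq_factor)
  bad <- which(!chemicals$chemical_class %in% CHEMICAL_CLASSES)
  if (length(bad) > 0) {
    stop("unknown chemical_class: ",
         paste(unique(chemicals$chemical_class[bad]), collapse = ", "),
         " (use one of: ", paste(CHEMICAL_CLASSES, collapse = ", "), ")",
         call. = FALSE)
  }
  neg <- which(!is.na(chemicals$eeq_factor) & chemicals$eeq_factor < 0)
  if (length(neg) > 0) {
    stop("negative eeq_factor for: ",
         paste(chemicals$chemical_id[neg], collapse = ", "), call. = FALSE)
  }
  chemicals
}

#' Read the site registry
#'
#' Columns: `site_id`, `river`, optional `sites_order` (ordinal position
#' along the sampled reach) and `archetype` (land-use archetype:
#' `urban_wwtp`, `agricultural`, `reference`, or `mixed`). Each site belongs
#' to exactly one river.
#'
#' @param path CSV path.
#' @return Site registry tibble.
#' @export
read_sites <- function(path) {
  sites <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  validate_sites(sites)
}

#' @rdname read_sites
#' @param sites A data frame to validate/normalize in place of a file.
#' @export
validate_sites <- function(sites) {
  need <- c("site_id", "river")
  missing <- setdiff(need, names(sites))
  if (length(missing) > 0) {
    stop("site registry missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sites <- tibble::as_tibble(sites)
  if (anyDuplicated(sites$site_id)) {
    dup <- unique(sites$site_id[duplicated(sites$site_id)])
    stop("duplicate site_id in registry: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if ("archetype" %in% names(sites)) {
    bad <- which(!is.na(sites$archetype) & !sites$archetype %in% ARCHETYPES)
    if (length(bad) > 0) {
      stop("unknown archetype: ",
           paste(unique(sites$archetype[bad]), collapse = ", "),
           call. = FALSE)
    }
  }
  sites
}

#' Read water-quality benchmarks
#'
#' Columns: `chemical_id`, `value` (micrograms per liter), `kind`
#' (`chronic` or `acute`), `source`. A chemical may have several entries;
#' [select_water_benchmark()] picks the screening value.
#'
#' @param path CSV path.
#' @return Benchmark tibble.
#' @export
read_water_benchmarks <- function(path) {
  bm <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("chemical_id", "value", "kind")
  missing <- setdiff(need, names(bm))
  if (length(missing) > 0) {
    stop("benchmark table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bm$value <- as.numeric(bm$value)
  if (any(is.na(bm$value) | bm$value <= 0)) {
    stop("benchmark values must be > 0", call. = FALSE)
  }
  bad <- which(!bm$kind %in% c("chronic", "acute"))
  if (length(bad) > 0) {
    stop("benchmark kind must be 'chronic' or 'acute'", call. = FALSE)
  }
  tibble::as_tibble(bm)
}

#' Read tiered sediment-quality guidelines
#'
#' Columns: `chemical_id`, `TEC`, `MEC`, `PEC` (micrograms per kilogram),
#' `source`. The threshold (TEC), midpoint (MEC), and probable (PEC) effect
#' concentrations must be ordered TEC <= MEC <= PEC and strictly positive.
#'
#' @param path CSV path.
#' @return Guideline tibble.
#' @export
read_sediment_guidelines <- function(path) {
  sg <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  validate_sediment_guidelines(sg)
}

#' @rdname read_sediment_guidelines
#' @param guidelines A data frame to validate in place of a file.
#' @export
validate_sediment_guidelines <- function(guidelines) {
  need <- c("chemical_id", "TEC", "MEC", "PEC")
  missing <- setdiff(need, names(guidelines))
  if (length(missing) > 0) {
    stop("guideline table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  guidelines <- tibble::as_tibble(guidelines)
  for (col in c("TEC", "MEC", "PEC")) {
    guidelines[[col]] <- as.numeric(guidelines[[col]])
  }
  bad <- which(guidelines$TEC <= 0 | guidelines$TEC > guidelines$MEC |
                 guidelines$MEC > guidelines$PEC)
  if (length(bad) > 0) {
    stop("guideline triple must satisfy 0 < TEC <= MEC <= PEC; offending ",
         "chemical(s): ", paste(guidelines$chemical_id[bad], collapse = ", "),
         call. = FALSE)
  }
  guidelines
}

#' Read estrogenic potency (EEQ) factors
#'
#' Columns: `chemical_id`, `eeq_factor` (dimensionless potency relative to
#' 17beta-estradiol), `source`. Factor tables are user-supplied input;
#' the file shipped with the package
#' (`eeq_factors_synthetic.csv`) contains synthetic example factors with
#' literature-plausible magnitudes and is not an authoritative compilation.
#'
#' @param path CSV path.
#' @return Factor tibble.
#' @export
read_eeq_factors <- function(path) {
  ef <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("chemical_id", "eeq_factor")
  missing <- setdiff(need, names(ef))
  if (length(missing) > 0) {
    stop("EEQ factor table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ef$eeq_factor <- as.numeric(ef$eeq_factor)
  if (any(is.na(ef$eeq_factor) | ef$eeq_factor < 0)) {
    stop("eeq_factor must be a non-negative number", call. = FALSE)
  }
  tibble::as_tibble(ef)
}

#' Read a published per-chemical summary table
#'
#' Parses a transcription of a per-matrix chemical summary (chemical class,
#' log Kow, reporting limit, sample count, median, maximum, detection
#' frequency). An empty `median` cell encodes a published median below the
#' chemical's reporting limit (printed "<RL"); it is read as `NA` with
#' `median_below_rl = TRUE`. The copy shipped under `inst/extdata`
#' transcribes the frequently detected (>= 30%) chemicals of a basin-wide
#' Great Lakes tributary survey.
#'
#' @param path CSV path; defaults to the shipped transcription.
#' @return Tibble with one row per chemical and matrix.
#' @export
read_summary_table <- function(path = system.file("extdata",
                                                  "chemical_summary_table.csv",
                                                  package = "cecscreen")) {
  tab <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("matrix", "chemical", "chemical_class", "reporting_limit",
            "n", "median", "maximum", "detection_frequency")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("summary table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab$median <- as.numeric(tab$median)
  tab$median_below_rl <- is.na(tab$median)
  tibble::as_tibble(tab)
}
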
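#' Select the screening benchmark for a chemical in water
#'
#' Returns the lowest chronic water-quality benchmark available for the
#' chemical, regardless of intended species; when no chronic benchmark
#' exists the lowest available acute benchmark is used instead (e.g. the
#' herbicide prometon carries only an acute value). Absence of any
#' benchmark is a valid outcome and yields `NA`.
#'
#' @param chemical_id Chemical id (scalar).
#' @param benchmarks Benchmark table (see [read_water_benchmarks()]).
#' @return Benchmark value in micrograms per liter, or `NA_real_`.
#' @export
select_water_benchmark <- function(chemical_id, benchmarks) {
  entries <- benchmarks[benchmarks$chemical_id == chemical_id, ]
  if (nrow(entries) == 0) return(NA_real_)
  chronic <- entries$value[entries$kind == "chronic"]
  if (length(chronic) > 0) return(min(chronic))
  acute <- entries$value[entries$kind == "acute"]
  if (length(acute) > 0) return(min(acute))
  NA_real_
}

#' Exceedance quotients of site maxima against water-quality benchmarks
#'
#' quotient = maximum site concentration / screening benchmark, for every
#' chemical with a benchmark; quotients greater than or equal to one are
#' flagged as exceedances (inclusive boundary). Chemicals without a
#' benchmark are omitted from the report; a site where the chemical was
#' never detected has quotient 0 and is not flagged.
#'
#' @param site_max A water `site_max_matrix` (micrograms per liter).
#' @param benchmarks Benchmark table (see [read_water_benchmarks()]).
#' @return Tibble with `site_id`, `chemical_id`, `site_max`, `benchmark`,
#'   `quotient`, `exceeds`.
#' @export
exceedance_quotients <- function(site_max, benchmarks) {
  if (any(benchmarks$value <= 0)) {
    stop("benchmarks must be strictly positive", call. = FALSE)
  }
  chems <- intersect(colnames(site_max), unique(benchmarks$chemical_id))
  if (length(chems) == 0) {
    return(tibble(site_id = character(), chemical_id = character(),
                  site_max = double(), benchmark = double(),
                  quotient = double(), exceeds = logical()))
  }
  bench <- vapply(chems, select_water_benchmark, numeric(1),
                  benchmarks = benchmarks)
  sub <- unclass(site_max)[, chems, drop = FALSE]
  out <- tibble::as_tibble(as.data.frame.table(sub,
                                               stringsAsFactors = FALSE))
  names(out) <- c("site_id", "chemical_id", "site_max")
  out$benchmark <- unname(bench[out$chemical_id])
  out$quotient <- out$site_max / out$benchmark
  out$exceeds <- out$quotient >= 1
  out
}

#' Classify a sediment concentration against TEC/MEC/PEC guidelines
#'
#' Returns the highest guideline tier the concentration meets or exceeds
#' (inclusive boundaries): `PEC` when >= PEC, `MEC` when >= MEC, `TEC`
#' when >= TEC, otherwise `below_TEC`. Adverse effects on benthic
#' invertebrates are predicted to be unlikely below the TEC and probable
#' above the PEC.
#'
#' @param concentration Numeric vector (micrograms per kilogram).
#' @param tec,mec,pec Guideline values with 0 < TEC <= MEC <= PEC.
#' @return Ordered factor over `below_TEC < TEC < MEC < PEC`.
#' @export
tier_classify <- function(concentration, tec, mec, pec) {
  if (any(is.na(c(tec, mec, pec))) || tec <= 0 || tec > mec || mec > pec) {
    stop("guideline triple must satisfy 0 < TEC <= MEC <= PEC",
         call. = FALSE)
  }
  tier <- ifelse(concentration >= pec, "PEC",
                 ifelse(concentration >= mec, "MEC",
                        ifelse(concentration >= tec, "TEC", "below_TEC")))
  factor(tier, levels = c("below_TEC", "TEC", "MEC", "PEC"), ordered = TRUE)
}

#' Tier classification of a sediment site-maximum matrix
#'
#' @param site_max A sediment `site_max_matrix` (micrograms per kilogram).
#' @param guidelines Guideline table (see [read_sediment_guidelines()]).
#'   Chemicals without a guideline are omitted.
#' @return Tibble with `site_id`, `chemical_id`, `site_max`, `TEC`, `MEC`,
#'   `PEC`, `tier`.
#' @export
sediment_tiers <- function(site_max, guidelines) {
  guidelines <- validate_sediment_guidelines(guidelines)
  chems <- intersect(colnames(site_max), guidelines$chemical_id)
  if (length(chems) == 0) {
    return(tibble(site_id = character(), chemical_id = character(),
                  site_max = double(), TEC = double(), MEC = double(),
                  PEC = double(),
                  tier = factor(character(),
                                levels = c("below_TEC", "TEC", "MEC", "PEC"),
                                ordered = TRUE)))
  }
  rows <- lapply(chems, function(ch) {
    g <- guidelines[guidelines$chemical_id == ch, ]
    conc <- unclass(site_max)[, ch]
    tibble(site_id = rownames(site_max), chemical_id = ch,
           site_max = unname(conc), TEC = g$TEC, MEC = g$MEC, PEC = g$PEC,
           tier = tier_classify(conc, g$TEC, g$MEC, g$PEC))
  })
  dplyr::bind_rows(rows)
}

#' Per-river and basin-wide exceedance percentages
#'
#' For each chemical (and, for sediment tier reports, each guideline tier),
#' the percentage of sites exceeding per river and basin-wide. The default
#' denominator is the number of sites in the river where the chemical was
#' detected; rivers with no detection of the chemical are reported with
#' `NA` percent (rendered "--" in the published table shapes). The
#' denominator can be switched to all sampled sites. Percentages are
#' returned at full precision; round only for display.
#'
#' @param report A quotient report ([exceedance_quotients()]) or tier report
#'   ([sediment_tiers()]).
#' @param sites Site registry mapping `site_id` to `river`.
#' @param denominator `"detected"` (default) or `"sampled"`.
#' @return Tibble with `river` (including a `"Basin Wide"` row per
#'   chemical), `chemical_id`, optionally `tier`, `n_sites`, `n_detected`,
#'   `n_exceeding`, `percent`.
#' @export
summarize_by_river <- function(report, sites,
                               denominator = c("detected", "sampled")) {
  denominator <- match.arg(denominator)
  unreg <- setdiff(unique(report$site_id), sites$site_id)
  if (length(unreg) > 0) {
    stop("site(s) not registered to a river: ",
         paste(unreg, collapse = ", "), call. = FALSE)
  }
  tiered <- "tier" %in% names(report)
  if (tiered) {
    long <- tidyr::pivot_longer(
      dplyr::mutate(report,
                    TEC = .data$tier >= "TEC",
                    MEC = .data$tier >= "MEC",
                    PEC = .data$tier >= "PEC"),
      cols = c("TEC", "MEC", "PEC"),
      names_to = "guideline_tier", values_to = "exceeds"
    )
  } else {
    long <- report
  }
  long <- dplyr::left_join(long, sites[c("site_id", "river")], by = "site_id")
  grouping <- c("river", "chemical_id", if (tiered) "guideline_tier")

  summarise_one <- function(df, river_label) {
    df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(setdiff(grouping, "river")))) |>
      dplyr::summarise(
        n_sites = dplyr::n_distinct(.data$site_id),
        n_detected = dplyr::n_distinct(.data$site_id[.data$site_max > 0]),
        n_exceeding = dplyr::n_distinct(.data$site_id[.data$exceeds]),
        .groups = "drop"
      ) |>
      dplyr::mutate(river = river_label, .before = 1)
  }

  per_river <- long |>
    dplyr::group_by(.data$river) |>
    dplyr::group_modify(~ summarise_one(.x, .y$river)[-1]) |>
    dplyr::ungroup()
  basin <- summarise_one(long, "Basin Wide")
  out <- dplyr::bind_rows(per_river, basin)
  denom <- if (denominator == "detected") out$n_detected else out$n_sites
  out$percent <- ifelse(out$n_detected == 0, NA_real_,
                        100 * out$n_exceeding / denom)
  if (tiered) {
    out$guideline_tier <- factor(out$guideline_tier,
                                 levels = c("TEC", "MEC", "PEC"))
    out <- dplyr::arrange(out, .data$chemical_id, .data$guideline_tier,
                          .data$river)
  } else {
    out <- dplyr::arrange(out, .data$chemical_id, .data$river)
  }
  tibble::as_tibble(out)
}

#' Census of sites, rivers, and chemicals with at least one exceedance
#'
#' @param report A quotient report ([exceedance_quotients()]), or a tier
#'   report ([sediment_tiers()]) with `tier_at_least` naming the tier that
#'   counts as an exceedance.
#' @param sites Site registry mapping `site_id` to `river`.
#' @param tier_at_least For tier reports: `"TEC"`, `"MEC"`, or `"PEC"`.
#' @return List: `n_sites_exceeding`, `percent_sites`, `n_rivers_exceeding`,
#'   `percent_rivers`, `chemicals_exceeded` (ids with >= 1 flag), counts of
#'   sites and rivers in the report.
#' @export
site_exceedance_census <- function(report, sites, tier_at_least = "TEC") {
  if ("tier" %in% names(report) && !"exceeds" %in% names(report)) {
    tier_at_least <- match.arg(tier_at_least, c("TEC", "MEC", "PEC"))
    report$exceeds <- report$tier >= tier_at_least
  }
  report <- dplyr::left_join(report, sites[c("site_id", "river")],
                             by = "site_id")
  all_sites <- unique(report$site_id)
  all_rivers <- unique(report$river)
  hit_sites <- unique(report$site_id[report$exceeds])
  hit_rivers <- unique(report$river[report$exceeds])
  list(
    n_sites = length(all_sites),
    n_sites_exceeding = length(hit_sites),
    percent_sites = 100 * length(hit_sites) / max(1L, length(all_sites)),
    n_rivers = length(all_rivers),
    n_rivers_exceeding = length(hit_rivers),
    percent_rivers = 100 * length(hit_rivers) / max(1L, length(all_rivers)),
    chemicals_exceeded = sort(unique(report$chemical_id[report$exceeds]))
  )
}

#' Count rivers with at least one exceedance in a published percent table
#'
#' Operates on river-by-chemical percent tables (the shape of the published
#' per-river exceedance summaries): a river counts as exceeding when any of
#' its percent cells is strictly positive; `NA` cells mean the chemical was
#' not detected in that river.
#'
#' @param percent_table Tibble with `river` and `percent` columns (long
#'   form), e.g. from the shipped `water_exceedance_percent.csv`.
#' @param tier Optional tier filter for sediment tables (`"TEC"`, `"MEC"`,
#'   `"PEC"`), applied to a `tier` column when present.
#' @return List: `n_rivers`, `n_rivers_exceeding`, `percent_rivers`.
#' @export
river_exceedance_census <- function(percent_table, tier = NULL) {
  if (!is.null(tier) && "tier" %in% names(percent_table)) {
    percent_table <- percent_table[percent_table$tier == tier, ]
  }
  by_river <- tapply(percent_table$percent, percent_table$river,
                     function(p) any(!is.na(p) & p > 0))
  list(
    n_rivers = length(by_river),
    n_rivers_exceeding = sum(by_river),
    percent_rivers = 100 * sum(by_river) / length(by_river)
  )
}
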
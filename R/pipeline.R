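#' Render a per-matrix chemical summary in the published table shape
#'
#' Rows are sorted by descending detection frequency; medians that fall
#' below the chemical's reporting limit are rendered `"<RL"`, matching the
#' convention of published survey summaries. Numeric cells are formatted
#' with [format()] at full precision and parse back to their values.
#'
#' @param freq_table Output of [chemical_summary()].
#' @param chemicals Chemical registry (for class and log Kow columns).
#' @param reporting_limits Named numeric vector (chemical id -> reporting
#'   limit) used for the `"<RL"` rule; defaults to the per-chemical maximum
#'   reporting limit found in `records` when supplied instead.
#' @param panel Optional chemical-id vector restricting the table.
#' @return A character tibble in display form: `chemical`, `chemical_class`,
#'   `log_kow`, `reporting_limit`, `n`, `median`, `maximum`,
#'   `detection_frequency`.
#' @export
render_table1 <- function(freq_table, chemicals, reporting_limits,
                          panel = NULL) {
  if (!is.null(panel)) {
    freq_table <- freq_table[freq_table$chemical_id %in% panel, ]
  }
  freq_table <- freq_table[order(-freq_table$detection_frequency,
                                 -freq_table$maximum,
                                 freq_table$chemical_id), ]
  idx <- match(freq_table$chemical_id, chemicals$chemical_id)
  rl <- unname(reporting_limits[freq_table$chemical_id])
  fmt <- function(x) {
    vapply(x, function(v) {
      if (is.na(v)) "--" else format(v, digits = 10, trim = TRUE,
                                     scientific = FALSE)
    }, character(1))
  }
  tibble(
    chemical = freq_table$chemical_id,
    chemical_class = chemicals$chemical_class[idx],
    log_kow = fmt(chemicals$log_kow[idx]),
    reporting_limit = fmt(rl),
    n = fmt(freq_table$n_analyzed),
    median = ifelse(!is.na(rl) & freq_table$median < rl, "<RL",
                    fmt(freq_table$median)),
    maximum = fmt(freq_table$maximum),
    detection_frequency = fmt(round(freq_table$detection_frequency))
  )
}

#' Default pipeline configuration
#'
#' @param seed Top-level seed; every stage's randomness derives from it.
#' @param threshold_percent Ubiquity (detection-frequency) threshold.
#' @param linkage Clustering linkage.
#' @param eeq_flag_levels EEQ screening flag levels (ng/L or ng/kg).
#' @param generator Arguments forwarded to [generator_config()].
#' @return A nested list; serializable to/from YAML.
#' @export
pipeline_config <- function(seed = 1, threshold_percent = 30,
                            linkage = "complete",
                            eeq_flag_levels = c(1, 10),
                            generator = list()) {
  list(seed = as.integer(seed), threshold_percent = threshold_percent,
       linkage = linkage, eeq_flag_levels = eeq_flag_levels,
       generator = generator)
}

#' Run the full screening pipeline on a synthetic network
#'
#' Chains the stages end to end: simulate (registries + censored records),
#' validate, reduce (censored recoding, per-chemical summaries, ubiquity
#' filtering, site maxima, class totals) in both matrices, EEQ scoring,
#' benchmark/guideline screening, and two-way co-occurrence clustering.
#' All intermediate tables are returned and, when `out_dir` is given,
#' persisted as delimited text together with a JSON run manifest (config
#' echo, seed, package version, per-stage row counts). The pipeline is a
#' pure function of its configuration: rerunning with the same config
#' yields byte-identical outputs.
#'
#' @param config A [pipeline_config()] list, or a path to a YAML file with
#'   the same structure.
#' @param out_dir Optional output directory.
#' @param benchmarks Water benchmark table; default: the shipped synthetic
#'   benchmarks covering the simulated panel.
#' @param guidelines Sediment guideline table; default: the shipped
#'   synthetic guidelines covering the simulated panel.
#' @return A list of stage outputs (see Details in the vignette).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         benchmarks = NULL, guidelines = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(benchmarks)) {
    benchmarks <- read_water_benchmarks(
      system.file("extdata", "benchmarks_water_synthetic.csv",
                  package = "cecscreen"))
  }
  if (is.null(guidelines)) {
    guidelines <- read_sediment_guidelines(
      system.file("extdata", "guidelines_sediment_synthetic.csv",
                  package = "cecscreen"))
  }
  gen_args <- config$generator %||% list()
  gen_args$seed <- config$seed
  gcfg <- do.call(generator_config, gen_args)

  registries <- generate_registries(gcfg)
  records <- simulate_records(registries, gcfg)
  issues <- validate_against_registries(records, registries$chemicals,
                                        registries$sites)
  if (nrow(issues) > 0) {
    stop("stage 'validate' failed: ", nrow(issues),
         " registry inconsistencies", call. = FALSE)
  }
  recoded <- recode_censored(records)

  per_matrix <- lapply(stats::setNames(MATRIX_LEVELS, MATRIX_LEVELS),
                       function(mat) {
    freq <- chemical_summary(recoded, mat)
    panel <- ubiquity_filter(freq, config$threshold_percent %||% 30)
    smax <- site_maxima(recoded, mat)
    totals <- class_totals(smax, registries$chemicals)
    eeq <- site_eeq(smax, registries$chemicals)
    eeq_report <- eeq_rank_report(eeq, registries$sites,
                                  config$eeq_flag_levels %||% c(1, 10))
    cluster <- if (length(panel) >= 2 && nrow(smax) >= 2) {
      two_way_order(restrict_to_panel(smax, panel),
                    linkage = config$linkage %||% "complete")
    }
    list(frequency = freq, panel = panel, site_max = smax,
         totals = totals, eeq = eeq, eeq_report = eeq_report,
         cluster = cluster)
  })

  quotients <- exceedance_quotients(per_matrix$water$site_max, benchmarks)
  tiers <- sediment_tiers(per_matrix$sediment$site_max, guidelines)
  screen <- list(
    quotients = quotients,
    water_summary = if (nrow(quotients) > 0) {
      summarize_by_river(quotients, registries$sites)
    },
    water_census = if (nrow(quotients) > 0) {
      site_exceedance_census(quotients, registries$sites)
    },
    tiers = tiers,
    sediment_summary = if (nrow(tiers) > 0) {
      summarize_by_river(tiers, registries$sites)
    }
  )

  result <- list(
    config = config, generator_config = gcfg, registries = registries,
    truth = planted_truth(registries), records = records,
    water = per_matrix$water, sediment = per_matrix$sediment,
    screen = screen,
    overlap = matrix_overlap(per_matrix$water$panel,
                             per_matrix$sediment$panel)
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

site_max_to_tibble <- function(site_max) {
  out <- tibble::as_tibble(as.data.frame(unclass(site_max)),
                           .name_repair = "minimal")
  dplyr::bind_cols(tibble(site_id = rownames(site_max)), out)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  wcsv <- function(x, name) readr::write_csv(x, p(name), na = "",
                                             progress = FALSE)
  write_records(result$records, p("records.csv"))
  wcsv(result$registries$chemicals, "chemicals.csv")
  wcsv(result$registries$sites, "sites.csv")
  counts <- list(records = nrow(result$records))
  for (mat in MATRIX_LEVELS) {
    st <- result[[mat]]
    wcsv(st$frequency, paste0("frequency_", mat, ".csv"))
    writeLines(st$panel, p(paste0("panel_", mat, ".txt")))
    wcsv(site_max_to_tibble(st$site_max), paste0("site_max_", mat, ".csv"))
    wcsv(st$totals$class_totals, paste0("class_totals_", mat, ".csv"))
    wcsv(st$eeq$totals, paste0("eeq_", mat, ".csv"))
    counts[[paste0("panel_", mat)]] <- length(st$panel)
    counts[[paste0("sites_", mat)]] <- nrow(st$site_max)
    if (!is.null(st$cluster)) {
      export_newick(st$cluster$chemical_dendrogram,
                    p(paste0("chemicals_", mat, ".nwk")))
      export_newick(st$cluster$site_dendrogram,
                    p(paste0("sites_", mat, ".nwk")))
    }
  }
  wcsv(result$screen$quotients, "quotients_water.csv")
  wcsv(dplyr::mutate(result$screen$tiers,
                     tier = as.character(.data$tier)), "tiers_sediment.csv")
  if (!is.null(result$screen$water_summary)) {
    wcsv(result$screen$water_summary, "river_summary_water.csv")
  }
  if (!is.null(result$screen$sediment_summary)) {
    wcsv(result$screen$sediment_summary, "river_summary_sediment.csv")
  }
  manifest <- list(
    package = "cecscreen",
    version = as.character(utils::packageVersion("cecscreen")),
    seed = result$config$seed,
    config = result$config[setdiff(names(result$config), "generator")],
    row_counts = counts
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}
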
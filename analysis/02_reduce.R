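#!/usr/bin/env Rscript
# Stage 2: data reduction.
#
# Recode left-censored results as zeroes, summarize detection frequency /
# median / maximum per chemical and matrix, apply the 30% ubiquity filter,
# reduce to per-site maxima, and total concentrations by chemical class.

suppressPackageStartupMessages(library(cecscreen))

run <- "results/run"
records <- recode_censored(read_records(file.path(run, "records.csv")))
chemicals <- read_chemicals(file.path(run, "chemicals.csv"))

rl <- with(cecscreen::default_chemical_panel(),
           stats::setNames(reporting_limit, chemical_id))

panels <- list()
for (mat in c("water", "sediment")) {
  freq <- chemical_summary(records, mat)
  panel <- ubiquity_filter(freq, 30)
  smax <- site_maxima(records, mat)
  totals <- class_totals(smax, chemicals)

  readr::write_csv(freq, file.path(run, paste0("frequency_", mat, ".csv")))
  writeLines(panel, file.path(run, paste0("panel_", mat, ".txt")))
  readr::write_csv(totals$class_totals,
                   file.path(run, paste0("class_totals_", mat, ".csv")))
  readr::write_csv(totals$site_totals,
                   file.path(run, paste0("site_totals_", mat, ".csv")))
  readr::write_csv(render_table1(freq, chemicals, rl, panel),
                   file.path(run, paste0("summary_table_", mat, ".csv")))
  cat(sprintf("%s: %d chemicals analyzed, %d in the >=30%% panel; ",
              mat, nrow(freq), length(panel)))
  cat(sprintf("site totals span %.3g-%.3g %s\n",
              min(totals$site_totals$site_total),
              max(totals$site_totals$site_total), matrix_units(mat)))
  panels[[mat]] <- panel
}

ov <- matrix_overlap(panels$water, panels$sediment)
cat(sprintf("panel overlap: %d of %d panel entries frequent in both matrices (%s)\n",
            ov$n_shared, ov$n_entries, paste(ov$shared, collapse = ", ")))
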
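#!/usr/bin/env Rscript
# Stage 3: estradiol-equivalent (EEQ) estrogenicity scoring.
#
# Per-site maxima of the estrogen-active chemicals are multiplied by their
# potency factors relative to 17beta-estradiol and summed, giving ng/L
# (water) and ng/kg (sediment) totals, then ranked within river and
# flagged against 1 and 10 ng/L screening levels.

suppressPackageStartupMessages(library(cecscreen))

run <- "results/run"
records <- recode_censored(read_records(file.path(run, "records.csv")))
chemicals <- read_chemicals(file.path(run, "chemicals.csv"))
sites <- read_sites(file.path(run, "sites.csv"))

for (mat in c("water", "sediment")) {
  eeq <- site_eeq(site_maxima(records, mat), chemicals)
  report <- eeq_rank_report(eeq, sites, flag_levels = c(1, 10))
  readr::write_csv(report, file.path(run, paste0("eeq_", mat, ".csv")))
  cat(sprintf("%s EEQ: %.3g-%.3g %s across %d sites; %d sites > 10\n",
              mat, min(eeq$totals$total_eeq), max(eeq$totals$total_eeq),
              eeq$units, nrow(eeq$totals), sum(report$above_10)))
}

truth <- unlist(jsonlite::read_json(file.path(run, "truth.json")))
eeq_w <- site_eeq(site_maxima(records, "water"), chemicals)$totals
by_arch <- tapply(eeq_w$total_eeq, truth[eeq_w$site_id], median)
cat("median water EEQ by planted archetype:\n")
print(round(by_arch, 2))
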
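#!/usr/bin/env Rscript
# Stage 4: benchmark and guideline screening.
#
# Water site-maxima are divided by the lowest chronic benchmark (acute as
# fallback) into exceedance quotients (>= 1 flags); sediment site-maxima
# are classified into TEC/MEC/PEC guideline tiers. Both are summarized per
# river and basin-wide, and a site/river census is reported.

suppressPackageStartupMessages(library(cecscreen))

run <- "results/run"
records <- recode_censored(read_records(file.path(run, "records.csv")))
sites <- read_sites(file.path(run, "sites.csv"))

bm <- read_water_benchmarks(
  system.file("extdata", "benchmarks_water_synthetic.csv",
              package = "cecscreen"))
sg <- read_sediment_guidelines(
  system.file("extdata", "guidelines_sediment_synthetic.csv",
              package = "cecscreen"))

q <- exceedance_quotients(site_maxima(records, "water"), bm)
readr::write_csv(q, file.path(run, "quotients_water.csv"))
readr::write_csv(summarize_by_river(q, sites),
                 file.path(run, "river_summary_water.csv"))
cen <- site_exceedance_census(q, sites)
jsonlite::write_json(cen, file.path(run, "census_water.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("water: benchmarks exceeded at %d of %d sites (%.0f%%), %d of %d rivers (%.0f%%)\n",
            cen$n_sites_exceeding, cen$n_sites, cen$percent_sites,
            cen$n_rivers_exceeding, cen$n_rivers, cen$percent_rivers))
cat(sprintf("water: chemicals with >= 1 exceedance: %s\n",
            paste(cen$chemicals_exceeded, collapse = ", ")))

tiers <- sediment_tiers(site_maxima(records, "sediment"), sg)
tiers_out <- dplyr::mutate(tiers, tier = as.character(tier))
readr::write_csv(tiers_out, file.path(run, "tiers_sediment.csv"))
readr::write_csv(summarize_by_river(tiers, sites),
                 file.path(run, "river_summary_sediment.csv"))
pec <- site_exceedance_census(tiers, sites, tier_at_least = "PEC")
cat(sprintf("sediment: PEC exceeded at %d of %d sites; TEC at %d sites\n",
            pec$n_sites_exceeding, pec$n_sites,
            site_exceedance_census(tiers, sites,
                                   tier_at_least = "TEC")$n_sites_exceeding))
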
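# cecscreen

Screening analysis of contaminants of emerging concern (CECs) in
multi-site water and sediment monitoring surveys. The package takes raw,
heavily left-censored concentration records — pharmaceuticals, pesticides,
flame retardants, sterols, hormones, PAHs and kin, measured at sites
across many rivers — through the standard survey reduction chain and the
screening comparisons a water-resources or ecotoxicology group needs:

* **Censored reduction** — validate quantified / estimated / nondetect
  reporting, recode left-censored results as zeroes, summarize detection
  frequency, median, and maximum per chemical and matrix, and keep only
  chemicals detected in ≥ 30% of samples (the *ubiquity filter*).
* **Site maxima and class totals** — one observation per site (the
  maximum detected concentration of each chemical), summed into chemical
  class and total site concentrations.
* **Estrogenicity (EEQ)** — additive estradiol equivalents per site:
  `EEQ_s = Σ_i 1000 · F_i · Cmax_{i,s}` with potency factors `F_i`
  relative to 17β-estradiol, in ng/L (water) or ng/kg (sediment).
* **Benchmark screening** — exceedance quotients `Q = Cmax / B` against
  the lowest chronic water-quality benchmark (lowest acute as fallback),
  flagged at `Q ≥ 1`; sediment classification into TEC / MEC / PEC
  guideline tiers; per-river and basin-wide exceedance percentages and
  censuses.
* **Co-occurrence clustering** — two-way (chemicals × sites)
  agglomerative clustering of Euclidean distances on rank-transformed
  site maxima, with deterministic tie-breaking, cluster cuts, and Newick
  export.
* **Synthetic data** — a seeded generator of registries and censored
  records for a 12-river network with planted land-use archetypes
  (urban/WWTP, agricultural, reference), lognormal concentrations, and
  log-Kow water/sediment partitioning, so everything above runs end to
  end with no downloads.

The methods vignette (`vignettes/cec-screening-methods.Rmd`) documents
the statistical choices and the generator's assumptions in detail.

## Worked example

The `analysis/` directory holds the numbered workflow. Running it in
order on the default seed:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_reduce.R
Rscript analysis/03_eeq.R
Rscript analysis/04_benchmarks.R
Rscript analysis/05_cluster.R
```

prints, among other things:

```
simulated 4500 records at 60 sites on 12 rivers (seed 1)
censoring: 76% of results are nondetects
water: 25 chemicals analyzed, 13 in the >=30% panel; site totals span 0-20.1 ug/L
panel overlap: 1 of 23 panel entries frequent in both matrices (PEST-02)
water EEQ: 0-23.7 ng/L across 60 sites; 2 sites > 10
water: benchmarks exceeded at 11 of 60 sites (18%), 5 of 12 rivers (42%)
sediment: PEC exceeded at 6 of 60 sites; TEC at 24 sites
water: clustered 60 sites x 13 chemicals; cutting sites at k=3 recovers planted archetypes with ARI 1.00
```

Reading the output: three quarters of simulated results are nondetects
(realistic for trace organics); 13 of 25 chemicals pass the 30% ubiquity
filter in water; per-site estrogenicity spans 0–24 ng/L with two sites
above the 10 ng/L effects-range flag; and cutting the site dendrogram at
k = 3 recovers the planted urban/agricultural/reference archetypes
exactly on this seed. All stage tables land under `results/run/`.

The same stages are available programmatically via `run_pipeline()`:

```r
library(cecscreen)
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "results/run2")
res$overlap$n_shared        # panel chemicals frequent in both matrices
res$screen$water_census     # sites/rivers with >= 1 benchmark exceedance
```

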
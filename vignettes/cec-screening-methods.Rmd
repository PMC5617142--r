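---
title: "Screening contaminants of emerging concern in water and sediment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening contaminants of emerging concern in water and sediment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cecscreen)
```

`cecscreen` implements the data-reduction and screening chain used in
basin-wide surveys of contaminants of emerging concern (CECs): organic
chemicals — pharmaceuticals, current-use pesticides, flame retardants,
sterols, hormones, PAHs — measured in surface water and bottom sediment at
sites spread over many rivers, each visited only a few times, with heavily
left-censored analytical results. This vignette describes the statistical
procedure, the choices the package makes where a survey protocol leaves
them open, and what the bundled synthetic-data generator does and does not
emulate.

## Censored reporting and recoding

Laboratory results arrive in three states. A result at or above the
laboratory reporting limit (LRL, conventionally twice the long-term method
detection limit) is *quantified*. A quantifiable detection below the LRL
is reported with its numeric value but flagged *estimated*. Otherwise the
result is left-censored: a *nondetect* carrying no value. `cecscreen`
enforces these invariants at parse time and, for reduction, recodes
nondetects as zeroes (`recode_censored()`). Zero-recoding keeps
rank-based statistics and sums well defined without imposing a
distributional model on the censored tail; it deliberately understates
censored concentrations, which is conservative for rank patterns but
means medians below an RL are reported qualitatively (`"<RL"`) in
rendered tables while the numeric median (zeroes included) is retained
internally. Estimated results count as detections throughout — the
information-rich reporting convention — and therefore also enter maxima
and EEQ sums; this choice is applied consistently and documented here
because survey write-ups rarely state it.

The package assumes one record per environmental sample; laboratory
duplicates and QC samples are expected to be excluded upstream.

## Reduction to site maxima

Each site's record for a chemical is reduced to the *maximum* concentration
over all its samples (`site_maxima()`), not a mean: with two visits per
site and most results censored, distribution-based mean estimators are not
identifiable, and for a screening exercise the maximum is the quantity of
toxicological interest. Class totals (`class_totals()`) sum these maxima
by chemical class and per site; because summands are maxima over different
samples, totals may be biased high — they are screening statistics.
Conservation (site total = sum of class totals) holds exactly.

Detection frequency uses the per-chemical analyzed count as denominator
(analytical panels differ between chemicals and matrices), and the
*ubiquity filter* (`ubiquity_filter()`) retains chemicals detected in at
least 30% of samples basin-wide, inclusive of the boundary. The threshold
is a tunable percentage (default 30) — it trades breadth of the chemical
panel against how basin-representative the co-occurrence analysis is.

## Estradiol equivalents

Estrogenicity is scored additively (`site_eeq()`): for each chemical with
a published potency factor relative to 17beta-estradiol,

$$\mathrm{EEQ}_{s} = \sum_i 1000 \cdot F_i \cdot C^{\max}_{i,s}$$

with concentrations in µg/L (water) or µg/kg (sediment) and totals in
ng/L or ng/kg. The additive, concentration-scaled form is homogeneous of
degree one and monotone; it ignores non-additive mixture effects by
design. Potency factors are an input table, not package constants — the
shipped `eeq_factors_synthetic.csv` carries synthetic factors with
literature-plausible magnitudes (1 for an estradiol-like hormone, 0.3
estrone-like, 10^-5 range for alkylphenols and bisphenols) and is intended
for testing, not assessment. The rank report flags totals strictly above
1 and 10 ng/L by default, the range at which sustained estrogen exposure
has been associated with vitellogenin induction in fish and mussels.

## Benchmarks and guidelines

Water screening divides each site maximum by the *lowest chronic*
benchmark available for the chemical regardless of intended species; when
only acute values exist the lowest acute benchmark is used
(`select_water_benchmark()`). Quotients at or above 1 are exceedances —
the boundary is inclusive. Sediment concentrations are classified against
threshold/midpoint/probable effect concentrations (TEC ≤ MEC ≤ PEC),
taking the highest tier met or exceeded, again inclusive
(`tier_classify()`).

River summaries report the percent of sites exceeding per chemical. The
denominator is genuinely ambiguous in published tables (a river can print
`0` for a detected-but-never-exceeding chemical and `--` for a
never-detected one, implying detection-conditioned denominators);
`summarize_by_river()` defaults to sites-where-detected and exposes
all-sampled-sites as an option. Percentages are kept at full precision
internally; rounding to whole percent happens only at display.

## Two-way co-occurrence clustering

Cluster analysis operates on the panel-restricted site-maximum matrix
after a rank transform. Ranks are computed *within each chemical across
sites* (default), so chemicals whose concentrations differ by orders of
magnitude contribute comparably, and any strictly monotone transform of a
chemical's concentrations leaves the analysis unchanged. Sites where a
panel chemical was never detected share the tied lowest average rank
rather than being dropped, keeping site vectors complete. The per-site
rank axis is available as an option.

Distances are Euclidean on ranks; agglomeration (`agglomerate()`) is
standard bottom-up hierarchical clustering with Lance–Williams updates.
Linkage is *complete* by default (the common default of the R function
family used for published heatmaps; single and average are options).
Because rank data produce many exactly tied distances, the merge order is
made deterministic: every cluster is labelled by its smallest member leaf
label, and among minimal-distance pairs the lexicographically smallest
label pair merges first. This guarantees bit-identical dendrograms across
runs and platforms; it is a tie-break convention, not a statistical claim.
Dendrograms export to Newick with branch lengths from merge heights
(leaves at height zero), and leaf orders come from recursive traversal
with the tighter (lower merge height) subcluster first. Exact
reproduction of any particular published heatmap's leaf order is out of
scope — it depends on unstated linkage and tie handling — but the
methodology (ranks, Euclidean distance, agglomerative clustering, two-way
ordering) is the same, and heatmaps are rendered from raw ranks without
re-scaling.

## The synthetic-data generator

Real survey data live in external data releases; the generator
(`generator_config()`, `simulate_records()`) provides a seeded stand-in
with the statistical structure the analysis assumes, so the whole
pipeline runs and can be tested end to end offline. Its defaults describe
a desk-scale survey: 12 rivers, 3–8 sites each, two water visits (spring
and late summer) and one sediment visit per site — roughly 450–600 water
and 225–300 sediment sample-slots against a 24-chemical panel.

For each site × visit × matrix × chemical, occurrence is Bernoulli with
probability (base probability × archetype multiplier, capped at 1) ×
a log Kow partition weight; concentrations given occurrence are lognormal
with a per-archetype mean shift expressed in units of the chemical's log
scale sd. Lognormality is a generator assumption, chosen because
trace-organic concentrations in surveys span orders of magnitude; the
survey methodology itself asserts no distribution. Values below the
reporting limit are reported (estimated) with probability 0.5 and
left-censored otherwise — a coarse stand-in for the increasing
false-negative probability of low-level determinations; the actual
gradient is not modelled.

Planted land-use archetypes drive the signal the co-occurrence analysis is
meant to find, and the defaults encode deliberately strong archetype
effects: urban/WWTP rivers carry a prominent pharmaceutical and flame
retardant signature (occurrence multipliers ≈ 1.9–2.0, concentration
shifts +2 sd), agricultural rivers a herbicide signature (shift +2 sd)
with livestock-driven fecal-indicator and sterol enrichment, and
reference rivers are sparse across the board (multipliers 0.05–0.4). Two
structural choices matter for recoverability and are worth stating: the
water-signature chemicals of the urban archetype all have low log Kow
(< 1.5), so their water-column occurrence at urban sites is near-certain
and within-archetype rank variance stays small; and the herbicides are
basin-ubiquitous in occurrence (as atrazine-like compounds are) while
remaining agricultural in *concentration*, which keeps them in the ≥ 30%
panel under any seed so the agricultural/reference contrast survives the
ubiquity filter. Under these defaults, cutting the site dendrogram at the
number of archetypes recovers the planted labels with median adjusted
Rand index ≥ 0.9 over 20 seeds.

Water/sediment partitioning is a logistic weight in log Kow around a
threshold of 3 (steepness 1.5 per log unit): chemicals below the
threshold occur mostly in water, above it mostly in sediment, mirroring
the empirical pattern that frequently detected chemicals split by
octanol–water partitioning. The generator does not scale sediment
concentrations by an organic-carbon partition model — both matrices share
each chemical's concentration distribution — and it models no hydrologic
transport, dilution, downstream autocorrelation, or seasonality. Tests
passing on generated data therefore certify the *reduction and inference
machinery*, not the field realism of any particular concentration value.

The generator's expectations are available in closed form for checking:
`occurrence_prob()` and `detection_prob()` return the exact per-slot
probabilities (detection accounts for the 0.5 reporting coin below the
RL), and `expected_site_eeq()` integrates `1 - F(v)^m` for the mixed
censored-lognormal visit distribution by quadrature (relative tolerance
1e-9) to give the exact expected per-site EEQ. Monte-Carlo recovery of
the pipeline EEQ agrees with this expectation within 10% relative error
at 1000 sites.

## Numerical conventions and degenerate inputs

* All tie-breaks (merge order, leaf order, panel ordering) are
  deterministic and lexicographic; rank ties use average ranks.
* Exceedance and tier boundaries are inclusive (quotient ≥ 1; tier met at
  equality); EEQ flag levels are strict (>).
* Every stage's randomness derives from a single integer seed; registry
  generation and record simulation use fixed offsets of it, so stages can
  be re-run in isolation and record files are byte-identical across
  reruns.
* A chemical constant across all sites is retained in the rank matrix
  (constant ranks) with a warning; clustering a single leaf is an error;
  guideline triples must satisfy 0 < TEC ≤ MEC ≤ PEC or the
  configuration is rejected; an all-zero site scores EEQ 0 and is never
  flagged.
* Test-suite problem sizes are chosen for exactness rather than scale:
  the agglomeration oracle enumerates all merges from scratch on
  instances of ≤ 8 leaves (1000 random instances), archetype recovery
  uses the generator's default 12-river network over 20 seeds, and the
  EEQ expectation check uses a single 1000-site river.

## Limitations

Beyond the generator simplifications above: no censored-data maximum
likelihood or Kaplan–Meier estimators (maxima of zero-recoded values are
the only site statistic); no temporal trend or seasonal stratification
(visits are pooled before maxima); no probabilistic risk
characterization, species-sensitivity distributions, or mixture toxicity
beyond per-chemical quotients and additive EEQ; and no laboratory QC
modelling. The shipped benchmark, guideline, and EEQ-factor tables for
the synthetic panel are labelled synthetic and exist so the screening
stages can be exercised; real assessments must supply versioned benchmark
tables with sources.
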
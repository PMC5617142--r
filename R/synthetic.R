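#' Default chemical panel for the synthetic monitoring network
#'
#' Twenty-four chemicals spanning the classes a basin-wide CEC survey
#' reports (pharmaceuticals, pesticides, sterols, PAHs, hormones, flame
#' retardants, fragrances, alkylphenols, industrial and fecal-indicator
#' chemicals). Each row carries the occurrence and concentration model for
#' one chemical: a base occurrence probability per sample slot, a lognormal
#' concentration model (`meanlog`, `sdlog`, natural-log scale), a reporting
#' limit, per-archetype occurrence multipliers (`mult_*`) and concentration
#' shifts (`shift_*`, in units of `sdlog` on the log scale), a log Kow
#' controlling water/sediment partitioning, and an estrogenic potency
#' factor for the estrogen-active chemicals. Urban/WWTP archetypes carry a
#' prominent pharmaceutical and flame-retardant signature, agricultural
#' archetypes a herbicide signature, and reference archetypes are sparse.
#'
#' @return A tibble with one row per chemical.
#' @export
default_chemical_panel <- function() {
  row <- function(id, class, kow, rl, p, mu, sig,
                  mu_u, mu_a, mu_r, mu_m, sh_u, sh_a, sh_r, sh_m,
                  eeq = NA_real_) {
    tibble(chemical_id = id, chemical_class = class, log_kow = kow,
           reporting_limit = rl, base_occurrence_prob = p,
           meanlog = mu, sdlog = sig,
           mult_urban_wwtp = mu_u, mult_agricultural = mu_a,
           mult_reference = mu_r, mult_mixed = mu_m,
           shift_urban_wwtp = sh_u, shift_agricultural = sh_a,
           shift_reference = sh_r, shift_mixed = sh_m,
           eeq_factor = eeq)
  }
  dplyr::bind_rows(
    row("PHARM-01", "Pharmaceutical", -0.9, 0.010, 0.50, log(0.05), 1.0,
        1.9, 0.25, 0.05, 1.0, 2.0, 0.0, -1.0, 0.5),
    row("PHARM-02", "Pharmaceutical", 0.2, 0.010, 0.50, log(0.05), 1.0,
        1.9, 0.25, 0.05, 1.0, 2.0, 0.0, -1.0, 0.5),
    row("PHARM-03", "Pharmaceutical", 1.4, 0.010, 0.50, log(0.05), 1.0,
        1.9, 0.25, 0.05, 1.0, 2.0, 0.0, -1.0, 0.5),
    row("PHARM-04", "Pharmaceutical", -1.6, 0.010, 0.50, log(0.05), 1.0,
        1.9, 0.25, 0.05, 1.0, 2.0, 0.0, -1.0, 0.5),
    row("PEST-01", "Pesticide", 2.61, 0.020, 0.70, log(0.03), 1.0,
        0.8, 1.4, 0.25, 1.0, 0.0, 2.0, -1.0, 0.5),
    row("PEST-02", "Pesticide", 3.13, 0.020, 0.70, log(0.03), 1.0,
        0.8, 1.4, 0.25, 1.0, 0.0, 2.0, -1.0, 0.5),
    row("PEST-03", "Pesticide", 2.18, 0.020, 0.70, log(0.03), 1.0,
        0.8, 1.4, 0.25, 1.0, 0.0, 2.0, -1.0, 0.5),
    row("STER-01", "Sterol", 7.69, 0.20, 0.90, log(1.0), 1.0,
        1.0, 1.1, 0.40, 1.0, 0.5, 1.0, 0.0, 0.3),
    row("STER-02", "Sterol", 8.25, 0.20, 0.90, log(1.0), 1.0,
        1.0, 1.1, 0.40, 1.0, 0.5, 1.0, 0.0, 0.3),
    row("STER-03", "Sterol", 8.63, 0.20, 0.90, log(1.0), 1.0,
        1.0, 1.1, 0.40, 1.0, 0.5, 1.0, 0.0, 0.3),
    row("FECAL-01", "Fecal indicator", 2.14, 0.040, 0.70, log(0.08), 1.0,
        1.1, 1.4, 0.35, 1.0, 0.5, 1.5, -0.5, 0.3),
    row("PAH-01", "PAH", 4.9, 0.030, 0.60, log(0.1), 1.2,
        1.6, 0.35, 0.25, 1.0, 1.5, 0.0, 0.0, 0.5),
    row("PAH-02", "PAH", 5.2, 0.030, 0.60, log(0.1), 1.2,
        1.6, 0.35, 0.25, 1.0, 1.5, 0.0, 0.0, 0.5),
    row("PAH-03", "PAH", 6.1, 0.030, 0.60, log(0.1), 1.2,
        1.6, 0.35, 0.25, 1.0, 1.5, 0.0, 0.0, 0.5),
    row("FLAME-01", "Flame retardant", 1.44, 0.30, 0.45, log(0.2), 1.0,
        2.0, 0.20, 0.05, 1.0, 2.0, 0.0, -1.0, 0.5),
    row("FLAME-02", "Flame retardant", 3.65, 0.30, 0.45, log(0.2), 1.0,
        2.0, 0.20, 0.05, 1.0, 2.0, 0.0, -1.0, 0.5),
    row("FRAG-01", "Fragrance", 5.9, 0.040, 0.50, log(0.1), 1.0,
        1.8, 0.35, 0.10, 1.0, 1.5, 0.0, 0.0, 0.5),
    row("HORM-01", "Hormone", 4.0, 0.0005, 0.35, log(0.002), 1.0,
        1.6, 1.2, 0.20, 1.0, 1.0, 0.5, 0.0, 0.5, eeq = 1.0),
    row("HORM-02", "Hormone", 3.13, 0.0005, 0.35, log(0.004), 1.0,
        1.6, 1.2, 0.20, 1.0, 1.0, 0.5, 0.0, 0.5, eeq = 0.3),
    row("ALKP-01", "Alkylphenol", 5.28, 0.030, 0.40, log(0.3), 1.2,
        1.7, 0.50, 0.15, 1.0, 1.5, 0.0, 0.0, 0.5, eeq = 3e-5),
    row("PLAS-01", "Plasticizer", 3.32, 0.030, 0.40, log(0.1), 1.0,
        1.6, 0.45, 0.15, 1.0, 1.0, 0.0, 0.0, 0.5, eeq = 1e-5),
    row("INDUST-01", "Industrial", 1.44, 0.14, 0.50, log(0.1), 1.0,
        1.8, 0.35, 0.10, 1.0, 1.5, 0.0, 0.0, 0.5),
    row("OTHER-01", "Other", 0.07, 0.060, 0.45, log(0.08), 1.0,
        1.7, 0.45, 0.15, 1.0, 1.5, 0.0, 0.0, 0.5),
    row("OTHER-02", "Other", -0.07, 0.060, 0.45, log(0.08), 1.0,
        1.7, 0.45, 0.15, 1.0, 1.5, 0.0, 0.0, 0.5),
    row("REPEL-01", "Insect repellant", 2.18, 0.040, 0.60, log(0.05), 1.2,
        1.5, 0.90, 0.30, 1.0, 1.0, 0.5, -0.5, 0.5)
  )
}

#' Configuration of the synthetic monitoring network
#'
#' The defaults mirror the footprint of a basin-wide tributary survey at
#' desk scale: 12 rivers with 3-8 sites each, each site visited twice for
#' water (spring and late summer) and once for sediment. Rivers carry
#' planted land-use archetypes (urban/WWTP, agricultural, reference by
#' default in roughly 5:4:3 proportion). Water/sediment occurrence is
#' weighted by each chemical's log Kow against `kow_partition_threshold`
#' via a logistic curve of steepness `kow_partition_steepness`.
#'
#' @param n_rivers Number of rivers.
#' @param sites_per_river Integer vector recycled over rivers, or `NULL` to
#'   draw uniformly from `3:8` (seeded).
#' @param visits_per_site Water sampling visits per site.
#' @param sediment_visits Sediment sampling visits per site.
#' @param archetype_assignment Character vector of archetypes per river, or
#'   `NULL` for the default proportions.
#' @param chemical_panel Panel tibble (see [default_chemical_panel()]).
#' @param kow_partition_threshold Log Kow above which chemicals
#'   preferentially occur in sediment rather than water.
#' @param kow_partition_steepness Logistic steepness of the partition.
#' @param estimated_below_rl_prob Probability that a simulated value below
#'   the reporting limit is still reported (as an estimated result) rather
#'   than left-censored.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_rivers = 12,
                             sites_per_river = NULL,
                             visits_per_site = 2,
                             sediment_visits = 1,
                             archetype_assignment = NULL,
                             chemical_panel = default_chemical_panel(),
                             kow_partition_threshold = 3,
                             kow_partition_steepness = 1.5,
                             estimated_below_rl_prob = 0.5,
                             seed = 1) {
  stopifnot(n_rivers >= 1, visits_per_site >= 1, sediment_visits >= 0,
            kow_partition_steepness > 0,
            estimated_below_rl_prob >= 0, estimated_below_rl_prob <= 1)
  if (any(chemical_panel$base_occurrence_prob < 0 |
            chemical_panel$base_occurrence_prob > 1)) {
    stop("base_occurrence_prob must lie in [0, 1]", call. = FALSE)
  }
  if (any(chemical_panel$sdlog <= 0)) {
    stop("sdlog must be > 0", call. = FALSE)
  }
  if (any(chemical_panel$reporting_limit <= 0)) {
    stop("reporting_limit must be > 0", call. = FALSE)
  }
  if (is.null(archetype_assignment)) {
    n_u <- round(0.42 * n_rivers)
    n_a <- round(0.33 * n_rivers)
    archetype_assignment <- c(rep("urban_wwtp", n_u),
                              rep("agricultural", n_a),
                              rep("reference", n_rivers - n_u - n_a))
  }
  archetype_assignment <- rep_len(archetype_assignment, n_rivers)
  stopifnot(all(archetype_assignment %in% ARCHETYPES))
  structure(
    list(n_rivers = n_rivers, sites_per_river = sites_per_river,
         visits_per_site = visits_per_site, sediment_visits = sediment_visits,
         archetype_assignment = archetype_assignment,
         chemical_panel = chemical_panel,
         kow_partition_threshold = kow_partition_threshold,
         kow_partition_steepness = kow_partition_steepness,
         estimated_below_rl_prob = estimated_below_rl_prob,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Logistic water/sediment weight from log Kow; low-Kow chemicals occur
# mostly in water, high-Kow mostly in sediment.
partition_weight <- function(log_kow, matrix, config) {
  z <- config$kow_partition_steepness *
    (config$kow_partition_threshold - log_kow)
  w <- stats::plogis(z)
  if (matrix == "water") w else 1 - w
}

#' Occurrence and detection probabilities of the generator
#'
#' `occurrence_prob()` is the per-sample-slot probability that a chemical
#' is present: the base probability times the archetype multiplier (capped
#' at 1) times the log-Kow partition weight for the matrix.
#' `detection_prob()` additionally accounts for censored reporting: a
#' present chemical whose concentration falls below the reporting limit is
#' reported (as estimated) only with probability
#' `estimated_below_rl_prob`, so
#' detection = occurrence * (1 - (1 - p_est) * P(conc < RL)).
#'
#' @param chemical_id Chemical id in the config's panel.
#' @param archetype One of `urban_wwtp`, `agricultural`, `reference`,
#'   `mixed`.
#' @param matrix `"water"` or `"sediment"`.
#' @param config A `generator_config`.
#' @return A probability.
#' @export
occurrence_prob <- function(chemical_id, archetype, matrix, config) {
  panel <- config$chemical_panel
  i <- match(chemical_id, panel$chemical_id)
  if (is.na(i)) stop("chemical not in panel: ", chemical_id, call. = FALSE)
  mult <- panel[[paste0("mult_", archetype)]][i]
  pmin(1, panel$base_occurrence_prob[i] * mult) *
    partition_weight(panel$log_kow[i], matrix, config)
}

#' @rdname occurrence_prob
#' @export
detection_prob <- function(chemical_id, archetype, matrix, config) {
  panel <- config$chemical_panel
  i <- match(chemical_id, panel$chemical_id)
  if (is.na(i)) stop("chemical not in panel: ", chemical_id, call. = FALSE)
  shift <- panel[[paste0("shift_", archetype)]][i]
  mu <- panel$meanlog[i] + shift * panel$sdlog[i]
  p_below <- stats::plnorm(panel$reporting_limit[i], mu, panel$sdlog[i])
  occurrence_prob(chemical_id, archetype, matrix, config) *
    (1 - (1 - config$estimated_below_rl_prob) * p_below)
}

#' Generate the chemical and site registries of the synthetic network
#'
#' Deterministic given the config seed: rivers `R01..`, site ids
#' `R01-1..`, each river assigned its planted archetype and a (possibly
#' drawn) number of sites; the chemical registry is derived from the
#' panel.
#'
#' @param config A `generator_config`.
#' @return List with `chemicals` and `sites` registry tibbles.
#' @export
generate_registries <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_rivers
  rivers <- sprintf("R%02d", seq_len(n))
  spr <- config$sites_per_river
  if (is.null(spr)) {
    spr <- sample(3:8, n, replace = TRUE)
  } else {
    spr <- rep_len(as.integer(spr), n)
  }
  sites <- tibble(
    river = rep(rivers, spr),
    archetype = rep(config$archetype_assignment, spr),
    sites_order = unlist(lapply(spr, seq_len))
  )
  sites$site_id <- paste0(sites$river, "-", sites$sites_order)
  sites <- sites[c("site_id", "river", "sites_order", "archetype")]

  panel <- config$chemical_panel
  chemicals <- tibble(
    chemical_id = panel$chemical_id,
    name = panel$chemical_id,
    chemical_class = panel$chemical_class,
    log_kow = panel$log_kow,
    analyzed_in = "water|sediment",
    eeq_factor = panel$eeq_factor
  )
  list(chemicals = validate_chemicals(chemicals),
       sites = validate_sites(sites))
}

#' Simulate censored concentration records
#'
#' For every site, visit, matrix, and panel chemical: presence is drawn
#' Bernoulli with the [occurrence_prob()] of the site's archetype; present
#' chemicals draw a lognormal concentration with the archetype's mean
#' shift; values below the reporting limit are reported as estimated with
#' probability `estimated_below_rl_prob` and left-censored (nondetect, no
#' value) otherwise — a coarse stand-in for the growing false-negative
#' probability of low-level laboratory determinations. Fully reproducible
#' from the config seed.
#'
#' @param registries Output of [generate_registries()].
#' @param config The same `generator_config`.
#' @return A validated record tibble.
#' @export
simulate_records <- function(registries, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  panel <- config$chemical_panel
  sites <- registries$sites

  visit_dates <- list(
    water = as.Date("2013-05-15") + 90 * (seq_len(config$visits_per_site) - 1),
    sediment = if (config$sediment_visits > 0) {
      as.Date("2013-08-15") + 90 * (seq_len(config$sediment_visits) - 1)
    } else as.Date(character())
  )

  blocks <- list()
  for (mat in MATRIX_LEVELS) {
    dates <- visit_dates[[mat]]
    if (length(dates) == 0) next
    grid <- expand.grid(
      chem = seq_len(nrow(panel)),
      visit = seq_along(dates),
      site = seq_len(nrow(sites)),
      KEEP.OUT.ATTRS = FALSE
    )
    arche <- sites$archetype[grid$site]
    mult <- mapply(function(i, a) panel[[paste0("mult_", a)]][i],
                   grid$chem, arche)
    shift <- mapply(function(i, a) panel[[paste0("shift_", a)]][i],
                    grid$chem, arche)
    w <- partition_weight(panel$log_kow[grid$chem], mat, config)
    p_eff <- pmin(1, panel$base_occurrence_prob[grid$chem] * mult) * w
    occurs <- stats::runif(nrow(grid)) < p_eff
    mu <- panel$meanlog[grid$chem] + shift * panel$sdlog[grid$chem]
    conc <- stats::rlnorm(nrow(grid), mu, panel$sdlog[grid$chem])
    keep_coin <- stats::runif(nrow(grid)) < config$estimated_below_rl_prob
    rl <- panel$reporting_limit[grid$chem]

    below <- conc < rl
    status <- ifelse(!occurs | (below & !keep_coin), "nondetect",
                     ifelse(below, "estimated", "quantified"))
    value <- ifelse(status == "nondetect", NA_real_, conc)

    blocks[[mat]] <- tibble(
      site_id = sites$site_id[grid$site],
      sample_id = paste0(sites$site_id[grid$site], "-", substr(mat, 1, 1),
                         grid$visit),
      date = dates[grid$visit],
      matrix = mat,
      chemical_id = panel$chemical_id[grid$chem],
      value = value,
      detect_status = status,
      reporting_limit = rl
    )
  }
  validate_records(dplyr::bind_rows(blocks))
}

#' Planted ground truth of a generated network
#'
#' @param registries Output of [generate_registries()].
#' @return List with `site_archetype` (named character vector, site ->
#'   planted land-use archetype) and `chemical_class` (named character
#'   vector, chemical -> class).
#' @export
planted_truth <- function(registries) {
  list(
    site_archetype = stats::setNames(registries$sites$archetype,
                                     registries$sites$site_id),
    chemical_class = stats::setNames(registries$chemicals$chemical_class,
                                     registries$chemicals$chemical_id)
  )
}

#' Analytic expectation of the per-site EEQ under the generator
#'
#' The generator's EEQ has a closed-form expectation per site: for each
#' estrogen-active chemical the censored-recoded per-visit value has a
#' known mixed distribution (a point mass at zero from non-occurrence and
#' censoring, plus the partially censored lognormal), the per-site value is
#' the maximum over visits, and E[max] follows from one-dimensional
#' quadrature of 1 - F(v)^m. Used as an independent oracle for
#' Monte-Carlo recovery checks of the pipeline.
#'
#' @param config A `generator_config`.
#' @param archetype Archetype of the sites being averaged over.
#' @param matrix `"water"` (default) or `"sediment"`.
#' @return Expected total EEQ per site, in ng/L (or ng/kg).
#' @export
expected_site_eeq <- function(config, archetype, matrix = "water") {
  panel <- config$chemical_panel
  active <- which(!is.na(panel$eeq_factor) & panel$eeq_factor > 0)
  m <- if (matrix == "water") config$visits_per_site else
    config$sediment_visits
  if (m == 0 || length(active) == 0) return(0)
  p_est <- config$estimated_below_rl_prob
  total <- 0
  for (i in active) {
    p <- occurrence_prob(panel$chemical_id[i], archetype, matrix, config)
    shift <- panel[[paste0("shift_", archetype)]][i]
    mu <- panel$meanlog[i] + shift * panel$sdlog[i]
    sig <- panel$sdlog[i]
    rl <- panel$reporting_limit[i]
    cdf <- function(v) {
      fx <- stats::plnorm(v, mu, sig)
      frl <- stats::plnorm(rl, mu, sig)
      cond <- ifelse(v < rl, p_est * fx + (1 - p_est) * frl, fx)
      (1 - p) + p * cond
    }
    upper <- stats::qlnorm(1 - 1e-12, mu, sig)
    e_max <- stats::integrate(function(v) 1 - cdf(v)^m, 0, upper,
                              rel.tol = 1e-9, subdivisions = 500L)$value
    total <- total + 1000 * panel$eeq_factor[i] * e_max
  }
  total
}
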
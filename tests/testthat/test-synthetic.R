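test_that("registries are deterministic given the seed and structurally sound", {
  cfg <- generator_config(seed = 42)
  r1 <- generate_registries(cfg)
  r2 <- generate_registries(cfg)
  expect_identical(r1, r2)
  expect_false(identical(
    r1$sites, generate_registries(generator_config(seed = 43))$sites))

  spr <- c(3, 5, 8, 4)
  cfg2 <- generator_config(n_rivers = 4, sites_per_river = spr, seed = 1)
  reg <- generate_registries(cfg2)
  expect_equal(nrow(reg$sites), sum(spr))
  expect_equal(anyDuplicated(reg$sites$site_id), 0L)
  expect_equal(length(unique(reg$sites$river)), 4L)
})

test_that("simulated record files are byte-identical across reruns", {
  cfg <- generator_config(n_rivers = 3, sites_per_river = 2, seed = 17)
  reg <- generate_registries(cfg)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_records(simulate_records(reg, cfg), p1)
  write_records(simulate_records(reg, cfg), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("every simulated record satisfies the censoring invariants", {
  for (s in c(2, 9)) {
    cfg <- generator_config(n_rivers = 4, sites_per_river = 3, seed = s)
    reg <- generate_registries(cfg)
    expect_silent(validate_records(simulate_records(reg, cfg)))
  }
})

test_that("an archetype multiplier of zero suppresses occurrence entirely", {
  panel <- dplyr::bind_rows(
    panel_row("NEVER", mult = c(0, 1, 1, 1), p = 0.9),
    panel_row("ALWAYS", mult = c(1, 1, 1, 1), p = 0.9))
  cfg <- generator_config(n_rivers = 2, sites_per_river = 5,
                          archetype_assignment = c("urban_wwtp",
                                                   "agricultural"),
                          chemical_panel = panel, seed = 3)
  reg <- generate_registries(cfg)
  rec <- simulate_records(reg, cfg)
  urban_sites <- reg$sites$site_id[reg$sites$archetype == "urban_wwtp"]
  hits <- rec$detect_status != "nondetect" & rec$chemical_id == "NEVER" &
    rec$site_id %in% urban_sites
  expect_equal(sum(hits), 0L)
  expect_equal(occurrence_prob("NEVER", "urban_wwtp", "water", cfg), 0)
})

test_that("empirical detection frequencies fall in the exact 99% binomial band", {
  # ~200 water sample slots of a single half-occurring chemical
  panel <- panel_row("COIN", p = 0.5, kow = 0, mu = log(10), rl = 1e-6)
  cfg <- generator_config(n_rivers = 1, sites_per_river = 100,
                          visits_per_site = 2, sediment_visits = 0,
                          archetype_assignment = "mixed",
                          chemical_panel = panel, seed = 8)
  reg <- generate_registries(cfg)
  rec <- simulate_records(reg, cfg)
  p <- detection_prob("COIN", "mixed", "water", cfg)
  n <- sum(rec$matrix == "water")
  k <- sum(rec$detect_status != "nondetect")
  expect_equal(n, 200L)
  band <- qbinom(c(0.005, 0.995), n, p)
  expect_gte(k, band[1])
  expect_lte(k, band[2])
})

test_that("urban pharmaceutical concentrations dominate reference at 2-sigma shift", {
  panel <- panel_row("PH", class = "Pharmaceutical", p = 1, kow = 0,
                     mu = log(0.05), sig = 1, mult = c(1, 1, 1, 1),
                     shift = c(2, 0, 0, 0), rl = 1e-9)
  cfg <- generator_config(n_rivers = 2, sites_per_river = 50,
                          archetype_assignment = c("urban_wwtp",
                                                   "reference"),
                          chemical_panel = panel, seed = 6)
  reg <- generate_registries(cfg)
  rec <- recode_censored(simulate_records(reg, cfg))
  truth <- planted_truth(reg)$site_archetype
  w <- rec[rec$matrix == "water", ]
  urb <- w$value[truth[w$site_id] == "urban_wwtp"]
  ref <- w$value[truth[w$site_id] == "reference"]
  expect_gt(median(urb), median(ref))
  expect_lt(wilcox.test(urb, ref, alternative = "greater")$p.value, 1e-6)
})

test_that("planted truth labels partition the sites and survive simulation", {
  cfg <- generator_config(n_rivers = 5, sites_per_river = 4, seed = 23)
  reg <- generate_registries(cfg)
  truth <- planted_truth(reg)
  expect_equal(length(truth$site_archetype), 20L)
  expect_setequal(names(truth$site_archetype), reg$sites$site_id)
  expect_equal(length(truth$chemical_class),
               nrow(cfg$chemical_panel))
  invisible(simulate_records(reg, cfg))
  expect_identical(truth, planted_truth(reg))
})

test_that("ubiquity filtering recovers the planted ubiquitous subset exactly", {
  panel <- dplyr::bind_rows(
    lapply(1:4, function(i) panel_row(sprintf("UBIQ-%d", i), p = 0.7,
                                      kow = 0, mu = log(1), rl = 1e-4)),
    lapply(1:4, function(i) panel_row(sprintf("RARE-%d", i), p = 0.08,
                                      kow = 0, mu = log(1), rl = 1e-4)))
  cfg <- generator_config(n_rivers = 5, sites_per_river = 10,
                          visits_per_site = 2, sediment_visits = 0,
                          archetype_assignment = "mixed",
                          chemical_panel = panel, seed = 12)
  reg <- generate_registries(cfg)
  rec <- recode_censored(simulate_records(reg, cfg))
  panel_out <- ubiquity_filter(chemical_summary(rec, "water"), 30)
  expect_setequal(panel_out, sprintf("UBIQ-%d", 1:4))
})

test_that("pipeline EEQ matches the generator's analytic expectation", {
  cfg <- generator_config(n_rivers = 1, sites_per_river = 1000,
                          archetype_assignment = "urban_wwtp", seed = 11)
  reg <- generate_registries(cfg)
  rec <- recode_censored(simulate_records(reg, cfg))
  sm <- site_maxima(rec, "water")
  mc <- mean(site_eeq(sm, reg$chemicals)$totals$total_eeq)
  analytic <- expected_site_eeq(cfg, "urban_wwtp", "water")
  expect_lt(abs(mc - analytic) / analytic, 0.10)
})

test_that("water/sediment partitioning follows log Kow around the threshold", {
  cfg <- generator_config(seed = 1)
  low <- occurrence_prob("PHARM-01", "mixed", "water", cfg) /
    occurrence_prob("PHARM-01", "mixed", "sediment", cfg)
  high <- occurrence_prob("STER-01", "mixed", "water", cfg) /
    occurrence_prob("STER-01", "mixed", "sediment", cfg)
  expect_gt(low, 1)   # log Kow << 3: mostly water
  expect_lt(high, 1)  # log Kow >> 3: mostly sediment
})
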
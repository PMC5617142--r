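make_site_max <- function(m, matrix = "water") {
  structure(m, class = c("site_max_matrix", "matrix", "array"),
            matrix = matrix, units = cecscreen::matrix_units(matrix))
}

test_that("benchmark selection prefers the lowest chronic, falls back to acute", {
  bm <- tibble::tibble(
    chemical_id = c("A", "A", "B", "B"),
    value = c(0.3, 0.5, 1.2, 2.0),
    kind = c("chronic", "chronic", "acute", "acute"))
  expect_equal(select_water_benchmark("A", bm), 0.3)
  # prometon rule: no chronic entry -> lowest acute
  expect_equal(select_water_benchmark("B", bm), 1.2)
  expect_true(is.na(select_water_benchmark("C", bm)))
})

test_that("exceedance quotients flag at the inclusive >= 1 boundary", {
  sm <- make_site_max(matrix(c(0.671, 0.04, 0), 3, 1,
                             dimnames = list(c("S1", "S2", "S3"), "FLU")))
  bm <- tibble::tibble(chemical_id = "FLU", value = 0.04, kind = "chronic")
  q <- exceedance_quotients(sm, bm)
  expect_equal(q$quotient[q$site_id == "S1"], 0.671 / 0.04)
  expect_true(q$exceeds[q$site_id == "S1"])
  # exactly equal -> quotient 1, flagged
  expect_equal(q$quotient[q$site_id == "S2"], 1)
  expect_true(q$exceeds[q$site_id == "S2"])
  # never detected -> 0, not flagged
  expect_false(q$exceeds[q$site_id == "S3"])
  # unbenchmarked chemicals are omitted
  sm2 <- make_site_max(matrix(1, 1, 2,
                              dimnames = list("S1", c("FLU", "NOB"))))
  expect_equal(unique(exceedance_quotients(sm2, bm)$chemical_id), "FLU")
})

test_that("quotients scale linearly with concentration", {
  set.seed(3)
  sm <- make_site_max(matrix(rlnorm(6), 3, 2,
                             dimnames = list(sprintf("S%d", 1:3),
                                             c("A", "B"))))
  bm <- tibble::tibble(chemical_id = c("A", "B"), value = c(0.2, 2),
                       kind = "chronic")
  q1 <- exceedance_quotients(sm, bm)
  q2 <- exceedance_quotients(make_site_max(sm * 2), bm)
  expect_equal(q2$quotient, 2 * q1$quotient)
})

test_that("tier classification uses inclusive boundaries and is monotone", {
  # published fluoranthene guideline triple
  expect_equal(as.character(tier_classify(20800, 423, 1327, 2230)), "PEC")
  expect_equal(as.character(tier_classify(423, 423, 1327, 2230)), "TEC")
  expect_equal(as.character(tier_classify(0, 423, 1327, 2230)), "below_TEC")
  expect_error(tier_classify(1, 10, 5, 20), "TEC <= MEC <= PEC")

  set.seed(41)
  for (i in 1:20) {
    g <- sort(rlnorm(3, 4, 1))
    conc <- sort(runif(50, 0, 2 * g[3]))
    tiers <- tier_classify(conc, g[1], g[2], g[3])
    expect_true(all(diff(as.integer(tiers)) >= 0))
    # reaching a tier implies exceeding all lower guidelines
    expect_true(all(conc[tiers >= "PEC"] >= g[2]))
    expect_true(all(conc[tiers >= "MEC"] >= g[1]))
  }
})

test_that("river summaries match a count-based oracle in both denominators", {
  set.seed(19)
  sites <- validate_sites(tibble::tibble(
    site_id = sprintf("S%02d", 1:12),
    river = rep(c("R1", "R2", "R3"), each = 4)))
  m <- matrix(round(rlnorm(24, -1, 2), 3) *
                rbinom(24, 1, 0.7), 12, 2,
              dimnames = list(sites$site_id, c("A", "B")))
  bm <- tibble::tibble(chemical_id = c("A", "B"), value = c(0.2, 0.5),
                       kind = "chronic")
  q <- exceedance_quotients(make_site_max(m), bm)
  for (denom in c("detected", "sampled")) {
    summ <- summarize_by_river(q, sites, denominator = denom)
    for (r in c("R1", "R2", "R3")) {
      for (ch in c("A", "B")) {
        in_river <- sites$site_id[sites$river == r]
        det <- sum(m[in_river, ch] > 0)
        exc <- sum(m[in_river, ch] >= bm$value[bm$chemical_id == ch])
        row <- summ[summ$river == r & summ$chemical_id == ch, ]
        if (det == 0) {
          expect_true(is.na(row$percent))
        } else {
          d <- if (denom == "detected") det else length(in_river)
          expect_equal(row$percent, 100 * exc / d)
        }
      }
    }
    expect_true(all(is.na(summ$percent) |
                      (summ$percent >= 0 & summ$percent <= 100)))
    # basin-wide site count equals the sum of per-river counts
    basin <- summ[summ$river == "Basin Wide", ]
    rivers <- summ[summ$river != "Basin Wide", ]
    expect_equal(basin$n_exceeding[order(basin$chemical_id)],
                 tapply(rivers$n_exceeding, rivers$chemical_id, sum)[
                   sort(unique(rivers$chemical_id))],
                 ignore_attr = TRUE)
  }
})

test_that("the site/river exceedance census matches a brute-force count", {
  set.seed(29)
  sites <- validate_sites(tibble::tibble(
    site_id = sprintf("S%02d", 1:15),
    river = rep(c("R1", "R2", "R3", "R4", "R5"), each = 3)))
  m <- matrix(rlnorm(30, -0.5, 1.5) * rbinom(30, 1, 0.6), 15, 2,
              dimnames = list(sites$site_id, c("A", "B")))
  bm <- tibble::tibble(chemical_id = c("A", "B"), value = c(0.5, 1),
                       kind = "chronic")
  q <- exceedance_quotients(make_site_max(m), bm)
  cen <- site_exceedance_census(q, sites)
  hit_sites <- rownames(m)[apply(
    sweep(m, 2, bm$value, `/`) >= 1, 1, any)]
  expect_equal(cen$n_sites_exceeding, length(hit_sites))
  expect_equal(cen$n_rivers_exceeding,
               length(unique(sites$river[sites$site_id %in% hit_sites])))
  expect_equal(cen$percent_sites, 100 * length(hit_sites) / 15)

  # empty report -> zeros; all-flagged -> 100%
  none <- exceedance_quotients(make_site_max(m * 0), bm)
  cen0 <- site_exceedance_census(none, sites)
  expect_equal(cen0$n_sites_exceeding, 0L)
  all_exc <- exceedance_quotients(make_site_max(m * 0 + 100), bm)
  expect_equal(site_exceedance_census(all_exc, sites)$percent_sites, 100)
})

test_that("tier reports feed the census with a tier cutoff", {
  sites <- validate_sites(tibble::tibble(site_id = c("S1", "S2"),
                                         river = c("R1", "R2")))
  g <- tibble::tibble(chemical_id = "X", TEC = 10, MEC = 100, PEC = 1000)
  sm <- make_site_max(matrix(c(5, 1500), 2, 1,
                             dimnames = list(c("S1", "S2"), "X")),
                      matrix = "sediment")
  tiers <- sediment_tiers(sm, g)
  expect_equal(site_exceedance_census(tiers, sites,
                                      tier_at_least = "PEC")$n_sites_exceeding,
               1L)
  expect_equal(site_exceedance_census(tiers, sites,
                                      tier_at_least = "TEC")$n_sites_exceeding,
               1L)
})
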
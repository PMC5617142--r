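make_site_max <- function(m, matrix = "water") {
  structure(m, class = c("site_max_matrix", "matrix", "array"),
            matrix = matrix, units = cecscreen::matrix_units(matrix))
}

test_that("rank transform uses average ranks for ties and shared lowest rank for zeros", {
  m <- matrix(c(1, 2, 2, 3), 4, 1, dimnames = list(sprintf("S%d", 1:4), "A"))
  expect_equal(unname(rank_transform(make_site_max(m))[, 1]),
               c(1, 2.5, 2.5, 4))
  z <- matrix(c(0, 0, 0.5, 2), 4, 1,
              dimnames = list(sprintf("S%d", 1:4), "A"))
  expect_equal(unname(rank_transform(make_site_max(z))[, 1]),
               c(1.5, 1.5, 3, 4))
  const <- matrix(1, 3, 1, dimnames = list(sprintf("S%d", 1:3), "A"))
  expect_warning(rank_transform(make_site_max(const)), "identical")
})

test_that("ranks are invariant under strictly monotone transforms", {
  set.seed(8)
  m <- matrix(rlnorm(30), 6, 5,
              dimnames = list(sprintf("S%d", 1:6), sprintf("C%d", 1:5)))
  base <- rank_transform(make_site_max(m))
  expect_equal(rank_transform(make_site_max(log1p(m) * 7)), base)
  expect_equal(rank_transform(make_site_max(m^3)), base)
})

test_that("rank transform agrees with a sort-and-assign oracle", {
  set.seed(12)
  m <- matrix(sample(c(0, 0, rlnorm(28)), 30, replace = TRUE), 6, 5,
              dimnames = list(sprintf("S%d", 1:6), sprintf("C%d", 1:5)))
  r <- suppressWarnings(rank_transform(make_site_max(m)))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    oracle <- vapply(unname(x), function(v) mean(which(sort(x) == v)),
                     numeric(1))
    expect_equal(unname(r[, j]), oracle)
  }
})

test_that("pairwise Euclidean distances match a double-loop oracle", {
  m <- matrix(c(1, 4, 1, 5), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  # rows (1,1) and (4,5): the 3-4-5 triangle
  expect_equal(as.numeric(pairwise_euclidean(m, "sites")), 5)
  expect_equal(as.numeric(pairwise_euclidean(rbind(m, m[1, , drop = FALSE]),
                                             "sites"))[2], 0)
  set.seed(4)
  r <- matrix(rnorm(24), 4, 6, dimnames = list(letters[1:4], LETTERS[1:6]))
  d <- as.matrix(pairwise_euclidean(r, "chemicals"))
  for (i in 1:6) {
    for (j in 1:6) {
      expect_equal(d[i, j], sqrt(sum((r[, i] - r[, j])^2)))
    }
  }
})

test_that("two leaves merge at their distance; collinear points merge nearest first", {
  d <- stats::dist(matrix(c(0, 3), 2, 1, dimnames = list(c("A", "B"), NULL)))
  dd <- agglomerate(d)
  expect_equal(dd$height, 3)
  expect_equal(export_newick(dd), "(A:3,B:3);")

  d3 <- stats::dist(matrix(c(0, 1, 10), 3, 1,
                           dimnames = list(c("p0", "p1", "p10"), NULL)))
  dd3 <- agglomerate(d3, "complete")
  expect_equal(dd3$height[1], 1)
  expect_equal(canonical_partition(dendrogram_partitions(dd3)[[1]]),
               canonical_partition(list(c("p0", "p1"), "p10")))
  expect_error(agglomerate(stats::dist(matrix(0, 1, 1))), "two leaves")
})

test_that("agglomeration equals the from-scratch re-scan oracle on random instances", {
  set.seed(99)
  for (trial in 1:60) {
    n <- sample(3:8, 1)
    x <- matrix(rnorm(2 * n), n)
    rownames(x) <- sample(sprintf("L%02d", 1:n))
    d <- stats::dist(x)
    for (lk in c("complete", "single")) {
      mine <- agglomerate(d, lk)
      oracle <- naive_agglomerate(d, lk)
      expect_equal(mine$height, oracle$heights)
      got <- lapply(dendrogram_partitions(mine), canonical_partition)
      want <- lapply(oracle$partitions, canonical_partition)
      expect_equal(got, want)
    }
  }
})

test_that("rank-valued (tied) distance matrices agree with the oracle too", {
  set.seed(100)
  for (trial in 1:30) {
    n <- sample(4:8, 1)
    m <- matrix(sample(0:3, n * 3, replace = TRUE), n)
    rownames(m) <- sprintf("S%d", seq_len(n))
    r <- apply(m, 2, rank)
    d <- stats::dist(r)
    mine <- agglomerate(d, "complete")
    oracle <- naive_agglomerate(d, "complete")
    expect_equal(mine$height, oracle$heights)
    expect_equal(lapply(dendrogram_partitions(mine), canonical_partition),
                 lapply(oracle$partitions, canonical_partition))
  }
})

test_that("agglomeration agrees with stats::hclust on tie-free instances", {
  set.seed(55)
  for (trial in 1:10) {
    n <- sample(5:12, 1)
    x <- matrix(rnorm(3 * n), n)
    rownames(x) <- sprintf("L%02d", seq_len(n))
    d <- stats::dist(x)
    for (lk in c("complete", "average", "single")) {
      mine <- agglomerate(d, lk)
      ref <- stats::hclust(d, method = lk)
      expect_equal(mine$height, ref$height)
      expect_equal(stats::cophenetic(as.hclust(mine)),
                   stats::cophenetic(ref))
    }
  }
})

test_that("complete-linkage merge heights are non-decreasing", {
  set.seed(21)
  for (trial in 1:10) {
    r <- apply(matrix(rlnorm(40), 8, 5), 2, rank)
    rownames(r) <- sprintf("S%d", 1:8)
    dd <- agglomerate(stats::dist(r), "complete")
    expect_true(all(diff(dd$height) >= 0))
  }
})

test_that("cluster cuts match stats::cutree and the merge-forest definition", {
  set.seed(61)
  x <- matrix(rnorm(20), 10, 2)
  rownames(x) <- sprintf("L%02d", 1:10)
  dd <- agglomerate(stats::dist(x), "complete")
  hc <- as.hclust(dd)
  for (k in c(1, 2, 3, 5, 10)) {
    mine <- cut_clusters(dd, k)
    ref <- stats::cutree(hc, k)
    expect_equal(length(unique(mine)), k)
    expect_equal(canonical_partition(mine), canonical_partition(ref))
  }
  expect_error(cut_clusters(dd, 0), "k must be")
  expect_error(cut_clusters(dd, 11), "k must be")
  # k = n gives singletons
  expect_equal(unname(cut_clusters(dd, 10)), 1:10)
})

test_that("Newick export round-trips through ape with cophenetic heights", {
  set.seed(14)
  x <- matrix(rnorm(14), 7, 2)
  rownames(x) <- sprintf("t%d", 1:7)
  dd <- agglomerate(stats::dist(x), "complete")
  tr <- ape::read.tree(text = export_newick(dd))
  expect_setequal(tr$tip.label, dd$labels)
  # patristic distance between two leaves = 2 * merge height
  pat <- ape::cophenetic.phylo(tr)
  cop <- as.matrix(stats::cophenetic(as.hclust(dd)))
  expect_equal(pat[rownames(cop), colnames(cop)], 2 * cop,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("two-way ordering yields bijective permutations and separates planted blocks", {
  # planted two-block structure: sites 1-4 high on chems A-C, sites 5-8 on D-F
  set.seed(33)
  m <- matrix(rlnorm(48, -3, 0.3), 8, 6,
              dimnames = list(sprintf("S%d", 1:8), LETTERS[1:6]))
  m[1:4, 1:3] <- m[1:4, 1:3] * 1e4
  m[5:8, 4:6] <- m[5:8, 4:6] * 1e4
  tw <- two_way_order(make_site_max(m))
  expect_setequal(tw$site_order, rownames(m))
  expect_setequal(tw$chemical_order, colnames(m))
  site_groups <- cut_clusters(tw$site_dendrogram, 2)
  expect_equal(canonical_partition(site_groups),
               canonical_partition(list(sprintf("S%d", 1:4),
                                        sprintf("S%d", 5:8))))
  chem_groups <- cut_clusters(tw$chemical_dendrogram, 2)
  expect_equal(canonical_partition(chem_groups),
               canonical_partition(list(LETTERS[1:3], LETTERS[4:6])))
  expect_equal(dim(tw$ordered_matrix), dim(m))
})

test_that("clustering is invariant under monotone per-chemical transforms", {
  set.seed(66)
  m <- matrix(rlnorm(40), 8, 5,
              dimnames = list(sprintf("S%d", 1:8), sprintf("C%d", 1:5)))
  t1 <- two_way_order(make_site_max(m))
  warped <- sweep(sqrt(m), 2, c(1, 10, 0.2, 5, 3), `*`)
  t2 <- two_way_order(make_site_max(warped))
  expect_equal(t1$site_order, t2$site_order)
  expect_equal(t1$chemical_order, t2$chemical_order)
  expect_equal(t1$site_dendrogram$height, t2$site_dendrogram$height)
})
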
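# Fixture builders and independent oracles shared across tests.

make_record <- function(site_id = "S1", sample_id = "S1-1",
                        date = as.Date("2013-05-15"), matrix = "water",
                        chemical_id = "CHEM-A", value = 0.5,
                        detect_status = "quantified",
                        reporting_limit = 0.04) {
  tibble::tibble(site_id = site_id, sample_id = sample_id, date = date,
                 matrix = matrix, chemical_id = chemical_id, value = value,
                 detect_status = detect_status,
                 reporting_limit = reporting_limit)
}

# Random valid record table: values drawn lognormal, censoring assigned to
# respect the reporting-limit invariants by construction.
random_records <- function(n = 60, n_sites = 5, n_chems = 4,
                           matrix = "water", rl = 0.05) {
  value <- rlnorm(n, log(0.05), 1.5)
  status <- ifelse(value >= rl, "quantified",
                   ifelse(runif(n) < 0.5, "estimated", "nondetect"))
  value[status == "nondetect"] <- NA_real_
  tibble::tibble(
    site_id = sample(sprintf("S%d", seq_len(n_sites)), n, replace = TRUE),
    sample_id = sprintf("samp-%03d", seq_len(n)),
    date = as.Date("2013-05-15") + sample(0:120, n, replace = TRUE),
    matrix = matrix,
    chemical_id = sample(sprintf("CHEM-%d", seq_len(n_chems)), n,
                         replace = TRUE),
    value = value,
    detect_status = status,
    reporting_limit = rl
  )
}

# One-row generator panels for controlled simulation scenarios.
panel_row <- function(id = "X-01", class = "Other", kow = 0, rl = 0.001,
                      p = 0.5, mu = log(1), sig = 1,
                      mult = c(1, 1, 1, 1), shift = c(0, 0, 0, 0),
                      eeq = NA_real_) {
  tibble::tibble(
    chemical_id = id, chemical_class = class, log_kow = kow,
    reporting_limit = rl, base_occurrence_prob = p, meanlog = mu,
    sdlog = sig,
    mult_urban_wwtp = mult[1], mult_agricultural = mult[2],
    mult_reference = mult[3], mult_mixed = mult[4],
    shift_urban_wwtp = shift[1], shift_agricultural = shift[2],
    shift_reference = shift[3], shift_mixed = shift[4],
    eeq_factor = eeq
  )
}

# From-scratch agglomeration oracle: at every step cluster distances are
# recomputed from the original distance matrix over current memberships
# (no Lance-Williams updates), with the same lexicographic tie rule.
naive_agglomerate <- function(d, linkage = "complete") {
  dm <- as.matrix(d)
  labels <- rownames(dm)
  clusters <- lapply(seq_along(labels), function(i) labels[i])
  heights <- numeric(0)
  partitions <- list()
  link_fun <- switch(linkage, complete = max, single = min, average = mean)
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        cross <- dm[clusters[[i]], clusters[[j]], drop = FALSE]
        dij <- link_fun(cross)
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        cand <- list(d = dij, key = key, i = i, j = j)
        if (is.null(best) || dij < best$d ||
            (dij == best$d && (key[1] < best$key[1] ||
                               (key[1] == best$key[1] &&
                                key[2] < best$key[2])))) {
          best <- cand
        }
      }
    }
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
    heights <- c(heights, best$d)
    partitions <- c(partitions, list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions)
}

# Canonical form of a partition (set of sorted label vectors) for equality
# comparison irrespective of cluster order/numbering.
canonical_partition <- function(groups) {
  if (is.list(groups)) {
    parts <- lapply(groups, sort)
  } else {
    parts <- split(names(groups), groups)
    parts <- lapply(parts, sort)
  }
  sorted <- sapply(parts, paste, collapse = "|")
  paste(sort(sorted), collapse = " // ")
}

# Partition sequence implied by a cec_dendrogram: after each merge, the
# groups from cutting at k = n - step.
dendrogram_partitions <- function(dend) {
  n <- length(dend$labels)
  lapply(seq_len(n - 1), function(step) {
    grp <- cut_clusters(dend, n - step)
    split(names(grp), grp)
  })
}
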
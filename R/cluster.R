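#' Rank-transform a site-maximum matrix
#'
#' Replaces concentrations by ranks so that chemicals with very different
#' concentration scales become comparable before Euclidean distances are
#' taken. With `within = "chemical"` (default) each chemical's values are
#' ranked across sites (1 = lowest), ties receiving average ranks; all
#' nondetect sites (zeroes) therefore share the lowest average rank. Ranks
#' absorb any strictly monotone transform of a chemical's concentrations.
#'
#' @param site_max A `site_max_matrix` (usually panel-restricted; see
#'   [restrict_to_panel()]).
#' @param within `"chemical"`: rank each chemical across sites;
#'   `"site"`: rank each site across chemicals.
#' @return Numeric matrix of ranks with the same dimnames (sites x
#'   chemicals). Chemicals constant across all sites keep constant ranks,
#'   with a warning.
#' @export
rank_transform <- function(site_max, within = c("chemical", "site")) {
  within <- match.arg(within)
  m <- unclass(site_max)
  if (within == "chemical") {
    constant <- apply(m, 2, function(x) length(unique(x)) == 1)
    if (any(constant)) {
      warning("chemical(s) with identical values at all sites: ",
              paste(colnames(m)[constant], collapse = ", "))
    }
    ranks <- apply(m, 2, rank, ties.method = "average")
  } else {
    ranks <- t(apply(m, 1, rank, ties.method = "average"))
  }
  dimnames(ranks) <- dimnames(m)
  ranks
}

#' Pairwise Euclidean distances along one axis of a rank matrix
#'
#' @param rank_matrix Sites-by-chemicals numeric matrix (no missing
#'   entries).
#' @param axis `"sites"` distances between site rows; `"chemicals"`
#'   distances between chemical columns.
#' @return A symmetric `dist` object with zero diagonal.
#' @export
pairwise_euclidean <- function(rank_matrix, axis = c("sites", "chemicals")) {
  axis <- match.arg(axis)
  if (anyNA(rank_matrix)) stop("rank matrix has missing entries",
                               call. = FALSE)
  if (axis == "sites") stats::dist(rank_matrix) else stats::dist(t(rank_matrix))
}

#' Agglomerative hierarchical clustering with deterministic tie-breaking
#'
#' Standard bottom-up agglomeration: starting from singletons, the pair of
#' clusters at minimal linkage distance is merged at each step until one
#' cluster remains. Linkage distances are maintained by the Lance-Williams
#' updates (complete = max, single = min, average = size-weighted mean).
#' When several pairs tie at the minimal distance, the pair whose cluster
#' labels (each cluster is labelled by its smallest member leaf label) are
#' lexicographically smallest is merged, which makes dendrograms
#' reproducible across runs and platforms.
#'
#' @param d A `dist` object (or symmetric matrix) with leaf labels.
#' @param linkage `"complete"` (default), `"average"`, or `"single"`.
#' @param axis Optional axis tag (`"chemicals"` or `"sites"`) carried on
#'   the result.
#' @return A `cec_dendrogram`: list with `labels`, `merge` (n-1 x 2 matrix,
#'   negative entries = leaves, positive = earlier merges, as in
#'   [stats::hclust()]), `height`, `order` (leaf permutation with the
#'   tighter subcluster first), `linkage`, `axis`.
#' @export
agglomerate <- function(d, linkage = c("complete", "average", "single"),
                        axis = NULL) {
  linkage <- match.arg(linkage)
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 2) stop("need at least two leaves to cluster", call. = FALSE)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  rownames(dm) <- colnames(dm) <- NULL
  diag(dm) <- Inf

  # Per active cluster: smallest member label (tie-break key), size, and
  # its id in hclust merge coding (-leaf or +merge step).
  active <- seq_len(n)
  key <- labels
  size <- rep(1L, n)
  code <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    sub <- dm[active, active, drop = FALSE]
    dmin <- min(sub)
    hits <- which(sub == dmin, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # lexicographic tie-break on the sorted pair of cluster labels
    ka <- key[active[hits[, 1]]]
    kb <- key[active[hits[, 2]]]
    lo <- pmin(ka, kb)
    hi <- pmax(ka, kb)
    pick <- order(lo, hi)[1]
    i <- active[hits[pick, 1]]
    j <- active[hits[pick, 2]]

    # child with the lexicographically smaller min-label first
    if (key[i] <= key[j]) {
      merge[step, ] <- c(code[i], code[j])
    } else {
      merge[step, ] <- c(code[j], code[i])
    }
    height[step] <- dmin

    others <- setdiff(active, c(i, j))
    new_d <- switch(linkage,
      complete = pmax(dm[i, others], dm[j, others]),
      single = pmin(dm[i, others], dm[j, others]),
      average = (size[i] * dm[i, others] + size[j] * dm[j, others]) /
        (size[i] + size[j])
    )
    dm[i, others] <- new_d
    dm[others, i] <- new_d
    dm[i, j] <- dm[j, i] <- Inf
    size[i] <- size[i] + size[j]
    key[i] <- min(key[i], key[j])
    code[i] <- step
    active <- setdiff(active, j)
  }

  dend <- structure(
    list(labels = labels, merge = merge, height = height,
         linkage = linkage, axis = axis),
    class = "cec_dendrogram"
  )
  dend$order <- dendrogram_order(dend)
  dend
}

# Leaf order by recursive traversal, visiting the tighter (lower merge
# height) subcluster first; leaves count as height 0 and label order breaks
# exact ties.
dendrogram_order <- function(dend) {
  node_height <- function(id) if (id < 0) 0 else dend$height[id]
  node_key <- function(id) {
    if (id < 0) dend$labels[-id] else
      min(node_key(dend$merge[id, 1]), node_key(dend$merge[id, 2]))
  }
  walk <- function(id) {
    if (id < 0) return(-id)
    a <- dend$merge[id, 1]
    b <- dend$merge[id, 2]
    ha <- node_height(a)
    hb <- node_height(b)
    first_a <- if (ha != hb) ha < hb else node_key(a) <= node_key(b)
    if (first_a) c(walk(a), walk(b)) else c(walk(b), walk(a))
  }
  walk(nrow(dend$merge))
}

#' @export
print.cec_dendrogram <- function(x, ...) {
  cat("Agglomerative dendrogram (", x$linkage, " linkage",
      if (!is.null(x$axis)) paste0(", axis: ", x$axis), "): ",
      length(x$labels), " leaves, merge heights ",
      signif(min(x$height), 4), " .. ", signif(max(x$height), 4), "\n",
      sep = "")
  invisible(x)
}

#' Convert a dendrogram to an `hclust` object
#'
#' @param x A `cec_dendrogram`.
#' @param ... Unused.
#' @return An object of class `hclust`.
#' @export
as.hclust.cec_dendrogram <- function(x, ...) {
  structure(
    list(merge = x$merge, height = x$height, order = x$order,
         labels = x$labels, method = x$linkage,
         call = match.call(), dist.method = "euclidean"),
    class = "hclust"
  )
}

#' Cut a dendrogram into k groups
#'
#' Undoes the last k-1 merges: group membership is the connected components
#' of the merge forest truncated before the (n-k+1)-th merge. Groups are
#' numbered by first appearance in leaf-label order.
#'
#' @param dend A `cec_dendrogram`.
#' @param k Number of groups, 1 <= k <= number of leaves.
#' @return Named integer vector (leaf label -> group in 1..k).
#' @export
cut_clusters <- function(dend, k) {
  n <- length(dend$labels)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n || k != round(k)) {
    stop("k must be an integer in [1, ", n, "]", call. = FALSE)
  }
  group <- seq_len(n)
  if (k < n) {
    comp_of_code <- integer(n - 1L)
    for (step in seq_len(n - k)) {
      ids <- dend$merge[step, ]
      members <- unlist(lapply(ids, function(id) {
        if (id < 0) -id else which(group == comp_of_code[id])
      }))
      tgt <- min(group[members])
      group[members] <- tgt
      comp_of_code[step] <- tgt
    }
  }
  out <- match(group, unique(group))
  names(out) <- dend$labels
  out
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are derived from merge heights: each branch's length is
#' its parent's merge height minus the child's (leaves sit at height 0), so
#' a two-leaf tree at height h renders as `(A:h,B:h);`. Labels containing
#' Newick metacharacters are quoted.
#'
#' @param dend A `cec_dendrogram`.
#' @param path Optional file path; when given the string is written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
export_newick <- function(dend, path = NULL) {
  quote_label <- function(lab) {
    if (grepl("[ ():,;\\[\\]']", lab)) {
      paste0("'", gsub("'", "''", lab), "'")
    } else lab
  }
  node_height <- function(id) if (id < 0) 0 else dend$height[id]
  render <- function(id, parent_h) {
    if (id < 0) {
      paste0(quote_label(dend$labels[-id]), ":",
             format(parent_h, digits = 10, trim = TRUE))
    } else {
      h <- dend$height[id]
      paste0("(", render(dend$merge[id, 1], h), ",",
             render(dend$merge[id, 2], h), "):",
             format(parent_h - h, digits = 10, trim = TRUE))
    }
  }
  root <- nrow(dend$merge)
  h <- dend$height[root]
  nwk <- paste0("(", render(dend$merge[root, 1], h), ",",
                render(dend$merge[root, 2], h), ");")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Two-way co-occurrence ordering of a site-maximum matrix
#'
#' The two-way cluster analysis behind co-occurrence heatmaps: the
#' panel-restricted site-maximum matrix is rank-transformed within each
#' chemical, both axes are clustered on Euclidean distances of the ranks,
#' and leaf orders are produced by recursive traversal with the tighter
#' subcluster first. The output is sufficient to render a heatmap: a rank
#' matrix plus row (site) and column (chemical) permutations.
#'
#' @param site_max A panel-restricted `site_max_matrix`.
#' @param linkage Linkage passed to [agglomerate()].
#' @param within Rank axis passed to [rank_transform()].
#' @return List: `chemical_dendrogram`, `site_dendrogram`, `site_order` and
#'   `chemical_order` (label permutations), `rank_matrix`, and
#'   `ordered_matrix` (rank matrix with both permutations applied).
#' @export
two_way_order <- function(site_max, linkage = "complete",
                          within = "chemical") {
  ranks <- suppressWarnings(rank_transform(site_max, within = within))
  chem_d <- agglomerate(pairwise_euclidean(ranks, "chemicals"),
                        linkage = linkage, axis = "chemicals")
  site_d <- agglomerate(pairwise_euclidean(ranks, "sites"),
                        linkage = linkage, axis = "sites")
  site_order <- site_d$labels[site_d$order]
  chem_order <- chem_d$labels[chem_d$order]
  list(
    chemical_dendrogram = chem_d,
    site_dendrogram = site_d,
    site_order = site_order,
    chemical_order = chem_order,
    rank_matrix = ranks,
    ordered_matrix = ranks[site_order, chem_order, drop = FALSE]
  )
}
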
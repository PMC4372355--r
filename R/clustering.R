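# Hierarchical clustering of salinity-response profiles: Euclidean
# distances and complete-linkage agglomeration, with explicit handling of
# the "gray" class (genes with no expression in at least one sample, whose
# log2 ratio is missing).
#
# The agglomeration is implemented here rather than delegated so that ties
# are broken reproducibly (lowest pair of cluster indices, leaves first in
# input order, then merged clusters in order of creation); the merge table
# follows the stats::hclust convention so results interoperate with base R
# dendrogram tooling.

#' Euclidean distance over shared observed positions
#'
#' @param a,b Equal-length numeric profiles; NA marks a missing (gray)
#'   position. The distance uses only positions observed in both profiles,
#'   of which there must be at least one.
#' @return Non-negative distance; symmetric in its arguments.
#' @export
euclidean_distance <- function(a, b) {
  stop_if_not(length(a) == length(b), "profiles differ in length")
  ok <- !is.na(a) & !is.na(b)
  stop_if_not(any(ok), "no shared non-missing positions between profiles")
  sqrt(sum((a[ok] - b[ok])^2))
}

#' Pairwise Euclidean distance matrix of profile rows
#'
#' @param mat Numeric matrix (genes x comparisons), NA = missing.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
profile_distances <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- euclidean_distance(mat[i, ], mat[j, ])
  }
  d
}

#' Complete-linkage agglomerative clustering
#'
#' Standard agglomeration with inter-cluster distance equal to the maximum
#' pairwise member distance. Ties are broken by the lowest pair of cluster
#' indices (leaves numbered first, merged clusters in creation order), so
#' the dendrogram is deterministic.
#'
#' @param d Square symmetric numeric matrix with zero diagonal.
#' @return A list of class `complete_linkage` with `merge` (hclust-style
#'   (n-1) x 2 table: negative entries are leaves, positive entries earlier
#'   merges), `height`, `order` (leaf order) and `labels`.
#' @export
complete_linkage <- function(d) {
  stop_if_not(is.matrix(d) && nrow(d) == ncol(d), "distance matrix not square")
  stop_if_not(isTRUE(all.equal(d, t(d), tolerance = 1e-12)),
              "distance matrix not symmetric")
  stop_if_not(all(abs(diag(d)) < 1e-12), "distance matrix diagonal not zero")
  n <- nrow(d)
  stop_if_not(n >= 2, "need at least two leaves")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # active clusters keyed by a running index: leaves are 1..n, the cluster
  # created at merge step s gets index n + s
  active <- seq_len(n)
  code <- -seq_len(n)            # hclust coding of each active cluster
  work <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (s in seq_len(n - 1)) {
    m <- length(active)
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dij <- work[i, j]
      if (dij < best_d - 1e-15) {
        best_d <- dij; best <- c(i, j)
      }
      # exact ties fall through: earlier (lower-index) pair already kept
    }
    i <- best[1]; j <- best[2]
    merge[s, ] <- sort(c(code[i], code[j]))
    height[s] <- best_d
    # complete linkage: new row is the max of the two merged rows
    new_row <- pmax(work[i, ], work[j, ])[-c(i, j)]
    work <- work[-c(i, j), -c(i, j), drop = FALSE]
    work <- rbind(cbind(work, new_row), c(new_row, 0))
    active <- c(active[-c(i, j)], n + s)
    code <- c(code[-c(i, j)], s)
  }

  order <- integer(0)
  expand <- function(k) {
    if (k < 0) return(-k)
    c(expand(merge[k, 1]), expand(merge[k, 2]))
  }
  order <- expand(merge[n - 1, 1])
  order <- c(order, expand(merge[n - 1, 2]))
  structure(list(merge = merge, height = height, order = order,
                 labels = labels),
            class = "complete_linkage")
}

#' Convert to a stats::hclust object
#'
#' @param x A `complete_linkage` object.
#' @return An object of class `hclust`, usable with [stats::cutree()],
#'   [plot()] etc.
#' @export
as_hclust <- function(x) {
  stop_if_not(inherits(x, "complete_linkage"), "not a complete_linkage object")
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "complete",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

#' Cluster log-ratio profiles with gray-mask handling
#'
#' Rows containing any missing value are carried through to the output
#' matrix (gray-masked, appended after the clustered rows) but excluded from
#' the distance computation under the default policy; the "pairwise" policy
#' instead keeps every row with at least one observation and uses
#' pairwise-complete distances.
#'
#' @param mat Numeric genes x comparisons matrix of log2 ratios, NA =
#'   missing (gene undetected in at least one sample of that comparison).
#' @param policy "complete_rows" (default) or "pairwise".
#' @return A list with `dendrogram` (a `complete_linkage` object over the
#'   clustered rows), `ordered` (the full matrix, clustered rows in leaf
#'   order followed by masked rows), `mask` (logical matrix of missing
#'   cells, aligned with `ordered`) and `masked_rows` (row names excluded
#'   from clustering).
#' @export
cluster_profiles <- function(mat, policy = c("complete_rows", "pairwise")) {
  policy <- match.arg(policy)
  stop_if_not(is.matrix(mat) && nrow(mat) >= 2,
              "need a matrix of at least two profiles")
  if (is.null(rownames(mat))) rownames(mat) <- as.character(seq_len(nrow(mat)))
  any_obs <- rowSums(!is.na(mat)) > 0
  stop_if_not(any(any_obs), "all rows fully missing")
  use <- if (policy == "complete_rows") rowSums(is.na(mat)) == 0 else any_obs
  stop_if_not(sum(use) >= 2,
              "fewer than two rows available for clustering under this policy")
  sub <- mat[use, , drop = FALSE]
  dend <- complete_linkage(profile_distances(sub))
  leaf_names <- rownames(sub)[dend$order]
  ordered <- rbind(mat[leaf_names, , drop = FALSE],
                   mat[!use, , drop = FALSE])
  list(dendrogram = dend,
       ordered = ordered,
       mask = is.na(ordered),
       masked_rows = rownames(mat)[!use])
}
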
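# Independent oracles, written naively on purpose: each re-derives the
# expected behaviour by brute force / direct arithmetic, without reusing the
# package's implementation path.

# per-read re-check of the three filtering rules by direct string scanning
naive_filter_label <- function(bases, qual, adaptors,
                               max_n = 0.10, q_thr = 5, max_lq = 0.50) {
  b <- strsplit(bases, "")[[1]]
  for (ad in adaptors) {
    a <- strsplit(ad, "")[[1]]
    if (length(a) <= length(b)) {
      for (s in 1:(length(b) - length(a) + 1)) {
        if (all(b[s:(s + length(a) - 1)] == a)) return("adaptor")
      }
    }
  }
  if (mean(b == "N") > max_n) return("high_n")
  q <- utf8ToInt(qual) - 33L
  if (mean(q <= q_thr) > max_lq) return("low_quality")
  "clean"
}

# direct arithmetic for the exact-test mass: binomial coefficient times
# powers, no log-gamma
ac_prob_direct <- function(x, y, N1, N2) {
  r <- N2 / N1
  # algebraically identical form that keeps the powers bounded for large y
  choose(x + y, y) * (r / (1 + r))^y * (1 + r)^-(x + 1)
}

# brute-force two-sided p by summation of the direct mass
ac_pvalue_brute <- function(x, y, N1, N2, extra = 1000) {
  lower <- sum(ac_prob_direct(x, 0:y, N1, N2))
  upper <- sum(ac_prob_direct(x, y:(x + y + extra), N1, N2))
  min(1, 2 * min(lower, upper))
}

# hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
hyper_enum_pvalue <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # successes are items 1..K
  mean(hits >= k)
}

# complete-linkage agglomeration recomputed from scratch at every step:
# cluster distances taken as the max over all member pairs of the original
# matrix, ties broken by lowest pair of cluster indices
naive_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))   # member leaf sets
  code <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    m <- length(clusters)
    best <- NULL; best_d <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dij <- max(d[clusters[[i]], clusters[[j]]])
      if (dij < best_d - 1e-15) { best_d <- dij; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    merge[s, ] <- sort(c(code[i], code[j]))
    height[s] <- best_d
    clusters[[length(clusters) + 1]] <- c(clusters[[i]], clusters[[j]])
    clusters <- clusters[-c(i, j)]
    code <- c(code[-c(i, j)], s)
  }
  list(merge = merge, height = height)
}

# tiny count-library pair over an explicit count table
make_library_pair <- function(x, y, lengths = NULL) {
  g <- sprintf("g%02d", seq_along(x))
  if (is.null(lengths)) lengths <- rep(1000L, length(x))
  names(lengths) <- g
  list(control = count_library("ctrl", stats::setNames(x, g), lengths),
       treatment = count_library("trt", stats::setNames(y, g), lengths))
}
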
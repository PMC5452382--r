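# Independent brute-force oracles used to validate the sweep-line engine
# and the pairwise statistics. They work on per-base occupancy vectors and
# never call the code paths they check.

# Per-base membership bitmask vectors, one per chromosome.
brute_masks <- function(sets) {
  ivs <- lapply(sets, function(s) s$intervals)
  chroms <- sort(unique(unlist(lapply(ivs, function(x) x$chrom))))
  out <- list()
  for (ch in chroms) {
    L <- max(unlist(lapply(ivs, function(x) x$end[x$chrom == ch])), 0)
    mask <- numeric(L)
    for (i in seq_along(ivs)) {
      cov <- logical(L)
      sub <- ivs[[i]][ivs[[i]]$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(sub))) {
        cov[seq.int(sub$start[k] + 1L, sub$end[k])] <- TRUE
      }
      mask <- mask + cov * 2^(i - 1)
    }
    out[[ch]] <- mask
  }
  out
}

# Combination counts from the per-base scan: base-pair mode tallies bases,
# region mode tallies maximal constant-mask runs.
oracle_combination_counts <- function(sets, mode) {
  masks <- brute_masks(sets)
  acc <- list()
  for (mask in masks) {
    r <- rle(mask)
    keep <- r$values > 0
    vals <- as.character(r$values[keep])
    add <- if (mode == "basepair") r$lengths[keep] else rep(1L, sum(keep))
    for (i in seq_along(vals)) {
      acc[[vals[i]]] <- (acc[[vals[i]]] %||% 0) + add[i]
    }
  }
  unlist(acc)[order(as.numeric(names(unlist(acc))))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-base coverage of one set (list chrom -> logical vector).
brute_coverage <- function(s, L_by_chrom) {
  out <- lapply(L_by_chrom, function(L) logical(L))
  iv <- s$intervals
  for (k in seq_len(nrow(iv))) {
    ch <- iv$chrom[k]
    out[[ch]][seq.int(iv$start[k] + 1L, iv$end[k])] <- TRUE
  }
  out
}

chrom_lengths <- function(sets) {
  ivs <- lapply(sets, function(s) s$intervals)
  chroms <- sort(unique(unlist(lapply(ivs, function(x) x$chrom))))
  sapply(chroms, function(ch)
    max(unlist(lapply(ivs, function(x) x$end[x$chrom == ch])), 0),
    simplify = FALSE)
}

oracle_jaccard <- function(a, b) {
  L <- chrom_lengths(list(a, b))
  ca <- brute_coverage(a, L); cb <- brute_coverage(b, L)
  inter <- sum(mapply(function(x, y) sum(x & y), ca, cb))
  uni <- sum(mapply(function(x, y) sum(x | y), ca, cb))
  if (uni == 0) 0 else inter / uni
}

# Merged intervals of one set recovered from its per-base coverage.
coverage_intervals <- function(cov_by_chrom) {
  out <- list()
  for (ch in names(cov_by_chrom)) {
    r <- rle(cov_by_chrom[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    sel <- r$values
    if (any(sel)) {
      out[[ch]] <- data.frame(chrom = ch, start = starts[sel],
                              end = ends[sel], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  do.call(rbind, out)
}

oracle_overlap_count <- function(a, b) {
  L <- chrom_lengths(list(a, b))
  ma <- coverage_intervals(brute_coverage(a, L))
  cb <- brute_coverage(b, L)
  n <- 0L
  for (k in seq_len(nrow(ma))) {
    if (any(cb[[ma$chrom[k]]][seq.int(ma$start[k] + 1L, ma$end[k])])) n <- n + 1L
  }
  n
}

# Full-enumeration Fisher oracle: walks every table with the observed
# margins, mass from log-factorials.
oracle_fisher <- function(n11, n12, n21, n22) {
  lf <- function(x) lgamma(x + 1)
  m <- n11 + n12; n <- n21 + n22; k <- n11 + n21; N <- m + n
  logp <- function(x) {
    lf(m) - lf(x) - lf(m - x) + lf(n) - lf(k - x) - lf(n - k + x) -
      (lf(N) - lf(k) - lf(N - k))
  }
  support <- max(0, k - n):min(k, m)
  p <- exp(logp(support))
  p_obs <- exp(logp(n11))
  list(p_left = sum(p[support <= n11]),
       p_right = sum(p[support >= n11]),
       p_two = min(1, sum(p[p <= p_obs * (1 + 1e-7)])))
}

# Standard random fixture family used across the oracle-equivalence tests:
# small genome, 2-5 sets, modest interval counts.
random_fixture <- function(seed, n_sets = NULL) {
  set.seed(seed)
  g <- genome(c(chrA = sample(2e4:5e4, 1), chrB = sample(1e4:5e4, 1)))
  if (is.null(n_sets)) n_sets <- sample(2:5, 1)
  sets <- lapply(seq_len(n_sets), function(i)
    random_regions(g, n = sample(5:200, 1),
                   length_range = sort(sample(20:800, 2)),
                   seed = seed * 13 + i, label = paste0("S", i)))
  list(genome = g, sets = sets)
}
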
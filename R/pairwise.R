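# Pairwise overlap statistics between region sets: overlap counts,
# fractions of overlap, the Jaccard statistic on bases, Fisher's exact test
# against a genome background, and relative-distance distributions — plus
# the n x n matrix assembly, correlation and hierarchical-clustering
# structure used by the heat-map display.

#' Number of query intervals overlapping a target set
#'
#' Counts merged intervals of `a` that overlap at least one merged interval
#' of `b` by >= 1 base. Book-ended intervals (zero shared bases) do not
#' count as overlapping.
#'
#' @param a,b [region_set()] objects (merged internally).
#' @return integer count.
#' @export
overlap_count <- function(a, b) {
  ma <- merge_regions(a)$intervals
  mb <- merge_regions(b)$intervals
  if (nrow(ma) == 0L || nrow(mb) == 0L) return(0L)
  total <- 0L
  for (ch in unique(ma$chrom)) {
    qa <- ma[ma$chrom == ch, , drop = FALSE]
    qb <- mb[mb$chrom == ch, , drop = FALSE]
    if (nrow(qb) == 0L) next
    # merged target is sorted and disjoint: the only candidates for
    # [s, e) are the last target starting at or before s, and the next one
    idx <- findInterval(qa$start, qb$start)
    hit_left <- idx >= 1L & qb$end[pmax(idx, 1L)] > qa$start
    nxt <- idx + 1L
    hit_right <- nxt <= nrow(qb) & qb$start[pmin(nxt, nrow(qb))] < qa$end
    total <- total + sum(hit_left | hit_right)
  }
  as.integer(total)
}

#' Fraction of query intervals overlapping a target set
#'
#' `overlap_count(a, b) / |merged a|`. Asymmetric: `a` is the query set
#' (matrix rows), `b` the target.
#'
#' @inheritParams overlap_count
#' @return real in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b) {
  na <- nrow(merge_regions(a)$intervals)
  if (na == 0L) stop("query set is empty; fraction of overlap undefined")
  overlap_count(a, b) / na
}

# Bases shared by two merged region sets (sweep over the pair).
intersect_bases <- function(a, b) {
  fr <- atomize(list(merge_regions(a), merge_regions(b)))
  both <- fr$mask == 3
  sum(fr$end[both] - fr$start[both])
}

#' Jaccard statistic between two region sets
#'
#' Intersection bases divided by union bases of the merged sets: 0 means no
#' overlap and 1 means full overlap. When both sets are empty the statistic
#' is undefined and reported as 0 with a warning.
#'
#' @inheritParams overlap_count
#' @return real in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  ta <- total_bases(a); tb <- total_bases(b)
  if (ta == 0 && tb == 0) {
    warning("both sets empty; Jaccard undefined, reporting 0", call. = FALSE)
    return(0)
  }
  ib <- intersect_bases(a, b)
  ib / (ta + tb - ib)
}

#' Fisher's exact test for the association of two region sets
#'
#' Builds a 2x2 contingency table from interval overlap counts against a
#' genome background, then computes the exact hypergeometric p-values at
#' fixed margins. The table heuristic: `n11` = merged `a` intervals hitting
#' `b`; `n12 = |a| - n11`; `n21 = |b| - overlap_count(b, a)`; `n22 =
#' max(0, S - n11 - n12 - n21)` where `S = floor(2G / (meanLenA +
#' meanLenB))` approximates the number of interval-sized slots in a genome
#' of total length `G`. The two-sided p-value sums the probabilities of all
#' tables (at fixed margins) no more probable than the observed one.
#'
#' @inheritParams overlap_count
#' @param genome a [genome()] covering every chromosome present in `a`/`b`.
#' @return list of class `fisher_result`: `table` (2x2 matrix), `p_left`,
#'   `p_right`, `p_two_sided`, `odds_ratio` (sample odds ratio, `Inf` when
#'   the off-diagonal is empty).
#' @export
fisher_test_regions <- function(a, b, genome) {
  stopifnot(inherits(genome, "genome"))
  ma <- merge_regions(a); mb <- merge_regions(b)
  miss <- setdiff(unique(c(ma$intervals$chrom, mb$intervals$chrom)),
                  names(genome))
  if (length(miss) > 0L) {
    stop(sprintf("chromosome '%s' absent from genome file", miss[1L]))
  }
  na <- nrow(ma$intervals); nb <- nrow(mb$intervals)
  if (na == 0L || nb == 0L) stop("both sets must be non-empty for Fisher's test")
  n11 <- overlap_count(ma, mb)
  n12 <- na - n11
  n21 <- nb - overlap_count(mb, ma)
  G <- sum(genome)
  mean_len <- total_bases(ma) / na + total_bases(mb) / nb
  S <- floor(2 * G / mean_len)
  n22 <- max(0, S - n11 - n12 - n21)
  tab <- matrix(c(n11, n21, n12, n22), 2L, 2L,
                dimnames = list(c("in A", "not in A"), c("in B", "not in B")))
  res <- hypergeom_pvals(n11, n12, n21, n22)
  odds <- if (n12 == 0 || n21 == 0) Inf else (n11 * n22) / (n12 * n21)
  structure(list(table = tab, p_left = res$p_left, p_right = res$p_right,
                 p_two_sided = res$p_two, odds_ratio = odds),
            class = "fisher_result")
}

# Exact hypergeometric p-values for a 2x2 table at fixed margins.
# Two-sided: total probability of tables no more probable than the observed
# one; a relative slack of 1e-7 treats numerically tied masses as equal.
hypergeom_pvals <- function(n11, n12, n21, n22) {
  m <- n11 + n12          # row 1 margin
  n <- n21 + n22          # row 2 margin
  k <- n11 + n21          # column 1 margin
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(n11, m, n, k)
  incl <- d <= d_obs * (1 + 1e-7)
  list(
    p_left  = stats::phyper(n11, m, n, k),
    p_right = stats::phyper(n11 - 1, m, n, k, lower.tail = FALSE),
    p_two   = if (all(incl)) 1 else min(1, sum(d[incl]))
  )
}

#' @export
print.fisher_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("p (left/right/two-sided): %.4g / %.4g / %.4g; odds ratio %.4g\n",
              x$p_left, x$p_right, x$p_two_sided, x$odds_ratio))
  invisible(x)
}

#' Relative-distance distribution between two region sets
#'
#' For every merged-`a` interval midpoint `m` flanked on the same
#' chromosome by target midpoints `l <= m <= r`, emits
#' `min(m - l, r - m) / (r - l)`, a value in `[0, 0.5]`. Midpoints without
#' both flanks are skipped; duplicate flanks (`r == l`) give 0 by
#' convention. If `a` midpoints fall uniformly between `b` midpoints the
#' distribution is uniform on `[0, 0.5]` with mean 0.25, so departures
#' towards 0 indicate spatial attraction.
#'
#' @inheritParams overlap_count
#' @return numeric vector (possibly empty, with a warning).
#' @export
reldist <- function(a, b) {
  ma <- merge_regions(a)$intervals
  mb <- merge_regions(b)$intervals
  out <- numeric()
  for (ch in unique(ma$chrom)) {
    am <- floor((ma$start[ma$chrom == ch] + ma$end[ma$chrom == ch]) / 2)
    bi <- mb[mb$chrom == ch, , drop = FALSE]
    if (nrow(bi) < 2L) next
    bm <- floor((bi$start + bi$end) / 2)   # merged => already sorted
    idx <- findInterval(am, bm)
    ok <- idx >= 1L & idx < length(bm)
    if (!any(ok)) next
    l <- bm[idx[ok]]; r <- bm[idx[ok] + 1L]; m <- am[ok]
    v <- ifelse(r == l, 0, pmin(m - l, r - m) / (r - l))
    out <- c(out, v)
  }
  if (length(out) == 0L) {
    warning("no query midpoint had two flanking target midpoints", call. = FALSE)
  }
  out
}

#' Assemble an n x n matrix of one pairwise statistic
#'
#' Cell `(i, j)` uses set `i` as query and set `j` as target. Scalars per
#' metric: `count` = [overlap_count()]; `frac` = [overlap_fraction()]
#' (asymmetric); `jaccard` = [jaccard()] (symmetric); `fisher` =
#' `-log10(p_two_sided)` capped at 320; `reldist` = median of the
#' [reldist()] distribution (uniform-null expectation 0.25), `NA` when the
#' distribution is empty. Set sizes (merged interval counts) are recorded
#' for the marginal bar plot.
#'
#' @param sets list of [region_set()] objects, length >= 2.
#' @param metric one of `"count"`, `"frac"`, `"jaccard"`, `"fisher"`,
#'   `"reldist"`.
#' @param genome required for `metric = "fisher"`.
#' @return list of class `pairwise_matrix`: `metric`, `labels`, `values`
#'   (n x n), `symmetric`, `set_sizes`.
#' @export
pairwise_matrix <- function(sets, metric = c("count", "frac", "jaccard",
                                             "fisher", "reldist"),
                            genome = NULL) {
  metric <- match.arg(metric)
  sets <- as_region_sets(sets)
  n <- length(sets)
  if (n < 2L) stop("need at least 2 sets")
  if (metric == "fisher" && is.null(genome)) {
    stop("metric 'fisher' requires a genome (chromosome sizes) file")
  }
  labels <- set_labels(sets)
  merged <- lapply(sets, merge_regions)
  sizes <- vapply(merged, function(s) nrow(s$intervals), 0L)
  vals <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (metric == "jaccard" && j < i) { vals[i, j] <- vals[j, i]; next }
    vals[i, j] <- switch(metric,
      count   = overlap_count(merged[[i]], merged[[j]]),
      frac    = overlap_fraction(merged[[i]], merged[[j]]),
      jaccard = jaccard(merged[[i]], merged[[j]]),
      fisher  = min(320, -log10(max(
                  fisher_test_regions(merged[[i]], merged[[j]], genome)$p_two_sided,
                  1e-320))),
      reldist = {
        d <- suppressWarnings(reldist(merged[[i]], merged[[j]]))
        if (length(d) == 0L) NA_real_ else stats::median(d)
      })
  }
  structure(list(metric = metric, labels = labels, values = vals,
                 symmetric = metric %in% c("jaccard"),
                 set_sizes = stats::setNames(sizes, labels)),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("pairwise_matrix: metric '%s', %d sets\n", x$metric,
              length(x$labels)))
  print(round(x$values, 4))
  invisible(x)
}

#' Correlation structure of a pairwise matrix
#'
#' Correlates the *columns* of the matrix: with the row-as-query
#' convention, column `j` is the profile of set `j` as a target across all
#' queries, so the result measures how similarly two targets are hit by the
#' whole collection. Spearman ties are handled by average ranks.
#'
#' @param m a [pairwise_matrix()].
#' @param method `"pearson"`, `"spearman"`, or `"kendall"`.
#' @return A `pairwise_matrix` with metric `"correlation"`; zero-variance
#'   columns yield `NA` cells with a warning.
#' @export
correlate_matrix <- function(m, method = c("pearson", "spearman", "kendall")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "pairwise_matrix"))
  v <- m$values
  sds <- apply(v, 2L, stats::sd)
  cc <- suppressWarnings(stats::cor(v, method = method))
  if (any(sds == 0, na.rm = TRUE)) {
    warning(sprintf("zero-variance column(s): %s; correlations set to NA",
                    paste(m$labels[sds == 0], collapse = ", ")), call. = FALSE)
    cc[sds == 0, ] <- NA_real_
    cc[, sds == 0] <- NA_real_
  }
  diag(cc) <- 1
  structure(list(metric = "correlation", labels = m$labels, values = cc,
                 symmetric = TRUE, set_sizes = m$set_sizes),
            class = "pairwise_matrix")
}

LINKAGES <- c(single = "single", complete = "complete", average = "average",
              mcquitty = "mcquitty", ward = "ward.D", ward2 = "ward.D2",
              centroid = "centroid", median = "median")
DISTANCES <- c("euclidean", "manhattan", "maximum", "canberra")

#' Hierarchical clustering order of a pairwise matrix
#'
#' Agglomerates the row vectors of the matrix with one of eight linkage
#' methods and four distance measures, returning the deterministic leaf
#' order used to arrange heat-map rows/columns.
#'
#' @param m a [pairwise_matrix()].
#' @param linkage one of `"single"`, `"complete"`, `"average"`,
#'   `"mcquitty"`, `"ward"`, `"ward2"`, `"centroid"`, `"median"`.
#' @param distance one of `"euclidean"`, `"manhattan"`, `"maximum"`,
#'   `"canberra"`.
#' @return list of class `hier_order`: `order` (leaf labels, left to
#'   right), `hclust` (the [stats::hclust()] merge tree).
#' @export
hierarchical_order <- function(m, linkage = "average",
                               distance = "euclidean") {
  stopifnot(inherits(m, "pairwise_matrix"))
  linkage <- match.arg(linkage, names(LINKAGES))
  distance <- match.arg(distance, DISTANCES)
  if (anyNA(m$values)) {
    stop("matrix contains missing values; impute or choose another metric before clustering")
  }
  d <- stats::dist(m$values, method = distance)
  hc <- stats::hclust(d, method = LINKAGES[[linkage]])
  hc$labels <- m$labels
  structure(list(order = m$labels[hc$order], hclust = hc),
            class = "hier_order")
}

#' Write a pairwise matrix as TSV
#'
#' First cell empty, header = set labels, one labelled row per set;
#' full-precision decimals (`count` matrices print as integers); missing
#' values print as `NA`.
#'
#' @param m a [pairwise_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pairwise_matrix <- function(m, path) {
  stopifnot(inherits(m, "pairwise_matrix"))
  con <- file(path, "wb")
  rows <- vapply(seq_along(m$labels), function(i)
    paste(c(m$labels[i], format_num(m$values[i, ])), collapse = "\t"), "")
  writeLines(c(paste(c("", m$labels), collapse = "\t"), rows), con, sep = "\n")
  close(con)
  invisible(path)
}

#' Write a relative-distance distribution as TSV
#' @param d numeric vector from [reldist()].
#' @param path output file path.
#' @param labels optional length-2 character vector naming query and target.
#' @return `path`, invisibly.
#' @export
write_reldist <- function(d, path, labels = c("A", "B")) {
  con <- file(path, "wb")
  writeLines(c(sprintf("# relative distances: %s vs %s", labels[1L], labels[2L]),
               "reldist", format_num(d)), con, sep = "\n")
  close(con)
  invisible(path)
}
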
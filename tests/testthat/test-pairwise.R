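rs <- function(starts, ends, chrom = "chr1", label = "x") {
  region_set(data.frame(chrom = rep_len(chrom, length(starts)),
                        start = starts, end = ends), label = label)
}

test_that("overlap counts and fractions follow the query-set convention", {
  a <- rs(c(0, 20), c(10, 30), label = "A")
  b <- rs(5, 6, label = "B")
  expect_equal(overlap_count(a, b), 1L)
  expect_equal(overlap_count(a, a), nrow(merge_regions(a)$intervals))
  expect_equal(overlap_count(a, rs(numeric(), numeric())), 0L)
  expect_equal(overlap_fraction(a, b), 1 / 2)
  expect_equal(overlap_fraction(a, a), 1)
  expect_equal(overlap_fraction(a, rs(100, 200)), 0)
  expect_error(overlap_fraction(rs(numeric(), numeric()), a), "empty")
})

test_that("book-ended intervals do not count as overlapping", {
  expect_equal(overlap_count(rs(0, 10), rs(10, 20)), 0L)
  expect_equal(jaccard(rs(0, 10), rs(10, 20)), 0)
})

test_that("jaccard obeys its contract bounds", {
  a <- rs(0, 10, label = "A"); b <- rs(5, 15, label = "B")
  expect_equal(jaccard(a, b), 5 / 15)
  expect_equal(jaccard(a, a), 1)
  expect_equal(jaccard(a, rs(100, 200)), 0)
  expect_warning(z <- jaccard(rs(numeric(), numeric()), rs(numeric(), numeric())),
                 "empty")
  expect_equal(z, 0)
})

test_that("pairwise statistics match brute-force oracles on random fixtures", {
  for (seed in 1:30) {
    fx <- random_fixture(seed + 2000)
    a <- fx$sets[[1L]]; b <- fx$sets[[2L]]
    expect_identical(overlap_count(a, b), oracle_overlap_count(a, b),
                     label = paste("count seed", seed))
    jo <- oracle_jaccard(a, b)
    j <- jaccard(a, b)
    expect_true(abs(j - jo) <= 1e-12 * max(jo, 1),
                label = paste("jaccard seed", seed))
    na <- nrow(merge_regions(a)$intervals)
    expect_equal(overlap_fraction(a, b), oracle_overlap_count(a, b) / na)
  }
})

test_that("Fisher p-values agree with a full enumeration oracle", {
  set.seed(99)
  for (trial in 1:50) {
    n <- matrix(sample(0:60, 4, replace = TRUE), 2)
    impl <- hypergeom_pvals(n[1, 1], n[1, 2], n[2, 1], n[2, 2])
    orac <- oracle_fisher(n[1, 1], n[1, 2], n[2, 1], n[2, 2])
    expect_equal(impl$p_left, orac$p_left, tolerance = 1e-9)
    expect_equal(impl$p_right, orac$p_right, tolerance = 1e-9)
    expect_equal(impl$p_two, orac$p_two, tolerance = 1e-9)
    # exact-test identity: one-sided p values overlap by the observed mass
    d_obs <- stats::dhyper(n[1, 1], n[1, 1] + n[1, 2], n[2, 1] + n[2, 2],
                           n[1, 1] + n[2, 1])
    expect_gte(impl$p_left + impl$p_right, 1 - 1e-12)
    expect_lte(impl$p_left + impl$p_right, 1 + d_obs + 1e-12)
  }
})

test_that("the symmetric 2x2 table yields p_two_sided exactly 1", {
  expect_equal(hypergeom_pvals(1, 1, 1, 1)$p_two, 1)
})

test_that("Fisher two-sided p matches stats::fisher.test as a cross-check", {
  set.seed(7)
  for (trial in 1:10) {
    n <- matrix(sample(1:40, 4), 2)
    impl <- hypergeom_pvals(n[1, 1], n[1, 2], n[2, 1], n[2, 2])
    ft <- stats::fisher.test(n)
    expect_equal(impl$p_two, ft$p.value, tolerance = 1e-9)
  }
})

test_that("fisher_test_regions builds its table from overlap counts", {
  g <- genome(c(chr1 = 100000))
  a <- rs(seq(0, 9000, by = 1000), seq(100, 9100, by = 1000), label = "A")
  b <- rs(seq(0, 4000, by = 1000), seq(150, 4150, by = 1000), label = "B")
  fr <- fisher_test_regions(a, b, g)
  expect_equal(fr$table[1, 1], 5)
  expect_equal(fr$table[1, 2], 5)
  expect_true(fr$p_two_sided >= 0 && fr$p_two_sided <= 1)
  expect_error(fisher_test_regions(a, b, genome(c(chr2 = 1000))), "chr1")
})

test_that("relative distances are scaled to the flanking midpoint spacing", {
  a <- rs(45, 55, label = "A")               # midpoint 50
  b <- rs(c(0, 99), c(1, 101), label = "B")  # midpoints 0, 100
  expect_equal(reldist(a, b), 0.5)
  a2 <- rs(99, 101)                          # midpoint 100
  b2 <- rs(c(0, 99, 200), c(1, 101, 201))    # midpoints 0, 100, 200
  expect_equal(reldist(a2, b2), 0)
  # self comparison yields all zeros
  fx <- random_fixture(3)
  expect_true(all(reldist(fx$sets[[1L]], fx$sets[[1L]]) == 0))
})

test_that("reldist values stay in [0, 0.5] and match the uniform null", {
  # fixed 1 kb grid of target midpoints, query midpoints uniform between
  set.seed(123)
  nb <- 201L
  b <- rs(seq(0, by = 1000, length.out = nb),
          seq(2, by = 1000, length.out = nb), label = "grid")  # midpoints at 1+1000k
  n <- 5000L
  mids <- floor(runif(n, 1, 1 + 1000 * (nb - 1)))
  a <- region_set(data.frame(chrom = "chr1", start = mids, end = mids + 2))
  d <- reldist(merge_regions(a), b)
  expect_true(all(d >= 0 & d <= 0.5))
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 0.25), 3 * se)
})

test_that("pairwise matrices respect symmetry and orientation contracts", {
  fx <- random_fixture(17, n_sets = 3)
  sets <- fx$sets
  mj <- pairwise_matrix(sets, "jaccard")
  expect_true(isTRUE(all.equal(mj$values, t(mj$values))))
  expect_equal(unname(diag(mj$values)), rep(1, 3))
  mf <- pairwise_matrix(sets, "frac")
  expect_equal(unname(diag(mf$values)), rep(1, 3))
  expect_equal(mf$values[1, 2],
               overlap_fraction(sets[[1L]], sets[[2L]]))  # row = query
  expect_equal(unname(mf$set_sizes),
               vapply(sets, function(s) nrow(merge_regions(s)$intervals), 0L))
  # identical sets: all-ones jaccard matrix
  same <- lapply(1:3, function(i) { s <- fx$sets[[1L]]; s$label <- paste0("c", i); s })
  expect_true(all(pairwise_matrix(same, "jaccard")$values == 1))
  expect_error(pairwise_matrix(sets, "fisher"), "genome")
})

test_that("fisher matrix cells are -log10 two-sided p, capped and finite", {
  fx <- random_fixture(23)
  m <- pairwise_matrix(fx$sets[1:2], "fisher", genome = fx$genome)
  expect_true(all(is.finite(m$values)))
  expect_true(all(m$values >= 0 & m$values <= 320))
  fr <- fisher_test_regions(fx$sets[[1L]], fx$sets[[2L]], fx$genome)
  expect_equal(m$values[1, 2], min(320, -log10(max(fr$p_two_sided, 1e-320))))
})

test_that("matrix correlation operates on target columns with rank ties averaged", {
  v <- matrix(c(1, 2, 3, 4,
                2, 4, 6, 8,
                4, 3, 2, 1,
                1, 1, 2, 2), 4, 4)
  m <- structure(list(metric = "frac", labels = paste0("S", 1:4),
                      values = v, symmetric = FALSE,
                      set_sizes = stats::setNames(rep(1L, 4), paste0("S", 1:4))),
                 class = "pairwise_matrix")
  cm <- correlate_matrix(m, "spearman")
  # brute-force rank-then-pearson oracle
  rank_cor <- function(x, y) stats::cor(rank(x), rank(y))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(cm$values[i, j], rank_cor(v[, i], v[, j]), tolerance = 1e-12)
  }
  expect_true(isTRUE(all.equal(cm$values, t(cm$values))))
  expect_equal(unname(diag(cm$values)), rep(1, 4))
  expect_true(all(cm$values >= -1 - 1e-12 & cm$values <= 1 + 1e-12))
  # monotone transform of a column leaves its spearman row unchanged
  v2 <- v; v2[, 2] <- exp(v2[, 2])
  m2 <- m; m2$values <- v2
  expect_equal(correlate_matrix(m2, "spearman")$values, cm$values)
})

test_that("zero-variance columns correlate as NA with a warning", {
  m <- structure(list(metric = "frac", labels = c("a", "b", "c"),
                      values = cbind(c(1, 2, 3), c(5, 5, 5), c(3, 1, 2)),
                      symmetric = FALSE,
                      set_sizes = stats::setNames(rep(1L, 3), c("a", "b", "c"))),
                 class = "pairwise_matrix")
  expect_warning(cm <- correlate_matrix(m, "pearson"), "zero-variance")
  expect_true(is.na(cm$values[1, 2]))
  expect_equal(unname(diag(cm$values)), rep(1, 3))
})

test_that("hierarchical clustering places identical rows adjacent", {
  v <- rbind(c(0, 1, 1), c(0, 1, 1), c(9, 9, 9))
  m <- structure(list(metric = "jaccard", labels = c("x", "y", "z"),
                      values = v, symmetric = TRUE,
                      set_sizes = stats::setNames(rep(1L, 3), c("x", "y", "z"))),
                 class = "pairwise_matrix")
  for (lk in names(LINKAGES)) {
    ho <- hierarchical_order(m, linkage = lk)
    pos <- match(c("x", "y"), ho$order)
    expect_equal(abs(diff(pos)), 1L, label = lk)
  }
})

test_that("single linkage on equidistant collinear rows chains at the step size", {
  v <- matrix(0, 4, 4)
  v[, 1] <- c(0, 2, 4, 6)  # rows equally spaced on a line
  m <- structure(list(metric = "frac", labels = paste0("r", 1:4),
                      values = v, symmetric = FALSE,
                      set_sizes = stats::setNames(rep(1L, 4), paste0("r", 1:4))),
                 class = "pairwise_matrix")
  ho <- hierarchical_order(m, linkage = "single", distance = "euclidean")
  expect_equal(ho$hclust$height, rep(2, 3))
  # n = 2: single merge, leaf order = input order
  m2 <- structure(list(metric = "frac", labels = c("a", "b"),
                       values = matrix(c(0, 1, 1, 0), 2), symmetric = TRUE,
                       set_sizes = stats::setNames(rep(1L, 2), c("a", "b"))),
                  class = "pairwise_matrix")
  expect_equal(hierarchical_order(m2)$order, c("a", "b"))
  m2$values[1, 1] <- NA
  expect_error(hierarchical_order(m2), "missing")
})

test_that("pairwise matrix TSV round-trips at full precision", {
  fx <- random_fixture(5, n_sets = 3)
  m <- pairwise_matrix(fx$sets, "jaccard")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_pairwise_matrix(m, p)
  back <- as.matrix(read.delim(p, row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(m$values), tolerance = 1e-13)
  expect_equal(rownames(back), m$labels)
})

test_that("jaccard agrees with a GenomicRanges cross-check", {
  for (seed in c(77, 78)) {
    fx <- random_fixture(seed, n_sets = 2)
    a <- fx$sets[[1L]]; b <- fx$sets[[2L]]
    gr <- function(s) GenomicRanges::reduce(GenomicRanges::GRanges(
      s$intervals$chrom,
      IRanges::IRanges(s$intervals$start + 1, s$intervals$end)))
    ga <- gr(a); gb <- gr(b)
    inter <- sum(IRanges::width(GenomicRanges::intersect(ga, gb)))
    uni <- sum(IRanges::width(GenomicRanges::union(ga, gb)))
    expect_equal(jaccard(a, b), inter / uni, tolerance = 1e-12)
  }
})
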
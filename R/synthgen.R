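# Seeded generators for synthetic region sets, name lists and genomes.
# They emulate the structure of the bundled demo data (several peak sets
# with partial mutual overlap on a small genome): no peak-shape or GC-bias
# realism is attempted, but pairs built with derived_regions() have an
# analytically known expected Jaccard, which links the generator to the
# statistics engine in tests.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards (no global state leaks).
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a random region set on a genome
#'
#' Chromosomes are chosen with probability proportional to their length,
#' starts uniformly along the chromosome, lengths uniformly in
#' `length_range`; intervals running past the chromosome end are clipped.
#' The output is deliberately NOT merged (duplicates and overlaps are
#' allowed) so that normalization code paths are exercised. Deterministic
#' given `seed`.
#'
#' @param genome a [genome()].
#' @param n number of intervals.
#' @param length_range `c(min, max)` interval length in bases.
#' @param seed integer seed.
#' @param label set label.
#' @return A [region_set()].
#' @export
random_regions <- function(genome, n, length_range = c(100L, 1000L),
                           seed = 1L, label = "random") {
  stopifnot(inherits(genome, "genome"), length(genome) > 0L,
            length_range[1L] <= length_range[2L], length_range[1L] >= 1)
  if (length_range[1L] > min(genome)) {
    stop("minimum interval length exceeds the smallest chromosome")
  }
  with_rng(seed, {
    ch <- sample(names(genome), n, replace = TRUE, prob = as.numeric(genome))
    L <- as.numeric(genome[ch])
    start <- floor(stats::runif(n, 0, L - 1))
    len <- floor(stats::runif(n, length_range[1L], length_range[2L] + 1))
    end <- pmin(start + len, L)
    region_set(data.frame(chrom = ch, start = start, end = end,
                          stringsAsFactors = FALSE), label = label)
  })
}

#' Derive a region set from a base set by thinning and jitter
#'
#' Merges the base set, keeps each interval independently with probability
#' `p`, and shifts each kept interval by a uniform integer in
#' `[-jitter, +jitter]` (clipped to chromosome bounds when a genome is
#' given, else to non-negative coordinates). With `jitter = 0` the derived
#' set is a subset of the merged base, so for equal-length non-overlapping
#' base intervals the Jaccard statistic between base and derived is exactly
#' `K / N` (`K` kept intervals out of `N`), with binomial expectation `p` —
#' the closed form used by the parameter-recovery tests.
#'
#' @param base a [region_set()].
#' @param p retention probability in `[0, 1]`.
#' @param jitter maximum absolute shift in bases.
#' @param seed integer seed.
#' @param genome optional [genome()] for bounds clipping.
#' @param label set label.
#' @return A [region_set()].
#' @export
derived_regions <- function(base, p, jitter = 0L, seed = 1L, genome = NULL,
                            label = paste0(base$label, "_derived")) {
  stopifnot(p >= 0, p <= 1, jitter >= 0)
  m <- merge_regions(base)$intervals
  with_rng(seed, {
    keep <- stats::runif(nrow(m)) < p
    m <- m[keep, , drop = FALSE]
    if (nrow(m) > 0L && jitter > 0) {
      shift <- floor(stats::runif(nrow(m), -jitter, jitter + 1))
      m$start <- m$start + shift
      m$end <- m$end + shift
      lo <- pmax(0, -m$start)
      m$start <- m$start + lo; m$end <- m$end + lo
      if (!is.null(genome)) {
        hi <- pmax(0, m$end - as.numeric(genome[m$chrom]))
        m$start <- m$start - hi; m$end <- m$end - hi
        m$start <- pmax(0, m$start)
      }
    }
    rownames(m) <- NULL
    region_set(m, label = label)
  })
}

#' Generate random name lists over a shared synthetic universe
#'
#' Each set is an independent sample without replacement of `set_size`
#' names from a universe of `universe_size` synthetic gene identifiers;
#' under this independence the expected pairwise intersection is
#' `set_size^2 / universe_size` (hypergeometric mean).
#'
#' @param n_sets number of sets.
#' @param universe_size universe size.
#' @param set_size names per set (`<= universe_size`).
#' @param seed integer seed.
#' @param labels optional labels (default `set1..setk`).
#' @return list of [name_set()] objects.
#' @export
random_name_lists <- function(n_sets, universe_size, set_size, seed = 1L,
                              labels = paste0("set", seq_len(n_sets))) {
  stopifnot(set_size <= universe_size, n_sets >= 1L)
  universe <- sprintf("gene%05d", seq_len(universe_size))
  with_rng(seed, {
    lapply(seq_len(n_sets), function(i)
      name_set(sample(universe, set_size), label = labels[i]))
  })
}

#' Generate the bundled demo fixture family
#'
#' Builds a small genome (two chromosomes, 300 kb total) and six region
#' sets with partial mutual overlap: a shared backbone of peaks thinned and
#' jittered differently per set, plus set-specific random peaks. The first
#' three sets stand in for histone-mark peak sets (Venn demo), the first
#' four for the UpSet demo, and all six for the pairwise heat-map demo.
#' Deterministic given `seed`.
#'
#' @param seed integer seed.
#' @return list with `genome` and `sets` (list of six [region_set()]).
#' @export
demo_fixture <- function(seed = 20170531L) {
  g <- genome(c(chr1 = 200000, chr2 = 100000))
  labels <- c("H3K27ac", "H3K4me3", "H3K27me3", "H3K4me2",
              "cellA_SE", "cellB_SE")
  backbone <- random_regions(g, n = 260L, length_range = c(150L, 900L),
                             seed = seed, label = "backbone")
  ps <- c(0.75, 0.65, 0.35, 0.6, 0.55, 0.5)
  jit <- c(40L, 60L, 120L, 60L, 200L, 250L)
  sets <- vector("list", 6L)
  for (i in seq_len(6L)) {
    shared <- derived_regions(backbone, p = ps[i], jitter = jit[i],
                              seed = seed + i, genome = g, label = labels[i])
    private <- random_regions(g, n = 40L + 15L * i,
                              length_range = c(150L, 700L),
                              seed = seed + 100L + i, label = labels[i])
    sets[[i]] <- region_set(rbind(shared$intervals, private$intervals),
                            label = labels[i])
  }
  list(genome = g, sets = sets)
}
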
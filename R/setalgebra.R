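# Multi-way decomposition of region sets into the 2^n - 1 exclusive
# membership categories that Venn and UpSet plots display. The engine is a
# per-chromosome sweep line over all merged-interval endpoints: between two
# consecutive endpoints membership in every set is constant, so the union of
# the inputs decomposes exactly into maximal constant-membership fragments.

MAX_SETS <- 16L  # bitmask width cap for combination decomposition

as_region_sets <- function(sets) {
  stopifnot(is.list(sets), all(vapply(sets, inherits, TRUE, "region_set")))
  sets
}

set_labels <- function(sets) {
  dedupe_labels(vapply(sets, function(s) s$label, ""))
}

#' Decompose region sets into membership fragments
#'
#' Sweeps over all interval endpoints per chromosome and emits the maximal
#' genomic fragments over which membership in every input set is constant.
#' The fragments are pairwise disjoint, sorted, and cover exactly the union
#' of the inputs; bases covered by no set are omitted. Bit `i` (value
#' `2^(i-1)`) of the `mask` column is set when the fragment lies inside set
#' `i` (input order).
#'
#' @param sets list of [region_set()] objects (merged internally), length
#'   2..16.
#' @return data frame with columns `chrom`, `start`, `end`, `mask`, plus a
#'   `"labels"` attribute with the (deduplicated) set labels.
#' @export
atomize <- function(sets) {
  sets <- as_region_sets(sets)
  n <- length(sets)
  if (n < 2L) stop("need at least 2 sets to decompose")
  if (n > MAX_SETS) stop(sprintf("at most %d sets supported", MAX_SETS))
  labels <- set_labels(sets)
  merged <- lapply(sets, function(s) merge_regions(s)$intervals)
  chroms <- sort(unique(unlist(lapply(merged, function(m) m$chrom))))
  pieces <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    per <- lapply(merged, function(m) m[m$chrom == ch, , drop = FALSE])
    bp <- sort(unique(unlist(lapply(per, function(m) c(m$start, m$end)))))
    if (length(bp) < 2L) next
    seg_start <- bp[-length(bp)]
    seg_end <- bp[-1L]
    mask <- numeric(length(seg_start))
    for (i in seq_len(n)) {
      m <- per[[i]]
      if (nrow(m) == 0L) next
      idx <- findInterval(seg_start, m$start)
      inside <- idx > 0L & seg_start < m$end[pmax(idx, 1L)]
      mask <- mask + inside * 2^(i - 1)
    }
    keep <- mask > 0
    if (!any(keep)) next
    ss <- seg_start[keep]; se <- seg_end[keep]; mk <- mask[keep]
    # collapse adjacent same-mask segments into maximal runs; segments
    # separated by an uncovered gap never join
    newrun <- c(TRUE, mk[-1L] != mk[-length(mk)] | ss[-1L] != se[-length(se)])
    run <- cumsum(newrun)
    first <- !duplicated(run)
    last <- c(first[-1L], TRUE)
    pieces[[ci]] <- data.frame(
      chrom = ch, start = ss[first], end = se[last], mask = mk[first],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), mask = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "labels") <- labels
  out
}

new_combination_table <- function(labels, mode, counts) {
  stopifnot(mode %in% c("region", "basepair", "list"))
  counts <- counts[counts > 0]
  counts <- counts[order(as.numeric(names(counts)))]
  structure(list(labels = labels, mode = mode, counts = counts),
            class = "combination_table")
}

#' @export
print.combination_table <- function(x, ...) {
  cat(sprintf("combination_table (%s mode): %d sets [%s], %d non-empty categories\n",
              x$mode, length(x$labels), paste(x$labels, collapse = ", "),
              length(x$counts)))
  invisible(x)
}

#' Human-readable combination string for a membership bitmask
#'
#' Labels of member sets joined by `"&"` in input order, e.g.
#' `"H3K27ac&H3K4me3"`.
#'
#' @param mask integer bitmask(s), bit `i` = membership of set `i`.
#' @param labels character vector of set labels.
#' @return character vector.
#' @export
mask_label <- function(mask, labels) {
  vapply(mask, function(m) {
    member <- bitwAnd(as.integer(m), bitwShiftL(1L, seq_along(labels) - 1L)) != 0L
    paste(labels[member], collapse = "&")
  }, "")
}

mask_degree <- function(mask) {
  vapply(mask, function(m) sum(bitwAnd(as.integer(m),
         bitwShiftL(1L, 0:(MAX_SETS - 1L))) != 0L), 0L)
}

#' Combination counts over the 2^n - 1 membership categories of region sets
#'
#' Counts are defined on the atomized fragment space: in `basepair` mode a
#' category's count is the number of bases whose membership pattern equals
#' that category; in `region` mode it is the number of maximal
#' constant-membership fragments with that pattern. Both definitions are
#' symmetric in the inputs and have an unambiguous per-base oracle (see the
#' package vignette for why fragment counting is used rather than counting
#' relative to a designated reference set).
#'
#' @param sets list of [region_set()] objects.
#' @param mode `"region"` or `"basepair"`.
#' @return A `combination_table`.
#' @export
combination_counts <- function(sets, mode = c("region", "basepair")) {
  mode <- match.arg(mode)
  fr <- atomize(sets)
  labels <- attr(fr, "labels")
  if (nrow(fr) == 0L) {
    return(new_combination_table(labels, mode, stats::setNames(numeric(), character())))
  }
  counts <- if (mode == "basepair") {
    tapply(fr$end - fr$start, fr$mask, sum)
  } else {
    tapply(rep(1, nrow(fr)), fr$mask, sum)
  }
  new_combination_table(labels, mode,
                        stats::setNames(as.numeric(counts), names(counts)))
}

#' Combination counts for name lists
#'
#' Each name in the union of the inputs is assigned its exact membership
#' bitmask; counts are the sizes of the resulting exclusive categories.
#'
#' @param sets list of [name_set()] objects, length >= 2.
#' @return A `combination_table` (mode `"list"`) with a `"members"`
#'   attribute mapping each union element to its mask.
#' @export
list_combination_counts <- function(sets) {
  stopifnot(is.list(sets), all(vapply(sets, inherits, TRUE, "name_set")))
  n <- length(sets)
  if (n < 2L) stop("need at least 2 sets to decompose")
  if (n > MAX_SETS) stop(sprintf("at most %d sets supported", MAX_SETS))
  labels <- dedupe_labels(vapply(sets, function(s) s$label, ""))
  universe <- sort(unique(unlist(lapply(sets, function(s) s$names))),
                   method = "radix")
  mask <- numeric(length(universe))
  for (i in seq_len(n)) {
    mask <- mask + (universe %in% sets[[i]]$names) * 2^(i - 1)
  }
  counts <- tapply(rep(1, length(universe)), mask, sum)
  tab <- new_combination_table(labels, "list",
                               stats::setNames(as.numeric(counts), names(counts)))
  attr(tab, "members") <- data.frame(element = universe, mask = mask,
                                     stringsAsFactors = FALSE)
  tab
}

# Expand a sparse counts vector to all 2^n - 1 masks (zeros included).
full_counts <- function(tab) {
  n <- length(tab$labels)
  all_masks <- seq_len(2^n - 1)
  out <- stats::setNames(numeric(length(all_masks)), as.character(all_masks))
  out[names(tab$counts)] <- tab$counts
  out
}

# Deterministic ordering used by all count-sorted outputs: descending
# count, then ascending degree, then C-locale lexicographic combination
# string.
combination_order <- function(counts, labels) {
  mask <- as.numeric(names(counts))
  combo <- mask_label(mask, labels)
  order(-counts, mask_degree(mask), combo, method = "radix")
}

#' Write the text outputs describing a combination decomposition
#'
#' Writes three plain-text files compatible with interactive downstream
#' exploration:
#' \describe{
#'   \item{combinations TSV}{columns `combination` (labels joined by
#'     `"&"`), `degree`, `count`; sorted by descending count, ties broken by
#'     ascending degree then lexicographic string. Empty categories are
#'     omitted unless `show_empty = TRUE`.}
#'   \item{binary membership matrix}{first column `element` (a name, or a
#'     fragment `chrom:start-end`), then one 0/1 column per set.}
#'   \item{sets CSV}{one column per set listing its elements downward,
#'     short columns padded with empty fields.}
#' }
#'
#' @param tab a `combination_table`.
#' @param elements optional data frame `element`/`mask` (defaults to the
#'   `"members"` attribute for list tables; pass the [atomize()] output,
#'   reformatted, for region tables — see [fragment_elements()]).
#' @param outdir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param show_empty also list zero-count categories in the TSV.
#' @return Named character vector of file paths.
#' @export
write_combination_outputs <- function(tab, elements = NULL, outdir = ".",
                                      prefix = "combinations",
                                      show_empty = FALSE) {
  stopifnot(inherits(tab, "combination_table"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (is.null(elements)) elements <- attr(tab, "members")

  counts <- if (show_empty && length(tab$labels) <= 10L) full_counts(tab)
            else tab$counts
  ord <- combination_order(counts, tab$labels)
  mask <- as.numeric(names(counts))[ord]
  tsv <- file.path(outdir, paste0(prefix, ".tsv"))
  con <- file(tsv, "wb")  # binary mode: Unix line endings everywhere
  writeLines(c("combination\tdegree\tcount",
               sprintf("%s\t%d\t%s", mask_label(mask, tab$labels),
                       mask_degree(mask),
                       format_num(counts[ord]))), con, sep = "\n")
  close(con)
  paths <- c(combinations = tsv)

  if (!is.null(elements)) {
    bm <- file.path(outdir, paste0(prefix, "_membership.tsv"))
    bits <- vapply(seq_along(tab$labels), function(i)
      as.integer(bitwAnd(as.integer(elements$mask), bitwShiftL(1L, i - 1L)) != 0L),
      integer(nrow(elements)))
    if (nrow(elements) == 1L) bits <- matrix(bits, nrow = 1L)
    con <- file(bm, "wb")
    writeLines(c(paste(c("element", tab$labels), collapse = "\t"),
                 paste(elements$element,
                       apply(bits, 1L, paste, collapse = "\t"),
                       sep = "\t")), con, sep = "\n")
    close(con)
    paths["membership"] <- bm

    sets_csv <- file.path(outdir, paste0(prefix, "_sets.csv"))
    cols <- lapply(seq_along(tab$labels), function(i)
      elements$element[bitwAnd(as.integer(elements$mask),
                               bitwShiftL(1L, i - 1L)) != 0L])
    depth <- max(c(1L, lengths(cols)))
    padded <- vapply(cols, function(x) c(x, rep("", depth - length(x))),
                     character(depth))
    if (depth == 1L) padded <- matrix(padded, nrow = 1L)
    con <- file(sets_csv, "wb")
    writeLines(c(paste(tab$labels, collapse = ","),
                 apply(padded, 1L, paste, collapse = ",")), con, sep = "\n")
    close(con)
    paths["sets"] <- sets_csv
  }
  paths
}

#' Element listing ("chrom:start-end" per fragment) for region tables
#'
#' @param fragments output of [atomize()].
#' @return data frame `element`/`mask`, suitable for
#'   [write_combination_outputs()].
#' @export
fragment_elements <- function(fragments) {
  data.frame(
    element = sprintf("%s:%d-%d", fragments$chrom,
                      as.integer(fragments$start), as.integer(fragments$end)),
    mask = fragments$mask,
    stringsAsFactors = FALSE
  )
}

# Full-precision, locale-independent number formatting for text outputs:
# integers print without decimals, reals with up to 15 significant digits.
format_num <- function(x) {
  out <- character(length(x))
  na <- is.na(x)
  int <- !na & x == floor(x) & abs(x) < 1e15
  out[na] <- "NA"
  out[int] <- sprintf("%.0f", x[int])
  rest <- !na & !int
  out[rest] <- formatC(x[rest], digits = 15, format = "g")
  out
}
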
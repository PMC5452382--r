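# Internal coordinate convention: every interval is stored 0-based
# half-open [start, end), the BED convention. GFF/GTF (1-based closed) and
# VCF (1-based POS) are converted at parse time so that all downstream
# arithmetic uses a single convention.

EMPTY_INTERVALS <- data.frame(
  chrom = character(), start = numeric(), end = numeric(),
  name = character(), strand = character(),
  stringsAsFactors = FALSE
)

#' Construct a region set
#'
#' A region set is a labelled collection of genomic intervals in 0-based
#' half-open coordinates. Zero- or negative-length intervals are rejected.
#'
#' @param intervals data frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `strand`.
#' @param label set label (used in figures and text outputs).
#' @param merged logical; `TRUE` asserts that the intervals are already
#'   sorted and non-overlapping with no book-ended pairs.
#' @return An object of class `region_set`.
#' @export
region_set <- function(intervals, label = "set", merged = FALSE) {
  stopifnot(is.data.frame(intervals))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(intervals))) {
    stop("intervals must have columns chrom, start, end")
  }
  iv <- data.frame(
    chrom  = as.character(intervals$chrom),
    start  = as.numeric(intervals$start),
    end    = as.numeric(intervals$end),
    name   = if ("name" %in% names(intervals))
               as.character(intervals$name) else rep(NA_character_, nrow(intervals)),
    strand = if ("strand" %in% names(intervals))
               as.character(intervals$strand) else rep(".", nrow(intervals)),
    stringsAsFactors = FALSE
  )
  if (nrow(iv) > 0L) {
    if (any(!is.finite(iv$start)) || any(!is.finite(iv$end))) {
      stop("non-numeric interval coordinates")
    }
    if (any(iv$start < 0)) stop("negative start coordinate")
    if (any(iv$end <= iv$start)) {
      stop("zero- or negative-length interval; filter before construction")
    }
    iv$strand[!(iv$strand %in% c("+", "-", "."))] <- "."
  }
  structure(
    list(label = as.character(label)[1L], intervals = iv,
         is_merged = isTRUE(merged)),
    class = "region_set"
  )
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set '%s': %d intervals on %d chromosome(s)%s\n",
              x$label, nrow(x$intervals),
              length(unique(x$intervals$chrom)),
              if (x$is_merged) " (merged)" else ""))
  invisible(x)
}

#' @export
length.region_set <- function(x) nrow(x$intervals)

#' Construct a name set
#'
#' @param names character vector; duplicates are removed, comparison is
#'   case-sensitive.
#' @param label set label.
#' @return An object of class `name_set`.
#' @export
name_set <- function(names, label = "set") {
  nm <- unique(as.character(names))
  nm <- nm[!is.na(nm) & nzchar(nm)]
  structure(list(label = as.character(label)[1L], names = nm),
            class = "name_set")
}

#' @export
print.name_set <- function(x, ...) {
  cat(sprintf("name_set '%s': %d unique names\n", x$label, length(x$names)))
  invisible(x)
}

#' @export
length.name_set <- function(x) length(x$names)

default_label <- function(path) tools::file_path_sans_ext(basename(path))

# Shared finish step for the three region parsers: drop non-positive-length
# records with a counted warning (real-world BED exports contain them) and
# attach the parse report.
finish_parse <- function(df, label, path, n_comment = 0L) {
  bad <- df$end <= df$start
  n_skipped <- sum(bad)
  if (n_skipped > 0L) {
    warning(sprintf("%s: skipped %d zero- or negative-length record(s)",
                    basename(path), n_skipped), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  rs <- region_set(df, label = label)
  attr(rs, "parse_report") <- list(
    path = path, n_records = nrow(df), n_skipped = n_skipped,
    n_comment = n_comment
  )
  rs
}

coord_or_stop <- function(x, path, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v))
  if (length(bad) > 0L) {
    stop(sprintf("%s, line %d: unparsable %s field '%s'",
                 path, lineno[bad[1L]], what, x[bad[1L]]), call. = FALSE)
  }
  v
}

#' Read a BED file
#'
#' BED is tab-separated with at least three columns and 0-based half-open
#' coordinates; `track`, `browser` and `#` lines are skipped. Records with
#' `start >= end` are skipped with a counted warning (see the parse report
#' in `attr(x, "parse_report")`).
#'
#' @param path file path.
#' @param label set label; defaults to the file basename without extension.
#' @return A [region_set()].
#' @export
read_bed <- function(path, label = default_label(path)) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  body <- lines[keep]
  if (length(body) == 0L) {
    warning(sprintf("%s: no records", basename(path)), call. = FALSE)
    return(finish_parse(EMPTY_INTERVALS, label, path,
                        n_comment = sum(!keep)))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  ncol <- lengths(f)
  if (any(ncol < 3L)) {
    stop(sprintf("%s, line %d: fewer than 3 tab-separated columns",
                 path, lineno[which(ncol < 3L)[1L]]), call. = FALSE)
  }
  df <- data.frame(
    chrom  = vapply(f, `[`, "", 1L),
    start  = coord_or_stop(vapply(f, `[`, "", 2L), path, lineno, "start"),
    end    = coord_or_stop(vapply(f, `[`, "", 3L), path, lineno, "end"),
    name   = ifelse(ncol >= 4L, vapply(f, function(z) z[4L], ""), NA_character_),
    strand = ifelse(ncol >= 6L, vapply(f, function(z) z[min(6L, length(z))], ""), "."),
    stringsAsFactors = FALSE
  )
  finish_parse(df, label, path, n_comment = sum(!keep))
}

#' Read a GFF/GTF file
#'
#' GFF coordinates are 1-based closed `[s, e]`; they are converted to the
#' internal 0-based half-open `[s - 1, e)` so that a GFF feature and the BED
#' line `(s - 1, e)` parse to identical intervals. Strand is taken from
#' column 7, the feature type (column 3) becomes the interval name.
#'
#' @inheritParams read_bed
#' @return A [region_set()].
#' @export
read_gff <- function(path, label = default_label(path)) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  body <- lines[keep]
  if (length(body) == 0L) {
    warning(sprintf("%s: no records", basename(path)), call. = FALSE)
    return(finish_parse(EMPTY_INTERVALS, label, path, n_comment = sum(!keep)))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  ncol <- lengths(f)
  if (any(ncol < 8L)) {
    stop(sprintf("%s, line %d: fewer than 8 tab-separated columns",
                 path, lineno[which(ncol < 8L)[1L]]), call. = FALSE)
  }
  s1 <- coord_or_stop(vapply(f, `[`, "", 4L), path, lineno, "start")
  e1 <- coord_or_stop(vapply(f, `[`, "", 5L), path, lineno, "end")
  df <- data.frame(
    chrom  = vapply(f, `[`, "", 1L),
    start  = s1 - 1,           # 1-based closed -> 0-based half-open
    end    = e1,
    name   = vapply(f, `[`, "", 3L),
    strand = vapply(f, `[`, "", 7L),
    stringsAsFactors = FALSE
  )
  finish_parse(df, label, path, n_comment = sum(!keep))
}

#' Read a VCF file
#'
#' Only CHROM, POS, ID and REF are consumed: each record becomes the
#' interval `[POS - 1, POS - 1 + nchar(REF))` covering its reference
#' allele. Genotype and INFO fields are ignored.
#'
#' @inheritParams read_bed
#' @return A [region_set()].
#' @export
read_vcf <- function(path, label = default_label(path)) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  body <- lines[keep]
  if (length(body) == 0L) {
    warning(sprintf("%s: no variant records", basename(path)), call. = FALSE)
    return(finish_parse(EMPTY_INTERVALS, label, path, n_comment = sum(!keep)))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  ncol <- lengths(f)
  if (any(ncol < 4L)) {
    stop(sprintf("%s, line %d: fewer than 4 tab-separated columns",
                 path, lineno[which(ncol < 4L)[1L]]), call. = FALSE)
  }
  pos <- coord_or_stop(vapply(f, `[`, "", 2L), path, lineno, "POS")
  ref <- vapply(f, `[`, "", 4L)
  df <- data.frame(
    chrom  = vapply(f, `[`, "", 1L),
    start  = pos - 1,
    end    = pos - 1 + nchar(ref),
    name   = vapply(f, `[`, "", 3L),
    strand = ".",
    stringsAsFactors = FALSE
  )
  finish_parse(df, label, path, n_comment = sum(!keep))
}

#' Read a plain-text name list
#'
#' One name per line; blank lines are ignored and surrounding whitespace is
#' stripped; duplicates are removed.
#'
#' @inheritParams read_bed
#' @return A [name_set()].
#' @export
read_list <- function(path, label = default_label(path)) {
  nm <- trimws(readLines(path, warn = FALSE))
  nm <- nm[nzchar(nm)]
  if (length(nm) == 0L) {
    warning(sprintf("%s: empty name list", basename(path)), call. = FALSE)
  }
  name_set(nm, label = label)
}

#' Read a genome (chromosome sizes) file
#'
#' Two tab-separated columns: chromosome name and length in bases. The
#' genome defines the background space for Fisher's exact test and the
#' bounds for the synthetic region generator.
#'
#' @param path file path.
#' @return A named numeric vector of class `genome` (names = chromosomes).
#' @export
read_genome <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^#", lines)
  body <- lines[keep]
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) < 2L)) {
    stop(sprintf("%s, line %d: expected 'chrom<TAB>length'",
                 path, which(keep)[which(lengths(f) < 2L)[1L]]), call. = FALSE)
  }
  nm <- vapply(f, `[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2L)))
  bad <- which(is.na(len) | len <= 0 | len != floor(len))
  if (length(bad) > 0L) {
    stop(sprintf("%s, line %d: chromosome length must be a positive integer",
                 path, which(keep)[bad[1L]]), call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop(sprintf("%s: duplicate chromosome name '%s'",
                 path, nm[duplicated(nm)][1L]), call. = FALSE)
  }
  genome(stats::setNames(len, nm))
}

#' Construct a genome from a named vector of chromosome lengths
#' @param sizes named numeric vector, chromosome name -> length in bases.
#' @return A named numeric vector of class `genome`.
#' @export
genome <- function(sizes) {
  stopifnot(!is.null(names(sizes)), all(sizes > 0),
            !anyDuplicated(names(sizes)))
  structure(as.numeric(stats::setNames(as.numeric(sizes), names(sizes))),
            names = names(sizes), class = "genome")
}

#' Merge a region set to sorted non-overlapping form
#'
#' Sorts intervals and unions every overlapping or book-ended pair
#' (bedtools-merge default semantics: intervals at distance 0 are joined).
#' Idempotent. Interval names and strands are dropped; strand is never used
#' by the intersection statistics.
#'
#' @param rs a [region_set()].
#' @return A merged `region_set` with `is_merged = TRUE`.
#' @export
merge_regions <- function(rs) {
  stopifnot(inherits(rs, "region_set"))
  if (rs$is_merged) return(rs)
  iv <- rs$intervals
  if (nrow(iv) <= 1L) {
    out <- region_set(iv[c("chrom", "start", "end")], rs$label, merged = TRUE)
    return(out)
  }
  ord <- order(iv$chrom, iv$start, iv$end, method = "radix")
  iv <- iv[ord, , drop = FALSE]
  new_chrom <- c(TRUE, iv$chrom[-1L] != iv$chrom[-nrow(iv)])
  # running max end within chromosome; a new merged block starts when the
  # interval begins strictly after everything seen so far (book-ends join)
  run_end <- iv$end
  grp <- numeric(nrow(iv))
  g <- 0; cur_end <- -Inf
  for (i in seq_len(nrow(iv))) {
    if (new_chrom[i] || iv$start[i] > cur_end) {
      g <- g + 1; cur_end <- iv$end[i]
    } else {
      cur_end <- max(cur_end, iv$end[i])
    }
    grp[i] <- g
    run_end[i] <- cur_end
  }
  first <- !duplicated(grp)
  last <- c(first[-1L], TRUE)
  merged <- data.frame(
    chrom = iv$chrom[first],
    start = iv$start[first],
    end   = run_end[last],
    stringsAsFactors = FALSE
  )
  rownames(merged) <- NULL
  region_set(merged, rs$label, merged = TRUE)
}

#' @export
merge.region_set <- function(x, y, ...) merge_regions(x)

#' Total bases covered by a region set
#'
#' Merges internally, then sums interval lengths, so overlapping input
#' intervals are not double-counted.
#'
#' @param rs a [region_set()].
#' @return total covered bases (numeric scalar).
#' @export
total_bases <- function(rs) {
  m <- merge_regions(rs)$intervals
  sum(m$end - m$start)
}

#' Write a region set as BED3 (or BED6 when names/strands are present)
#'
#' @param rs a [region_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(rs, path) {
  iv <- rs$intervals
  has_meta <- any(!is.na(iv$name)) || any(iv$strand != ".")
  lines <- if (nrow(iv) == 0L) character() else if (has_meta) {
    sprintf("%s\t%d\t%d\t%s\t0\t%s", iv$chrom, as.integer(iv$start),
            as.integer(iv$end), ifelse(is.na(iv$name), ".", iv$name),
            iv$strand)
  } else {
    sprintf("%s\t%d\t%d", iv$chrom, as.integer(iv$start), as.integer(iv$end))
  }
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Write a genome file ("chrom<TAB>length")
#' @param g a [genome()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(g, path) {
  writeLines(sprintf("%s\t%d", names(g), as.integer(g)), path)
  invisible(path)
}

# Unique labels for a list of sets: duplicates get numeric suffixes.
dedupe_labels <- function(labels) {
  out <- labels
  dup <- duplicated(labels) | duplicated(labels, fromLast = TRUE)
  if (any(dup)) {
    for (lb in unique(labels[dup])) {
      idx <- which(labels == lb)
      out[idx] <- paste0(lb, "_", seq_along(idx))
    }
  }
  out
}
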
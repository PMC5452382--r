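---
title: "Methods: multi-set interval intersection statistics and their visualization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-set interval intersection statistics and their visualization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overlapviz)
```

## The problem

Sequencing assays routinely produce *region sets* — collections of genomic
intervals such as ChIP-seq peaks, open-chromatin regions, or variant
positions — and *name lists* such as differentially expressed genes. The
recurring analysis question is the same in both cases: how do two or more
such sets intersect? overlapviz answers it at three scales:

* **Venn diagrams** (2–6 sets): every one of the $2^n - 1$ exclusive
  membership categories with its count;
* **UpSet plots** ($n \ge 2$): the same decomposition as a ranked bar/dot
  matrix, which stays readable when Venn diagrams do not;
* **pairwise heat maps** (any $n$): one scalar statistic per ordered pair
  of sets, optionally correlated and hierarchically clustered.

All three views are computed by one native interval engine and written both
as figures (PDF/SVG/PNG/TIFF) and as plain-text matrices for downstream
interactive exploration.

## Data model and coordinate conventions

Internally every interval is 0-based half-open `[start, end)`, the BED
convention. GFF/GTF (1-based closed) and VCF (1-based `POS`, span =
reference allele length) are converted at parse time, so a GFF feature
`[s, e]` and the BED line `(s-1, e)` are the same interval. One convention
for all arithmetic removes a whole class of off-by-one errors.

Parsing is deliberately forgiving about one malady that real exports
contain: zero- or negative-length records are skipped and counted in a
parse report rather than aborting the run. Truly unparsable coordinates are
an error naming file and line. Strand is parsed and preserved but ignored
by every intersection statistic; overlap here is purely positional, and
this is a documented limitation.

Before any statistic is computed a set is **merged**: sorted, with every
overlapping *or book-ended* pair unioned (distance-0 intervals join,
matching the de-facto default of the standard interval toolkits). Merging
is idempotent and preserves covered bases — both properties are tested on
random inputs.

## The sweep-line decomposition

The combinatorial core is `atomize()`. Per chromosome, the sorted union of
all merged-interval endpoints cuts the axis into elementary segments on
which membership in every set is constant. Each segment gets a bitmask
(bit $i$ set ⇔ inside set $i$), uncovered segments are dropped, and
adjacent same-mask segments are fused into **maximal constant-membership
fragments**. The fragments are disjoint, sorted, and cover exactly the
union of the inputs, which yields two conservation identities used as
permanent tests: base-pair category counts sum to the union's covered
bases, and list-mode counts sum to the union's cardinality.

Counting those fragments raises a definitional question that "number of
overlapping peaks" glosses over: when one peak in set A spans two peaks in
set B, peak-wise category counts depend on which set is treated as the
reference. This package defines **region-mode counts on the fragment
space** — each maximal constant-membership block counts once. The
definition is symmetric in the inputs, invariant under input order (bits
permute, counts do not), and has an unambiguous per-base brute-force
oracle, against which the sweep line is checked exactly on hundreds of
seeded random fixtures. The price is a deliberate divergence from any
reference-set convention: a category count here is "contiguous blocks with
exactly this membership", not "peaks of set X". Base-pair mode
(`mode = "basepair"`) sidesteps the ambiguity entirely and is what the
Jaccard statistic uses.

Bitmask width caps the decomposition at 16 sets; Venn rendering is capped
at 6 by the geometry itself.

## Pairwise statistics

With rows as the *query* set and columns as the *target*:

* **count** — merged query intervals overlapping ≥ 1 merged target
  interval by ≥ 1 base (book-ends do not overlap).
* **frac** — count divided by the number of merged query intervals;
  asymmetric by construction.
* **jaccard** — intersection bases / union bases of the merged sets, in
  $[0,1]$, 1 iff the merged sets are identical, 0 iff no base is shared.
  Two empty sets are reported as 0 with a warning rather than NaN.
* **fisher** — Fisher's exact test on a 2×2 table built from interval
  overlap against a genome background (below); the heat-map cell is
  $-\log_{10} p_{two}$ capped at 320 to stay finite in text outputs.
* **reldist** — the relative-distance distribution: for each query
  midpoint $m$ with flanking target midpoints $l \le m \le r$, the value
  $\min(m-l, r-m)/(r-l) \in [0, 0.5]$. Under a uniform null the
  distribution is flat with mean 0.25; spatial attraction shifts mass
  toward 0. The heat-map scalar is the distribution **median** (null
  expectation 0.25); the full distribution can be written as TSV.
  Midpoints are $\lfloor (start+end)/2 \rfloor$; query midpoints without
  two flanks are skipped, and duplicate flanks score 0 by convention.

### The Fisher contingency table

The test itself is exact; the table construction is a declared heuristic,
since interval data do not come with natural "trials". After merging both
sets:

$$n_{11} = \mathrm{count}(A \to B), \quad n_{12} = |A| - n_{11}, \quad
  n_{21} = |B| - \mathrm{count}(B \to A),$$
$$n_{22} = \max(0,\; S - n_{11} - n_{12} - n_{21}), \qquad
  S = \left\lfloor \frac{2G}{\bar\ell_A + \bar\ell_B} \right\rfloor,$$

where $G$ is total genome length and $\bar\ell$ the mean merged interval
length. $S$ approximates the number of interval-sized slots the genome
offers, mirroring the genome-slot heuristic of the classic interval
toolkits. On that table the hypergeometric left, right, and two-sided
p-values are computed exactly (two-sided = total probability of all tables
at fixed margins no more probable than the observed one, with a $10^{-7}$
relative slack so numerically tied masses count as tied — the same tie
rule the standard implementations use; when every table qualifies the
p-value is exactly 1). The reported odds ratio is the sample odds ratio
$n_{11}n_{22}/(n_{12}n_{21})$, `Inf` when an off-diagonal cell is empty.
The p-values are validated against a log-factorial full-enumeration oracle
to $10^{-9}$ and cross-checked against `stats::fisher.test`. No
multiple-testing correction is applied across the $n(n-1)/2$ pairs; the
heat map is exploratory, not a calibrated screen.

### Correlation and clustering

`correlate_matrix()` correlates the **columns** of a pairwise matrix
(Pearson, Spearman with average ranks, or Kendall via `stats::cor`). With
the row-as-query convention, column $j$ is the profile of set $j$ as a
target across all queries, so the correlation asks "how similarly are two
targets hit by the whole collection" — the natural input for clustering
data sets. Zero-variance columns produce NA cells with a warning; the
diagonal is fixed at 1.

`hierarchical_order()` exposes eight linkages (`single`, `complete`,
`average`, `mcquitty`, `ward`, `ward2`, `centroid`, `median`; the two Ward
variants map to `hclust`'s `ward.D` and `ward.D2`) over four distances
(`euclidean`, `manhattan`, `maximum`, `canberra`) on the matrix rows, via
`stats::dist` + `stats::hclust`. Leaf order is deterministic, with ties
resolved by input order. Matrices containing NA are rejected with a
pointer to impute or change metric rather than silently dropping rows.

## Figures

Figures are assembled into a device-independent display list and rendered
by two backends: base graphics onto the `pdf()`/`png()`/`tiff()` devices,
and a purpose-built SVG serializer. The serializer exists because
cairo-based SVG devices outline text into glyph paths; writing the SVG
directly keeps every label a literal `<text>` node (searchable,
post-editable in vector editors) and, with fixed-precision coordinates and
no randomness anywhere in layout, makes repeated renders byte-identical —
which the test suite asserts.

**Venn geometry.** 2–3 sets use circles, 4–5 the standard congruent
ellipse arrangements, 6 the published six-triangle Venn layout — all
shipped as fixed template coordinates; area-proportional (Euler) geometry
is out of scope. Category label anchors are *not* hand-placed: each
template is rasterized once on a 441×441 grid, and each of the $2^n - 1$
constant-membership regions receives the centroid (median point, with an
in-region fallback for non-convex slivers) of its grid samples. This
guarantees by construction that every representable category gets exactly
one label; a region a template could not represent would fall back to a
margin listing (no shipped template needs it — the grid check covers all
63 regions at $n = 6$). Zero counts are printed as 0 rather than hidden.

**UpSet ranking.** Default ranking is by descending count with
deterministic ties: ascending degree, then C-locale lexicographic
combination string ("A&B" style, labels joined in input order). The
alternative `degree` sort orders by ascending degree, ties by descending
count. Empty combinations are hidden by default and available via
`show_empty` — with many sets the $2^n - 1$ zero rows are noise.

**Heat maps.** Square style for any matrix; the lower-triangular style
with a marginal set-size bar plot is reserved for symmetric metrics and
rejects asymmetric input with a pointer to the square style. Color scales:
diverging blue–white–red fixed to $[-1, 1]$ for correlation matrices,
sequential white–blue normalized to the data range otherwise. Missing
values render grey and print as the single sentinel `NA` in text outputs.

## Synthetic data

The generator exists so every statistic and figure is testable without any
download. `random_regions()` draws chromosomes proportional to length,
starts uniformly, lengths uniformly in a range, clipping at chromosome
ends, and deliberately does **not** merge its output so normalization
paths stay exercised. `derived_regions()` thins a merged base set with
retention probability $p$ and jitters survivors by a bounded uniform
shift. With zero jitter the derived set is a subset of the base, so for
$N$ equal-length disjoint base intervals the Jaccard statistic is exactly
$K/N$ for $K$ kept intervals — binomial expectation $p$. This closed form
links the generator to the statistics engine: the recovery tests demand
the exact $K/N$ identity per realization and agreement of the mean with
$p$ within three standard errors. Every generator call runs in a private
RNG stream seeded by its `seed` argument and restores the caller's
`.Random.seed`.

What the generator does *not* emulate: peak-shape or width distributions
of real ChIP-seq, GC or mappability bias, chromosome-specific density, or
correlated replicate structure. Passing tests therefore demonstrate
algorithmic correctness on structurally realistic inputs, not biological
fidelity of any particular assay.

The six bundled demo sets (three histone-mark-like peak sets, a fourth
mark for the UpSet demo, two super-enhancer-like sets) were generated once
by `demo_fixture()` at a fixed seed on a 300 kb two-chromosome toy genome
— a shared thinned/jittered backbone plus per-set private peaks, giving
every pair a distinct intermediate Jaccard — and committed as BED files so
the `--test` outputs stay stable; a test verifies the shipped files still
equal the generator's output.

## Problem sizes and numerical choices

The oracle-equivalence suites run 200 seeded fixtures (two-chromosome
genomes ≤ 100 kb, 2–5 sets, up to 200 intervals each) against per-base
brute-force scans — large enough to hit chromosome boundaries, empty
chromosomes, nested and book-ended configurations, small enough that the
whole test suite stays in the tens of seconds. Counts must match exactly;
ratio statistics to $10^{-12}$ relative; Fisher p-values to $10^{-9}$
against enumeration. The parameter-recovery and relative-distance null
checks use 1000 base intervals / 5000 query midpoints and three-standard-
error bands, which keeps their false-alarm probability per run below
1 %.

Other fixed choices: coordinates are stored as doubles (exact for any
genome position below $2^{53}$, immune to 32-bit overflow on products);
text writers emit Unix line endings and C-locale sorted, full-precision
("%.15g") numbers so outputs are diffable across platforms; set labels
default to file basenames, with numeric suffixes de-duplicating clashes;
chromosomes missing from a genome file are an error only for operations
that need the background (Fisher), never for parsing.

## Known limitations

* Strand-aware intersection is not implemented; all statistics are
  positional.
* Compressed inputs, tabix indexes, BED12 block structure, and VCF
  genotype fields are not consumed.
* The Fisher table construction is a heuristic background model, not a
  calibrated enrichment test; for calibrated inference use a
  permutation/shuffling framework.
* Region-mode Venn/UpSet counts are fragment counts (see above), not
  reference-set peak counts; base-pair mode is recommended when exact
  interpretability matters.
* Venn templates are fixed-shape, not area-proportional.
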
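three_set_tab <- function() {
  d <- demo_fixture()
  combination_counts(d$sets[1:3], "region")
}

test_that("every plot family writes nonempty files in all four formats", {
  d <- demo_fixture()
  tab <- three_set_tab()
  out <- withr::local_tempdir()
  spec <- figure_spec(format = "all", dpi = 96)
  pv <- plot_venn(tab, spec, file.path(out, "v"))
  pu <- plot_upset(tab, spec, file.path(out, "u"))
  m <- pairwise_matrix(d$sets[1:3], "jaccard")
  ph <- plot_heatmap(m, spec, path = file.path(out, "h"))
  for (p in c(pv, pu, ph)) {
    expect_true(file.exists(p), label = p)
    expect_gt(file.info(p)$size, 0)
  }
  expect_setequal(tools::file_ext(pv), c("pdf", "svg", "png", "tiff"))
})

test_that("venn SVG carries each category count exactly the right number of times", {
  tab <- three_set_tab()
  out <- withr::local_tempdir()
  p <- plot_venn(tab, figure_spec(format = "svg"), file.path(out, "v"))
  texts <- svg_texts(p[["svg"]])
  counts <- full_counts(tab)
  for (val in unique(counts)) {
    expect_equal(svg_count(texts, format_num(val)), sum(counts == val),
                 label = sprintf("count %s", val))
  }
  for (lb in tab$labels) expect_equal(svg_count(texts, lb), 1)
})

test_that("venn diagrams span two to six sets and refuse seven", {
  d <- demo_fixture()
  out <- withr::local_tempdir()
  for (n in c(2, 4, 5, 6)) {
    sets <- if (n <= 6) d$sets[seq_len(min(n, 6))]
    tab <- combination_counts(sets, "region")
    p <- plot_venn(tab, figure_spec(format = "svg"),
                   file.path(out, paste0("v", n)))
    texts <- svg_texts(p[["svg"]])
    counts <- full_counts(tab)
    # every one of the 2^n - 1 categories is labelled, zeros included
    total_labels <- sum(vapply(unique(counts), function(val)
      svg_count(texts, format_num(val)), 0))
    expect_gte(total_labels, length(counts))
  }
  seven <- lapply(1:7, function(i) {
    s <- d$sets[[1 + (i %% 6)]]; s$label <- paste0("s", i); s
  })
  expect_error(plot_venn(combination_counts(seven, "region"),
                         figure_spec(), file.path(out, "v7")), "upset")
})

test_that("two identical sets put all weight on the shared category", {
  d <- demo_fixture()
  a <- merge_regions(d$sets[[1L]]); a$label <- "A"
  b <- merge_regions(d$sets[[1L]]); b$label <- "B"
  tab <- combination_counts(list(a, b), "region")
  expect_setequal(names(tab$counts), "3")
  out <- withr::local_tempdir()
  p <- plot_venn(tab, figure_spec(format = "svg"), file.path(out, "same"))
  texts <- svg_texts(p[["svg"]])
  expect_equal(svg_count(texts, "0"), 2)  # the two exclusive categories
})

test_that("upset bars rank by frequency with documented tie-breaks", {
  counts <- stats::setNames(c(5, 10, 2), c("1", "3", "2"))  # A, AB, B
  tab <- structure(list(labels = c("A", "B"), mode = "list", counts = counts),
                   class = "combination_table")
  ord <- upset_order(counts, tab$labels, "frequency")
  expect_equal(mask_label(as.numeric(names(counts)[ord]), tab$labels),
               c("A&B", "A", "B"))
  ord2 <- upset_order(counts, tab$labels, "degree")
  expect_equal(mask_label(as.numeric(names(counts)[ord2]), tab$labels),
               c("A", "B", "A&B"))
  out <- withr::local_tempdir()
  p <- plot_upset(tab, figure_spec(format = "svg"), file.path(out, "u"))
  texts <- svg_texts(p[["svg"]])
  for (v in c("10", "5", "2")) expect_equal(svg_count(texts, v), 1)
  expect_error(plot_upset(structure(list(labels = c("A", "B"), mode = "list",
                                         counts = stats::setNames(numeric(), character())),
                                    class = "combination_table"),
                          figure_spec(), file.path(out, "empty")), "no non-empty")
})

test_that("heat map styles enforce the symmetry contract", {
  d <- demo_fixture()
  out <- withr::local_tempdir()
  mfrac <- pairwise_matrix(d$sets[1:3], "frac")
  expect_error(plot_heatmap(mfrac, figure_spec(extra = list(style = "tribar")),
                            path = file.path(out, "bad")), "square")
  p <- plot_heatmap(mfrac, figure_spec(format = "svg",
                                       extra = list(style = "square")),
                    path = file.path(out, "ok"))
  texts <- svg_texts(p[["svg"]])
  for (lb in mfrac$labels) expect_equal(svg_count(texts, lb), 2)  # row + col
  mj <- pairwise_matrix(d$sets[1:3], "jaccard")
  pt <- plot_heatmap(mj, figure_spec(format = "svg",
                                     extra = list(style = "tribar")),
                     path = file.path(out, "tri"))
  expect_true(file.exists(pt[["svg"]]))
})

test_that("clustered heat maps keep identical profiles adjacent", {
  a <- merge_regions(demo_fixture()$sets[[1L]])
  sets <- list(a, a, merge_regions(demo_fixture()$sets[[3L]]))
  for (i in 1:3) sets[[i]]$label <- c("dup1", "dup2", "other")[i]
  m <- pairwise_matrix(sets, "jaccard")
  out <- withr::local_tempdir()
  p <- plot_heatmap(m, figure_spec(format = "svg"),
                    cluster = list(linkage = "complete", distance = "euclidean"),
                    path = file.path(out, "cl"))
  ho <- hierarchical_order(m, "complete", "euclidean")
  expect_equal(abs(diff(match(c("dup1", "dup2"), ho$order))), 1L)
  expect_true(file.exists(p[["svg"]]))
})

test_that("re-rendering an identical scene is byte-identical", {
  tab <- three_set_tab()
  out <- withr::local_tempdir()
  p1 <- plot_venn(tab, figure_spec(format = "svg"), file.path(out, "a"))
  p2 <- plot_venn(tab, figure_spec(format = "svg"), file.path(out, "b"))
  expect_identical(readLines(p1[["svg"]]), readLines(p2[["svg"]]))
})
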
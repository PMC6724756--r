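random_count_table <- function(n, channels, seed, region = NULL) {
  set.seed(seed)
  counts <- matrix(rpois(n * length(channels), 2.5), n,
                   dimnames = list(NULL, channels))
  make_cell_table(counts, region = region)
}

test_that("percent positive and conditionals follow from the flags", {
  counts <- matrix(c(rep(5L, 4), rep(0L, 6),     # A: 4 of 10 positive
                     rep(5L, 10)),               # B: all positive
                   ncol = 2, dimnames = list(NULL, c("A", "B")))
  tab <- make_cell_table(counts, region = "roi")
  s <- summarize_region(tab, "roi")
  expect_equal(s$n_cells, 10L)
  expect_equal(unname(s$percent_positive["A"]), 40)
  expect_equal(unname(s$percent_positive["B"]), 100)
  expect_equal(s$conditional["A", "B"], 40)   # % of B+ cells that are A+
  expect_equal(s$conditional["B", "A"], 100)
  expect_equal(unname(s$class_counts[["A+B"]]), 4L)
  expect_equal(unname(s$class_counts[["B"]]), 6L)
  expect_equal(sum(s$class_counts), s$n_cells)
  expect_error(summarize_region(tab, "elsewhere"), "unknown region")
})

test_that("an empty conditioning set reports missing, not zero", {
  counts <- matrix(c(rep(5L, 3), rep(0L, 3)), ncol = 2,
                   dimnames = list(NULL, c("A", "B")))
  s <- summarize_region(make_cell_table(counts))
  expect_true(is.na(s$conditional["A", "B"]))
  expect_equal(s$conditional["B", "A"], 0)
})

test_that("summaries match the nested-loop oracle on randomized tables", {
  for (seed in 1:12) {
    k <- 1 + seed %% 3
    tab <- random_count_table(200, LETTERS[seq_len(k)], seed = 400 + seed)
    s <- summarize_region(tab)
    flags <- sapply(LETTERS[seq_len(k)], function(ch) tab[[paste0("positive_", ch)]])
    flags <- matrix(flags, ncol = k, dimnames = list(NULL, LETTERS[seq_len(k)]))
    want <- oracle_summary(flags)
    expect_equal(s$percent_positive, want$percent_positive)
    expect_equal(s$conditional, want$conditional)
    expect_equal(s$class_counts[order(names(s$class_counts))],
                 want$class_counts[order(names(want$class_counts))])
    # consistency: cond(A|B) * pct(B) / 100 = % positive for both
    for (a in colnames(flags)) for (b in colnames(flags)) {
      if (a == b || is.na(s$conditional[a, b])) next
      both <- 100 * mean(flags[, a] & flags[, b])
      expect_equal(s$conditional[a, b] * s$percent_positive[[b]] / 100, both)
    }
  }
})

test_that("summaries are invariant to cell order", {
  tab <- random_count_table(150, c("A", "B"), seed = 5, region = "roi")
  perm <- tab[sample(nrow(tab)), ]
  attributes(perm)[c("channels", "threshold", "strays", "class")] <-
    attributes(tab)[c("channels", "threshold", "strays", "class")]
  a <- summarize_region(tab, "roi"); b <- summarize_region(perm, "roi")
  expect_equal(a$percent_positive, b$percent_positive)
  expect_equal(a$class_counts, b$class_counts)
})

test_that("the heatmap table carries percentages and not-quantified markers", {
  # two regions on one label image with different planted means
  lab <- matrix(0L, 24, 40)
  for (i in 1:6) lab[(1 + 3 * (i - 1)):(2 + 3 * (i - 1)), 2:3] <- i       # left
  for (i in 7:12) lab[(1 + 3 * (i - 7)):(2 + 3 * (i - 7)), 32:33] <- i    # right
  counts <- c(rep(6L, 6), rep(2L, 6))   # left mean 6, right mean 2 (< 4)
  rows <- integer(0); cols <- integer(0)
  for (i in 1:12) {
    p <- which(lab == i, arr.ind = TRUE)[1, ]
    rows <- c(rows, rep(p[1], counts[i])); cols <- c(cols, rep(p[2], counts[i]))
  }
  fs <- list(p = structure(data.frame(row = rows, col = cols, value = 1),
                           class = c("focus_set", "data.frame"), channel = "p"))
  left <- matrix(0, 24, 40); left[, 1:20] <- 1
  right <- matrix(0, 24, 40); right[, 21:40] <- 1
  tab <- build_cell_table(lab, lab, fs, regions = list(L = left, R = right))
  hm <- heatmap_table(tab)
  expect_equal(hm$percent["L", "p"], 100)   # all left cells have 6 foci
  expect_true(is.na(hm$percent["R", "p"]))  # mean 2 < 4: not quantified
  expect_false(hm$quantified["R", "p"])
  expect_match(hm$reason["R", "p"], "below 4 dots")
  # region marked unseparable is excluded even with high counts
  hm2 <- heatmap_table(tab, separable = c(L = FALSE))
  expect_false(hm2$quantified["L", "p"])
  expect_match(hm2$reason["L", "p"], "not separable")
  # zero positives in a quantifiable region is a true 0%, not a marker
  tab0 <- make_cell_table(matrix(rep(c(4L, 5L, 4L, 5L, 2L), 4)[1:10], ncol = 1,
                                 dimnames = list(NULL, "p")), region = "roi")
  hm0 <- heatmap_table(tab0, min_mean_foci = 4)
  expect_true(hm0$quantified["roi", "p"])
})

test_that("co-expression classes span the power set and match brute force", {
  counts <- matrix(c(5, 5, 5,   5, 5, 0,   5, 0, 0,   0, 0, 0), 4, 3,
                   byrow = TRUE, dimnames = list(NULL, c("A", "B", "C")))
  tab <- make_cell_table(counts)
  cls <- classify_cells(tab)
  expect_equal(as.character(cls), c("A+B+C", "A+B", "A", "none"))
  expect_equal(levels(cls),
               c("none", "A", "B", "C", "A+B", "A+C", "B+C", "A+B+C"))

  for (seed in 1:6) {
    tab <- random_count_table(120, c("A", "B", "C"), seed = 900 + seed)
    got <- table(classify_cells(tab))
    flags <- sapply(c("A", "B", "C"), function(ch) tab[[paste0("positive_", ch)]])
    want <- oracle_summary(matrix(flags, ncol = 3,
                                  dimnames = list(NULL, c("A", "B", "C"))))
    expect_equal(as.integer(got[names(want$class_counts)]),
                 unname(as.integer(want$class_counts)))
  }

  too_many <- random_count_table(10, c("A", "B", "C", "D"), seed = 1)
  expect_error(classify_cells(too_many), "at most 3")
})
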
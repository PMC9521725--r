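mark_set <- function(units, marked, deep = NULL) {
  data.frame(channel = units, marked = marked,
             deep_value_ms = if (is.null(deep)) ifelse(marked, 20, NA)
                             else deep,
             stringsAsFactors = FALSE)
}

test_that("identical annotation sets score as pure agreement", {
  units <- sprintf("u%02d", 1:20)
  marked <- rep(c(TRUE, FALSE), each = 10)
  rep_ <- match_annotations(mark_set(units, marked), mark_set(units, marked))
  expect_identical(rep_$counts$tp, 10L)
  expect_identical(rep_$counts$tn, 10L)
  expect_identical(rep_$counts$fp, 0L)
  expect_identical(rep_$counts$fn, 0L)
  expect_identical(rep_$counts$total, 20L)
})

test_that("disjoint markings land entirely in the false-positive cell", {
  units <- sprintf("u%02d", 1:20)
  rep_ <- match_annotations(mark_set(units, rep(TRUE, 20)),
                            mark_set(units, rep(FALSE, 20)))
  expect_identical(rep_$counts$fp, 20L)
  expect_identical(rep_$counts$tp + rep_$counts$tn + rep_$counts$fn, 0L)
})

test_that("confusion counts always sum to the number of scored units", {
  set.seed(404)
  for (k in 1:20) {
    n <- sample(5:60, 1)
    units <- sprintf("u%03d", seq_len(n))
    a <- mark_set(units, runif(n) < 0.5)
    b <- mark_set(units, runif(n) < 0.5)
    cnt <- match_annotations(a, b)$counts
    expect_identical(cnt$total, n)
  }
})

test_that("sensitivity and specificity reproduce the published expert statistics", {
  e1 <- confusion_counts(tp = 1451, tn = 1812, fp = 136, fn = 281)
  expect_equal(round(sensitivity(e1), 1), 83.8)
  expect_equal(round(specificity(e1), 1), 93.0)
  e2 <- confusion_counts(tp = 1562, tn = 2016, fp = 25, fn = 77)
  expect_equal(round(sensitivity(e2), 1), 95.3)
  expect_equal(round(specificity(e2), 1), 98.8)
  # degenerate but defined cases
  expect_equal(round(sensitivity(confusion_counts(0, 3, 0, 5)), 1), 0.0)
  expect_equal(round(specificity(confusion_counts(1, 7, 0, 1)), 1), 100.0)
})

test_that("rates with an empty denominator are typed undefined, not 0 or 100", {
  se <- sensitivity(confusion_counts(tp = 0, tn = 9, fp = 1, fn = 0))
  expect_true(is.na(se))
  expect_true(isTRUE(attr(se, "undefined")))
  sp <- specificity(confusion_counts(tp = 4, tn = 0, fp = 0, fn = 2))
  expect_true(is.na(sp))
  expect_true(isTRUE(attr(sp, "undefined")))
})

test_that("both rates are invariant under scaling all four counts", {
  base <- c(tp = 13, tn = 29, fp = 4, fn = 7)
  r1 <- confusion_counts(base[1], base[2], base[3], base[4])
  for (k in c(2L, 5L, 17L)) {
    rk <- confusion_counts(k * base[1], k * base[2], k * base[3], k * base[4])
    expect_equal(sensitivity(rk), sensitivity(r1))
    expect_equal(specificity(rk), specificity(r1))
  }
})

test_that("kappa is 1 for identical labelings and matches the hand-computed cross-tab", {
  lab <- c(rep(TRUE, 6), rep(FALSE, 9))
  expect_equal(cohen_kappa(lab, lab), 1)
  # cross-tab a=45 b=15 c=25 d=15: p_o = 0.60, p_e = 0.54, kappa = 0.06/0.46
  a <- c(rep(TRUE, 45), rep(TRUE, 15), rep(FALSE, 25), rep(FALSE, 15))
  b <- c(rep(TRUE, 45), rep(FALSE, 15), rep(TRUE, 25), rep(FALSE, 15))
  expect_equal(cohen_kappa(a, b), 0.06 / 0.46, tolerance = 1e-12)
  expect_equal(cohen_kappa(a, b), 0.1304348, tolerance = 1e-6)
})

test_that("kappa equals the brute-force oracle on 100 random 2x2 tables and never exceeds 1", {
  set.seed(271)
  for (k in 1:100) {
    n <- sample(10:200, 1)
    a <- runif(n) < runif(1, 0.1, 0.9)
    b <- if (runif(1) < 0.3) (a == (runif(n) < 0.9)) else runif(n) < runif(1, 0.1, 0.9)
    want <- brute_kappa(a, b)
    got <- cohen_kappa(a, b)
    if (is.na(want)) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, want, tolerance = 1e-12)
      expect_lte(got, 1)
    }
  }
})

test_that("degenerate marginals follow the kappa formula exactly", {
  # both raters degenerate on the same class: p_e = 1, undefined
  out <- cohen_kappa(rep(TRUE, 10), rep(TRUE, 10))
  expect_true(is.na(out))
  expect_true(isTRUE(attr(out, "undefined")))
  # all-positive vs all-negative: p_o = 0 but p_e = 0 too, so kappa = 0
  expect_equal(cohen_kappa(rep(TRUE, 10), rep(FALSE, 10)),
               brute_kappa(rep(TRUE, 10), rep(FALSE, 10)))
  expect_equal(cohen_kappa(rep(TRUE, 10), rep(FALSE, 10)), 0)
  # symmetric half/half disagreement: p_o = 0, kappa = -1
  a <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(cohen_kappa(a, !a), -1)
  expect_error(cohen_kappa(rep(TRUE, 3), rep(TRUE, 4)),
               class = "unit_mismatch")
})

test_that("the published correction counts yield the published percentages", {
  # reconstruct unit sets realizing counts 5390/375/110/10 over 5885
  n_unchanged <- 5390; n_changed <- 375; n_deleted <- 110; n_added <- 10
  alg_units <- sprintf("u%04d", seq_len(n_unchanged + n_changed + n_deleted))
  alg <- data.frame(channel = alg_units, deep_value_ms = 30)
  corr <- rbind(
    data.frame(channel = alg_units[seq_len(n_unchanged)], deep_value_ms = 30),
    data.frame(channel = alg_units[n_unchanged + seq_len(n_changed)],
               deep_value_ms = 60),          # revised by more than 5 ms
    data.frame(channel = sprintf("add%02d", seq_len(n_added)),
               deep_value_ms = 25)           # expert-added marks
  )                                          # deleted = algorithm rows absent here
  bk <- categorize_corrections(alg, corr)
  expect_identical(unname(bk$counts),
                   as.integer(c(n_unchanged, n_changed, n_deleted, n_added)))
  expect_identical(bk$total, 5885L)
  expect_equal(unname(bk$percentages), c(91.6, 6.4, 1.9, 0.2))
  expect_equal(sum(bk$percentages), 100, tolerance = 0.1)
})

test_that("identity and total-removal corrections are classified at the extremes", {
  alg <- data.frame(channel = c("a", "b", "c"), deep_value_ms = c(15, 25, 40))
  same <- categorize_corrections(alg, alg)
  expect_equal(unname(same$percentages), c(100, 0, 0, 0))
  gone <- categorize_corrections(alg,
                                 data.frame(channel = character(0),
                                            deep_value_ms = numeric(0)))
  expect_equal(unname(gone$percentages), c(0, 0, 100, 0))
})

test_that("correction percentages always sum to 100 within rounding", {
  set.seed(88)
  for (k in 1:15) {
    n <- sample(20:80, 1)
    units <- sprintf("u%03d", seq_len(n))
    alg <- data.frame(channel = units, deep_value_ms = runif(n, 5, 80))
    keep <- runif(n) < 0.8
    corr <- data.frame(channel = units[keep],
                       deep_value_ms = alg$deep_value_ms[keep] +
                         sample(c(0, 12), sum(keep), replace = TRUE))
    if (runif(1) < 0.5) {
      corr <- rbind(corr, data.frame(channel = "extra1", deep_value_ms = 20))
    }
    bk <- categorize_corrections(alg, corr)
    expect_lte(abs(sum(bk$percentages) - 100), 0.1 + 1e-9)
    expect_identical(sum(bk$counts), bk$total)
  }
})

test_that("decrement histograms bin half-open and reject bad edges", {
  expect_identical(unname(histogram_by_deep(c(5, 12, 160), c(0, 50, 150, 300))),
                   c(2L, 0L, 1L))
  expect_identical(unname(histogram_by_deep(numeric(0), c(0, 10, 20))),
                   c(0L, 0L))
  # boundary values land in the right-hand bin; the top edge is exclusive
  expect_identical(unname(histogram_by_deep(c(0, 50, 300), c(0, 50, 150, 300))),
                   c(1L, 1L, 0L))
  expect_error(histogram_by_deep(1:3, c(0, 10, 10)), class = "bad_edges")
})

test_that("uniform decrements split evenly between two equal bins", {
  set.seed(55)
  vals <- runif(1000, 0, 100)
  h <- histogram_by_deep(vals, c(0, 50, 100))
  expect_identical(sum(h), 1000L)
  sd_bin <- sqrt(1000 * 0.25)
  expect_true(all(abs(h - 500) <= 3 * sd_bin))
})

test_that("duplicate marks on one unit are rejected", {
  dup <- data.frame(channel = c("a", "a"), deep_value_ms = c(10, 20))
  expect_error(categorize_corrections(dup, dup), class = "duplicate_marks")
})
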
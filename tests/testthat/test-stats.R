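# Rank-sum testing, box-plot summaries, Bonferroni, group comparisons.

test_that("five-number summary matches the 1.5xIQR box-plot conventions", {
  s <- five_number_summary(5)
  expect_equal(c(s$median, s$q1, s$q3), c(5, 5, 5))
  expect_length(s$outliers, 0)

  s <- five_number_summary(c(1, 2, 3, 100))
  expect_identical(s$outliers, 100)        # far point flagged
  expect_equal(s$whisker_high, 3)          # whisker clamps to observed data

  expect_equal(five_number_summary(c(4, 5, 6, 7, 8))$median, 6)
  expect_error(five_number_summary(numeric(0)), "empty")

  # quartile methods differ where interpolation matters
  x <- c(1, 2, 3, 4)
  expect_equal(five_number_summary(x, "linear")$q1, 1.75)    # type 7
  expect_equal(five_number_summary(x, "lower")$q1, 1)        # type 1
  expect_equal(five_number_summary(x, "midpoint")$q1, 1.5)   # type 2
})

test_that("five-number summary is permutation-invariant and shift-equivariant", {
  set.seed(5150)
  for (i in 1:20) {
    x <- round(rlnorm(sample(3:40, 1), log(10), 0.5), 2)
    s1 <- five_number_summary(x)
    s2 <- five_number_summary(sample(x))
    s2$data <- s1$data <- NULL
    expect_equal(s2, s1)
    shift <- runif(1, -3, 3)
    s3 <- five_number_summary(x + shift)
    expect_equal(s3$median, s1$median + shift)
    expect_equal(s3$q1, s1$q1 + shift)
    expect_equal(s3$q3, s1$q3 + shift)
    expect_equal(s3$outliers, s1$outliers + shift)
  }
})

test_that("exact rank-sum enumeration matches the brute-force oracle and wilcox.test", {
  set.seed(88)
  for (i in 1:25) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- rnorm(nx); y <- rnorm(ny)        # continuous: no ties
    t <- wilcoxon_rank_sum(x, y, mode = "exact")
    expect_equal(t$p, oracle_exact_p(x, y), tolerance = 1e-12)
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(t$p, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(t$U, unname(ref$statistic))
  }
})

test_that("worked exact example, symmetry and degenerate inputs behave", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), mode = "exact")$p,
               0.1)
  # swap symmetry
  expect_equal(wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3), mode = "exact")$p,
               0.1)
  # identical samples: ties force the approximation, p = 1
  expect_message(t <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3),
                                        mode = "exact"), "tied")
  expect_equal(t$p, 1)
  # all observations equal across both samples: degenerate, p = 1
  expect_warning(t2 <- wilcoxon_rank_sum(rep(2, 4), rep(2, 5)), "degenerate")
  expect_equal(t2$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("normal approximation approaches the exact p as samples grow", {
  set.seed(303)
  deltas <- vapply(c(15, 30, 60), function(n) {
    x <- rnorm(n / 3); y <- rnorm(n - n / 3) + 0.3
    pe <- wilcoxon_rank_sum(x, y, mode = "exact")$p
    pa <- wilcoxon_rank_sum(x, y, mode = "normal_approx")$p
    abs(pe - pa)
  }, numeric(1))
  expect_lt(deltas[3], deltas[1])
  expect_lt(deltas[3], 0.01)
})

test_that("tie-corrected approximation agrees with wilcox.test on tied data", {
  set.seed(99)
  for (i in 1:10) {
    x <- sample(1:6, 20, replace = TRUE)
    y <- sample(1:6, 25, replace = TRUE) + sample(0:1, 25, replace = TRUE)
    t <- wilcoxon_rank_sum(x, y, mode = "normal_approx")
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(t$p, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("Bonferroni adjustment multiplies by the family size and caps at 1", {
  expect_equal(bonferroni_adjust(c(0.01, 0.02, 0.5)), c(0.03, 0.06, 1.0))
  expect_equal(bonferroni_adjust(0.2), 0.2)         # m = 1 identity
  set.seed(12)
  p <- runif(7, 1e-6, 1)
  out <- bonferroni_adjust(p)
  expect_true(all(out >= p) && all(out <= 1))       # monotone, capped
  expect_error(bonferroni_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bonferroni_adjust(1.2), "\\(0, 1\\]")
})

make_grouped <- function(onset, nsfs, sex = NULL, n_inframe = NULL,
                         tm = NULL, manifestation = "DM") {
  df <- data.frame(
    patient_id = sprintf("G%03d", seq_along(onset)),
    sex = if (is.null(sex)) rep("female", length(onset)) else sex,
    onset = onset, nsfs_dose = nsfs,
    n_inframe = if (is.null(n_inframe)) 2L - nsfs else n_inframe,
    tm_dose = if (is.null(tm)) rep(NA_integer_, length(onset)) else tm,
    stringsAsFactors = FALSE)
  attr(df, "manifestation") <- manifestation
  class(df) <- c("wfs_grouped", "data.frame")
  df
}

test_that("group comparisons summarise, test pairwise, and adjust within family", {
  set.seed(21)
  g <- make_grouped(onset = c(rnorm(30, 8), rnorm(30, 7), rnorm(30, 5)),
                    nsfs = rep(0:2, each = 30))
  cmp <- compare_dose_groups(g, "nsfs")
  expect_s3_class(cmp, "group_comparison")
  expect_named(cmp$per_group, c("NSFS0", "NSFS1", "NSFS2"))
  expect_identical(nrow(cmp$pairwise), 3L)          # Bonferroni family m = 3
  expect_equal(cmp$pairwise$p_adj, pmin(1, cmp$pairwise$p_raw * 3))
  expect_true(all(vapply(cmp$per_group, `[[`, integer(1), "n") == 30L))
  # summary mirrors the group-table layout
  s <- summary(cmp)
  expect_identical(names(s), c("manifestation", "group", "n", "median",
                               "lower_quartile", "upper_quartile"))
})

test_that("empty groups are omitted and degenerate comparisons are not errors", {
  g <- make_grouped(onset = c(5, 6, 7, 8), nsfs = c(0L, 0L, 2L, 2L))
  cmp <- compare_dose_groups(g, "nsfs")
  expect_identical(cmp$dropped_groups, "NSFS1")
  expect_identical(nrow(cmp$pairwise), 1L)
  expect_true(cmp$testable)

  solo <- compare_dose_groups(make_grouped(c(5, 6), c(0L, 0L)), "nsfs")
  expect_false(solo$testable)
  expect_identical(nrow(solo$pairwise), 0L)

  none <- compare_dose_groups(make_grouped(numeric(0), integer(0)), "nsfs")
  expect_false(none$testable)
})

test_that("TM groupings restrict to the right genotype subsets", {
  g <- make_grouped(
    onset = c(5, 6, 7, 8, 9, 10),
    nsfs = c(0L, 0L, 0L, 1L, 1L, 2L),
    n_inframe = c(2L, 2L, 2L, 1L, 1L, 0L),
    tm = c(2L, 1L, 0L, 1L, 0L, NA))
  two <- compare_dose_groups(g, "tm_two_inframe")
  expect_named(two$per_group, c("NTM0", "NTM1", "NTM2"))
  expect_identical(sum(vapply(two$per_group, `[[`, integer(1), "n")), 3L)
  one <- compare_dose_groups(g, "tm_one_inframe")
  expect_named(one$per_group, c("NTM0", "NTM1"))
  expect_identical(sum(vapply(one$per_group, `[[`, integer(1), "n")), 2L)
})

test_that("sex comparisons drop unknown sex and support dose strata", {
  g <- make_grouped(onset = c(5, 6, 7, 8, 9, 10),
                    nsfs = c(0L, 0L, 1L, 1L, 2L, 2L),
                    sex = c("male", "female", "male", "female", "unknown",
                            "female"))
  cmp <- sex_stratified_comparison(g)
  expect_named(cmp$per_group, c("male", "female"))
  expect_identical(sum(vapply(cmp$per_group, `[[`, integer(1), "n")), 5L)
  d0 <- sex_stratified_comparison(g, within_dose = 0)
  expect_identical(sum(vapply(d0$per_group, `[[`, integer(1), "n")), 2L)
  # all-unknown sex: not testable, not an error
  gu <- make_grouped(onset = c(5, 6), nsfs = c(0L, 0L),
                     sex = c("unknown", "unknown"))
  expect_false(sex_stratified_comparison(gu)$testable)
})
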
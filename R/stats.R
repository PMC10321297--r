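# Rank-based two-sample testing and box-plot summaries.
#
# The exact Wilcoxon rank-sum test enumerates the permutation distribution of
# the rank sum directly; the large-sample path uses mid-ranks with the
# standard tie-corrected normal approximation. Both are authored here because
# downstream code needs the enumeration semantics (two-sided extremity
# counting) to be explicit and testable against a brute-force oracle.

QUARTILE_METHODS <- c(linear = 7L, lower = 1L, midpoint = 2L)

#' Box-plot five-number summary of onset ages
#'
#' Median and quartiles of a sample of ages, plus the 1.5 x IQR whisker and
#' outlier decomposition used in onset box plots: whiskers extend to the most
#' extreme observations within `q1 - 1.5*IQR` and `q3 + 1.5*IQR`, and every
#' observation beyond those fences is an outlier point.
#'
#' @param ages Numeric vector of ages in years, `length >= 1`, no `NA`s
#'   (filter upstream).
#' @param method Quartile interpolation: `"linear"` (interpolation between
#'   order statistics; `quantile` type 7), `"lower"` (type 1) or
#'   `"midpoint"` (type 2).
#' @return An object of class `five_num`: list with `n`, `median`, `q1`,
#'   `q3`, `whisker_low`, `whisker_high`, `outliers`.
#' @examples
#' five_number_summary(c(1, 2, 3, 100))
#' @export
five_number_summary <- function(ages, method = c("linear", "lower",
                                                 "midpoint")) {
  method <- match.arg(method)
  if (!length(ages)) stop("five_number_summary: empty sample", call. = FALSE)
  if (anyNA(ages) || !is.numeric(ages))
    stop("five_number_summary: ages must be numeric without NA",
         call. = FALSE)
  qt <- stats::quantile(ages, probs = c(0.25, 0.5, 0.75),
                        type = QUARTILE_METHODS[[method]], names = FALSE)
  iqr <- qt[3] - qt[1]
  lo_fence <- qt[1] - 1.5 * iqr
  hi_fence <- qt[3] + 1.5 * iqr
  inside <- ages >= lo_fence & ages <= hi_fence
  structure(list(n = length(ages), median = qt[2], q1 = qt[1], q3 = qt[3],
                 whisker_low = min(ages[inside]),
                 whisker_high = max(ages[inside]),
                 outliers = sort(ages[!inside]), method = method),
            class = "five_num")
}

#' @export
print.five_num <- function(x, ...) {
  cat(sprintf("n=%d  median=%.4g  [q1=%.4g, q3=%.4g]  whiskers=[%.4g, %.4g]",
              x$n, x$median, x$q1, x$q3, x$whisker_low, x$whisker_high))
  if (length(x$outliers))
    cat("  outliers:", paste(signif(x$outliers, 4), collapse = ", "))
  cat("\n")
  invisible(x)
}

# Exact two-sided p by complete enumeration of the C(n, nx) equally likely
# rank assignments; extremity measured symmetrically about E[W].
.exact_rank_sum_p <- function(w_obs, nx, n) {
  splits <- utils::combn(n, nx)
  w_all <- colSums(splits)
  mu <- nx * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

#' Wilcoxon rank-sum test for two onset samples
#'
#' Two-sided two-sample rank-sum test. In `"exact"` mode the permutation
#' distribution of the rank sum is enumerated completely (all `choose(n, nx)`
#' equally likely rank assignments) and the p-value is the probability of a
#' rank sum at least as far from its null expectation as the observed one;
#' exact enumeration requires untied data and a feasible enumeration size,
#' otherwise it falls back to the approximation with a message. In
#' `"normal_approx"` mode mid-ranks are used with the tie-corrected normal
#' approximation (no continuity correction by default). `"auto"` picks exact
#' when the data are untied and the total sample is small.
#'
#' @param x,y Non-empty numeric vectors (ages in years).
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @param continuity Apply a 0.5 continuity correction in the approximation.
#' @param exact_limit Largest total sample size for which `"auto"` chooses
#'   enumeration (default 20).
#' @return Object of class `rank_sum_test`: list with `U` (Mann-Whitney
#'   statistic for `x`), `W` (rank sum of `x`), `p` (two-sided), `n_x`,
#'   `n_y`, `method_used`, `ties`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), mode = "exact")$p  # 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal_approx"),
                              continuity = FALSE, exact_limit = 20L) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y))
    stop("wilcoxon_rank_sum: both samples must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("wilcoxon_rank_sum: NA values not allowed", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)                      # mid-ranks under ties
  w <- sum(r[seq_len(nx)])
  u <- w - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0L

  use_exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = !ties && n <= exact_limit)
  if (use_exact && ties) {
    message("wilcoxon_rank_sum: tied observations; exact enumeration ",
            "not applicable, using the tie-corrected normal approximation")
    use_exact <- FALSE
  }
  if (use_exact && choose(n, nx) > 5e6) {
    message("wilcoxon_rank_sum: enumeration of ", format(choose(n, nx)),
            " rank splits infeasible, using the normal approximation")
    use_exact <- FALSE
  }

  if (use_exact) {
    p <- .exact_rank_sum_p(w, nx, n)
    method <- "exact_enumeration"
  } else {
    mu <- nx * (n + 1) / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab)
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      warning("wilcoxon_rank_sum: all observations tied across both samples;",
              " test is degenerate, p = 1", call. = FALSE)
      p <- 1
    } else {
      z <- w - mu
      if (continuity) z <- sign(z) * max(0, abs(z) - 0.5)
      p <- min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
    }
    method <- if (continuity) "normal_approx_cc" else "normal_approx"
  }
  structure(list(U = u, W = w, p = p, n_x = nx, n_y = ny,
                 method_used = method, ties = ties),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: U = %.4g, W = %.4g, p = %.4g (%s, n = %d vs %d)\n",
              x$U, x$W, x$p, x$method_used, x$n_x, x$n_y))
  invisible(x)
}

#' Bonferroni adjustment of a family of p-values
#'
#' Multiplies each p-value by the family size `m = length(p_values)` and
#' caps at 1; order is preserved. The family is one set of pairwise
#' comparisons within a single manifestation and grouping, never across
#' manifestations.
#'
#' @param p_values Numeric vector, each in `(0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bonferroni_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0) || any(p_values > 1))
    stop("bonferroni_adjust: p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "bonferroni")
}

.grouping_labels <- function(patients, grouping) {
  switch(grouping,
    nsfs = {
      lab <- factor(patients$nsfs_dose, levels = 0:2,
                    labels = c("NSFS0", "NSFS1", "NSFS2"))
      list(patients = patients, labels = lab)
    },
    tm_two_inframe = {
      sub <- patients[!is.na(patients$n_inframe) & patients$n_inframe == 2L &
                      !is.na(patients$tm_dose), , drop = FALSE]
      list(patients = sub,
           labels = factor(sub$tm_dose, levels = 0:2,
                           labels = c("NTM0", "NTM1", "NTM2")))
    },
    tm_one_inframe = {
      sub <- patients[!is.na(patients$n_inframe) & patients$n_inframe == 1L &
                      !is.na(patients$tm_dose), , drop = FALSE]
      list(patients = sub,
           labels = factor(sub$tm_dose, levels = 0:1,
                           labels = c("NTM0", "NTM1")))
    },
    sex = {
      sub <- patients[patients$sex %in% c("male", "female"), , drop = FALSE]
      list(patients = sub,
           labels = factor(sub$sex, levels = c("male", "female")))
    },
    stop(sprintf("unknown grouping '%s'", grouping), call. = FALSE))
}

#' Compare onset ages across allele-dose (or sex) groups
#'
#' The core analysis object: splits eligible patients for one manifestation
#' into dose groups, summarises each group's onset distribution
#' (five-number box-plot summary) and runs all pairwise Wilcoxon rank-sum
#' tests among non-empty groups, with Bonferroni adjustment over the
#' pairwise family within this comparison.
#'
#' Groupings:
#' \describe{
#'   \item{`"nsfs"`}{NSFS allele dose 0/1/2 over all eligible patients.}
#'   \item{`"tm_two_inframe"`}{TM in-frame dose 0/1/2 among patients with
#'     two in-frame alleles (zero NSFS).}
#'   \item{`"tm_one_inframe"`}{TM in-frame dose 0/1 among patients with
#'     exactly one in-frame allele (one NSFS).}
#'   \item{`"sex"`}{male vs female (patients of unknown sex dropped).}
#' }
#'
#' @param patients A `wfs_grouped` data frame from [filter_eligible()].
#' @param grouping One of the groupings above.
#' @param quartile_method Passed to [five_number_summary()].
#' @param mode Passed to [wilcoxon_rank_sum()].
#' @return Object of class `group_comparison`: `manifestation`, `grouping`,
#'   `per_group` (named list of `five_num`), `pairwise` (data frame with
#'   `group_a`, `group_b`, `U`, `p_raw`, `p_adj`), `testable`,
#'   `dropped_groups`, `settings`. With fewer than two non-empty groups the
#'   comparison is reported `testable = FALSE`, not an error.
#' @seealso [sex_stratified_comparison()], [run_analysis()]
#' @export
compare_dose_groups <- function(patients,
                                grouping = c("nsfs", "tm_two_inframe",
                                             "tm_one_inframe", "sex"),
                                quartile_method = "linear",
                                mode = "auto") {
  grouping <- match.arg(grouping)
  stopifnot(inherits(patients, "data.frame"))
  g <- .grouping_labels(patients, grouping)
  ages <- split(g$patients$onset, g$labels)
  sizes <- vapply(ages, length, integer(1))
  dropped <- names(sizes)[sizes == 0L]
  ages <- ages[sizes > 0L]

  per_group <- lapply(ages, five_number_summary, method = quartile_method)
  for (g in names(per_group)) per_group[[g]]$data <- ages[[g]]  # for plot()
  labels <- names(ages)
  pairwise <- data.frame(group_a = character(0), group_b = character(0),
                         U = numeric(0), p_raw = numeric(0),
                         p_adj = numeric(0), stringsAsFactors = FALSE)
  testable <- length(labels) >= 2L
  if (testable) {
    pairs <- utils::combn(labels, 2L)
    res <- apply(pairs, 2L, function(pr) {
      t <- wilcoxon_rank_sum(ages[[pr[1]]], ages[[pr[2]]], mode = mode)
      c(U = t$U, p = t$p)
    })
    pairwise <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                           U = res["U", ], p_raw = res["p", ],
                           p_adj = bonferroni_adjust(res["p", ]),
                           stringsAsFactors = FALSE)
  }
  structure(list(manifestation = attr(patients, "manifestation"),
                 grouping = grouping, per_group = per_group,
                 pairwise = pairwise, testable = testable,
                 dropped_groups = dropped,
                 settings = list(quartile_method = quartile_method,
                                 mode = mode, sidedness = "two_sided",
                                 continuity = FALSE)),
            class = "group_comparison")
}

#' Sex-stratified onset comparison
#'
#' Male-vs-female onset comparison for one manifestation, over the whole
#' eligible cohort or restricted to one NSFS-dose stratum. Patients of
#' unknown sex are dropped from this comparison only.
#'
#' @inheritParams compare_dose_groups
#' @param within_dose Optional NSFS dose (0, 1 or 2) restricting the stratum.
#' @return A `group_comparison` with grouping `"sex"`.
#' @export
sex_stratified_comparison <- function(patients, within_dose = NULL,
                                      quartile_method = "linear",
                                      mode = "auto") {
  if (!is.null(within_dose)) {
    stopifnot(within_dose %in% 0:2)
    man <- attr(patients, "manifestation")
    patients <- patients[!is.na(patients$nsfs_dose) &
                         patients$nsfs_dose == within_dose, , drop = FALSE]
    attr(patients, "manifestation") <- man
  }
  out <- compare_dose_groups(patients, grouping = "sex",
                             quartile_method = quartile_method, mode = mode)
  out$within_dose <- within_dose
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s by %s\n",
              if (is.null(x$manifestation)) "?" else x$manifestation,
              x$grouping))
  print(summary(x), row.names = FALSE)
  if (x$testable) {
    cat("pairwise Wilcoxon rank-sum (Bonferroni m =",
        nrow(x$pairwise), "):\n")
    pw <- x$pairwise
    pw$U <- signif(pw$U, 6); pw$p_raw <- signif(pw$p_raw, 4)
    pw$p_adj <- signif(pw$p_adj, 4)
    print(pw, row.names = FALSE)
  } else {
    cat("not testable: fewer than two non-empty groups\n")
  }
  if (length(x$dropped_groups))
    cat("empty group(s) omitted:", paste(x$dropped_groups, collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
summary.group_comparison <- function(object, ...) {
  rows <- lapply(names(object$per_group), function(g) {
    s <- object$per_group[[g]]
    data.frame(manifestation = if (is.null(object$manifestation)) NA_character_
                               else object$manifestation,
               group = g, n = s$n, median = s$median,
               lower_quartile = s$q1, upper_quartile = s$q3,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
as.data.frame.group_comparison <- function(x, ...) summary(x)

#' Box plot of a group comparison
#'
#' Base-graphics box plot following the onset-figure conventions: median
#' line, quartile box edges, whiskers at 1.5 x IQR, outliers as individual
#' points, group sample sizes on the x axis.
#'
#' @param x A `group_comparison`.
#' @param y Ignored.
#' @param ... Passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.group_comparison <- function(x, y, ...) {
  groups <- names(x$per_group)
  if (!length(groups)) {
    warning("nothing to plot: no non-empty groups", call. = FALSE)
    return(invisible(x))
  }
  ages <- lapply(groups, function(g) {
    s <- x$per_group[[g]]
    # reconstructable only from raw data; stash during compare is simpler
    s$data
  })
  if (any(vapply(ages, is.null, logical(1))))
    stop("plot.group_comparison: raw data not retained", call. = FALSE)
  names(ages) <- sprintf("%s\n(n=%d)", groups,
                         vapply(x$per_group, `[[`, integer(1), "n"))
  graphics::boxplot(ages, range = 1.5,
                    ylab = "Age of onset (years)",
                    main = sprintf("%s by %s",
                                   if (is.null(x$manifestation)) ""
                                   else x$manifestation, x$grouping), ...)
  invisible(x)
}
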
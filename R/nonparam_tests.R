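#' Test-result container
#'
#' Lightweight container used by every hypothesis test in the package.
#'
#' @param method Character label of the procedure.
#' @param statistic Test statistic (chi-square-type statistics are
#'   non-negative; the two-sample median Z is signed).
#' @param df Degrees of freedom (integer, vector of two for F-tests, or
#'   `NULL` for normal-deviate tests).
#' @param p_value p-value in \[0, 1\].
#' @param ... Further named elements stored alongside (tables, counts...).
#' @return List of class `sa_test`.
#' @export
sa_test <- function(method, statistic, df, p_value, ...) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = min(p_value, 1), ...),
            class = "sa_test")
}

#' @export
print.sa_test <- function(x, ...) {
  dfs <- if (is.null(x$df)) "" else paste0(", df = ", paste(x$df, collapse = ","))
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g\n",
              x$method, x$statistic, dfs, x$p_value))
  invisible(x)
}

pooled_or_stop <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) < 2) {
    stop("degenerate data: all pooled observations identical", call. = FALSE)
  }
  pooled
}

median_table <- function(groups, grand_median) {
  above <- vapply(groups, function(g) sum(g > grand_median), numeric(1))
  rbind(above = above, at_or_below = lengths(groups) - above)
}

#' Brown-Mood k-sample median test
#'
#' Counts, per group, observations strictly above versus at-or-below the
#' grand median of the pooled sample, and tests homogeneity of those
#' proportions with a Pearson chi-square on the 2 x k table
#' (df = k - 1). Ties with the grand median fall in the at-or-below row.
#'
#' @param groups List of k >= 2 non-empty numeric vectors.
#' @param continuity Apply the Yates correction (2-group case only).
#'   Off by default so the two-group statistic matches the k-sample
#'   formula.
#' @return [sa_test] with the chi-square statistic, df, upper-tail
#'   p-value, the grand median and the 2 x k `table`.
#' @details The statistic depends on the data only through position
#'   relative to the pooled median, so it is invariant under any strictly
#'   increasing transformation. A pooled sample with all values identical
#'   (or with no observation above its median) is degenerate and raises
#'   an error.
#' @export
moods_median_test <- function(groups, continuity = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2, all(lengths(groups) > 0))
  pooled <- pooled_or_stop(groups)
  med <- stats::median(pooled)
  tab <- median_table(groups, med)
  if (any(rowSums(tab) == 0)) {
    stop("degenerate data: a median-table row is empty", call. = FALSE)
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  adj <- if (continuity && length(groups) == 2) pmin(abs(tab - E), 0.5) else 0
  stat <- sum((abs(tab - E) - adj)^2 / E)
  k <- length(groups)
  sa_test(method = "Brown-Mood median test",
          statistic = stat, df = k - 1L,
          p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
          grand_median = med, table = tab)
}

#' Two-sample median test, normal-deviate form
#'
#' Signed Z for the first sample's count above the pooled grand median
#' against its hypergeometric expectation; positive Z means sample `a`
#' sits above the pooled median more often than expected. Used for the
#' two-group (e.g. cross-species) contrasts.
#'
#' @param a,b Non-empty numeric vectors.
#' @return [sa_test] with the signed `statistic` (Z), `df = NULL`, the
#'   two-sided normal p-value and the underlying 2 x 2 `table`.
#' @details `Z^2` equals the uncorrected 2 x 2 Pearson chi-square times
#'   `(N - 1) / N` (the finite-population factor), because the
#'   hypergeometric variance conditions on both margins.
#' @export
two_sample_median_z <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  pooled <- pooled_or_stop(list(a, b))
  med <- stats::median(pooled)
  tab <- median_table(list(a = a, b = b), med)
  m <- sum(tab["above", ])
  N <- length(pooled)
  na <- length(a)
  e_a <- na * m / N
  v_a <- na * (N - na) * m * (N - m) / (N^2 * (N - 1))
  if (v_a <= 0) {
    stop("degenerate data: zero hypergeometric variance", call. = FALSE)
  }
  z <- (tab["above", "a"] - e_a) / sqrt(v_a)
  sa_test(method = "Brown-Mood two-sample median test (Z)",
          statistic = z, df = NULL,
          p_value = 2 * stats::pnorm(-abs(z)),
          grand_median = med, table = tab)
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA F on absolute deviations from each group's centre
#' (classic Levene uses the mean; `center = "median"` gives the
#' Brown-Forsythe variant), df = (k - 1, N - k).
#'
#' @param groups List of k >= 2 numeric vectors, each of length >= 2.
#' @param center `"mean"` (default) or `"median"`.
#' @return [sa_test] with the F statistic, both df and the p-value.
#' @export
levenes_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 2)) {
    stop("every group needs at least 2 members", call. = FALSE)
  }
  cfun <- if (center == "mean") mean else stats::median
  devs <- lapply(groups, function(g) abs(g - cfun(g)))
  x <- unlist(devs, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  an <- stats::anova(stats::lm(x ~ g))
  f <- an$`F value`[1]
  if (is.na(f)) f <- 0  # all deviations identical
  k <- length(groups)
  N <- length(x)
  sa_test(method = sprintf("Levene's test (%s-centred)", center),
          statistic = f, df = c(k - 1L, N - k),
          p_value = if (f == 0) 1 else an$`Pr(>F)`[1])
}

#' Post-hoc pairwise median tests
#'
#' Runs [moods_median_test()] on every unordered pair of groups, each pair
#' using its own pooled grand median, and adjusts the p-values for
#' multiplicity (Bonferroni by default; raw p-values always reported).
#'
#' @param groups Named list of k >= 3 numeric vectors (unnamed groups get
#'   `g1..gk`).
#' @param adjust Adjustment method passed to [stats::p.adjust()]
#'   (`"bonferroni"` or `"none"`).
#' @return Data frame with one row per pair: `group_a`, `group_b`,
#'   `statistic`, `df`, `p_raw`, `p_adjusted`.
#' @export
pairwise_posthoc_median <- function(groups, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(groups), length(groups) >= 3)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  pairs <- utils::combn(names(groups), 2)
  res <- apply(pairs, 2, function(pr) {
    tst <- moods_median_test(groups[pr])
    data.frame(group_a = pr[1], group_b = pr[2],
               statistic = tst$statistic, df = tst$df,
               p_raw = tst$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = adjust)
  out
}
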
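#' Inverse-variance weighted regression of allele frequency on effect-size ratio
#'
#' Fits `allele_freq ~ ratio` by weighted least squares (Gaussian family,
#' identity link), the model used for the pooled and per-category
#' frequency analyses. The deviance is the weighted residual sum of
#' squares; the residual standard error is `sqrt(deviance / df)`.
#'
#' @param records Data frame with columns `ratio`, `allele_freq` and
#'   `weight` (inverse-variance weights, all positive). Typically the SA
#'   subset of [snp_sa_stats()] output.
#' @return An object of class `sa_regression`: a list with elements
#'   `slope`, `slope_se`, `intercept`, `deviance`, `df`, `p_value`
#'   (t-test on the slope), `rse` and `n`.
#' @export
fit_weighted_regression <- function(records) {
  records <- check_regression_input(records)
  if (nrow(records) < 3) {
    stop("need at least 3 records to fit the weighted regression", call. = FALSE)
  }
  if (stats::var(records$ratio) == 0) {
    stop("effect-size ratio has zero variance: singular design", call. = FALSE)
  }
  fit <- stats::lm(allele_freq ~ ratio, data = records, weights = weight)
  sm <- summary(fit)
  co <- sm$coefficients
  dev <- sum(records$weight * stats::residuals(fit)^2)
  df <- fit$df.residual
  structure(list(
    slope = unname(co["ratio", "Estimate"]),
    slope_se = unname(co["ratio", "Std. Error"]),
    intercept = unname(co["(Intercept)", "Estimate"]),
    deviance = dev,
    df = df,
    p_value = unname(co["ratio", "Pr(>|t|)"]),
    rse = sqrt(dev / df),
    n = nrow(records)
  ), class = "sa_regression")
}

check_regression_input <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("ratio", "allele_freq", "weight")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(records$ratio))) {
    stop("non-finite effect-size ratios in input", call. = FALSE)
  }
  if (any(records$weight <= 0)) {
    stop("all weights must be positive", call. = FALSE)
  }
  records
}

#' @export
print.sa_regression <- function(x, ...) {
  cat(sprintf(
    "Weighted regression (n = %d): slope = %.4f +/- %.4f, p = %.3g\n  deviance = %.3f on %d df, RSE = %.4f\n",
    x$n, x$slope, x$slope_se, x$p_value, x$deviance, x$df, x$rse))
  invisible(x)
}

#' Category main-effect and interaction model for allele frequency
#'
#' Fits the full weighted Gaussian model
#' `allele_freq ~ ratio + category + ratio:category` and tests, by
#' deviance-difference F-tests against nested reductions, (i) the variant
#' functional category main effect (`ratio + category` vs `ratio`) and
#' (ii) the category-by-ratio interaction (full vs `ratio + category`).
#'
#' @param records Data frame with columns `ratio`, `allele_freq`, `weight`
#'   and `category`; at least two categories, each with at least 3 records.
#' @return List of class `sa_interaction` with elements `main_effect_test`
#'   and `interaction_test`, each an [sa_test] carrying the F statistic,
#'   numerator/denominator df, the deviance difference and the p-value.
#' @details Categories enter as a factor with lexicographic level order;
#'   the reported deviance-difference tests are invariant to that choice.
#'   When a reduced model already fits exactly (zero residual deviance)
#'   the corresponding statistic is reported as 0 with p = 1.
#' @export
fit_interaction_model <- function(records) {
  records <- check_regression_input(records)
  if (!"category" %in% names(records)) {
    stop("missing columns: category", call. = FALSE)
  }
  records$category <- factor(as.character(records$category))
  counts <- table(records$category)
  if (length(counts) < 2) {
    stop("need at least 2 categories", call. = FALSE)
  }
  small <- names(counts)[counts < 3]
  if (length(small)) {
    stop("category with fewer than 3 records: ", paste(small, collapse = ", "),
         call. = FALSE)
  }
  m_ratio <- stats::lm(allele_freq ~ ratio, data = records, weights = weight)
  m_add   <- stats::lm(allele_freq ~ ratio + category, data = records,
                       weights = weight)
  m_full  <- stats::lm(allele_freq ~ ratio * category, data = records,
                       weights = weight)
  wdev <- function(m) sum(records$weight * stats::residuals(m)^2)
  dev_full <- wdev(m_full)
  df_full <- m_full$df.residual
  nested_f <- function(m_reduced, m_bigger, label) {
    d_red <- wdev(m_reduced)
    d_big <- wdev(m_bigger)
    ddf <- m_reduced$df.residual - m_bigger$df.residual
    delta <- max(d_red - d_big, 0)
    tol <- 1e-10 * max(1, d_red)
    if (delta <= tol) {
      stat <- 0
      p <- 1
    } else if (dev_full <= tol) {
      stat <- Inf
      p <- 0
    } else {
      stat <- (delta / ddf) / (dev_full / df_full)
      p <- stats::pf(stat, ddf, df_full, lower.tail = FALSE)
    }
    sa_test(method = paste0("F-test (", label, ")"), statistic = stat,
            df = c(ddf, df_full), p_value = p, deviance_diff = delta)
  }
  structure(list(
    main_effect_test = nested_f(m_ratio, m_add, "category main effect"),
    interaction_test = nested_f(m_add, m_full, "ratio x category interaction")
  ), class = "sa_interaction")
}

#' @export
print.sa_interaction <- function(x, ...) {
  print(x$main_effect_test)
  print(x$interaction_test)
  invisible(x)
}

#' Category-stratified frequency regressions
#'
#' Fits [fit_weighted_regression()] to each variant functional category
#' separately. Categories with too few records (or a singular design) are
#' reported as skipped with the reason, never silently dropped.
#'
#' @param records As for [fit_interaction_model()].
#' @return Named list, one element per category present: either an
#'   `sa_regression` or a list with `skipped = TRUE` and `reason`.
#' @export
fit_stratified <- function(records) {
  records <- check_regression_input(records)
  if (!"category" %in% names(records)) {
    stop("missing columns: category", call. = FALSE)
  }
  cats <- sort(unique(as.character(records$category)))
  out <- lapply(cats, function(cat) {
    sub <- records[records$category == cat, , drop = FALSE]
    tryCatch(fit_weighted_regression(sub),
             error = function(e) list(skipped = TRUE, reason = conditionMessage(e),
                                      n = nrow(sub)))
  })
  names(out) <- cats
  out
}

#' Regression summary table
#'
#' Assembles the per-category and pooled weighted-regression results into
#' one table (functional category, n, slope, slope SE, deviance, p-value,
#' RSE), with skipped categories flagged.
#'
#' @param records As for [fit_interaction_model()].
#' @return Data frame with one row per category plus a `"pooled"` row.
#' @export
regression_table <- function(records) {
  strat <- fit_stratified(records)
  pooled <- fit_weighted_regression(records)
  row_of <- function(name, fit) {
    if (isTRUE(fit$skipped)) {
      data.frame(functional_category = name, n = fit$n, slope = NA_real_,
                 slope_se = NA_real_, deviance = NA_real_, p_value = NA_real_,
                 rse = NA_real_, skipped = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(functional_category = name, n = fit$n, slope = fit$slope,
                 slope_se = fit$slope_se, deviance = fit$deviance,
                 p_value = fit$p_value, rse = fit$rse, skipped = FALSE,
                 stringsAsFactors = FALSE)
    }
  }
  rows <- c(Map(row_of, names(strat), strat), list(row_of("pooled", pooled)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
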
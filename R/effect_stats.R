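#' Convert a z-score to Cohen's d
#'
#' Converts a standard-normal association statistic to a standardized
#' mean-difference effect size via the correlation scale: \eqn{r = z/\sqrt{n}},
#' then \eqn{d = 2r/\sqrt{1 - r^2}}. Both steps are exposed so an alternate
#' conversion chain can be substituted upstream.
#'
#' @param z Numeric vector of z-scores.
#' @param n Integer vector (or scalar) of sample sizes, recycled against `z`.
#'   Must be at least 2.
#' @return Numeric vector of Cohen's d values, same sign as `z`.
#' @details The conversion is undefined when `|z| / sqrt(n) >= 1`; such inputs
#'   raise an error rather than returning `NaN`.
#' @examples
#' z_to_cohens_d(2, 100)   # 0.4082...
#' z_to_cohens_d(0, 100)   # 0
#' @export
z_to_cohens_d <- function(z, n) {
  if (!is.numeric(z) || !is.numeric(n)) {
    stop("`z` and `n` must be numeric", call. = FALSE)
  }
  if (any(n < 2)) {
    stop("sample size must be at least 2", call. = FALSE)
  }
  r <- z / sqrt(n)
  if (any(abs(r) >= 1)) {
    stop("|z|/sqrt(n) >= 1: conversion to Cohen's d undefined", call. = FALSE)
  }
  2 * r / sqrt(1 - r^2)
}

#' Cross-sex effect-size ratio
#'
#' Ratio of the beneficial (positive) to the deleterious (negative) effect
#' size of a sexually antagonistic allele. Always negative for a valid SA
#' pair; values below -1 indicate the benefit outweighs the detriment.
#'
#' @param d_benefit Positive Cohen's d in the benefitting sex.
#' @param d_detriment Negative Cohen's d in the harmed sex.
#' @return `d_benefit / d_detriment`, a negative number.
#' @export
effect_size_ratio <- function(d_benefit, d_detriment) {
  if (any(d_detriment == 0)) {
    stop("deleterious effect size is zero: ratio undefined", call. = FALSE)
  }
  if (any(d_benefit <= 0) || any(d_detriment > 0)) {
    stop("not a sexually antagonistic pair: need d_benefit > 0 and d_detriment < 0",
         call. = FALSE)
  }
  d_benefit / d_detriment
}

#' Classify the net cross-sex effect of an allele
#'
#' An effect-size ratio below -1 means the beneficial effect in one sex
#' exceeds the deleterious effect in the other (net beneficial); above -1
#' the detriment dominates (net deleterious); exactly -1 is the boundary.
#'
#' @param ratio Numeric vector of (negative) effect-size ratios.
#' @return Character vector with values `"net_beneficial"`,
#'   `"net_deleterious"` or `"boundary"`.
#' @export
classify_net_effect <- function(ratio) {
  if (any(ratio >= 0)) {
    stop("effect-size ratio must be negative for an SA allele", call. = FALSE)
  }
  ifelse(ratio < -1, "net_beneficial",
         ifelse(ratio > -1, "net_deleterious", "boundary"))
}

#' Sexual antagonism index (SAI)
#'
#' Per-locus conflict-intensity proxy
#' \deqn{SAI = \frac{d_M d_F}{\sqrt{(d_M^2 + d_F^2)/2}}}
#' Negative for sexually antagonistic pairs (opposite-sign effects),
#' symmetric in its arguments, and scale-equivariant: scaling both effects
#' by c > 0 scales SAI by c, so it is proportional to the absolute
#' intensity of the antagonistic effects. For equal-and-opposite effects
#' `sai(d, -d) = -|d|`.
#'
#' @param d_male,d_female Cohen's d effect sizes in each sex.
#' @param denominator `"rms"` (default) uses the root-mean-square
#'   `sqrt((d_M^2 + d_F^2)/2)`, which keeps SAI in units of d;
#'   `"mean_square"` uses the unrooted mean square, retained as an
#'   alternative reading of the index.
#' @return Numeric vector of SAI values.
#' @export
sai <- function(d_male, d_female, denominator = c("rms", "mean_square")) {
  denominator <- match.arg(denominator)
  if (any(d_male == 0 & d_female == 0)) {
    stop("SAI undefined when both effect sizes are zero", call. = FALSE)
  }
  ms <- (d_male^2 + d_female^2) / 2
  den <- if (denominator == "rms") sqrt(ms) else ms
  d_male * d_female / den
}

#' Per-SNP sexual-antagonism statistics
#'
#' Augments a validated SNP table with the quantities the downstream
#' analyses consume: the SAI, a sexual-antagonism flag (opposite-sign,
#' nonzero effects in the two sexes), the effect-size ratio (benefit over
#' detriment, `NA` for non-SA records) and the net-effect class.
#'
#' @param snps Data frame with at least columns `d_male`, `d_female`
#'   (see [read_snp_table()] for the full schema).
#' @return The input with columns `sai`, `is_sa`, `ratio` and `net_effect`
#'   appended.
#' @export
snp_sa_stats <- function(snps) {
  stopifnot(is.data.frame(snps), all(c("d_male", "d_female") %in% names(snps)))
  dm <- snps$d_male
  df_ <- snps$d_female
  snps$sai <- sai(dm, df_)
  snps$is_sa <- dm != 0 & df_ != 0 & sign(dm) != sign(df_)
  benefit <- pmax(dm, df_)
  detriment <- pmin(dm, df_)
  snps$ratio <- NA_real_
  snps$ratio[snps$is_sa] <-
    effect_size_ratio(benefit[snps$is_sa], detriment[snps$is_sa])
  snps$net_effect <- NA_character_
  snps$net_effect[snps$is_sa] <- classify_net_effect(snps$ratio[snps$is_sa])
  snps
}
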
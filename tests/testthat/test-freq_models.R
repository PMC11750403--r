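test_that("weighted regression recovers exact and degenerate fits", {
  # collinear points: exact fit
  rec <- data.frame(ratio = c(-2, -1, 0), allele_freq = c(0.40, 0.30, 0.20),
                    weight = 1)
  fit <- suppressWarnings(fit_weighted_regression(rec))
  expect_equal(fit$slope, -0.10)
  expect_equal(fit$deviance, 0, tolerance = 1e-12)
  expect_equal(fit$rse, 0, tolerance = 1e-6)
  # flat response: zero slope
  rec2 <- data.frame(ratio = c(-3, -2, -1, -0.5), allele_freq = 0.25,
                     weight = c(1, 2, 3, 4))
  fit2 <- suppressWarnings(fit_weighted_regression(rec2))
  expect_equal(fit2$slope, 0, tolerance = 1e-12)

  expect_error(fit_weighted_regression(rec[1:2, ]), "at least 3")
  rec3 <- data.frame(ratio = -1, allele_freq = c(0.1, 0.2, 0.3), weight = 1)
  expect_error(fit_weighted_regression(rec3), "singular")
  rec4 <- make_records(20, -0.1)
  rec4$weight[3] <- 0
  expect_error(fit_weighted_regression(rec4), "positive")
})

test_that("equal weights reduce to OLS and weights matter only relatively", {
  rec <- make_records(40, slope = -0.08, seed = 3)
  rec$weight <- 1
  fit <- fit_weighted_regression(rec)
  # closed-form OLS oracle
  x <- rec$ratio; y <- rec$allele_freq
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$slope, b, tolerance = 1e-10)
  expect_equal(fit$deviance, sum((y - (mean(y) - b * mean(x)) - b * x)^2),
               tolerance = 1e-10)
  expect_equal(fit$rse, sqrt(fit$deviance / (nrow(rec) - 2)))
  # doubling weights changes deviance scale but not inference
  rec2 <- make_records(40, slope = -0.08, seed = 4)
  f1 <- fit_weighted_regression(rec2)
  rec2$weight <- rec2$weight * 2
  f2 <- fit_weighted_regression(rec2)
  expect_equal(f2$slope, f1$slope)
  expect_equal(f2$slope_se, f1$slope_se)
  expect_equal(f2$p_value, f1$p_value)
})

test_that("slope recovery from the generator at a known truth", {
  cfg <- synthetic_config(n_genes = 50, snps_per_gene = 10,
                          freq_slope = -0.15, freq_noise_sd = 0.05, seed = 11)
  sim <- generate_snp_table(cfg)
  rec <- snp_sa_stats(sim$snps)
  # fit on records whose frequency could not have been truncated
  # (ratio in the band where intercept + slope*ratio stays 3 noise-sd
  # inside (0.005, 0.5]); conditioning on a regressor leaves WLS unbiased
  lo <- (0.005 + 3 * cfg$freq_noise_sd - cfg$freq_intercept) / cfg$freq_slope
  hi <- (0.5 - 3 * cfg$freq_noise_sd - cfg$freq_intercept) / cfg$freq_slope
  keep <- rec$ratio >= hi & rec$ratio <= lo
  expect_gt(sum(keep), 100)
  fit <- fit_weighted_regression(rec[keep, ])
  expect_lt(abs(fit$slope - (-0.15)), 3 * fit$slope_se)
})

test_that("interaction model detects different slopes and not identical ones", {
  # identical generating model, no noise: both tests null
  x <- rep(seq(-3, -0.5, length.out = 20), 2)
  rec <- data.frame(ratio = x, allele_freq = 0.3 + 0.05 * x, weight = 1,
                    category = rep(c("missense", "synonymous"), each = 20))
  res <- fit_interaction_model(rec)
  expect_equal(res$main_effect_test$statistic, 0)
  expect_equal(res$main_effect_test$p_value, 1)
  expect_equal(res$interaction_test$statistic, 0)
  expect_equal(res$interaction_test$p_value, 1)

  # one dataset duplicated under two labels: category adds nothing
  set.seed(8)
  base <- make_records(60, -0.1, noise_sd = 0.03, seed = 8)
  dup <- rbind(cbind(base, category = "missense"),
               cbind(base, category = "regulatory"))
  res2 <- fit_interaction_model(dup)
  expect_equal(res2$interaction_test$statistic, 0)
  expect_equal(res2$main_effect_test$statistic, 0)

  # built-in slope difference: -0.05 vs -0.25, n = 500 each, sd 0.05
  set.seed(99)
  mk <- function(slope, n) data.frame(
    ratio = -runif(n, 0.2, 3),
    weight = 1)
  a <- mk(-0.05, 500)
  a$allele_freq <- 0.35 - 0.05 * a$ratio + rnorm(500, 0, 0.05)
  b <- mk(-0.25, 500)
  b$allele_freq <- 0.35 - 0.25 * b$ratio + rnorm(500, 0, 0.05)
  both <- rbind(cbind(a, category = "missense"),
                cbind(b, category = "synonymous"))
  res3 <- fit_interaction_model(both)
  expect_lt(res3$interaction_test$p_value, 0.01)
  # cross-check against a from-scratch nested F computation
  w <- both$weight
  m_add <- lm(allele_freq ~ ratio + category, data = both, weights = w)
  m_full <- lm(allele_freq ~ ratio * category, data = both, weights = w)
  d_add <- sum(w * resid(m_add)^2); d_full <- sum(w * resid(m_full)^2)
  f_oracle <- ((d_add - d_full) / 1) / (d_full / m_full$df.residual)
  expect_equal(res3$interaction_test$statistic, f_oracle, tolerance = 1e-10)

  # full-model deviance never exceeds a nested reduction's
  expect_lte(d_full, d_add)

  small <- rbind(cbind(make_records(10, -0.1), category = "missense"),
                 cbind(make_records(2, -0.1), category = "synonymous"))
  expect_error(fit_interaction_model(small), "synonymous")
})

test_that("stratified fits match per-category pooled fits and report skips", {
  rec <- make_records(30, -0.12, seed = 5)
  rec$category <- "regulatory"
  strat <- fit_stratified(rec)
  expect_length(strat, 1)
  pooled <- fit_weighted_regression(rec)
  expect_equal(strat$regulatory$slope, pooled$slope)
  expect_equal(strat$regulatory$deviance, pooled$deviance)

  # per-category truths at the reported slope magnitudes
  set.seed(21)
  mk <- function(slope, cat, n = 800) {
    r <- make_records(n, slope, noise_sd = 0.04, seed = match(cat,
      c("missense", "synonymous", "regulatory")))
    r$category <- cat
    r
  }
  rec3 <- rbind(mk(-0.215, "missense"), mk(-0.143, "synonymous"),
                mk(-0.107, "regulatory"))
  # regenerate the frequencies at each category's own slope
  strat3 <- fit_stratified(rec3)
  expect_setequal(names(strat3), c("missense", "synonymous", "regulatory"))
  truths <- c(missense = -0.215, synonymous = -0.143, regulatory = -0.107)
  for (cat in names(truths)) {
    f <- strat3[[cat]]
    expect_lt(abs(f$slope - truths[[cat]]), 3 * f$slope_se)
  }

  # a category too small to fit is reported as skipped, not dropped
  rec4 <- rbind(mk(-0.1, "missense", 30),
                cbind(make_records(2, -0.1), category = "synonymous"))
  strat4 <- fit_stratified(rec4)
  expect_true(strat4$synonymous$skipped)
  expect_match(strat4$synonymous$reason, "at least 3")
  tab <- regression_table(rec4)
  expect_true(tab$skipped[tab$functional_category == "synonymous"])
  expect_equal(tab$functional_category[nrow(tab)], "pooled")
})
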
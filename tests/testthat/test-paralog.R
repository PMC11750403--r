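test_that("family construction matches union-find by hand and validates input", {
  pairs <- data.frame(gene_a = c("A", "B", "D"), gene_b = c("B", "C", "E"),
                      diopt_score = c(3, 1, 0))
  res <- build_paralog_families(pairs, LETTERS[1:5])
  fam <- unname(lapply(split(res$families$gene_id, res$families$family_id),
                       sort))
  fam <- fam[order(vapply(fam, "[", "", 1))]
  expect_equal(fam, list(c("A", "B", "C"), "D", "E"))
  counts <- setNames(res$counts$n_paralogs, res$counts$gene_id)
  expect_equal(counts[c("A", "B", "C", "D", "E")],
               c(A = 1L, B = 2L, C = 1L, D = 0L, E = 0L))
  expect_equal(res$n_families, 3)

  # no pairs: all singletons
  res0 <- build_paralog_families(pairs[0, ], LETTERS[1:4])
  expect_equal(res0$n_families, 4)
  expect_true(all(res0$counts$n_paralogs == 0))

  # raising min_score never merges families or increases counts
  res2 <- build_paralog_families(pairs, LETTERS[1:5], min_score = 2)
  expect_gte(res2$n_families, res$n_families)
  expect_true(all(res2$counts$n_paralogs <= res$counts$n_paralogs))

  expect_error(build_paralog_families(
    data.frame(gene_a = "A", gene_b = "A", diopt_score = 2), "A"), "self-pair")
  expect_error(build_paralog_families(
    data.frame(gene_a = c("A", "B"), gene_b = c("B", "A"),
               diopt_score = c(2, 5)), c("A", "B")), "conflicting")
  # duplicate pair with the same score is deduplicated, not an error
  resd <- build_paralog_families(
    data.frame(gene_a = c("A", "B"), gene_b = c("B", "A"),
               diopt_score = c(2, 2)), c("A", "B"))
  expect_equal(resd$counts$n_paralogs, c(1L, 1L))

  # family-size count option bounds the partner count from above
  resf <- build_paralog_families(pairs, LETTERS[1:5], count = "family")
  expect_equal(setNames(resf$counts$n_paralogs, resf$counts$gene_id)[["B"]], 2L)
})

test_that("families equal a transitive-closure oracle on random small graphs", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    universe <- paste0("g", sprintf("%02d", seq_len(n)))
    n_edges <- sample(0:(n + 2), 1)
    if (n_edges > 0) {
      ab <- t(replicate(n_edges, sample(universe, 2)))
      pairs <- unique(data.frame(gene_a = pmin(ab[, 1], ab[, 2]),
                                 gene_b = pmax(ab[, 1], ab[, 2]),
                                 stringsAsFactors = FALSE))
      pairs$diopt_score <- sample(1:5, nrow(pairs), replace = TRUE)
    } else {
      pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                          diopt_score = integer(0))
    }
    res <- build_paralog_families(pairs, universe)
    oracle <- oracle_families(pairs, universe)
    ours <- split(res$families$gene_id, res$families$family_id)
    canon <- function(f) sort(unname(vapply(f, function(x) paste(sort(x),
                                                                 collapse = ","), "")))
    expect_equal(canon(ours), canon(oracle))
    # partition conservation and the family-size bound on counts
    expect_equal(sum(lengths(ours)), n)
    fam_size <- setNames(rep(lengths(ours), lengths(ours)), unlist(ours))
    expect_true(all(res$counts$n_paralogs <=
                      fam_size[res$counts$gene_id] - 1))
  }
})

test_that("per-tertile paralogue proportions test against a background panel", {
  # proportions equal to background: exactly zero statistic
  gs <- data.frame(tertile = rep(c("low", "medium", "high"), each = 10),
                   has_paralog = rep(c(TRUE, FALSE), 15))
  res <- proportion_with_paralogs_test(gs, 5000, 5000)
  expect_equal(nrow(res), 3)
  expect_equal(res$statistic, rep(0, 3), tolerance = 1e-12)
  expect_equal(res$proportion, rep(0.5, 3))

  # longhand 2x2 check: 27/23 vs 5000/5000
  gs2 <- data.frame(tertile = "high",
                    has_paralog = rep(c(TRUE, FALSE), c(27, 23)))
  res2 <- proportion_with_paralogs_test(gs2, 5000, 5000)
  tab <- rbind(c(27, 23), c(5000, 5000))
  expect_equal(res2$statistic, oracle_pearson_chisq(tab))
  expect_equal(res2$df, 1L)
  # chi-square invariant under transposing the 2x2
  expect_equal(oracle_pearson_chisq(tab), oracle_pearson_chisq(t(tab)))

  # tiny background triggers the low-expected flag
  gs3 <- data.frame(tertile = "low", has_paralog = c(TRUE, rep(FALSE, 40)))
  res3 <- proportion_with_paralogs_test(gs3, 1, 60)
  expect_true(res3$low_expected)
})

test_that("rank-sum test matches exhaustive enumeration and is rank-invariant", {
  # full enumeration on the spec's small instance
  o <- oracle_wilcoxon_exact(c(1, 2), c(3, 4))
  tst <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(tst$statistic, o$W)
  expect_true(tst$exact)
  expect_equal(tst$p_value, o$p)

  set.seed(5)
  for (i in 1:50) {
    nx <- sample(2:4, 1); ny <- sample(2:4, 1)
    x <- runif(nx); y <- runif(ny)  # continuous: no ties
    o <- oracle_wilcoxon_exact(x, y)
    tst <- wilcoxon_rank_sum(x, y)
    expect_equal(tst$statistic, o$W)
    expect_equal(tst$p_value, o$p)
    # agreement with the standard implementation's exact p
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(tst$p_value, ref$p.value)
    expect_equal(tst$u, unname(ref$statistic))
  }

  # identical samples: p ~ 1; shift invariance of W and p
  t0 <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_gte(t0$p_value, 0.99)
  a <- rnorm(30); b <- rnorm(40)
  t1 <- wilcoxon_rank_sum(a, b)
  t2 <- wilcoxon_rank_sum(a + 100, b + 100)
  expect_equal(t1$statistic, t2$statistic)
  expect_equal(t1$p_value, t2$p_value)

  # tie-corrected normal branch agrees with wilcox.test(correct = FALSE)
  set.seed(6)
  x <- sample(1:5, 40, replace = TRUE)
  y <- sample(2:6, 45, replace = TRUE)
  tn <- wilcoxon_rank_sum(x, y)
  expect_false(tn$exact)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(tn$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(tn$u, unname(ref$statistic))
})

test_that("tertile count comparisons filter zeros and detect built-in elevation", {
  res <- paralog_count_tertile_tests(c(0, 0, 2, 3),
                                     c("low", "medium", "low", "medium"),
                                     restrict_to_positive = TRUE)
  expect_equal(res$n_a + res$n_b, 2L)  # {2, 3} survive the filter

  # all counts equal across tertiles: p ~ 1 everywhere
  eq <- paralog_count_tertile_tests(rep(2, 60),
                                    rep(c("low", "medium", "high"), 20))
  expect_true(all(eq$p_value[!eq$skipped] > 0.99))

  # a tertile emptied by the filter is skipped with a reason
  res2 <- paralog_count_tertile_tests(c(0, 0, 1, 2, 3, 4),
                                      c("low", "low", "medium", "medium",
                                        "high", "high"))
  expect_true(all(res2$skipped[res2$group_a == "low" | res2$group_b == "low"]))
  expect_equal(nrow(res2), 3)
})

test_that("generator with elevated medium/high counts is detected with power", {
  # count mean multiplied by exp(0.5 * tertile index); n = 120 genes per
  # tertile keeps the rank-sum comparisons well powered
  reps <- 60
  hits_lm <- hits_lh <- logical(reps)
  rzt <- function(n, m) {
    lam <- uniroot(function(l) l / (1 - exp(-l)) - m, c(1e-9, m))$root
    qpois(exp(-lam) + runif(n) * (1 - exp(-lam)), lam)
  }
  set.seed(31)
  for (i in seq_len(reps)) {
    low <- rzt(120, 2.5)
    med <- rzt(120, 2.5 * exp(0.5))
    high <- rzt(120, 2.5 * exp(1.0))
    res <- paralog_count_tertile_tests(
      c(low, med, high), rep(c("low", "medium", "high"), each = 120),
      restrict_to_positive = TRUE)
    hits_lm[i] <- res$p_value[res$group_a == "low" &
                                res$group_b == "medium"] < 0.05
    hits_lh[i] <- res$p_value[res$group_a == "low" &
                                res$group_b == "high"] < 0.05
  }
  expect_gte(mean(hits_lm), 0.8)
  expect_gte(mean(hits_lh), 0.8)
})
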
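test_that("generators are pure functions of config and seed", {
  cfg <- synthetic_config(n_genes = 30, seed = 42)
  s1 <- generate_snp_table(cfg)
  s2 <- generate_snp_table(cfg)
  expect_identical(s1, s2)
  gc <- merge(s1$genes, pool_gene_sai(s1$snps, "all"), by = "gene_id")
  m1 <- generate_recomb_map(cfg, gc)
  m2 <- generate_recomb_map(cfg, gc)
  expect_identical(m1, m2)
  gc$tertile <- assign_tertiles(gc$mean_sai, gc$gene_id)
  gc2 <- assign_recomb_rate(gc, m1)
  p1 <- generate_paralog_pairs(cfg, gc2, gc2)
  p2 <- generate_paralog_pairs(cfg, gc2, gc2)
  expect_identical(p1, p2)
  l1 <- generate_liftover_map(cfg, 1e5)
  l2 <- generate_liftover_map(cfg, 1e5)
  expect_identical(l1, l2)
  # a different seed changes the data
  s3 <- generate_snp_table(synthetic_config(n_genes = 30, seed = 43))
  expect_false(identical(s1$snps, s3$snps))
})

test_that("SNP tables respect the schema and encode the truth", {
  cfg <- synthetic_config(n_genes = 10, snps_per_gene = 3, seed = 2)
  sim <- generate_snp_table(cfg)
  expect_silent(validate_snp_table(sim$snps))
  expect_true(all(sim$snps$gene_id %in% sim$genes$gene_id))
  expect_equal(length(unique(sim$genes$gene_id)), 10)
  # genes non-overlapping and SNPs inside their genes
  g <- sim$genes[order(sim$genes$start), ]
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  idx <- match(sim$snps$gene_id, sim$genes$gene_id)
  expect_true(all(sim$snps$pos > sim$genes$start[idx] &
                    sim$snps$pos <= sim$genes$end[idx]))
  # every SNP is sexually antagonistic with opposite-sign effects
  expect_true(all(sign(sim$snps$d_male) != sign(sim$snps$d_female)))
  expect_true(all(sim$snps$allele_freq > 0 & sim$snps$allele_freq <= 0.5))
  # truth latents reproduce the observable ratio
  st <- snp_sa_stats(sim$snps)
  expect_equal(st$ratio, sim$truth$snp_latents$ratio)
  expect_equal(st$sai, sim$truth$snp_latents$sai)
  # clamp bookkeeping is consistent
  tr <- sim$truth$snp_latents
  expect_equal(sim$snps$allele_freq[!tr$clamped], tr$freq_raw[!tr$clamped])
})

test_that("noise-free generation recovers the frequency slope exactly", {
  cfg <- synthetic_config(n_genes = 40, freq_noise_sd = 0, seed = 9)
  sim <- generate_snp_table(cfg)
  rec <- snp_sa_stats(sim$snps)
  keep <- !sim$truth$snp_latents$clamped
  fit <- suppressWarnings(fit_weighted_regression(rec[keep, ]))
  expect_equal(fit$slope, cfg$freq_slope, tolerance = 1e-10)
  expect_equal(fit$intercept, cfg$freq_intercept, tolerance = 1e-10)
})

test_that("recombination map tiles the chromosome and encodes the conflict effect", {
  cfg <- synthetic_config(n_genes = 60, sai_recomb_effect = 1, seed = 12)
  sim <- generate_snp_table(cfg)
  gc <- merge(sim$genes, pool_gene_sai(sim$snps, "all"), by = "gene_id")
  win <- generate_recomb_map(cfg, gc)
  # exact tiling: contiguous, equal width, covering all genes
  expect_true(all(win$start[-1] == win$end[-nrow(win)]))
  expect_true(all(win$end - win$start == cfg$window_size))
  expect_gte(max(win$end), max(gc$end))
  expect_true(all(win$rate_cM_per_Mb >= 0))

  # under the null the same seed's base rates are untouched; with the
  # effect on, exactly the high-tertile-overlapping windows are scaled
  cfg2 <- synthetic_config(n_genes = 60, sai_recomb_effect = 2, seed = 12)
  win2 <- generate_recomb_map(cfg2, gc)
  ratio <- win2$rate_cM_per_Mb / win$rate_cM_per_Mb
  expect_true(all(abs(ratio - 1) < 1e-12 | abs(ratio - 2) < 1e-12))
  tert <- assign_tertiles(gc$mean_sai, gc$gene_id)
  hi <- gc[tert == "high", ]
  touched <- vapply(seq_len(nrow(win)), function(i)
    any(hi$start < win$end[i] & hi$end > win$start[i]), logical(1))
  expect_equal(abs(ratio - 2) < 1e-12, touched)
})

test_that("paralogue generation responds to conflict and recombination", {
  cfg <- synthetic_config(n_genes = 90, seed = 5)
  sim <- generate_snp_table(cfg)
  gc <- merge(sim$genes, pool_gene_sai(sim$snps, "all"), by = "gene_id")
  gc$tertile <- assign_tertiles(gc$mean_sai, gc$gene_id)
  gc$recomb_rate <- rlnorm(nrow(gc), log(2), 0.5)
  pg <- generate_paralog_pairs(cfg, gc, gc)
  expect_true(all(pg$pairs$diopt_score >= 1 & pg$pairs$diopt_score <= 15))
  expect_true(all(pg$pairs$gene_a != pg$pairs$gene_b))
  expect_equal(nrow(pg$background_genes), cfg$n_background_genes)
  # universe covers SA genes, background and partners
  expect_true(all(c(pg$pairs$gene_a, pg$pairs$gene_b) %in% pg$gene_universe))

  # null configuration: proportions statistically flat across tertiles
  cfg0 <- synthetic_config(n_genes = 150, paralog_recomb_coef = 0,
                           paralog_sai_coef = 0, seed = 6)
  sim0 <- generate_snp_table(cfg0)
  gc0 <- merge(sim0$genes, pool_gene_sai(sim0$snps, "all"), by = "gene_id")
  gc0$tertile <- assign_tertiles(gc0$mean_sai, gc0$gene_id)
  gc0$recomb_rate <- rlnorm(nrow(gc0), log(2), 0.5)
  pg0 <- generate_paralog_pairs(cfg0, gc0, gc0)
  fam0 <- build_paralog_families(pg0$pairs, pg0$gene_universe)
  gs0 <- merge(gc0[, c("gene_id", "tertile")], fam0$counts, by = "gene_id")
  gs0$has_paralog <- gs0$n_paralogs > 0
  res0 <- proportion_with_paralogs_test(
    gs0, sum(pg0$background_genes$has_paralog),
    sum(!pg0$background_genes$has_paralog))
  expect_true(all(res0$p_value > 0.001))
  expect_true(all(abs(res0$proportion -
                        mean(pg0$background_genes$has_paralog)) < 0.2))
})

test_that("liftover map generation is invertible with bounded unmapped mass", {
  cfg <- synthetic_config(unmapped_frac = 0.05, seed = 19)
  span <- 500000
  map <- generate_liftover_map(cfg, span)
  pos <- seq(1, span, by = 101)
  fwd <- liftover(rep("chrS", length(pos)), pos, map)
  frac_unmapped <- mean(!fwd$mapped)
  expect_lt(frac_unmapped, 0.20)
  inv <- invert_liftover_map(map)
  back <- liftover(fwd$chrom[fwd$mapped], fwd$pos[fwd$mapped], inv)
  expect_equal(back$pos, pos[fwd$mapped])
})
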
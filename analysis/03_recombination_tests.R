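#!/usr/bin/env Rscript
# Step 3: conflict intensity versus recombination rate.
#
# SNPs (and genes, via their pooled missense SAI) are lifted to the
# assembly of the recombination map, given the length-weighted mean rate
# of overlapping windows, and split into conflict tertiles by the
# sexual-antagonism index (most negative SAI = "high" conflict). The
# Brown-Mood median test asks whether median recombination rate differs
# across tertiles; Levene's test compares spread; pairwise post-hoc
# median tests (Bonferroni) localise any difference.
#
# Reads  results/inputs/{snps,genes,map,lift}.tsv
# Writes results/recombination/recomb_tests.tsv
#        results/recombination/gene_conflicts.tsv

suppressPackageStartupMessages(library(saconflict))

out_dir <- "results/recombination"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

snps <- read_snp_table("results/inputs/snps.tsv")
genes <- read_gene_intervals("results/inputs/genes.tsv")
win <- read_recomb_map("results/inputs/map.tsv")
lift <- read_liftover_map("results/inputs/lift.tsv")

## gene level: pool missense SAI per gene, lift, rate, tertile, test
gconf <- merge(genes, pool_gene_sai(snps, "missense"), by = "gene_id")
p1 <- liftover(gconf$chrom, gconf$start + 1L, lift)
p2 <- liftover(gconf$chrom, gconf$end, lift)
ok <- p1$mapped & p2$mapped
message(sprintf("liftover: %d of %d genes mapped", sum(ok), nrow(gconf)))
gconf <- gconf[ok, ]
gconf$start <- p1$pos[ok] - 1L
gconf$end <- p2$pos[ok]
gconf <- assign_recomb_rate(gconf, win)
gconf <- gconf[!is.na(gconf$recomb_rate), ]
gconf$tertile <- assign_tertiles(gconf$mean_sai, gconf$gene_id)
write_tsv(gconf, file.path(out_dir, "gene_conflicts.tsv"))

rows <- list()
add_test <- function(analysis, tst, p_adjusted = NA_real_) {
  rows[[length(rows) + 1]] <<- data.frame(
    analysis = analysis, method = tst$method, statistic = tst$statistic,
    df = paste(tst$df, collapse = ","), p_raw = tst$p_value,
    p_adjusted = p_adjusted)
}

g_groups <- split(gconf$recomb_rate, gconf$tertile)
add_test("gene_level_median", moods_median_test(g_groups))
add_test("gene_level_levene", levenes_test(g_groups))

## SNP level: every variant carries its own SAI
pts <- data.frame(chrom = snps$chrom, start = snps$pos - 1L, end = snps$pos,
                  snp_id = snps$snp_id,
                  sai = sai(snps$d_male, snps$d_female),
                  category = snps$category)
q1 <- liftover(pts$chrom, pts$end, lift)
pts <- pts[q1$mapped, ]
pts$start <- q1$pos[q1$mapped] - 1L
pts$end <- q1$pos[q1$mapped]
pts <- assign_recomb_rate(pts, win)
pts <- pts[!is.na(pts$recomb_rate), ]
pts$tertile <- assign_tertiles(pts$sai, pts$snp_id)
s_groups <- split(pts$recomb_rate, pts$tertile)
add_test("all_variants_median", moods_median_test(s_groups))
add_test("all_variants_levene", levenes_test(s_groups))
post <- pairwise_posthoc_median(s_groups, adjust = "bonferroni")
for (i in seq_len(nrow(post))) {
  rows[[length(rows) + 1]] <- data.frame(
    analysis = sprintf("all_variants_posthoc_%s_vs_%s",
                       post$group_a[i], post$group_b[i]),
    method = "Brown-Mood median test", statistic = post$statistic[i],
    df = as.character(post$df[i]), p_raw = post$p_raw[i],
    p_adjusted = post$p_adjusted[i])
}

## per functional category
for (cat in sort(unique(pts$category))) {
  sub <- pts[pts$category == cat, ]
  if (nrow(sub) >= 9) {
    tert <- assign_tertiles(sub$sai, sub$snp_id)
    add_test(paste0("category_", cat, "_median"),
             moods_median_test(split(sub$recomb_rate, tert)))
  }
}

tests <- do.call(rbind, rows)
write_test_results(tests, file.path(out_dir, "recomb_tests.tsv"))
print(tests, digits = 4)
message("wrote recombination tables to ", out_dir)
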
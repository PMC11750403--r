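#!/usr/bin/env Rscript
# Step 2: allele-frequency models.
#
# For every sexually antagonistic SNP we form the cross-sex effect-size
# ratio (benefit effect / detriment effect, always negative) and regress
# minor-allele frequency on it with inverse-variance weights. A more
# negative ratio means the benefit outweighs the detriment, so under
# balancing selection the slope should be negative. We fit the pooled
# model, a ratio x functional-category interaction model, and
# per-category stratified models.
#
# Reads  results/inputs/snps.tsv
# Writes results/frequency/regression_table.tsv
#        results/frequency/interaction_tests.tsv

suppressPackageStartupMessages(library(saconflict))

out_dir <- "results/frequency"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

snps <- read_snp_table("results/inputs/snps.tsv")
rec <- snp_sa_stats(snps)
rec <- rec[rec$is_sa, ]
message(sprintf("%d of %d SNPs have opposite-sign effects (sexually antagonistic)",
                nrow(rec), nrow(snps)))

reg <- regression_table(rec)
write_tsv(reg, file.path(out_dir, "regression_table.tsv"))
print(reg, digits = 4)

inter <- fit_interaction_model(rec)
print(inter)
write_test_results(
  rbind(
    data.frame(analysis = "category_main_effect",
               method = inter$main_effect_test$method,
               statistic = inter$main_effect_test$statistic,
               df = paste(inter$main_effect_test$df, collapse = ","),
               p_raw = inter$main_effect_test$p_value, p_adjusted = NA_real_),
    data.frame(analysis = "ratio_category_interaction",
               method = inter$interaction_test$method,
               statistic = inter$interaction_test$statistic,
               df = paste(inter$interaction_test$df, collapse = ","),
               p_raw = inter$interaction_test$p_value, p_adjusted = NA_real_)),
  file.path(out_dir, "interaction_tests.tsv"))

message("wrote frequency-model tables to ", out_dir)
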
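#!/usr/bin/env Rscript
# Step 4: gene duplication versus conflict and recombination.
#
# Paralogue families are the connected components of the scored pair
# graph; a gene's paralogue count is its number of distinct direct
# partners. Three questions:
#   (1) is the proportion of genes with at least one paralogue elevated
#       in high-conflict tertiles relative to the genome-wide background
#       (2x2 Pearson chi-square per tertile)?
#   (2) among genes that have paralogues, do counts differ between
#       tertiles (pairwise Wilcoxon rank-sum)?
#   (3) do genes with paralogues sit in regions of higher recombination
#       (Wilcoxon rank-sum on rates, all rated genes)?
#
# Reads  results/inputs/pairs.tsv, results/inputs/genes.tsv,
#        results/inputs/map.tsv, results/recombination/gene_conflicts.tsv
# Writes results/paralogs/{paralog_proportions,paralog_count_tests,
#        paralog_tests}.tsv

suppressPackageStartupMessages(library(saconflict))

out_dir <- "results/paralogs"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

pairs <- read_paralog_pairs("results/inputs/pairs.tsv")
genes <- read_gene_intervals("results/inputs/genes.tsv")
win <- read_recomb_map("results/inputs/map.tsv")
gconf <- utils::read.delim("results/recombination/gene_conflicts.tsv")

universe <- unique(c(genes$gene_id, pairs$gene_a, pairs$gene_b))
fam <- build_paralog_families(pairs, universe)
message(sprintf("%d genes in %d families from %d pairs",
                nrow(fam$families), fam$n_families, nrow(pairs)))

gstat <- merge(gconf[, c("gene_id", "tertile", "recomb_rate")], fam$counts,
               by = "gene_id")
gstat$has_paralog <- gstat$n_paralogs > 0

# background: annotated genes outside the conflict analysis set
bg <- fam$counts[fam$counts$gene_id %in%
                   setdiff(genes$gene_id, gconf$gene_id), ]
prop <- proportion_with_paralogs_test(gstat, sum(bg$n_paralogs > 0),
                                      sum(bg$n_paralogs == 0))
write_tsv(prop, file.path(out_dir, "paralog_proportions.tsv"))
print(prop, digits = 4)

counts <- paralog_count_tertile_tests(gstat$n_paralogs, gstat$tertile,
                                      restrict_to_positive = TRUE)
write_tsv(counts, file.path(out_dir, "paralog_count_tests.tsv"))
print(counts, digits = 4)

# recombination of with- vs without-paralogue genes, conflict set plus
# rated background genes
bg_rates <- assign_recomb_rate(merge(genes, bg, by = "gene_id"), win)
bg_rates <- bg_rates[!is.na(bg_rates$recomb_rate), ]
all_rates <- rbind(
  data.frame(recomb_rate = gstat$recomb_rate, has = gstat$has_paralog),
  data.frame(recomb_rate = bg_rates$recomb_rate,
             has = bg_rates$n_paralogs > 0))
wp <- wilcoxon_rank_sum(all_rates$recomb_rate[all_rates$has],
                        all_rates$recomb_rate[!all_rates$has])
print(wp)
write_test_results(
  data.frame(analysis = "genes_with_vs_without_paralogs_recomb",
             method = wp$method, statistic = wp$statistic,
             df = NA_character_, p_raw = wp$p_value,
             p_adjusted = NA_real_),
  file.path(out_dir, "paralog_tests.tsv"))

message("wrote paralogue tables to ", out_dir)
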
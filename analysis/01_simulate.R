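#!/usr/bin/env Rscript
# Step 1: generate a complete synthetic study and write every input
# table to disk, exactly as a real study would provide them.
#
# Outputs (results/inputs/):
#   snps.tsv   - per-SNP sex-specific effects, category, allele frequency
#   genes.tsv  - gene intervals in the source assembly
#   map.tsv    - windowed recombination map in the target assembly
#   pairs.tsv  - scored paralogue pairs
#   lift.tsv   - assembly liftover blocks
#
# Downstream steps (02-04) read these files back, so the whole analysis
# can be re-run against real data by swapping the files in results/inputs.

suppressPackageStartupMessages(library(saconflict))

out_dir <- "results/inputs"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = 20240101)

sim <- generate_snp_table(cfg)
message(sprintf("simulated %d SNPs across %d genes",
                nrow(sim$snps), nrow(sim$genes)))

# the recombination map lives in the *target* assembly: lift the gene
# intervals first so the conflict effect is written into the right windows
lift <- generate_liftover_map(cfg, span = max(sim$genes$end) + 1000)
gconf <- merge(sim$genes, pool_gene_sai(sim$snps, "missense"), by = "gene_id")
p1 <- liftover(gconf$chrom, gconf$start + 1L, lift)
p2 <- liftover(gconf$chrom, gconf$end, lift)
ok <- p1$mapped & p2$mapped
lifted <- gconf[ok, ]
lifted$start <- p1$pos[ok] - 1L
lifted$end <- p2$pos[ok]
win <- generate_recomb_map(cfg, lifted)

rated <- assign_recomb_rate(lifted, win)
pg <- generate_paralog_pairs(
  cfg,
  cbind(rated, tertile = assign_tertiles(rated$mean_sai, rated$gene_id)),
  rated[!is.na(rated$recomb_rate), ])

# a real annotation covers every gene, not just the conflict set: give
# the background genes intervals too (separate chromosome, no SNPs)
bg_genes <- data.frame(
  chrom = "chrB",
  start = seq(0, by = 4000, length.out = nrow(pg$background_genes)),
  gene_id = pg$background_genes$gene_id)
bg_genes$end <- bg_genes$start + 2000
all_genes <- rbind(sim$genes,
                   bg_genes[, c("chrom", "start", "end", "gene_id")])

write_snp_table(sim$snps, file.path(out_dir, "snps.tsv"))
write_gene_intervals(all_genes, file.path(out_dir, "genes.tsv"))
write_recomb_map(win, file.path(out_dir, "map.tsv"))
write_paralog_pairs(pg$pairs, file.path(out_dir, "pairs.tsv"))
write_liftover_map(lift, file.path(out_dir, "lift.tsv"))

message("wrote input tables to ", out_dir)
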
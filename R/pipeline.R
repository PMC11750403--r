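#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: either a synthetic-study
#' configuration or the paths of the four real input tables, plus the
#' analysis switches (granularity of the all-variant median test, the
#' category used for gene-level SAI pooling, zero-paralogue exclusion,
#' multiplicity adjustment, continuity-correction flags) with defaults
#' matching the package's documented conventions.
#'
#' @param synthetic Use the bundled generator (`TRUE`) or read real
#'   inputs from `paths` (`FALSE`). Exactly one mode is active.
#' @param synthetic_cfg A [synthetic_config()]; its seed is overridden
#'   by `seed` when given.
#' @param paths Named list for real mode: `snp_table`, `recomb_map`,
#'   `gene_intervals`, `paralog_pairs`, and optionally `liftover_map`.
#' @param seed Integer seed driving every random choice.
#' @param pool_category Variant category pooled per gene for the
#'   gene-level conflict analysis (`"missense"` by default).
#' @param granularity `"snp"`, `"gene"` or `"both"` for the
#'   conflict-vs-recombination median tests.
#' @param exclude_zero_paralogs Drop genes with zero paralogues from the
#'   count comparisons (the count distributions are reported without
#'   singleton genes).
#' @param adjust Post-hoc multiplicity adjustment, `"bonferroni"` or
#'   `"none"`.
#' @param continuity Continuity correction for two-group chi-square
#'   tests.
#' @param two_species In synthetic mode, also generate a second,
#'   weaker-conflict species and run the cross-species SAI contrast.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = TRUE,
                            synthetic_cfg = synthetic_config(),
                            paths = list(),
                            seed = 1L,
                            pool_category = "missense",
                            granularity = c("both", "snp", "gene"),
                            exclude_zero_paralogs = TRUE,
                            adjust = c("bonferroni", "none"),
                            continuity = FALSE,
                            two_species = TRUE) {
  granularity <- match.arg(granularity)
  adjust <- match.arg(adjust)
  if (synthetic && length(paths)) {
    stop("exactly one of synthetic mode and real input paths may be active",
         call. = FALSE)
  }
  if (!synthetic) {
    need <- c("snp_table", "recomb_map", "gene_intervals", "paralog_pairs")
    missing <- setdiff(need, names(paths))
    if (length(missing)) {
      stop("real mode needs paths: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  if (synthetic) synthetic_cfg$seed <- as.integer(seed)
  structure(list(synthetic = synthetic, synthetic_cfg = synthetic_cfg,
                 paths = paths, seed = as.integer(seed),
                 pool_category = pool_category, granularity = granularity,
                 exclude_zero_paralogs = exclude_zero_paralogs,
                 adjust = adjust, continuity = continuity,
                 two_species = two_species),
            class = "pipeline_config")
}

lift_intervals <- function(intervals, map) {
  if (is.null(map)) {
    intervals$mapped <- TRUE
    return(intervals)
  }
  p1 <- liftover(intervals$chrom, intervals$start + 1L, map)
  p2 <- liftover(intervals$chrom, intervals$end, map)
  ok <- p1$mapped & p2$mapped & p1$chrom == p2$chrom & p2$pos >= p1$pos
  out <- intervals
  out$chrom <- ifelse(ok, p1$chrom, intervals$chrom)
  out$start <- ifelse(ok, p1$pos - 1L, intervals$start)
  out$end <- ifelse(ok, p2$pos, intervals$end)
  out$mapped <- ok
  out
}

test_row <- function(analysis, tst, p_adjusted = NA_real_) {
  data.frame(analysis = analysis, method = tst$method,
             statistic = tst$statistic,
             df = if (is.null(tst$df)) NA_character_ else
               paste(tst$df, collapse = ","),
             p_raw = tst$p_value, p_adjusted = p_adjusted,
             stringsAsFactors = FALSE)
}

tertile_battery <- function(values, rates, ids, analysis_prefix, adjust) {
  tert <- assign_tertiles(values, ids)
  groups <- split(rates, tert)
  rows <- list(
    test_row(paste0(analysis_prefix, "_median"), moods_median_test(groups)),
    test_row(paste0(analysis_prefix, "_levene"), levenes_test(groups)))
  post <- pairwise_posthoc_median(groups, adjust = adjust)
  for (i in seq_len(nrow(post))) {
    rows[[length(rows) + 1]] <- data.frame(
      analysis = paste0(analysis_prefix, "_posthoc_", post$group_a[i], "_vs_",
                        post$group_b[i]),
      method = "Brown-Mood median test", statistic = post$statistic[i],
      df = as.character(post$df[i]), p_raw = post$p_raw[i],
      p_adjusted = post$p_adjusted[i], stringsAsFactors = FALSE)
  }
  list(rows = do.call(rbind, rows), tertile = tert)
}

#' Run the full conflict / recombination / duplication pipeline
#'
#' Orchestrates the three analyses end to end: (a) allele-frequency
#' regressions on the effect-size ratio (pooled, category interaction,
#' stratified), (b) conflict-intensity tertiles against recombination
#' rate (all-variant and gene-level Brown-Mood median tests, Levene's
#' tests, post-hoc pairwise tests, per-category tests), (c) paralogue
#' proportions, counts and the with-vs-without-paralogue recombination
#' comparison, plus (d) a two-species SAI contrast when two species
#' labels are present. Inputs are generated (synthetic mode) or read
#' from the configured paths; identical config and seed give identical
#' outputs, and every record entering is accounted for in the manifest.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory; result TSVs and `manifest.tsv` are
#'   written there atomically (staged, then moved — no partial outputs
#'   on failure).
#' @return (Invisibly) a list with all result objects: `regression`
#'   (table), `interaction`, `stratified`, `recomb_tests`,
#'   `paralog_proportions`, `paralog_count_tests`, `paralog_tests`,
#'   `species_contrast` (or `NULL`), `gene_conflicts`, `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  manifest <- list(seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("saconflict")),
                   mode = if (cfg$synthetic) "synthetic" else "real")

  ## ---- acquire inputs ----
  species2_sai <- NULL
  if (cfg$synthetic) {
    sim <- generate_snp_table(cfg$synthetic_cfg)
    snps <- sim$snps
    genes <- sim$genes
    lift_map <- generate_liftover_map(cfg$synthetic_cfg,
                                      span = max(genes$end) + 1000)
    pooled0 <- pool_gene_sai(snps, cfg$pool_category)
    gc0 <- merge(genes, pooled0, by = "gene_id")
    gc_lifted <- lift_intervals(gc0, lift_map)
    windows <- generate_recomb_map(cfg$synthetic_cfg,
                                   gc_lifted[gc_lifted$mapped, , drop = FALSE])
    if (cfg$two_species) {
      cfg2 <- cfg$synthetic_cfg
      cfg2$seed <- cfg$synthetic_cfg$seed + 1000L
      cfg2$n_genes <- max(3L, round(cfg$synthetic_cfg$n_genes / 4))
      cfg2$effect_sd <- cfg$synthetic_cfg$effect_sd * 0.6
      sim2 <- generate_snp_table(cfg2)
      species2_sai <- sai(sim2$snps$d_male, sim2$snps$d_female)
    }
  } else {
    snps <- read_snp_table(cfg$paths$snp_table)
    genes <- read_gene_intervals(cfg$paths$gene_intervals)
    windows <- read_recomb_map(cfg$paths$recomb_map)
    lift_map <- if (!is.null(cfg$paths$liftover_map))
      read_liftover_map(cfg$paths$liftover_map) else NULL
    if ("species" %in% names(snps)) {
      sp <- unique(snps$species)
      if (length(sp) == 2) {
        species2_sai <- sai(snps$d_male[snps$species == sp[2]],
                            snps$d_female[snps$species == sp[2]])
        snps <- snps[snps$species == sp[1], , drop = FALSE]
      }
    }
  }
  snps <- snp_sa_stats(validate_snp_table(snps)[, snp_table_columns])
  snps$sai <- sai(snps$d_male, snps$d_female)
  manifest$n_snps <- nrow(snps)
  manifest$n_snps_sa <- sum(snps$is_sa)
  manifest$n_snps_not_sa <- sum(!snps$is_sa)
  manifest$n_genes <- length(unique(snps$gene_id))

  ## ---- (a) allele-frequency models ----
  sa_rec <- snps[snps$is_sa, , drop = FALSE]
  reg_tab <- regression_table(sa_rec)
  interaction <- fit_interaction_model(sa_rec)
  stratified <- fit_stratified(sa_rec)

  ## ---- (b) recombination-rate association ----
  pooled <- pool_gene_sai(snps, cfg$pool_category)
  gconf <- merge(genes, pooled, by = "gene_id")
  manifest$n_genes_pooled <- nrow(gconf)
  manifest$n_genes_without_interval <- nrow(pooled) - nrow(gconf)
  gconf <- lift_intervals(gconf, lift_map)
  manifest$n_genes_unmapped_liftover <- sum(!gconf$mapped)
  gconf <- gconf[gconf$mapped, , drop = FALSE]
  gconf <- assign_recomb_rate(gconf, windows)
  manifest$n_genes_missing_rate <- attr(gconf, "n_missing")
  gconf <- gconf[!is.na(gconf$recomb_rate), , drop = FALSE]

  recomb_rows <- list()
  if (cfg$granularity %in% c("both", "gene")) {
    gb <- tertile_battery(gconf$mean_sai, gconf$recomb_rate, gconf$gene_id,
                          "gene_level", cfg$adjust)
    gconf$tertile <- gb$tertile
    recomb_rows[[length(recomb_rows) + 1]] <- gb$rows
  } else {
    gconf$tertile <- assign_tertiles(gconf$mean_sai, gconf$gene_id)
  }
  snp_pts <- NULL
  if (cfg$granularity %in% c("both", "snp")) {
    snp_pts <- data.frame(chrom = snps$chrom, start = snps$pos - 1L,
                          end = snps$pos, snp_id = snps$snp_id,
                          sai = snps$sai, category = snps$category,
                          stringsAsFactors = FALSE)
    snp_pts <- lift_intervals(snp_pts, lift_map)
    manifest$n_snps_unmapped_liftover <- sum(!snp_pts$mapped)
    snp_pts <- snp_pts[snp_pts$mapped, , drop = FALSE]
    snp_pts <- assign_recomb_rate(snp_pts, windows)
    manifest$n_snps_missing_rate <- attr(snp_pts, "n_missing")
    snp_pts <- snp_pts[!is.na(snp_pts$recomb_rate), , drop = FALSE]
    sb <- tertile_battery(snp_pts$sai, snp_pts$recomb_rate, snp_pts$snp_id,
                          "all_variants", cfg$adjust)
    recomb_rows[[length(recomb_rows) + 1]] <- sb$rows
    for (cat in sort(unique(snp_pts$category))) {
      sub <- snp_pts[snp_pts$category == cat, , drop = FALSE]
      if (nrow(sub) >= 9) {
        tert <- assign_tertiles(sub$sai, sub$snp_id)
        tst <- moods_median_test(split(sub$recomb_rate, tert))
        recomb_rows[[length(recomb_rows) + 1]] <-
          test_row(paste0("category_", cat, "_median"), tst)
      }
    }
  }
  recomb_tests <- do.call(rbind, recomb_rows)

  ## ---- (c) paralogues ----
  if (cfg$synthetic) {
    pg <- generate_paralog_pairs(cfg$synthetic_cfg,
                                 gconf[, c("gene_id", "tertile")],
                                 gconf[, c("gene_id", "recomb_rate")])
    pairs <- pg$pairs
    universe <- pg$gene_universe
    background <- pg$background_genes
  } else {
    pairs <- read_paralog_pairs(cfg$paths$paralog_pairs)
    universe <- unique(c(genes$gene_id, pairs$gene_a, pairs$gene_b))
    background <- NULL
  }
  fam <- build_paralog_families(pairs, universe)
  counts <- fam$counts
  gstat <- merge(gconf[, c("gene_id", "tertile", "recomb_rate")], counts,
                 by = "gene_id")
  gstat$has_paralog <- gstat$n_paralogs > 0
  if (is.null(background)) {
    # background = annotated genes outside the SA analysis set; pair
    # members without an annotated interval cannot be rated or counted
    bg_ids <- setdiff(genes$gene_id, gconf$gene_id)
    bg_counts <- counts[counts$gene_id %in% bg_ids, , drop = FALSE]
    bg_with <- sum(bg_counts$n_paralogs > 0)
    bg_without <- sum(bg_counts$n_paralogs == 0)
    bg_rates <- merge(genes, bg_counts, by = "gene_id")
    bg_rates <- assign_recomb_rate(bg_rates, windows)
    bg_rates <- bg_rates[!is.na(bg_rates$recomb_rate), , drop = FALSE]
    bg_rate_df <- data.frame(recomb_rate = bg_rates$recomb_rate,
                             has_paralog = bg_rates$n_paralogs > 0)
  } else {
    bg_counts <- merge(background, counts, by = "gene_id")
    bg_with <- sum(bg_counts$n_paralogs > 0)
    bg_without <- sum(bg_counts$n_paralogs == 0)
    bg_rate_df <- data.frame(recomb_rate = bg_counts$recomb_rate,
                             has_paralog = bg_counts$n_paralogs > 0)
  }
  manifest$n_background_with_paralog <- bg_with
  manifest$n_background_without_paralog <- bg_without
  prop_tests <- proportion_with_paralogs_test(
    gstat, bg_with, bg_without, correct = cfg$continuity)
  count_tests <- paralog_count_tertile_tests(
    gstat$n_paralogs, gstat$tertile,
    restrict_to_positive = cfg$exclude_zero_paralogs)
  manifest$n_genes_zero_paralog_filtered <-
    if (cfg$exclude_zero_paralogs) sum(gstat$n_paralogs == 0) else 0L
  all_rate_df <- rbind(
    data.frame(recomb_rate = gstat$recomb_rate, has_paralog = gstat$has_paralog),
    bg_rate_df)
  wp <- wilcoxon_rank_sum(all_rate_df$recomb_rate[all_rate_df$has_paralog],
                          all_rate_df$recomb_rate[!all_rate_df$has_paralog])
  paralog_tests <- test_row("genes_with_vs_without_paralogs_recomb", wp)

  ## ---- (d) cross-species contrast ----
  species_contrast <- NULL
  if (!is.null(species2_sai)) {
    z <- two_sample_median_z(snps$sai, species2_sai)
    lv <- levenes_test(list(snps$sai, species2_sai))
    species_contrast <- rbind(test_row("species_sai_median", z),
                              test_row("species_sai_levene", lv))
  }

  ## ---- write outputs atomically ----
  staging <- tempfile("saconflict_run_")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  write_tsv(reg_tab, file.path(staging, "regression_table.tsv"))
  write_test_results(rbind(
    test_row("category_main_effect", interaction$main_effect_test),
    test_row("ratio_category_interaction", interaction$interaction_test)),
    file.path(staging, "interaction_tests.tsv"))
  write_test_results(recomb_tests, file.path(staging, "recomb_tests.tsv"))
  write_tsv(prop_tests, file.path(staging, "paralog_proportions.tsv"))
  write_tsv(count_tests, file.path(staging, "paralog_count_tests.tsv"))
  write_test_results(paralog_tests, file.path(staging, "paralog_tests.tsv"))
  if (!is.null(species_contrast)) {
    write_test_results(species_contrast,
                       file.path(staging, "species_contrast.tsv"))
  }
  mdf <- data.frame(key = names(manifest),
                    value = vapply(manifest, as.character, ""),
                    stringsAsFactors = FALSE)
  write_tsv(mdf, file.path(staging, "manifest.tsv"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (f in list.files(staging)) {
    file.copy(file.path(staging, f), file.path(out_dir, f), overwrite = TRUE)
  }

  invisible(list(regression = reg_tab, interaction = interaction,
                 stratified = stratified, recomb_tests = recomb_tests,
                 paralog_proportions = prop_tests,
                 paralog_count_tests = count_tests,
                 paralog_tests = paralog_tests,
                 species_contrast = species_contrast,
                 gene_conflicts = gconf, paralog_counts = counts,
                 manifest = manifest))
}
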
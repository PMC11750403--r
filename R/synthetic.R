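#' Synthetic-study configuration
#'
#' Parameters of the seeded generator that emulates the four inputs the
#' pipeline consumes: a candidate-SA SNP table with opposite-sign sex
#' effects, a piecewise-constant recombination map whose rates can be
#' elevated over high-conflict genes, paralogue pairs whose incidence
#' depends on recombination rate and conflict tertile, and an assembly
#' liftover map. Defaults mirror the structure of the real study inputs:
#' 337 SA genes carrying ~2372 SNPs in total, a pooled frequency-on-ratio
#' slope of -0.126, and tertile paralogue proportions in the 0.42-0.54
#' range.
#'
#' @param n_genes Number of SA genes on the synthetic chromosome.
#' @param snps_per_gene Mean of the zero-truncated Poisson SNP count per
#'   gene (default 2372/337).
#' @param effect_sd Scale (Cohen's d) of the half-normal per-sex effect
#'   magnitudes.
#' @param freq_intercept,freq_slope,freq_noise_sd Minor-allele frequency
#'   model: `freq = intercept + slope * ratio + N(0, noise_sd)`, clamped
#'   to (0.005, 0.5].
#' @param freq_scale `"linear"` (default) or `"logit"`, a robustness
#'   alternative generating frequencies on the logit of 2*frequency.
#' @param category_probs Named probabilities for the three variant
#'   functional categories (missense, synonymous, regulatory).
#' @param gene_length_range,gene_gap_range Uniform ranges (bp) for gene
#'   lengths and intergenic gaps.
#' @param window_size Recombination-map window width (bp).
#' @param rate_log_mean,rate_log_sd Log-normal parameters of the base
#'   recombination rate (log cM/Mb).
#' @param sai_recomb_effect Multiplicative rate elevation (>= 1) applied
#'   to windows overlapping genes in the highest-conflict tertile.
#' @param paralog_base_logodds,paralog_recomb_coef,paralog_sai_coef
#'   Logit-scale model of a gene having at least one paralogue:
#'   `base + recomb_coef * standardized rate + sai_coef * tertile index`
#'   (low = 0, medium = 1, high = 2; background genes use index 0).
#' @param paralog_count_mean Mean of the zero-truncated Poisson partner
#'   count for genes with paralogues.
#' @param paralog_count_tertile_coef Log-scale elevation of the partner
#'   count mean per conflict-tertile step (`mean * exp(coef * index)`),
#'   so higher-conflict genes can carry more paralogues, not just more
#'   often at least one.
#' @param n_background_genes Non-SA genes emulating the genome-wide
#'   comparator panel.
#' @param unmapped_frac Fraction of the chromosome deliberately left out
#'   of the liftover map to exercise the unmapped path.
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 337,
                             snps_per_gene = 2372 / 337,
                             effect_sd = 0.2,
                             freq_intercept = 0.2,
                             freq_slope = -0.126,
                             freq_noise_sd = 0.07,
                             freq_scale = c("linear", "logit"),
                             category_probs = c(missense = 0.2,
                                                synonymous = 0.2,
                                                regulatory = 0.6),
                             gene_length_range = c(1000, 5000),
                             gene_gap_range = c(5000, 20000),
                             window_size = 20000,
                             rate_log_mean = log(2),
                             rate_log_sd = 0.5,
                             sai_recomb_effect = 1.5,
                             paralog_base_logodds = -0.32,
                             paralog_recomb_coef = 0.3,
                             paralog_sai_coef = 0.25,
                             paralog_count_mean = 2.5,
                             paralog_count_tertile_coef = 0.2,
                             n_background_genes = 2000,
                             unmapped_frac = 0.05,
                             seed = 1L) {
  freq_scale <- match.arg(freq_scale)
  stopifnot(n_genes >= 1, snps_per_gene > 0, effect_sd > 0,
            freq_noise_sd >= 0, window_size > 0, rate_log_sd > 0,
            sai_recomb_effect >= 1, paralog_count_mean > 0,
            unmapped_frac >= 0, unmapped_frac < 1)
  if (abs(sum(category_probs) - 1) > 1e-8) {
    stop("category_probs must sum to 1", call. = FALSE)
  }
  if (!setequal(names(category_probs),
                c("missense", "synonymous", "regulatory"))) {
    stop("category_probs must be named missense/synonymous/regulatory",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "synthetic_config")
}

# zero-truncated Poisson with a given mean (> 1)
rztpois <- function(n, mean) {
  stopifnot(mean > 1)
  lambda <- stats::uniroot(
    function(l) l / (1 - exp(-l)) - mean,
    interval = c(1e-9, mean), tol = 1e-10)$root
  p0 <- exp(-lambda)
  as.integer(stats::qpois(p0 + stats::runif(n) * (1 - p0), lambda))
}

#' Generate a synthetic candidate-SA SNP table
#'
#' Places `n_genes` non-overlapping genes on one synthetic chromosome
#' (`chrS`), draws a zero-truncated Poisson number of SNPs per gene, and
#' for each SNP draws opposite-sign sex effects (half-normal magnitudes,
#' benefitting sex random), a variant functional category, an
#' inverse-variance weight (from a simulated per-SNP sample size) and a
#' minor-allele frequency following the configured linear (or logit)
#' model in the effect-size ratio, truncated to (0.005, 0.5].
#'
#' @param cfg A [synthetic_config()].
#' @return List with `snps` (the 9-column SNP table), `genes`
#'   (`chrom`, `start`, `end`, `gene_id`; 0-based half-open) and `truth`
#'   (the config plus per-SNP latents: true ratio, SAI, the pre-clamp
#'   frequency and a `clamped` flag) — sufficient to recompute every
#'   latent quantity downstream checks need.
#' @export
generate_snp_table <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  lens <- round(stats::runif(n, cfg$gene_length_range[1], cfg$gene_length_range[2]))
  gaps <- round(stats::runif(n, cfg$gene_gap_range[1], cfg$gene_gap_range[2]))
  starts <- cumsum(gaps + c(0, lens[-n]))
  genes <- data.frame(chrom = "chrS", start = starts, end = starts + lens,
                      gene_id = sprintf("G%04d", seq_len(n)),
                      stringsAsFactors = FALSE)
  n_snps_per <- if (cfg$snps_per_gene > 1) rztpois(n, cfg$snps_per_gene)
                else 1L + stats::rpois(n, max(cfg$snps_per_gene - 1, 0))
  gi <- rep(seq_len(n), n_snps_per)
  m <- length(gi)
  pos <- genes$start[gi] + 1L +
    floor(stats::runif(m) * (genes$end[gi] - genes$start[gi]))
  benefit <- abs(stats::rnorm(m, 0, cfg$effect_sd))
  detriment <- -abs(stats::rnorm(m, 0, cfg$effect_sd))
  male_benefits <- stats::runif(m) < 0.5
  d_male <- ifelse(male_benefits, benefit, detriment)
  d_female <- ifelse(male_benefits, detriment, benefit)
  ratio <- benefit / detriment
  n_i <- sample(150:250, m, replace = TRUE)
  weight <- n_i / 4  # inverse of a 4/N effect-size variance
  noise <- stats::rnorm(m, 0, cfg$freq_noise_sd)
  if (cfg$freq_scale == "linear") {
    freq_raw <- cfg$freq_intercept + cfg$freq_slope * ratio + noise
  } else {
    eta <- stats::qlogis(2 * cfg$freq_intercept) + cfg$freq_slope * ratio + noise
    freq_raw <- 0.5 * stats::plogis(eta)
  }
  typical <- cfg$freq_intercept + cfg$freq_slope * (-1)
  if (cfg$freq_scale == "linear" && (typical <= 0.005 || typical > 0.5)) {
    warning("frequency model lies outside (0.005, 0.5] at a typical ratio of -1; ",
            "clamping will dominate", call. = FALSE)
  }
  freq <- pmin(pmax(freq_raw, 0.005), 0.5)
  clamped <- freq != freq_raw
  category <- sample(names(cfg$category_probs), m, replace = TRUE,
                     prob = cfg$category_probs)
  snps <- data.frame(
    snp_id = sprintf("S%05d", seq_len(m)),
    chrom = "chrS",
    pos = as.integer(pos),
    gene_id = genes$gene_id[gi],
    category = category,
    d_male = d_male,
    d_female = d_female,
    weight = weight,
    allele_freq = freq,
    stringsAsFactors = FALSE)
  truth <- list(config = cfg,
                snp_latents = data.frame(
                  snp_id = snps$snp_id, ratio = ratio,
                  sai = sai(d_male, d_female),
                  freq_raw = freq_raw, clamped = clamped,
                  stringsAsFactors = FALSE))
  list(snps = snps, genes = genes, truth = truth)
}

#' Generate a synthetic windowed recombination map
#'
#' Tiles the synthetic chromosome with contiguous fixed-width windows,
#' draws log-normal base rates, then multiplies the rate of every window
#' overlapping a gene in the highest-conflict tertile (most negative
#' pooled SAI) by `sai_recomb_effect`. With `sai_recomb_effect = 1` the
#' map carries no conflict signal.
#'
#' @param cfg A [synthetic_config()].
#' @param gene_conflicts Data frame with `chrom`, `start`, `end`,
#'   `gene_id` and `mean_sai` (e.g. gene table joined with
#'   [pool_gene_sai()] output).
#' @return Data frame with `chrom`, `start`, `end` (0-based half-open,
#'   tiling the chromosome exactly) and `rate_cM_per_Mb`.
#' @export
generate_recomb_map <- function(cfg, gene_conflicts) {
  stopifnot(inherits(cfg, "synthetic_config"),
            all(c("chrom", "start", "end", "gene_id", "mean_sai") %in%
                  names(gene_conflicts)))
  set.seed(cfg$seed + 1L)
  span <- max(gene_conflicts$end) + cfg$window_size
  n_win <- ceiling(span / cfg$window_size)
  starts <- (seq_len(n_win) - 1L) * cfg$window_size
  rates <- stats::rlnorm(n_win, cfg$rate_log_mean, cfg$rate_log_sd)
  tert <- assign_tertiles(gene_conflicts$mean_sai, gene_conflicts$gene_id)
  hi <- gene_conflicts[tert == "high", , drop = FALSE]
  if (nrow(hi)) {
    win <- data.frame(chrom = "chrS", start = starts,
                      end = starts + cfg$window_size)
    q <- GenomicRanges::GRanges(win$chrom,
      IRanges::IRanges(win$start + 1L, win$end))
    s <- GenomicRanges::GRanges(hi$chrom, IRanges::IRanges(hi$start + 1L, hi$end))
    touched <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(q, s)))
    rates[touched] <- rates[touched] * cfg$sai_recomb_effect
  }
  data.frame(chrom = "chrS", start = starts, end = starts + cfg$window_size,
             rate_cM_per_Mb = rates, stringsAsFactors = FALSE)
}

#' Generate synthetic paralogue pairs
#'
#' Each gene (SA genes plus a background panel emulating the genome-wide
#' comparator) has at least one paralogue with probability
#' `plogis(base + recomb_coef * z(rate) + sai_coef * tertile_index)`;
#' background genes use tertile index 0. Genes with a paralogue receive a
#' zero-truncated Poisson number of partners, each a fresh synthetic gene
#' id, and every emitted pair carries a DIOPT score drawn uniformly from
#' 1..15.
#'
#' @param cfg A [synthetic_config()].
#' @param gene_conflicts Data frame with `gene_id` and `tertile`
#'   (levels low/medium/high) for the SA genes.
#' @param recomb_rates Data frame with `gene_id` and `recomb_rate` for
#'   the SA genes.
#' @return List with `pairs` (`gene_a`, `gene_b`, `diopt_score`),
#'   `background_genes` (`gene_id`, `recomb_rate`, `has_paralog`) and
#'   `gene_universe` (SA + background + partner ids).
#' @export
generate_paralog_pairs <- function(cfg, gene_conflicts, recomb_rates) {
  stopifnot(inherits(cfg, "synthetic_config"),
            all(c("gene_id", "tertile") %in% names(gene_conflicts)),
            all(c("gene_id", "recomb_rate") %in% names(recomb_rates)))
  set.seed(cfg$seed + 2L)
  sa <- merge(gene_conflicts[, c("gene_id", "tertile")],
              recomb_rates[, c("gene_id", "recomb_rate")], by = "gene_id")
  sa <- sa[order(sa$gene_id), ]
  bg <- data.frame(
    gene_id = sprintf("B%05d", seq_len(cfg$n_background_genes)),
    tertile = rep(NA_character_, cfg$n_background_genes),
    recomb_rate = stats::rlnorm(cfg$n_background_genes, cfg$rate_log_mean,
                                cfg$rate_log_sd),
    stringsAsFactors = FALSE)
  all_rates <- c(sa$recomb_rate, bg$recomb_rate)
  zrate <- (all_rates - mean(all_rates)) / stats::sd(all_rates)
  tert_idx <- c(match(as.character(sa$tertile),
                      c("low", "medium", "high")) - 1L,
                rep(0L, nrow(bg)))
  eta <- cfg$paralog_base_logodds + cfg$paralog_recomb_coef * zrate +
    cfg$paralog_sai_coef * tert_idx
  has <- stats::runif(length(eta)) < stats::plogis(eta)
  owners <- c(sa$gene_id, bg$gene_id)[has]
  owner_means <- cfg$paralog_count_mean *
    exp(cfg$paralog_count_tertile_coef * tert_idx[has])
  n_partners <- integer(length(owners))
  for (m in unique(owner_means)) {
    sel <- owner_means == m
    n_partners[sel] <- if (m > 1) rztpois(sum(sel), m) else 1L
  }
  total <- sum(n_partners)
  partner_ids <- sprintf("P%06d", seq_len(total))
  pairs <- data.frame(
    gene_a = rep(owners, n_partners),
    gene_b = partner_ids,
    diopt_score = sample(1:15, total, replace = TRUE),
    stringsAsFactors = FALSE)
  bg$has_paralog <- has[-seq_len(nrow(sa))]
  list(pairs = pairs,
       background_genes = bg[, c("gene_id", "recomb_rate", "has_paralog")],
       gene_universe = c(sa$gene_id, bg$gene_id, partner_ids))
}

#' Generate a synthetic assembly liftover map
#'
#' Partitions the chromosome into random-length blocks; most map to a
#' shifted target coordinate system with non-overlapping target
#' intervals (so the map is invertible), while a configured fraction is
#' deliberately left unmapped to exercise the unmapped path.
#'
#' @param cfg A [synthetic_config()].
#' @param span Chromosome length (bp) to cover.
#' @return A [liftover_map()] (all `+` strand).
#' @export
generate_liftover_map <- function(cfg, span) {
  stopifnot(inherits(cfg, "synthetic_config"), span > 0)
  set.seed(cfg$seed + 3L)
  n_draw <- ceiling(span / 5000) + 2
  lens <- round(stats::runif(n_draw, 5000, 20000))
  bounds <- cumsum(c(0, lens))
  bounds <- bounds[bounds < span]
  ends <- c(bounds[-1], span)
  nb <- length(bounds)
  mapped <- stats::runif(nb) >= cfg$unmapped_frac
  if (!any(mapped)) mapped[1] <- TRUE
  blen <- (ends - bounds)[mapped]
  gaps <- round(stats::runif(sum(mapped), 0, 2000))
  tstarts <- cumsum(c(0, (blen + gaps)[-length(blen)]))
  liftover_map(data.frame(
    source_chrom = "chrS",
    source_start = bounds[mapped],
    source_end = ends[mapped],
    target_chrom = "chrS",
    target_start = tstarts,
    strand = "+",
    stringsAsFactors = FALSE))
}
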
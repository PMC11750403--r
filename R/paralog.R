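#' Build paralogue families from scored gene pairs
#'
#' Gene pairs with a DIOPT score of at least `min_score` are treated as
#' paralogues. Families are the connected components of the resulting
#' graph over the gene universe (singletons included), and each gene's
#' paralogue count is its number of distinct direct qualifying partners.
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b`, `diopt_score`
#'   (non-negative integers). Pairs are unordered and are canonicalized
#'   so `gene_a < gene_b`; a duplicated canonical pair with conflicting
#'   scores is an error, as is a self-pair.
#' @param gene_universe Character vector of gene ids; pair members not in
#'   it are added.
#' @param min_score Minimum DIOPT score for a pair to qualify (>= 1).
#' @param count Paralogue-count definition: `"partners"` (default;
#'   distinct direct qualifying partners) or `"family"` (family size
#'   minus one).
#' @return List with `families` (data frame `family_id`, `gene_id`),
#'   `counts` (data frame `gene_id`, `n_paralogs`) and `n_families`.
#'   Families partition the universe: every gene appears exactly once.
#' @export
build_paralog_families <- function(pairs, gene_universe, min_score = 1,
                                   count = c("partners", "family")) {
  count <- match.arg(count)
  stopifnot(min_score >= 1)
  need <- c("gene_a", "gene_b", "diopt_score")
  missing <- setdiff(need, names(pairs))
  if (length(missing)) {
    stop("pair table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(pairs$gene_a == pairs$gene_b)) {
    stop("self-pair in paralogue table", call. = FALSE)
  }
  if (any(pairs$diopt_score < 0)) {
    stop("DIOPT scores must be non-negative", call. = FALSE)
  }
  a <- pmin(pairs$gene_a, pairs$gene_b)
  b <- pmax(pairs$gene_a, pairs$gene_b)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    sc <- tapply(pairs$diopt_score, key, function(s) length(unique(s)))
    if (any(sc > 1)) {
      stop("duplicate gene pair with conflicting DIOPT scores", call. = FALSE)
    }
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]
    pairs <- pairs[keep, , drop = FALSE]
  }
  universe <- sort(unique(c(gene_universe, a, b)))
  qual <- pairs$diopt_score >= min_score
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[qual], to = b[qual], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = universe, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  # renumber components by first (sorted) member for determinism
  first_seen <- !duplicated(comp)
  renum <- stats::setNames(seq_len(sum(first_seen)), comp[first_seen])
  fam_idx <- renum[as.character(comp)]
  families <- data.frame(
    family_id = sprintf("F%05d", fam_idx),
    gene_id = universe, stringsAsFactors = FALSE)
  if (count == "partners") {
    deg <- igraph::degree(g)  # duplicates removed above, so = distinct partners
    n_par <- as.integer(deg[universe])
  } else {
    fam_sizes <- table(fam_idx)
    n_par <- as.integer(fam_sizes[as.character(fam_idx)]) - 1L
  }
  list(families = families,
       counts = data.frame(gene_id = universe, n_paralogs = n_par,
                           stringsAsFactors = FALSE),
       n_families = length(renum))
}

pearson_chisq_2x2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(statistic = sum((tab - E)^2 / E), expected = E)
}

#' Proportion of genes with paralogues, per tertile vs background
#'
#' For each conflict-intensity tertile, tests whether the fraction of its
#' genes having at least one paralogue differs from a genome-wide
#' background via a 2 x 2 Pearson chi-square (df = 1, no continuity
#' correction by default).
#'
#' @param gene_status Data frame with columns `tertile` (factor or
#'   character) and `has_paralog` (logical), one row per SA gene.
#' @param background_with,background_without Genome-wide counts of genes
#'   with and without paralogues (both > 0).
#' @param correct Apply the Yates continuity correction.
#' @return Data frame with one row per tertile: counts, `proportion`,
#'   `statistic`, `df`, `p_value` and a `low_expected` flag set when any
#'   expected cell is below 1.
#' @export
proportion_with_paralogs_test <- function(gene_status, background_with,
                                          background_without,
                                          correct = FALSE) {
  stopifnot(all(c("tertile", "has_paralog") %in% names(gene_status)),
            background_with > 0, background_without > 0)
  terts <- if (is.factor(gene_status$tertile)) levels(gene_status$tertile)
           else sort(unique(as.character(gene_status$tertile)))
  rows <- lapply(terts, function(tt) {
    sel <- gene_status$tertile == tt
    n_with <- sum(gene_status$has_paralog[sel])
    n_without <- sum(sel) - n_with
    if (sum(sel) == 0) stop("empty tertile: ", tt, call. = FALSE)
    tab <- rbind(tertile = c(n_with, n_without),
                 background = c(background_with, background_without))
    cs <- pearson_chisq_2x2(tab)
    stat <- cs$statistic
    if (correct) {
      E <- cs$expected
      stat <- sum((pmax(abs(tab - E) - 0.5, 0))^2 / E)
    }
    data.frame(tertile = tt, n_with = n_with, n_without = n_without,
               proportion = n_with / sum(sel),
               statistic = stat, df = 1L,
               p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
               low_expected = any(cs$expected < 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum test with midranks for ties. The p-value is exact (from the
#' null Mann-Whitney distribution) when both samples have at most
#' `exact_max_n` observations and there are no ties; otherwise a normal
#' approximation with tie correction is used (continuity correction off
#' by default, consistent with the package's chi-square conventions).
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_max_n Per-sample size threshold for the exact branch.
#' @param correct Continuity correction in the normal approximation.
#' @return [sa_test] with `statistic` = rank sum of `x`, plus `u` (the
#'   Mann-Whitney U, the "W" that R's `wilcox.test` prints), `exact`
#'   flag and the two-sided `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 25, correct = FALSE) {
  stopifnot(length(x) > 0, length(y) > 0)
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  U <- W - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  exact <- nx <= exact_max_n && ny <= exact_max_n && !ties
  if (exact) {
    p <- min(1, 2 * min(stats::pwilcox(U, nx, ny),
                        stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)))
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(r)
    n <- nx + ny
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      if (correct) z <- sign(z) * max(abs(z) - 0.5, 0)
      p <- 2 * stats::pnorm(-abs(z) / sqrt(sigma2))
    }
  }
  sa_test(method = if (exact) "Wilcoxon rank-sum (exact)"
                   else "Wilcoxon rank-sum (normal approx.)",
          statistic = W, df = NULL, p_value = min(p, 1),
          u = U, exact = exact, n_x = nx, n_y = ny)
}

#' Pairwise paralogue-count comparisons across tertiles
#'
#' Compares per-gene paralogue counts between every pair of
#' conflict-intensity tertiles with [wilcoxon_rank_sum()], optionally
#' first excluding genes with zero paralogues (as the count distributions
#' are displayed and tested without singleton genes).
#'
#' @param counts Numeric vector of per-gene paralogue counts.
#' @param tertile Factor/character vector aligned with `counts`.
#' @param restrict_to_positive Drop zero counts before testing.
#' @return Data frame with one row per tertile pair: `group_a`,
#'   `group_b`, sample sizes, `W` (rank sum of the first group), `u`
#'   (Mann-Whitney U), `p_value`, and `skipped` with a `reason` when a
#'   tertile is emptied by the filter.
#' @export
paralog_count_tertile_tests <- function(counts, tertile,
                                        restrict_to_positive = TRUE) {
  stopifnot(length(counts) == length(tertile))
  tertile <- as.character(tertile)
  terts <- intersect(c("low", "medium", "high"), unique(tertile))
  if (length(terts) < 2) stop("need at least 2 tertile groups", call. = FALSE)
  if (restrict_to_positive) {
    keep <- counts > 0
    counts <- counts[keep]
    tertile <- tertile[keep]
  }
  pairs <- utils::combn(terts, 2)
  rows <- apply(pairs, 2, function(pr) {
    xa <- counts[tertile == pr[1]]
    xb <- counts[tertile == pr[2]]
    if (!length(xa) || !length(xb)) {
      return(data.frame(group_a = pr[1], group_b = pr[2],
                        n_a = length(xa), n_b = length(xb),
                        W = NA_real_, u = NA_real_, p_value = NA_real_,
                        skipped = TRUE,
                        reason = "group empty after zero-count filter",
                        stringsAsFactors = FALSE))
    }
    tst <- wilcoxon_rank_sum(xa, xb)
    data.frame(group_a = pr[1], group_b = pr[2],
               n_a = length(xa), n_b = length(xb),
               W = tst$statistic, u = tst$u, p_value = tst$p_value,
               skipped = FALSE, reason = NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
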
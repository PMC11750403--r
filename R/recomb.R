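#' Construct and validate a liftover map
#'
#' A liftover map is an ordered set of blocks, each mapping a 0-based
#' half-open source interval affinely onto a target location. Source
#' intervals must not overlap within a chromosome.
#'
#' @param blocks Data frame with columns `source_chrom`, `source_start`,
#'   `source_end`, `target_chrom`, `target_start`, `strand` (`"+"` or
#'   `"-"`).
#' @return The validated data frame with class `liftover_map`.
#' @export
liftover_map <- function(blocks) {
  need <- c("source_chrom", "source_start", "source_end",
            "target_chrom", "target_start", "strand")
  missing <- setdiff(need, names(blocks))
  if (length(missing)) {
    stop("liftover map missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(blocks$source_start >= blocks$source_end)) {
    stop("liftover map has empty or inverted source intervals", call. = FALSE)
  }
  if (!all(blocks$strand %in% c("+", "-"))) {
    stop("liftover strand must be '+' or '-'", call. = FALSE)
  }
  for (chr in unique(blocks$source_chrom)) {
    b <- blocks[blocks$source_chrom == chr, ]
    b <- b[order(b$source_start), ]
    if (nrow(b) > 1 && any(b$source_start[-1] < b$source_end[-nrow(b)])) {
      stop("liftover map has overlapping source intervals on ", chr,
           call. = FALSE)
    }
  }
  blocks <- blocks[order(blocks$source_chrom, blocks$source_start), ]
  rownames(blocks) <- NULL
  class(blocks) <- c("liftover_map", "data.frame")
  blocks
}

#' Lift 1-based positions between assembly coordinate systems
#'
#' Positions falling inside a block map affinely; positions in no block
#' are returned as unmapped (never silently dropped — callers count them).
#'
#' @param chrom Character vector of source chromosomes.
#' @param pos Integer vector of 1-based source positions.
#' @param map A [liftover_map()].
#' @return Data frame with columns `chrom`, `pos` (target coordinates,
#'   `NA` where unmapped) and logical `mapped`.
#' @export
liftover <- function(chrom, pos, map) {
  stopifnot(inherits(map, "liftover_map"), length(chrom) == length(pos))
  out_chrom <- rep(NA_character_, length(pos))
  out_pos <- rep(NA_integer_, length(pos))
  p0 <- pos - 1L  # 0-based
  for (chr in unique(chrom)) {
    sel <- which(chrom == chr)
    b <- map[map$source_chrom == chr, , drop = FALSE]
    if (!nrow(b)) next
    idx <- findInterval(p0[sel], b$source_start)
    ok <- idx >= 1 & p0[sel] < b$source_end[pmax(idx, 1)]
    hit <- sel[ok]
    bi <- idx[ok]
    fwd <- b$strand[bi] == "+"
    off <- p0[hit] - b$source_start[bi]
    len <- b$source_end[bi] - b$source_start[bi]
    t0 <- ifelse(fwd, b$target_start[bi] + off,
                 b$target_start[bi] + (len - 1L) - off)
    out_chrom[hit] <- b$target_chrom[bi]
    out_pos[hit] <- as.integer(t0 + 1L)
  }
  data.frame(chrom = out_chrom, pos = out_pos,
             mapped = !is.na(out_pos), stringsAsFactors = FALSE)
}

#' Invert a liftover map
#'
#' Swaps source and target so that lifting a mapped position through the
#' map and then its inverse is the identity. Only defined when target
#' intervals are themselves non-overlapping (true of generated maps).
#'
#' @param map A [liftover_map()].
#' @return The inverse [liftover_map()].
#' @export
invert_liftover_map <- function(map) {
  stopifnot(inherits(map, "liftover_map"))
  len <- map$source_end - map$source_start
  liftover_map(data.frame(
    source_chrom = map$target_chrom,
    source_start = map$target_start,
    source_end = map$target_start + len,
    target_chrom = map$source_chrom,
    target_start = map$source_start,
    strand = map$strand,
    stringsAsFactors = FALSE
  ))
}

#' Pool per-SNP SAI to gene level
#'
#' Computes the arithmetic mean SAI across a gene's qualifying SNPs (by
#' default missense only, matching the gene-level conflict-intensity
#' analysis; the recombination map's resolution is coarser than single
#' SNPs). Genes with no qualifying SNP are absent from the output.
#'
#' @param snps SNP table (see [read_snp_table()]); a `sai` column is
#'   computed if not already present.
#' @param category One of `"missense"`, `"synonymous"`, `"regulatory"`,
#'   `"all"`.
#' @return Data frame with columns `gene_id`, `n_snps`, `mean_sai`,
#'   ordered by `gene_id`.
#' @export
pool_gene_sai <- function(snps, category = "missense") {
  stopifnot(is.data.frame(snps), "gene_id" %in% names(snps))
  category <- match.arg(category,
                        c("missense", "synonymous", "regulatory", "all"))
  if (!"sai" %in% names(snps)) snps <- snp_sa_stats(snps)
  keep <- if (category == "all") rep(TRUE, nrow(snps)) else
    snps$category == category
  sub <- snps[keep, , drop = FALSE]
  if (!nrow(sub)) {
    return(data.frame(gene_id = character(0), n_snps = integer(0),
                      mean_sai = numeric(0), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(sub$sai, by = list(gene_id = sub$gene_id),
                          FUN = mean)
  cnt <- stats::aggregate(sub$sai, by = list(gene_id = sub$gene_id),
                          FUN = length)
  out <- data.frame(gene_id = agg$gene_id, n_snps = as.integer(cnt$x),
                    mean_sai = agg$x, stringsAsFactors = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}

#' Assign recombination rates to genomic intervals
#'
#' For each query interval, returns the overlap-length-weighted mean rate
#' of the recombination-map windows it intersects (a query contained in a
#' single window inherits that window's rate; a point query gets its
#' containing window's rate). Queries overlapping no window get `NA` and
#' are counted in the `n_missing` attribute.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and an identifier column.
#' @param windows Recombination map: data frame with `chrom`, `start`,
#'   `end` (0-based half-open, non-overlapping per chromosome) and
#'   `rate_cM_per_Mb` (>= 0).
#' @return `intervals` with a `recomb_rate` column appended; attribute
#'   `n_missing` counts intervals with no overlapping window.
#' @export
assign_recomb_rate <- function(intervals, windows) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)),
            all(c("chrom", "start", "end", "rate_cM_per_Mb") %in% names(windows)))
  if (any(windows$rate_cM_per_Mb < 0)) {
    stop("recombination rates must be non-negative", call. = FALSE)
  }
  q <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end))
  s <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(start = windows$start + 1L, end = windows$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(q)[qi], IRanges::ranges(s)[si]))
  num <- rep(0, nrow(intervals))
  den <- rep(0, nrow(intervals))
  for (i in seq_along(qi)) {
    num[qi[i]] <- num[qi[i]] + ov[i] * windows$rate_cM_per_Mb[si[i]]
    den[qi[i]] <- den[qi[i]] + ov[i]
  }
  rate <- ifelse(den > 0, num / den, NA_real_)
  intervals$recomb_rate <- rate
  attr(intervals, "n_missing") <- sum(den == 0)
  intervals
}

#' Conflict-intensity tertiles
#'
#' Splits SAI values into three equal-sized groups. More-negative SAI
#' means more intense sexual antagonism, so the most negative third is
#' labelled `"high"` conflict intensity. When n is not divisible by 3 the
#' extra members go to the higher-intensity groups first; ties are broken
#' stably by value then identifier, so permuting the input never changes
#' membership.
#'
#' @param values Numeric SAI vector, length >= 3.
#' @param ids Optional identifier vector for deterministic tie-breaking
#'   (defaults to input order, which then breaks ties by position).
#' @return Factor with levels `low`, `medium`, `high`, aligned to
#'   `values`.
#' @export
assign_tertiles <- function(values, ids = NULL) {
  n <- length(values)
  if (n < 3) stop("need at least 3 values to form tertiles", call. = FALSE)
  if (is.null(ids)) ids <- seq_len(n)
  stopifnot(length(ids) == n)
  ord <- order(values, ids)  # ascending: most negative (highest conflict) first
  q <- n %/% 3
  r <- n %% 3
  sizes <- c(high = q + (r >= 1), medium = q + (r >= 2), low = q)
  lab_sorted <- rep(c("high", "medium", "low"), times = sizes)
  out <- character(n)
  out[ord] <- lab_sorted
  factor(out, levels = c("low", "medium", "high"))
}
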
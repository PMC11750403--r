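# Readers and writers for the tab-separated formats the pipeline
# consumes and emits. Coordinate conventions are converted exactly once
# at this boundary: SNP positions are 1-based in files and in memory;
# interval files (recombination map, gene intervals, liftover blocks)
# are BED-style 0-based half-open both on disk and in memory.

read_tsv_checked <- function(path, required, numeric_cols = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(basename(path), ": missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning(basename(path), ": ignoring unknown columns: ",
            paste(extra, collapse = ", "), call. = FALSE)
    df <- df[, required, drop = FALSE]
  }
  for (cc in numeric_cols) {
    if (!is.numeric(df[[cc]])) {
      stop(basename(path), ": column '", cc, "' is not numeric", call. = FALSE)
    }
    if (anyNA(df[[cc]])) {
      stop(basename(path), ": missing values in numeric column '", cc, "' (row ",
           which(is.na(df[[cc]]))[1], ")", call. = FALSE)
    }
  }
  df
}

#' Write a data frame as unquoted TSV
#'
#' All result tables in this package are plain tab-separated text with a
#' header row, no quoting and no row names; this is the single writer
#' they all go through.
#'
#' @param df Data frame.
#' @param path File path.
#' @return (Invisibly) `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

snp_table_columns <- c("snp_id", "chrom", "pos", "gene_id", "category",
                       "d_male", "d_female", "weight", "allele_freq")

#' Validate a SNP table
#'
#' Checks the 9-column candidate-SA SNP schema: 1-based positive
#' positions, categories among missense/synonymous/regulatory, positive
#' inverse-variance weights, and minor-allele frequencies in (0, 0.5].
#'
#' @param snps Data frame to validate.
#' @return The validated data frame (columns in canonical order).
#' @export
validate_snp_table <- function(snps) {
  missing <- setdiff(snp_table_columns, names(snps))
  if (length(missing)) {
    stop("SNP table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_cat <- setdiff(unique(snps$category),
                     c("missense", "synonymous", "regulatory"))
  if (length(bad_cat)) {
    stop("unknown variant category: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  }
  if (any(snps$pos < 1)) stop("SNP positions must be 1-based (>= 1)", call. = FALSE)
  if (any(snps$weight <= 0)) stop("weights must be positive", call. = FALSE)
  if (any(snps$allele_freq <= 0 | snps$allele_freq > 0.5)) {
    stop("allele frequencies must be minor-allele frequencies in (0, 0.5]",
         call. = FALSE)
  }
  snps[, snp_table_columns]
}

#' Read / write the candidate-SA SNP table
#'
#' Tab-separated with a header row and columns exactly
#' `snp_id, chrom, pos, gene_id, category, d_male, d_female, weight,
#' allele_freq`; positions 1-based; no missing numeric values.
#'
#' @param path File path.
#' @return `read_snp_table` returns the validated data frame.
#' @export
read_snp_table <- function(path) {
  df <- read_tsv_checked(path, snp_table_columns,
                         numeric_cols = c("pos", "d_male", "d_female",
                                          "weight", "allele_freq"))
  validate_snp_table(df)
}

#' @rdname read_snp_table
#' @param snps SNP table to write.
#' @export
write_snp_table <- function(snps, path) {
  write_tsv(validate_snp_table(snps), path)
}

#' Read / write a windowed recombination map
#'
#' BED4-like TSV with columns `chrom`, `start`, `end` (0-based
#' half-open, non-overlapping and sorted per chromosome) and
#' `rate_cM_per_Mb` (non-negative).
#'
#' @param path File path.
#' @return `read_recomb_map` returns the validated data frame.
#' @export
read_recomb_map <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "rate_cM_per_Mb"),
                         numeric_cols = c("start", "end", "rate_cM_per_Mb"))
  if (any(df$rate_cM_per_Mb < 0)) {
    stop(basename(path), ": negative recombination rate", call. = FALSE)
  }
  if (any(df$start >= df$end)) {
    stop(basename(path), ": empty or inverted window", call. = FALSE)
  }
  df <- df[order(df$chrom, df$start), ]
  for (chr in unique(df$chrom)) {
    b <- df[df$chrom == chr, ]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
      stop(basename(path), ": overlapping windows on ", chr, call. = FALSE)
    }
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_recomb_map
#' @param windows Map to write.
#' @export
write_recomb_map <- function(windows, path) write_tsv(windows, path)

#' Read / write gene intervals
#'
#' BED-like TSV with columns `chrom`, `start`, `end` (0-based
#' half-open) and `gene_id`.
#'
#' @param path File path.
#' @return `read_gene_intervals` returns the validated data frame.
#' @export
read_gene_intervals <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "gene_id"),
                         numeric_cols = c("start", "end"))
  if (any(df$start >= df$end)) {
    stop(basename(path), ": empty or inverted gene interval", call. = FALSE)
  }
  df
}

#' @rdname read_gene_intervals
#' @param genes Gene table to write.
#' @export
write_gene_intervals <- function(genes, path) write_tsv(genes, path)

#' Read / write a paralogue pair table
#'
#' TSV with columns `gene_a`, `gene_b`, `diopt_score` (non-negative
#' integer count of tools supporting the homology call).
#'
#' @param path File path.
#' @return `read_paralog_pairs` returns the validated data frame.
#' @export
read_paralog_pairs <- function(path) {
  df <- read_tsv_checked(path, c("gene_a", "gene_b", "diopt_score"),
                         numeric_cols = "diopt_score")
  if (any(df$diopt_score < 0)) {
    stop(basename(path), ": negative DIOPT score", call. = FALSE)
  }
  df
}

#' @rdname read_paralog_pairs
#' @param pairs Pair table to write.
#' @export
write_paralog_pairs <- function(pairs, path) write_tsv(pairs, path)

#' Read / write a liftover map
#'
#' TSV with the six [liftover_map()] columns; validated on load
#' (overlapping source intervals are an error).
#'
#' @param path File path.
#' @return `read_liftover_map` returns a validated [liftover_map()].
#' @export
read_liftover_map <- function(path) {
  df <- read_tsv_checked(path, c("source_chrom", "source_start", "source_end",
                                 "target_chrom", "target_start", "strand"),
                         numeric_cols = c("source_start", "source_end",
                                          "target_start"))
  liftover_map(df)
}

#' @rdname read_liftover_map
#' @param map Map to write.
#' @export
write_liftover_map <- function(map, path) write_tsv(as.data.frame(map), path)

#' Write a test-result table
#'
#' TSV with columns `analysis`, `method`, `statistic`, `df`, `p_raw`,
#' `p_adjusted`.
#'
#' @param results Data frame with those columns.
#' @param path File path.
#' @export
write_test_results <- function(results, path) {
  need <- c("analysis", "method", "statistic", "df", "p_raw", "p_adjusted")
  missing <- setdiff(need, names(results))
  if (length(missing)) {
    stop("results table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  write_tsv(results[, need], path)
}
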
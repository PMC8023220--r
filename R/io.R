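#' Read a gene-level count table
#'
#' The table is tab-separated with gene ids in the first column and one
#' column per sample; the header row carries sample ids that must all be
#' present in the sample sheet.  Cells must be non-negative integers.
#'
#' @param path path to the TSV file.
#' @param meta a [sample_sheet()] describing the samples.
#' @return An [expression_matrix()] with metadata aligned to the columns.
#' @export
read_counts <- function(path, meta) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("count table ", path, " has no sample columns")
  gene_ids <- as.character(df[[1]])
  sample_ids <- colnames(df)[-1]
  unknown <- setdiff(sample_ids, meta$sample_id)
  if (length(unknown)) {
    stop("sample(s) in count table absent from sample sheet: ",
         paste(unknown, collapse = ", "))
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "numeric")
  bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "invalid count for gene '%s', sample '%s': must be a non-negative integer",
      gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]))
  }
  rownames(mat) <- gene_ids
  expression_matrix(mat, meta)
}

#' Write a gene-level count table
#'
#' Inverse of [read_counts()]: first column `gene_id`, one column per sample.
#'
#' @param em an [expression_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(em, path) {
  df <- data.frame(gene_id = rownames(em$counts),
                   em$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read called m6A peaks
#'
#' Consumes peak-caller output as a 7-column BED-like table
#' (`chrom, start, end, name, fold_enrichment, summit_offset, qvalue`),
#' 0-based half-open.  The summit is `start + summit_offset` and must fall
#' inside the interval.
#'
#' @param path path to the table; a header line is expected.
#' @param replicate integer replicate label attached to every record.
#' @return A `data.frame` of peak records with columns
#'   `chrom, start, end, name, fold_enrichment, summit, qvalue, replicate`.
#' @export
read_peaks <- function(path, replicate = 1L) {
  need <- c("chrom", "start", "end", "name", "fold_enrichment",
            "summit_offset", "qvalue")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) return(empty_peaks(replicate))
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("peak file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in c("start", "end", "fold_enrichment", "summit_offset", "qvalue")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("peak file %s line %d: non-numeric '%s'",
                   path, bad[1] + 1L, col))
    }
    df[[col]] <- v
  }
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("peak file %s line %d: start >= end", path, bad[1] + 1L))
  }
  summit <- df$start + df$summit_offset
  bad <- which(summit < df$start | summit >= df$end)
  if (length(bad)) {
    stop(sprintf("peak file %s line %d: summit outside [start, end)",
                 path, bad[1] + 1L))
  }
  if (any(df$fold_enrichment <= 0)) {
    bad <- which(df$fold_enrichment <= 0)[1]
    stop(sprintf("peak file %s line %d: fold_enrichment must be > 0",
                 path, bad + 1L))
  }
  data.frame(chrom = as.character(df$chrom), start = df$start, end = df$end,
             name = as.character(df$name),
             fold_enrichment = df$fold_enrichment, summit = summit,
             qvalue = df$qvalue, replicate = as.integer(replicate),
             stringsAsFactors = FALSE)
}

empty_peaks <- function(replicate = 1L) {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), fold_enrichment = numeric(),
             summit = numeric(), qvalue = numeric(),
             replicate = integer(), stringsAsFactors = FALSE)
}

#' Write peak records in the 7-column BED-like dialect
#'
#' @param peaks a peak `data.frame` as returned by [read_peaks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  df <- data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                   name = peaks$name, fold_enrichment = peaks$fold_enrichment,
                   summit_offset = peaks$summit - peaks$start,
                   qvalue = peaks$qvalue, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an F1 allele-specific count table
#'
#' Tab-separated columns `gene_id, assay, a1_count, a2_count`: reads
#' assignable to the P1 allele (`a1`) and the P2 allele (`a2`) per gene and
#' assay, restricted upstream to genes with at least one discriminating SNP.
#'
#' @param path path to the TSV file.
#' @return A validated `data.frame` with those four columns.
#' @export
read_allele_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "assay", "a1_count", "a2_count")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("allele count table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in c("a1_count", "a2_count")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop(sprintf("allele count table %s, gene '%s': %s must be a non-negative integer",
                   path, df$gene_id[bad[1]], col))
    }
    df[[col]] <- v
  }
  bad_a <- setdiff(unique(df$assay), c("mrna_input", "m6a_ip", "polysome"))
  if (length(bad_a)) stop("unknown assay in allele counts: ",
                          paste(bad_a, collapse = ", "))
  df[, need]
}

#' Write an F1 allele-specific count table
#'
#' @param ac allele count `data.frame` (see [read_allele_counts()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(ac, path) {
  utils::write.table(ac[, c("gene_id", "assay", "a1_count", "a2_count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
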
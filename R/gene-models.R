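#' Construct a gene model
#'
#' One representative transcript per gene, held in 0-based half-open
#' genomic coordinates (BED convention).  The 5'/3' UTR intervals and the
#' spliced (mature) length are derived from the exons and the CDS span.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end) of 0-based half-open exon
#'   intervals; will be sorted; must be non-overlapping.
#' @param cds_start 0-based genomic coordinate of the first CDS base
#'   (leftmost).
#' @param cds_end 0-based half-open genomic end of the CDS (rightmost).
#' @return A list of class `"GeneModel"` with fields `gene_id, chrom,
#'   strand, exons, cds_start, cds_end, utr5, utr3, mature_length` plus the
#'   transcript-coordinate positions of the start and stop codons
#'   (`tx_start_codon`, `tx_stop_codon`).
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds_start, cds_end) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 1] >= exons[, 2])) stop(gene_id, ": exon with start >= end")
  if (nrow(exons) > 1 &&
      any(exons[-1, 1] < exons[-nrow(exons), 2])) {
    stop(gene_id, ": overlapping exons")
  }
  if (!strand %in% c("+", "-")) stop(gene_id, ": strand must be + or -")
  if (cds_start >= cds_end) stop(gene_id, ": cds_start must be < cds_end")
  if (is.na(genomic_pos_to_tx(exons, strand, cds_start)) ||
      is.na(genomic_pos_to_tx(exons, strand, cds_end - 1))) {
    stop(gene_id, ": CDS boundaries outside exons")
  }
  mature_length <- sum(exons[, 2] - exons[, 1])
  # genomic-side UTR intervals: exonic sequence outside the CDS span
  left  <- clip_intervals(exons, -Inf, cds_start)
  right <- clip_intervals(exons, cds_end, Inf)
  if (strand == "+") { utr5 <- left; utr3 <- right } else {
    utr5 <- right; utr3 <- left
  }
  # first and last CDS base in transcript (5'->3') coordinates
  if (strand == "+") {
    tx_start_codon <- genomic_pos_to_tx(exons, strand, cds_start)
    tx_stop_codon  <- genomic_pos_to_tx(exons, strand, cds_end - 1)
  } else {
    tx_start_codon <- genomic_pos_to_tx(exons, strand, cds_end - 1)
    tx_stop_codon  <- genomic_pos_to_tx(exons, strand, cds_start)
  }
  structure(list(gene_id = gene_id, chrom = as.character(chrom),
                 strand = strand, exons = exons,
                 cds_start = cds_start, cds_end = cds_end,
                 utr5 = utr5, utr3 = utr3,
                 mature_length = mature_length,
                 tx_start_codon = tx_start_codon,
                 tx_stop_codon = tx_stop_codon),
            class = "GeneModel")
}

clip_intervals <- function(ivl, lo, hi) {
  s <- pmax(ivl[, 1], lo)
  e <- pmin(ivl[, 2], hi)
  keep <- s < e
  cbind(start = s[keep], end = e[keep])
}

# 0-based genomic position -> 0-based spliced transcript coordinate (NA if
# the position is not exonic).  Exons must be sorted by start.
genomic_pos_to_tx <- function(exons, strand, pos) {
  widths <- exons[, 2] - exons[, 1]
  before <- c(0, cumsum(widths))[-(nrow(exons) + 1)]
  hit <- which(pos >= exons[, 1] & pos < exons[, 2])
  if (!length(hit)) return(NA_real_)
  plus_coord <- unname(before[hit] + (pos - exons[hit, 1]))
  if (strand == "+") plus_coord else sum(widths) - 1 - plus_coord
}

# 0-based transcript coordinate -> genomic position (inverse of the above)
tx_pos_to_genomic <- function(exons, strand, txpos) {
  widths <- exons[, 2] - exons[, 1]
  total <- sum(widths)
  if (txpos < 0 || txpos >= total) return(NA_real_)
  plus_coord <- if (strand == "+") txpos else total - 1 - txpos
  before <- c(0, cumsum(widths))
  hit <- findInterval(plus_coord, before, rightmost.closed = FALSE)
  exons[hit, 1] + (plus_coord - before[hit])
}

#' Transcript coordinate of a genomic position within a gene model
#'
#' @param model a [gene_model()].
#' @param pos 0-based genomic position.
#' @return 0-based position along the spliced transcript (5' to 3'), or
#'   `NA` if `pos` is not exonic.
#' @export
model_tx_coord <- function(model, pos) {
  genomic_pos_to_tx(model$exons, model$strand, pos)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features (1-based inclusive coordinates per
#' the GFF3 standard), keeps the longest mRNA per gene as its
#' representative transcript, and converts coordinates to the internal
#' 0-based half-open convention.  Genes lacking a CDS, or whose CDS falls
#' outside the exons, are skipped with a warning.
#'
#' @param path path to a GFF3 file.
#' @return A named list of [gene_model()] objects, class `"GeneModels"`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(gr$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  seqname <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  fstart <- GenomicRanges::start(gr)
  fend <- GenomicRanges::end(gr)

  genes <- which(type == "gene")
  mrnas <- which(type %in% c("mRNA", "transcript"))
  exons <- which(type == "exon")
  cdss <- which(type == "CDS")

  tx_by_gene <- split(mrnas, parents[mrnas])
  exon_by_tx <- split(exons, parents[exons])
  cds_by_tx <- split(cdss, parents[cdss])

  models <- list()
  for (g in genes) {
    gid <- ids[g]
    tx <- tx_by_gene[[gid]]
    if (is.null(tx) || !length(tx)) {
      warning("gene ", gid, " has no mRNA feature; skipped")
      next
    }
    tx_ids <- ids[tx]
    tx_len <- vapply(tx_ids, function(t) {
      ex <- exon_by_tx[[t]]
      if (is.null(ex)) 0 else sum(fend[ex] - fstart[ex] + 1)
    }, numeric(1))
    best <- tx_ids[which.max(tx_len)]
    ex <- exon_by_tx[[best]]
    cd <- cds_by_tx[[best]]
    if (is.null(ex) || !length(ex)) {
      warning("gene ", gid, " transcript ", best, " has no exons; skipped")
      next
    }
    if (is.null(cd) || !length(cd)) {
      warning("gene ", gid, " has no CDS feature; skipped")
      next
    }
    # 1-based inclusive -> 0-based half-open
    exm <- cbind(start = fstart[ex] - 1, end = fend[ex])
    cds_start <- min(fstart[cd]) - 1
    cds_end <- max(fend[cd])
    str <- if (strand[g] %in% c("+", "-")) strand[g] else "+"
    m <- tryCatch(
      gene_model(gid, seqname[g], str, exm, cds_start, cds_end),
      error = function(e) {
        warning("gene ", gid, " skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(m)) models[[gid]] <- m
  }
  structure(models, class = "GeneModels")
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon/CDS features, converting the internal 0-based
#' half-open coordinates back to GFF3's 1-based inclusive convention.
#'
#' @param models a `"GeneModels"` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  rows <- lapply(models, function(m) {
    span <- c(min(m$exons[, 1]), max(m$exons[, 2]))
    tx_id <- paste0(m$gene_id, "_T001")
    n_ex <- nrow(m$exons)
    data.frame(
      seqid = m$chrom,
      source = "heteromics",
      type = c("gene", "mRNA", rep("exon", n_ex), "CDS"),
      start = c(span[1] + 1, span[1] + 1, m$exons[, 1] + 1, m$cds_start + 1),
      end = c(span[2], span[2], m$exons[, 2], m$cds_end),
      score = ".", strand = m$strand, phase = ".",
      attributes = c(paste0("ID=", m$gene_id),
                     paste0("ID=", tx_id, ";Parent=", m$gene_id),
                     paste0("ID=", tx_id, ":exon:", seq_len(n_ex),
                            ";Parent=", tx_id),
                     paste0("ID=", tx_id, ":cds;Parent=", tx_id)),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Genomic span GRanges for a set of gene models
#'
#' Used for interval queries such as assigning peak summits to genes.
#'
#' @param models a `"GeneModels"` list.
#' @return A [GenomicRanges::GRanges] with one range per gene (0-based
#'   half-open converted to the GRanges 1-based convention) and a
#'   `gene_id` metadata column.
#' @export
models_span_granges <- function(models) {
  if (!length(models)) {
    return(GenomicRanges::GRanges())
  }
  chrom <- vapply(models, `[[`, character(1), "chrom")
  start0 <- vapply(models, function(m) min(m$exons[, 1]), numeric(1))
  end0 <- vapply(models, function(m) max(m$exons[, 2]), numeric(1))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = vapply(models, `[[`, character(1), "strand"))
  gr$gene_id <- vapply(models, `[[`, character(1), "gene_id")
  gr
}
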
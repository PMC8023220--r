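#' Compute FPKM from raw counts
#'
#' FPKM for gene g in sample s is
#' `count[g,s] * 1e9 / (total_counts[s] * mature_length[g])`, with
#' per-sample totals taken over the genes present in the matrix and gene
#' length the spliced (exon-union) length of the representative transcript.
#'
#' @param em an [expression_matrix()].
#' @param models a `"GeneModels"` list covering every gene in `em`.
#' @return A list of class `"FpkmMatrix"` with elements `fpkm` (genes x
#'   samples real matrix) and `samples` (the sample sheet).
#' @export
compute_fpkm <- function(em, models) {
  genes <- rownames(em$counts)
  missing <- setdiff(genes, names(models))
  if (length(missing)) {
    stop("gene(s) without a model: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  }
  len <- vapply(models[genes], `[[`, numeric(1), "mature_length")
  totals <- colSums(em$counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(em$counts)[totals == 0], collapse = ", "))
  }
  fpkm <- sweep(em$counts, 2, totals, "/") * 1e9 / len
  structure(list(fpkm = fpkm, samples = em$samples), class = "FpkmMatrix")
}

group_key <- function(samples) paste(samples$genotype, samples$assay, sep = ".")

# mean FPKM over replicates, one column per (genotype, assay) group
group_mean_fpkm <- function(f) {
  key <- group_key(f$samples)
  groups <- unique(key)
  out <- vapply(groups, function(g)
    rowMeans(f$fpkm[, key == g, drop = FALSE]), numeric(nrow(f$fpkm)))
  dimnames(out) <- list(rownames(f$fpkm), groups)
  out
}

#' Flag expressed genes per genotype and assay
#'
#' A gene is expressed in a (genotype, assay) group when its mean FPKM
#' over the group's replicates is at least `threshold`.
#'
#' @param f an `"FpkmMatrix"` from [compute_fpkm()].
#' @param threshold minimum mean-replicate FPKM (default 1).
#' @return A logical matrix, genes x `"genotype.assay"` groups.
#' @export
expressed_filter <- function(f, threshold = 1.0) {
  stopifnot(threshold >= 0)
  group_mean_fpkm(f) >= threshold
}

#' Compute translational efficiency per genotype
#'
#' TE = mean-replicate polysome FPKM / mean-replicate mRNA-input FPKM,
#' defined only for genes passing the expressed filter in the input assay
#' of that genotype; `NA` otherwise.
#'
#' @param f an `"FpkmMatrix"` containing both `mrna_input` and `polysome`
#'   samples for the requested genotypes.
#' @param expressed logical matrix from [expressed_filter()].
#' @param genotypes genotypes to compute (default: all present).
#' @return A real matrix, genes x genotypes, with `NA` where undefined.
#' @export
compute_te <- function(f, expressed, genotypes = unique(f$samples$genotype)) {
  gm <- group_mean_fpkm(f)
  out <- matrix(NA_real_, nrow(f$fpkm), length(genotypes),
                dimnames = list(rownames(f$fpkm), genotypes))
  for (g in genotypes) {
    poly_col <- paste0(g, ".polysome")
    in_col <- paste0(g, ".mrna_input")
    if (!poly_col %in% colnames(gm) || !in_col %in% colnames(gm)) {
      stop("genotype ", g, " lacks polysome and/or mrna_input samples")
    }
    ok <- expressed[, in_col]
    te <- gm[, poly_col] / gm[, in_col]
    te[!ok] <- NA_real_
    out[, g] <- te
  }
  out
}

#' Build high-confidence consensus peaks from two replicates
#'
#' Peaks overlapping (>= 1 bp) between the two biological replicates are
#' designated high-confidence.  A replicate peak overlapping several
#' partners pairs with the partner of largest overlap; every input peak is
#' used at most once.  The consensus interval is the union of the two
#' replicate intervals, the summit comes from the replicate with larger
#' fold enrichment, and the consensus m6A level is the mean of the two
#' replicate fold enrichments.
#'
#' @param rep1,rep2 peak `data.frame`s as returned by [read_peaks()].
#' @return A `data.frame` of consensus peaks with columns
#'   `chrom, start, end, summit, m6a_level`; the `gene_id`/`segment`
#'   columns are added by [annotate_peaks()].
#' @export
consensus_peaks <- function(rep1, rep2) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), summit = numeric(),
                      m6a_level = numeric(), stringsAsFactors = FALSE)
  if (nrow(rep1) == 0 || nrow(rep2) == 0) return(empty)
  gr1 <- GenomicRanges::GRanges(rep1$chrom,
                                IRanges::IRanges(rep1$start + 1, rep1$end))
  gr2 <- GenomicRanges::GRanges(rep2$chrom,
                                IRanges::IRanges(rep2$start + 1, rep2$end))
  ov <- GenomicRanges::findOverlaps(gr1, gr2)
  if (!length(ov)) return(empty)
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  width <- pmin(rep1$end[q], rep2$end[s]) - pmax(rep1$start[q], rep2$start[s])
  # greedy maximal matching by overlap width; each peak used at most once
  ord <- order(-width, q, s)
  used1 <- logical(nrow(rep1)); used2 <- logical(nrow(rep2))
  keep <- logical(length(ord))
  for (i in ord) {
    if (!used1[q[i]] && !used2[s[i]]) {
      keep[i] <- TRUE
      used1[q[i]] <- TRUE
      used2[s[i]] <- TRUE
    }
  }
  q <- q[keep]; s <- s[keep]
  pick1 <- rep1$fold_enrichment[q] >= rep2$fold_enrichment[s]
  out <- data.frame(
    chrom = rep1$chrom[q],
    start = pmin(rep1$start[q], rep2$start[s]),
    end = pmax(rep1$end[q], rep2$end[s]),
    summit = ifelse(pick1, rep1$summit[q], rep2$summit[s]),
    m6a_level = (rep1$fold_enrichment[q] + rep2$fold_enrichment[s]) / 2,
    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Assign a peak summit to a transcript segment
#'
#' Classification works on the spliced-transcript coordinate of the summit
#' with the codon windows taking priority: (1) within `window_nt/2` nt of
#' the start codon (inclusive) -> `"start"`; (2) within `window_nt/2` nt of
#' the stop codon -> `"stop"`; then (3) 5'UTR, (4) CDS, (5) 3'UTR by
#' position relative to the codons; (6) a summit inside the gene span but
#' not exonic -> `"intron"`; (7) anything else -> `"intergenic"`.
#'
#' @param summit 0-based genomic coordinate of the peak summit.
#' @param model a [gene_model()], or `NULL` when no gene contains the
#'   summit.
#' @param window_nt even window width centred on each codon (default 200).
#' @return One of `"utr5", "start", "cds", "stop", "utr3", "intron",
#'   "intergenic"`.
#' @export
assign_segment <- function(summit, model, window_nt = 200L) {
  if (is.null(model)) return("intergenic")
  half <- window_nt / 2
  tx <- model_tx_coord(model, summit)
  if (is.na(tx)) {
    span <- c(min(model$exons[, 1]), max(model$exons[, 2]))
    if (summit >= span[1] && summit < span[2]) return("intron")
    return("intergenic")
  }
  if (abs(tx - model$tx_start_codon) <= half) return("start")
  if (abs(tx - model$tx_stop_codon) <= half) return("stop")
  if (tx < model$tx_start_codon) return("utr5")
  if (tx > model$tx_stop_codon) return("utr3")
  "cds"
}

#' Annotate consensus peaks with gene and segment
#'
#' Assigns each peak to the gene whose span contains its summit (preferring
#' a gene in which the summit is exonic when spans overlap), then labels
#' the transcript segment via [assign_segment()].
#'
#' @param peaks consensus peak `data.frame` from [consensus_peaks()].
#' @param models a `"GeneModels"` list.
#' @param window_nt codon window width in nt (default 200).
#' @return `peaks` with `gene_id` (NA when intergenic) and `segment`
#'   columns appended.
#' @export
annotate_peaks <- function(peaks, models, window_nt = 200L) {
  peaks$gene_id <- NA_character_
  peaks$segment <- rep("intergenic", nrow(peaks))
  if (!nrow(peaks)) return(peaks)
  spans <- models_span_granges(models)
  summit_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$summit + 1, peaks$summit + 1))
  ov <- GenomicRanges::findOverlaps(summit_gr, spans, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  for (i in unique(q)) {
    cand <- spans$gene_id[s[q == i]]
    exonic <- vapply(cand, function(g)
      !is.na(model_tx_coord(models[[g]], peaks$summit[i])), logical(1))
    gid <- if (any(exonic)) cand[which(exonic)[1]] else cand[1]
    peaks$gene_id[i] <- gid
    peaks$segment[i] <- assign_segment(peaks$summit[i], models[[gid]],
                                       window_nt)
  }
  peaks
}

#' Per-gene m6A level from annotated consensus peaks
#'
#' The m6A level of a gene is the maximum consensus-peak level over its
#' peaks; genes without a consensus peak are unmodified and absent from
#' the result.
#'
#' @param peaks annotated consensus peaks (with `gene_id` and `m6a_level`).
#' @return A `data.frame` with columns `gene_id, m6a_level, n_peaks`.
#' @export
gene_m6a_level <- function(peaks) {
  p <- peaks[!is.na(peaks$gene_id), , drop = FALSE]
  if (!nrow(p)) {
    return(data.frame(gene_id = character(), m6a_level = numeric(),
                      n_peaks = integer(), stringsAsFactors = FALSE))
  }
  lev <- tapply(p$m6a_level, p$gene_id, max)
  n <- tapply(p$m6a_level, p$gene_id, length)
  data.frame(gene_id = names(lev), m6a_level = as.numeric(lev),
             n_peaks = as.integer(n), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fraction of peaks per transcript segment
#'
#' @param peaks annotated consensus peaks.
#' @return Named numeric vector of fractions over all peaks; sums to 1.
#' @export
segment_distribution <- function(peaks) {
  if (!nrow(peaks)) stop("no peaks to summarise")
  tab <- table(peaks$segment)
  as.numeric(tab) / sum(tab) -> frac
  names(frac) <- names(tab)
  frac
}
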
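# Shared fixtures and independent brute-force oracles.

# three-exon plus-strand gene: exons (0-based half-open)
# [1000,1200) [1500,1900) [2300,2800); mature length 200+400+500 = 1100
# CDS from genomic 1100 to 2500 -> transcript start codon at 100,
# stop codon at 799 (5'UTR 100 nt, spliced CDS 700 nt, 3'UTR 300 nt)
plus_model <- function() {
  gene_model("gplus", "chr1", "+",
             rbind(c(1000, 1200), c(1500, 1900), c(2300, 2800)),
             cds_start = 1100, cds_end = 2500)
}

# same exon layout on the minus strand with CDS 1600..2600: the 5'UTR is
# the high-coordinate side (200 nt), start codon at transcript position
# 200, stop codon at 799, 3'UTR 300 nt
minus_model <- function() {
  gene_model("gminus", "chr1", "-",
             rbind(c(1000, 1200), c(1500, 1900), c(2300, 2800)),
             cds_start = 1600, cds_end = 2600)
}

make_sheet <- function(genotypes, assay = "mrna_input", nrep = 2) {
  ids <- as.vector(outer(seq_len(nrep), genotypes,
                         function(r, g) paste0(g, "_", assay, "_r", r)))
  sample_sheet(ids, rep(genotypes, each = nrep), assay,
               rep(seq_len(nrep), length(genotypes)))
}

make_em <- function(counts, genotypes, assay = "mrna_input", nrep = 2) {
  sheet <- make_sheet(genotypes, assay, nrep)
  colnames(counts) <- sheet$sample_id
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%04d", seq_len(nrow(counts)))
  }
  expression_matrix(counts, sheet)
}

nb_counts <- function(n_genes, mu, nrep, disp = 0.1) {
  sapply(seq_len(nrep), function(j) rnbinom(n_genes, mu = mu, size = 1 / disp))
}

# independent median-of-ratios oracle, written straight from the
# definition with explicit loops
bf_size_factors <- function(counts) {
  keep <- apply(counts, 1, function(r) all(r > 0))
  ref <- numeric(sum(keep))
  sub <- counts[keep, , drop = FALSE]
  for (i in seq_len(nrow(sub))) ref[i] <- prod(sub[i, ])^(1 / ncol(sub))
  sf <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    sf[j] <- median(sub[, j] / ref)
  }
  sf / prod(sf)^(1 / length(sf))
}

# brute-force consensus oracle: enumerate all overlapping pairs, accept
# greedily by decreasing overlap width, each peak once
bf_consensus <- function(rep1, rep2) {
  pairs <- list()
  for (i in seq_len(nrow(rep1))) {
    for (j in seq_len(nrow(rep2))) {
      if (rep1$chrom[i] != rep2$chrom[j]) next
      w <- min(rep1$end[i], rep2$end[j]) - max(rep1$start[i], rep2$start[j])
      if (w > 0) pairs[[length(pairs) + 1]] <- c(i, j, w)
    }
  }
  if (!length(pairs)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), summit = numeric(),
                      m6a_level = numeric()))
  }
  pm <- do.call(rbind, pairs)
  pm <- pm[order(-pm[, 3], pm[, 1], pm[, 2]), , drop = FALSE]
  used1 <- logical(nrow(rep1)); used2 <- logical(nrow(rep2))
  out <- list()
  for (r in seq_len(nrow(pm))) {
    i <- pm[r, 1]; j <- pm[r, 2]
    if (used1[i] || used2[j]) next
    used1[i] <- TRUE; used2[j] <- TRUE
    pick1 <- rep1$fold_enrichment[i] >= rep2$fold_enrichment[j]
    out[[length(out) + 1]] <- data.frame(
      chrom = rep1$chrom[i],
      start = min(rep1$start[i], rep2$start[j]),
      end = max(rep1$end[i], rep2$end[j]),
      summit = if (pick1) rep1$summit[i] else rep2$summit[j],
      m6a_level = (rep1$fold_enrichment[i] + rep2$fold_enrichment[j]) / 2,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# independent segment oracle: builds the explicit transcript-order vector
# of genomic positions by walking exons, locates the summit and the codon
# positions in it, then applies the priority rules
bf_segment <- function(model, summit, window_nt = 200) {
  ex <- model$exons
  gpos <- unlist(lapply(seq_len(nrow(ex)), function(i)
    seq(ex[i, 1], ex[i, 2] - 1)))
  if (model$strand == "-") gpos <- rev(gpos)
  tx <- match(summit, gpos)
  if (is.na(tx)) {
    span <- range(c(ex[, 1], ex[, 2] - 1))
    if (summit >= span[1] && summit <= span[2]) return("intron")
    return("intergenic")
  }
  tx <- tx - 1
  first_cds <- if (model$strand == "+") model$cds_start else model$cds_end - 1
  last_cds <- if (model$strand == "+") model$cds_end - 1 else model$cds_start
  st <- match(first_cds, gpos) - 1
  sp <- match(last_cds, gpos) - 1
  half <- window_nt / 2
  if (abs(tx - st) <= half) return("start")
  if (abs(tx - sp) <= half) return("stop")
  if (tx < st) return("utr5")
  if (tx > sp) return("utr3")
  "cds"
}

random_peaks <- function(n, chrom = "chr1", replicate = 1L) {
  start <- sort(sample.int(20000, n)) * 5
  width <- sample(50:300, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + width,
             name = paste0("p", seq_len(n)),
             fold_enrichment = runif(n, 1, 10),
             summit = start + floor(width / 2),
             qvalue = 1e-5, replicate = replicate,
             stringsAsFactors = FALSE)
}

# adjusted Rand index between two labelings (closed form from the
# pair-counting contingency table)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
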
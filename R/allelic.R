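#' Exact binomial test of allelic bias in the hybrid
#'
#' Two-sided exact binomial test of the P1-allele read count against an
#' equal (0.5) expectation, per gene, for one assay.  Genes below the
#' minimum informative depth are reported with `NA`.
#'
#' @param t allele count `data.frame` with columns `gene_id, a1_count,
#'   a2_count` (an `assay` column, if present, must be single-valued).
#' @param alpha per-gene significance cutoff (default 0.01, unadjusted).
#' @param min_depth minimum `a1 + a2` for a test (default 10).
#' @return A `data.frame`: `gene_id, a1_count, a2_count, ratio_log2, p,
#'   biased, direction` (direction in `a1_higher/a2_higher/none`).
#' @export
allelic_bias_test <- function(t, alpha = 0.01, min_depth = 10) {
  if ("assay" %in% names(t) && length(unique(t$assay)) > 1) {
    stop("allelic_bias_test expects a single assay; split the table first")
  }
  a1 <- t$a1_count; a2 <- t$a2_count
  n <- a1 + a2
  p <- rep(NA_real_, nrow(t))
  idx <- which(n >= min_depth)
  p[idx] <- vapply(idx, function(i)
    stats::binom.test(a1[i], n[i], p = 0.5)$p.value, numeric(1))
  biased <- p < alpha
  ratio_log2 <- log2((a1 + 0.5) / (a2 + 0.5))
  direction <- ifelse(is.na(biased) | !biased, "none",
                      ifelse(a1 > a2, "a1_higher", "a2_higher"))
  direction[is.na(p)] <- NA_character_
  data.frame(gene_id = t$gene_id, a1_count = a1, a2_count = a2,
             ratio_log2 = ratio_log2, p = p, biased = biased,
             direction = direction, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify cis/trans regulatory divergence
#'
#' Combines parental expression divergence (A) with F1 allelic divergence
#' (B).  Three exact tests per gene at the unadjusted `alpha` cutoff:
#' `testA`, a binomial test of the between-parent normalized SNP-covered
#' counts against equality; `testB`, a binomial test of the F1 allele
#' counts ([allelic_bias_test()]); `testAB`, a Fisher exact test of the
#' 2x2 table (parents vs F1 alleles) for `A != B`.  Categories:
#' cis-only (A!=0, B!=0, A=B); trans-only (A!=0, B=0, A!=B);
#' cis-and-trans (A!=0, B!=0, A!=B; enhancing when the cis effect
#' `B` and the trans effect `A - B` share a sign, compensating
#' otherwise); fully compensatory (A=0, B!=0, A!=B; merged into
#' cis-and-trans); conserved otherwise.  Test-outcome combinations outside
#' this table (e.g. parents diverged but neither B nor the A-B comparison
#' reaches significance) are resolved as conserved and counted, never
#' dropped.
#'
#' @param parental `data.frame` with `gene_id, p1_count, p2_count`:
#'   per-gene SNP-covered read totals for each parent; normalized between
#'   parents by their SNP-covered library sizes before testing.
#' @param f1_alleles allele count `data.frame` for the F1 (one assay):
#'   `gene_id, a1_count, a2_count`.
#' @param alpha per-test significance cutoff (default 0.01).
#' @param min_depth minimum depth per side of each test (default 10);
#'   below it the gene is unclassified.
#' @return A `data.frame`: `gene_id, A_log2, B_log2, pA, pB, pAB,
#'   category, subtype` with category in
#'   `cis_only/trans_only/cis_and_trans/conserved` (NA when unclassified)
#'   and subtype in `enhancing/compensating/fully_compensatory/none`.
#' @export
classify_cis_trans <- function(parental, f1_alleles, alpha = 0.01,
                               min_depth = 10) {
  genes <- intersect(parental$gene_id, f1_alleles$gene_id)
  pa <- parental[match(genes, parental$gene_id), ]
  fa <- f1_alleles[match(genes, f1_alleles$gene_id), ]
  lib1 <- sum(as.numeric(parental$p1_count))
  lib2 <- sum(as.numeric(parental$p2_count))
  if (lib1 == 0 || lib2 == 0) stop("a parent has zero SNP-covered reads")
  scale_to <- sqrt(lib1 * lib2)
  p1n <- round(pa$p1_count * scale_to / lib1)
  p2n <- round(pa$p2_count * scale_to / lib2)
  a1 <- fa$a1_count; a2 <- fa$a2_count

  n <- length(genes)
  pA <- pB <- pAB <- rep(NA_real_, n)
  ok <- (p1n + p2n >= min_depth) & (a1 + a2 >= min_depth)
  for (i in which(ok)) {
    pA[i] <- stats::binom.test(p1n[i], p1n[i] + p2n[i], p = 0.5)$p.value
    pB[i] <- stats::binom.test(a1[i], a1[i] + a2[i], p = 0.5)$p.value
    pAB[i] <- stats::fisher.test(
      matrix(c(p1n[i], p2n[i], a1[i], a2[i]), nrow = 2))$p.value
  }
  A_log2 <- log2((p1n + 0.5) / (p2n + 0.5))
  B_log2 <- log2((a1 + 0.5) / (a2 + 0.5))
  sA <- pA < alpha; sB <- pB < alpha; sAB <- pAB < alpha

  category <- rep(NA_character_, n)
  subtype <- rep(NA_character_, n)
  category[ok] <- "conserved"; subtype[ok] <- "none"
  ci <- ok & sA & sB & !sAB
  category[ci] <- "cis_only"
  tr <- ok & sA & !sB & sAB
  category[tr] <- "trans_only"
  ct <- ok & sA & sB & sAB
  category[ct] <- "cis_and_trans"
  trans_eff <- A_log2 - B_log2
  subtype[ct] <- ifelse(B_log2[ct] * trans_eff[ct] >= 0,
                        "enhancing", "compensating")
  fc <- ok & !sA & sB & sAB
  category[fc] <- "cis_and_trans"
  subtype[fc] <- "fully_compensatory"

  data.frame(gene_id = genes, A_log2 = A_log2, B_log2 = B_log2,
             pA = pA, pB = pB, pAB = pAB, category = category,
             subtype = subtype, row.names = NULL, stringsAsFactors = FALSE)
}

#' Tabulate cis/trans categories
#'
#' @param calls `data.frame` from [classify_cis_trans()], or a named
#'   vector of category counts in the order cis_only, trans_only,
#'   cis_and_trans, conserved.
#' @return A `data.frame` with `category, n, percent` where percentages
#'   (one decimal, [percent_round()]) are of the classified total.
#' @export
cis_trans_table <- function(calls) {
  cats <- c("cis_only", "trans_only", "cis_and_trans", "conserved")
  if (is.data.frame(calls)) {
    cl <- calls$category[!is.na(calls$category)]
    n <- vapply(cats, function(k) sum(cl == k), integer(1))
  } else {
    n <- as.integer(calls)
    names(n) <- cats
  }
  total <- sum(n)
  if (total == 0) stop("no classified genes")
  data.frame(category = cats, n = as.integer(n),
             percent = percent_round(as.numeric(n), total),
             row.names = NULL, stringsAsFactors = FALSE)
}
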
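#' Median-of-ratios size factors
#'
#' Computes per-sample normalization factors against a geometric-mean
#' pseudo-reference built from genes with nonzero counts in every sample,
#' then rescales the factors to geometric mean 1.  When no gene is nonzero
#' in all samples the function falls back to total-count scaling with a
#' message.
#'
#' @param counts genes x samples count matrix (or an
#'   [expression_matrix()]).
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "ExpressionMatrix")) counts <- counts$counts
  all_nonzero <- rowSums(counts == 0) == 0
  if (!any(all_nonzero)) {
    message("size_factors: no gene nonzero in every sample; ",
            "falling back to total-count scaling")
    sf <- colSums(counts)
  } else {
    ref <- exp(rowMeans(log(counts[all_nonzero, , drop = FALSE])))
    sf <- apply(counts[all_nonzero, , drop = FALSE], 2,
                function(col) stats::median(col / ref))
  }
  if (any(sf <= 0)) stop("non-positive size factor; check input counts")
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

# Gene-wise method-of-moments dispersion on normalized counts, pooled over
# the two groups, then shrunk 50/50 toward a fitted mean-dispersion trend
# (a0 + a1/mean, the usual parametric form for RNA-seq data).
estimate_dispersions <- function(norm, group_idx) {
  base_mean <- rowMeans(norm)
  raw <- rep(NA_real_, nrow(norm))
  num <- rep(0, nrow(norm)); den <- rep(0, nrow(norm))
  for (idx in group_idx) {
    n <- length(idx)
    if (n < 2) next
    m <- rowMeans(norm[, idx, drop = FALSE])
    v <- apply(norm[, idx, drop = FALSE], 1, stats::var)
    d <- ifelse(m > 0, (v - m) / m^2, NA_real_)
    ok <- !is.na(d)
    num[ok] <- num[ok] + (n - 1) * d[ok]
    den[ok] <- den[ok] + (n - 1)
  }
  raw <- ifelse(den > 0, num / pmax(den, 1), NA_real_)
  # trend fitted on the unclamped estimates so clamping does not bias it
  fit_ok <- !is.na(raw) & base_mean > 1
  trend <- rep(NA_real_, nrow(norm))
  if (sum(fit_ok) >= 10) {
    co <- stats::coef(stats::lm(raw[fit_ok] ~ I(1 / base_mean[fit_ok])))
    a0 <- max(co[1], 1e-4); a1 <- max(co[2], 0)
    trend <- a0 + a1 / pmax(base_mean, 1e-8)
  } else {
    trend <- rep(max(stats::median(raw, na.rm = TRUE), 1e-4), nrow(norm))
  }
  raw_clamped <- pmin(pmax(raw, 1e-8), 10)
  disp <- 0.5 * raw_clamped + 0.5 * pmin(pmax(trend, 1e-8), 10)
  disp[is.na(disp)] <- pmin(pmax(trend[is.na(disp)], 1e-8), 10)
  disp
}

#' Negative-binomial Wald test between two sample groups
#'
#' Per gene: size-factor normalization, gene-wise method-of-moments
#' dispersion shrunk 50/50 toward the dispersion-mean trend, then a Wald
#' test on the log fold change between the two groups with the
#' delta-method standard error `sqrt((1/mu_a + disp)/n_a +
#' (1/mu_b + disp)/n_b)` and a moderated t reference whose degrees of
#' freedom combine the per-gene residual df with a prior df contributed
#' by the dispersion trend.  Log2 fold changes are computed
#' from normalized group means with pseudocount 0.5; p-values are BH
#' adjusted across tested genes.
#'
#' @param em an [expression_matrix()] containing (at least) the two groups.
#' @param contrast character vector `c(group_a, group_b)`; positive
#'   `log2fc` means higher in `group_a`.  Matched against
#'   `em$samples$genotype` by default.
#' @param cfg a [run_config()].
#' @param group optional character vector overriding the per-sample group
#'   labels (same length as samples), e.g. to contrast pseudo-samples.
#' @param sf optional fixed size factors (skips estimation).
#' @return A `data.frame`: `gene_id, base_mean, log2fc, p, p_adj,
#'   significant`.  Genes with all-zero counts in both groups get `NA`
#'   statistics and `significant = NA`.
#' @export
nb_test <- function(em, contrast, cfg = run_config(), group = NULL,
                    sf = NULL) {
  if (is.null(group)) group <- em$samples$genotype
  stopifnot(length(contrast) == 2)
  ia <- which(group == contrast[1]); ib <- which(group == contrast[2])
  if (length(ia) < 2 || length(ib) < 2) {
    stop("each side of the contrast needs >= 2 replicates")
  }
  counts <- em$counts[, c(ia, ib), drop = FALSE]
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  na <- length(ia); nb <- length(ib)
  ja <- seq_len(na); jb <- na + seq_len(nb)
  ma <- rowMeans(norm[, ja, drop = FALSE])
  mb <- rowMeans(norm[, jb, drop = FALSE])
  testable <- ma + mb > 0
  disp <- estimate_dispersions(norm, list(ja, jb))
  beta <- log((ma + 0.5) / (mb + 0.5))
  se <- sqrt((1 / (ma + 0.5) + disp) / na + (1 / (mb + 0.5) + disp) / nb)
  stat <- beta / se
  # moderated reference: shrinking the dispersion toward the trend adds
  # information beyond the per-gene residual df, so the t reference uses
  # residual df plus a prior df of three times the residual
  p <- 2 * stats::pt(-abs(stat), df = 4 * (na + nb - 2))
  p[!testable] <- NA_real_
  p_adj <- rep(NA_real_, length(p))
  p_adj[testable] <- stats::p.adjust(p[testable], method = "BH")
  log2fc <- beta / log(2)
  log2fc[!testable] <- NA_real_
  p_eff <- if (cfg$multiple_testing == "bh_fdr") p_adj else p
  significant <- p_eff < cfg$alpha & abs(log2fc) >= log2(cfg$fc_threshold)
  data.frame(gene_id = rownames(em$counts),
             base_mean = (ma + mb) / 2,
             log2fc = log2fc, p = p, p_adj = p_adj,
             significant = significant,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build mid-parent pseudo-samples
#'
#' Pairs P1 and P2 replicates in index order and averages their
#' size-factor-normalized counts; unequal replicate numbers are paired up
#' to the minimum with a message.
#'
#' @param em an [expression_matrix()] for one assay containing P1, P2 and
#'   F1 samples.
#' @return A list with `mpv` (genes x pairs real matrix of mid-parent
#'   normalized counts) and `f1_norm` (genes x F1-replicates normalized
#'   counts), both on the common normalized scale.
#' @export
mpv_pseudo_samples <- function(em) {
  sf <- size_factors(em$counts)
  norm <- sweep(em$counts, 2, sf, "/")
  g <- em$samples$genotype
  i1 <- which(g == "P1")[order(em$samples$replicate[g == "P1"])]
  i2 <- which(g == "P2")[order(em$samples$replicate[g == "P2"])]
  i3 <- which(g == "F1")
  if (length(i1) < 2 || length(i2) < 2 || length(i3) < 2) {
    stop("P1, P2 and F1 each need >= 2 replicates for the MPV contrast")
  }
  k <- min(length(i1), length(i2))
  if (length(i1) != length(i2)) {
    message("mpv_pseudo_samples: unequal parental replicates; pairing the first ",
            k, " of each")
  }
  mpv <- (norm[, i1[seq_len(k)], drop = FALSE] +
            norm[, i2[seq_len(k)], drop = FALSE]) / 2
  colnames(mpv) <- paste0("MPV_rep", seq_len(k))
  list(mpv = mpv, f1_norm = norm[, i3, drop = FALSE])
}

#' Test the hybrid against the in-silico mid-parent value
#'
#' Constructs mid-parent pseudo-samples with [mpv_pseudo_samples()]
#' (rounded to the nearest integer for the count model) and runs the
#' [nb_test()] machinery on F1 versus MPV with unit size factors (both
#' sides are already on the normalized scale).
#'
#' @param em an [expression_matrix()] for one assay with P1, P2, F1.
#' @param cfg a [run_config()].
#' @return A `data.frame` as from [nb_test()]; positive `log2fc` means the
#'   hybrid exceeds the mid-parent value.
#' @export
mpv_contrast <- function(em, cfg = run_config()) {
  ps <- mpv_pseudo_samples(em)
  mat <- round(cbind(ps$f1_norm, ps$mpv))
  grp <- c(rep("F1", ncol(ps$f1_norm)), rep("MPV", ncol(ps$mpv)))
  colnames(mat) <- make.unique(c(colnames(ps$f1_norm), colnames(ps$mpv)))
  meta <- sample_sheet(colnames(mat),
                       genotype = ifelse(grp == "F1", "F1", "P1"),
                       assay = "mrna_input",
                       replicate = stats::ave(seq_along(grp), grp,
                                              FUN = seq_along))
  em2 <- expression_matrix(mat, meta)
  nb_test(em2, c("F1", "MPV"), cfg, group = grp,
          sf = rep(1, ncol(mat)))
}

# Per-replicate log2 translational efficiency: genes x (genotype,replicate),
# from size-factor-normalized polysome and input counts with pseudocount 0.5.
# Replicates are matched within genotype by replicate index.
te_replicate_log2 <- function(poly, input) {
  sfp <- size_factors(poly$counts)
  sfi <- size_factors(input$counts)
  np <- sweep(poly$counts, 2, sfp, "/")
  ni <- sweep(input$counts, 2, sfi, "/")
  keyp <- paste(poly$samples$genotype, poly$samples$replicate, sep = ".")
  keyi <- paste(input$samples$genotype, input$samples$replicate, sep = ".")
  common <- intersect(keyp, keyi)
  if (!length(common)) stop("no matched (genotype, replicate) pairs between assays")
  lt <- log2((np[, match(common, keyp), drop = FALSE] + 0.5) /
               (ni[, match(common, keyi), drop = FALSE] + 0.5))
  colnames(lt) <- common
  attr(lt, "genotype") <- sub("\\..*$", "", common)
  lt
}

#' Differential translational efficiency between two groups
#'
#' Per gene and replicate, TE is measured as `log2((poly_norm + 0.5) /
#' (input_norm + 0.5))` on size-factor-normalized counts; groups are then
#' compared by a two-sided Welch-type test (unpooled group variances
#' floored at the 10th percentile of the gene-wise variance distribution,
#' t reference on `n_a + n_b - 2` df).  The effect
#' is the difference of mean log2 TE; BH adjustment across tested genes;
#' significant iff the (adjusted) p is below `alpha` and `|effect| >=
#' log2(fc_threshold)`.
#'
#' The contrast may name `"MPV"` on either side: mid-parent TE
#' pseudo-replicates are then built by pairing P1/P2 replicates and
#' averaging their linear-scale TE.
#'
#' @param poly,input [expression_matrix()] objects for the polysome and
#'   mRNA-input assays with matched genotypes/replicates.
#' @param contrast `c(group_a, group_b)` of genotypes (or `"MPV"`).
#' @param cfg a [run_config()].
#' @param expressed optional logical matrix from [expressed_filter()];
#'   genes not expressed (input assay) in both groups get `NA` results.
#' @return A `data.frame`: `gene_id, effect, p, p_adj, significant`
#'   (`effect` in log2 units, positive when `group_a` is higher).
#' @export
te_test <- function(poly, input, contrast, cfg = run_config(),
                    expressed = NULL) {
  lt <- te_replicate_log2(poly, input)
  geno <- attr(lt, "genotype")
  get_side <- function(g) {
    if (g == "MPV") {
      i1 <- which(geno == "P1"); i2 <- which(geno == "P2")
      k <- min(length(i1), length(i2))
      if (k < 2) stop("MPV TE side needs >= 2 replicate pairs")
      log2((2^lt[, i1[seq_len(k)], drop = FALSE] +
              2^lt[, i2[seq_len(k)], drop = FALSE]) / 2)
    } else {
      idx <- which(geno == g)
      if (length(idx) < 2) stop("group ", g, " needs >= 2 replicates")
      lt[, idx, drop = FALSE]
    }
  }
  a <- get_side(contrast[1]); b <- get_side(contrast[2])
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  floor_v <- stats::quantile(c(va, vb), 0.10, na.rm = TRUE)
  va <- pmax(va, floor_v); vb <- pmax(vb, floor_v)
  se2a <- va / na; se2b <- vb / nb
  stat <- (ma - mb) / sqrt(se2a + se2b)
  # unpooled (Welch) standard error, but a fixed two-sample reference df:
  # per-gene Satterthwaite df from 2-df variance estimates is too
  # unstable at these replicate numbers, and the variance floor already
  # guards the unequal-variance case
  p <- 2 * stats::pt(-abs(stat), df = na + nb - 2)
  keep <- rep(TRUE, nrow(lt))
  if (!is.null(expressed)) {
    col_of <- function(g) {
      gg <- if (g == "MPV") c("P1", "P2") else g
      cols <- paste0(gg, ".mrna_input")
      rowSums(expressed[, cols, drop = FALSE]) == length(cols)
    }
    keep <- col_of(contrast[1]) & col_of(contrast[2])
  }
  p[!keep] <- NA_real_
  p_adj <- rep(NA_real_, length(p))
  p_adj[keep] <- stats::p.adjust(p[keep], method = "BH")
  effect <- ma - mb
  effect[!keep] <- NA_real_
  p_eff <- if (cfg$multiple_testing == "bh_fdr") p_adj else p
  data.frame(gene_id = rownames(lt), effect = effect, p = p, p_adj = p_adj,
             significant = p_eff < cfg$alpha &
               abs(effect) >= log2(cfg$fc_threshold),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Threshold-based differential m6A modification between two conditions
#'
#' Consensus m6A levels are peak-caller summaries without residual
#' replicate variance, so the comparison is a declared threshold rule
#' rather than a p-value test: a gene is differential when it is modified
#' in one condition only (gain/loss), or modified in both with a level
#' ratio of at least `fc_threshold`.
#'
#' @param levels_a,levels_b named numeric vectors of per-gene m6A levels
#'   (or `data.frame`s from [gene_m6a_level()]); genes absent (or 0) are
#'   unmodified.
#' @param cfg a [run_config()].
#' @param universe gene ids over which to report (default: union of the
#'   two level sets).
#' @return A `data.frame`: `gene_id, level_a, level_b, log2fc, significant,
#'   direction` with direction in `"gain"/"loss"/"none"` (gain = higher in
#'   condition a).
#' @export
m6a_diff <- function(levels_a, levels_b, cfg = run_config(),
                     universe = NULL) {
  as_vec <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$m6a_level, x$gene_id) else x
  }
  la <- as_vec(levels_a); lb <- as_vec(levels_b)
  if (is.null(universe)) universe <- union(names(la), names(lb))
  a <- ifelse(is.na(la[universe]), 0, la[universe])
  b <- ifelse(is.na(lb[universe]), 0, lb[universe])
  mod_a <- a > 0; mod_b <- b > 0
  ratio_ok <- mod_a & mod_b &
    (pmax(a, b) / pmin(a, b) >= cfg$fc_threshold)
  significant <- (mod_a != mod_b) | ratio_ok
  direction <- ifelse(!significant, "none",
                      ifelse(a > b, "gain", "loss"))
  log2fc <- ifelse(mod_a & mod_b, log2(a / b),
                   ifelse(mod_a, Inf, ifelse(mod_b, -Inf, NA_real_)))
  data.frame(gene_id = universe, level_a = as.numeric(a),
             level_b = as.numeric(b), log2fc = log2fc,
             significant = significant, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}
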
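#' Simulation design for a synthetic hybrid-vs-parents run
#'
#' Encodes the study conditions emulated by the generator: two parents and
#' their F1 hybrid, three assays (mRNA input, m6A IP, polysome), two
#' biological replicates each, negative-binomial counts with per-gene
#' dispersion, planted additive/non-additive structure per layer, planted
#' cis/trans allelic architectures, and replicate peak sets with partial
#' overlap.
#'
#' @param n_genes number of genes (default 5000).
#' @param replicates biological replicates per genotype and assay
#'   (default 2, the study design).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene baseline expression mean (defaults `log(200)`, 1).
#' @param dispersion_range uniform range of the per-gene NB dispersion
#'   (default `c(0.05, 0.2)`).
#' @param lib_factor_range uniform range of per-sample library-size
#'   factors (default `c(0.8, 1.2)`).
#' @param heterosis_fractions named list per layer (`mrna`, `m6a`, `te`)
#'   of fractions for patterns `AHP, HP, LP, BLP`; remainders are
#'   additive.  Defaults reproduce the study's non-additive proportions
#'   (5.7%, 44.3%, 10.2% per layer with its reference up/down split).
#' @param ahp_effect fold applied above the higher parent for AHP genes
#'   (and symmetrically below the lower parent for BLP); default 2.
#' @param pattern_parent_fc parental fold divergence for HP/LP genes
#'   (default 4, so the hybrid departs from the mid-parent value by 1.6x).
#' @param parent_div_frac extra fraction of genes with diverged parents
#'   but additive hybrids (mRNA layer; default 0.15).
#' @param parent_div_fc parental fold for those genes (default 2).
#' @param te_sdlog log-normal sd of the baseline translational efficiency
#'   (default 0.3).
#' @param m6a_prob baseline probability that a gene is m6A modified
#'   (default 0.4).
#' @param m6a_level_meanlog,m6a_level_sdlog log-normal parameters of peak
#'   fold enrichment (defaults `log(4)`, 0.3).
#' @param segment_fractions distribution of peak positions over transcript
#'   segments; defaults to the reference configuration (3'UTR 69.9%, stop
#'   21.1%, CDS 3.2%, start 0.2%, 5'UTR 0.6%, intron 5.1%), renormalized.
#' @param peak_halfwidth half width of simulated peaks in bp (default 75).
#' @param peak_jitter max absolute bp jitter between replicate peak
#'   boundaries (default 20).
#' @param false_peak_frac fraction of single-replicate (non-reproducible)
#'   peaks added per replicate (default 0.1).
#' @param cis_trans_fractions named fractions of genes with planted
#'   allelic architectures `cis_only, trans_only, enhancing, compensating,
#'   fully_compensatory`; defaults follow the reference mRNA-layer
#'   category proportions.
#' @param cis_trans_effect log2 magnitude of the planted parental
#'   divergence for cis-only/trans-only genes (default 1.5).
#' @param allelic_depth expected SNP-covered read depth per gene per assay
#'   (default 500).
#' @param rng_seed integer seed (default 1).
#' @return A validated list of class `"SimulationDesign"`.
#' @export
simulation_design <- function(
    n_genes = 5000, replicates = 2,
    baseline_meanlog = log(200), baseline_sdlog = 1,
    dispersion_range = c(0.05, 0.2),
    lib_factor_range = c(0.8, 1.2),
    heterosis_fractions = list(
      mrna = c(AHP = 0.0131, HP = 0.0131, LP = 0.0154, BLP = 0.0154),
      m6a = c(AHP = 0.1398, HP = 0.1398, LP = 0.0817, BLP = 0.0817),
      te = c(AHP = 0.0362, HP = 0.0362, LP = 0.0148, BLP = 0.0148)),
    ahp_effect = 2, pattern_parent_fc = 4,
    parent_div_frac = 0.15, parent_div_fc = 2,
    te_sdlog = 0.3,
    m6a_prob = 0.4, m6a_level_meanlog = log(4), m6a_level_sdlog = 0.3,
    segment_fractions = c(utr3 = 0.699, stop = 0.211, cds = 0.032,
                          start = 0.002, utr5 = 0.006, intron = 0.051),
    peak_halfwidth = 75, peak_jitter = 20, false_peak_frac = 0.1,
    cis_trans_fractions = c(cis_only = 0.041, trans_only = 0.037,
                            enhancing = 0.011, compensating = 0.011,
                            fully_compensatory = 0.010),
    cis_trans_effect = 1.5,
    allelic_depth = 500, rng_seed = 1L) {
  stopifnot(n_genes >= 10, replicates >= 2,
            length(dispersion_range) == 2, all(dispersion_range > 0),
            ahp_effect > 1, pattern_parent_fc > 1, parent_div_fc > 1,
            m6a_prob >= 0, m6a_prob <= 1, allelic_depth > 0)
  for (layer in c("mrna", "m6a", "te")) {
    fr <- heterosis_fractions[[layer]]
    if (is.null(fr) || !all(c("AHP", "HP", "LP", "BLP") %in% names(fr))) {
      stop("heterosis_fractions$", layer, " must name AHP, HP, LP, BLP")
    }
    if (sum(fr) > 1) stop("heterosis fractions for ", layer, " exceed 1")
  }
  if (sum(cis_trans_fractions) > 1) stop("cis/trans fractions exceed 1")
  if (abs(sum(segment_fractions) - 1) > 0.01) {
    stop("segment_fractions must sum to ~1")
  }
  segment_fractions <- segment_fractions / sum(segment_fractions)
  structure(as.list(environment()), class = "SimulationDesign")
}

# random gene geometry on one synthetic chromosome; returns GeneModels
simulate_gene_models <- function(n_genes) {
  models <- vector("list", n_genes)
  cursor <- 1000
  for (i in seq_len(n_genes)) {
    utr5 <- sample(150:300, 1)
    cds <- sample(200:500, 1) * 3
    utr3 <- sample(400:900, 1)
    L <- utr5 + cds + utr3
    n_ex <- sample(1:3, 1)
    # split the mature transcript into exons at interior cut points
    cuts <- if (n_ex > 1) sort(sample(seq(50, L - 50, by = 10), n_ex - 1)) else integer(0)
    seg_len <- diff(c(0, cuts, L))
    introns <- if (n_ex > 1) sample(100:300, n_ex - 1, replace = TRUE) else integer(0)
    starts <- cursor + c(0, cumsum(seg_len[-n_ex] + introns))
    exons <- cbind(start = starts, end = starts + seg_len)
    strand <- sample(c("+", "-"), 1)
    # CDS occupies mature positions [utr5, utr5 + cds) in 5'->3' order
    g1 <- tx_pos_to_genomic(exons, strand, utr5)
    g2 <- tx_pos_to_genomic(exons, strand, utr5 + cds - 1)
    gid <- sprintf("G%05d", i)
    models[[i]] <- gene_model(gid, "chr1", strand, exons,
                              cds_start = min(g1, g2),
                              cds_end = max(g1, g2) + 1)
    cursor <- max(exons[, 2]) + 500
  }
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  structure(models, class = "GeneModels")
}

# draw a transcript position inside the requested segment, respecting the
# inclusive codon windows of assign_segment; falls back to utr3 when the
# segment is infeasible for the gene's geometry
draw_segment_position <- function(model, segment, half = 100) {
  L <- model$mature_length
  st <- model$tx_start_codon; sp <- model$tx_stop_codon
  rng <- switch(segment,
    start = c(max(0, st - half), min(L - 1, st + half)),
    stop = c(max(0, sp - half), min(L - 1, sp + half)),
    utr5 = if (st - half - 1 >= 0) c(0, st - half - 1) else NULL,
    utr3 = if (sp + half + 1 <= L - 1) c(sp + half + 1, L - 1) else NULL,
    cds = if (st + half + 1 <= sp - half - 1)
      c(st + half + 1, sp - half - 1) else NULL,
    intron = NULL)
  if (segment == "intron") {
    if (nrow(model$exons) > 1) {
      j <- sample(nrow(model$exons) - 1, 1)
      gpos <- sample(model$exons[j, 2]:(model$exons[j + 1, 1] - 1), 1)
      return(list(genomic = gpos, segment = "intron"))
    }
    rng <- c(sp + half + 1, L - 1)  # fallback: utr3
    segment <- "utr3"
  }
  if (is.null(rng) || rng[1] > rng[2]) {
    rng <- c(sp + half + 1, L - 1)
    segment <- "utr3"
  }
  txpos <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
  list(genomic = tx_pos_to_genomic(model$exons, model$strand, txpos),
       segment = segment)
}

#' Simulate a complete synthetic run with known truth
#'
#' Draws gene models, per-genotype expression/TE/m6A means with planted
#' heterotic patterns, NB counts for all genotype x assay x replicate
#' libraries, replicate m6A peak sets (with boundary jitter and
#' single-replicate false peaks), and F1 allele plus parental SNP-covered
#' counts under planted cis/trans architectures.  Deterministic given
#' `design$rng_seed`.
#'
#' @param design a [simulation_design()].
#' @return A list of class `"SyntheticRun"` with elements `counts`
#'   (one [expression_matrix()] covering all samples), `models`, `peaks`
#'   (genotype -> list of two replicate peak `data.frame`s),
#'   `allele_counts`, `parental_snp_counts`, `truth` (one row per gene),
#'   and `design`.
#' @export
simulate_run <- function(design) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(design$rng_seed)

  n <- design$n_genes
  models <- simulate_gene_models(n)
  gene_ids <- names(models)

  base <- stats::rlnorm(n, design$baseline_meanlog, design$baseline_sdlog)
  disp <- stats::runif(n, design$dispersion_range[1],
                       design$dispersion_range[2])

  draw_patterns <- function(fractions) {
    pat <- rep("additive", n)
    counts <- round(fractions * n)
    idx <- sample.int(n, sum(counts))
    pat[idx] <- rep(names(counts), counts)
    pat
  }
  pat_mrna <- draw_patterns(design$heterosis_fractions$mrna)
  pat_m6a <- draw_patterns(design$heterosis_fractions$m6a)
  pat_te <- draw_patterns(design$heterosis_fractions$te)
  hp_parent <- sample(c("P1", "P2"), n, replace = TRUE)

  # per-genotype means for one layer given its baseline and pattern labels
  layer_means <- function(b, pat, hp, parent_fc, effect) {
    p_hi <- b; p_lo <- b; f1 <- b
    i <- pat == "AHP"; f1[i] <- effect * b[i]
    i <- pat == "HP"; p_hi[i] <- parent_fc * b[i]; f1[i] <- p_hi[i]
    i <- pat == "LP"; p_hi[i] <- parent_fc * b[i]; f1[i] <- b[i]
    i <- pat == "BLP"; f1[i] <- b[i] / effect
    p1 <- ifelse(hp == "P1", p_hi, p_lo)
    p2 <- ifelse(hp == "P1", p_lo, p_hi)
    cbind(P1 = p1, P2 = p2, F1 = f1)
  }

  mrna <- layer_means(base, pat_mrna, hp_parent,
                      design$pattern_parent_fc, design$ahp_effect)
  # parents additively diverged for a further slice of genes (additive F1)
  free <- which(pat_mrna == "additive")
  pdiv <- sample(free, round(design$parent_div_frac * n))
  up1 <- hp_parent[pdiv] == "P1"
  mrna[pdiv[up1], "P1"] <- mrna[pdiv[up1], "P1"] * design$parent_div_fc
  mrna[pdiv[!up1], "P2"] <- mrna[pdiv[!up1], "P2"] * design$parent_div_fc
  mrna[pdiv, "F1"] <- (mrna[pdiv, "P1"] + mrna[pdiv, "P2"]) / 2

  te_base <- stats::rlnorm(n, 0, design$te_sdlog)
  te <- layer_means(te_base, pat_te, hp_parent,
                    design$pattern_parent_fc, design$ahp_effect)

  # m6A levels: pattern genes are forced modified; the rest modified with
  # probability m6a_prob at an equal level in all genotypes
  lev_base <- stats::rlnorm(n, design$m6a_level_meanlog,
                            design$m6a_level_sdlog)
  modified <- stats::runif(n) < design$m6a_prob | pat_m6a != "additive"
  m6a <- layer_means(lev_base, pat_m6a, hp_parent,
                     design$pattern_parent_fc, design$ahp_effect)
  m6a[!modified, ] <- 0

  # planted allelic architecture: explicit architectures on genes whose
  # parents are otherwise undisturbed; genes with pattern- or
  # divergence-driven parental difference become cis (allelic ratio
  # mirrors the parents); everything else is conserved
  arch <- rep("conserved", n)
  parent_ratio_log2 <- log2(mrna[, "P1"] / mrna[, "P2"])
  diverged <- abs(parent_ratio_log2) > 1e-9
  candidates <- which(!diverged & pat_mrna == "additive")
  arch_counts <- round(design$cis_trans_fractions * n)
  if (sum(arch_counts) > length(candidates)) {
    stop("infeasible cis/trans fractions given the heterosis fractions")
  }
  chosen <- sample(candidates, sum(arch_counts))
  arch[chosen] <- rep(names(arch_counts), arch_counts)
  arch[diverged] <- "cis"

  sgn <- sample(c(1, -1), n, replace = TRUE)
  e <- design$cis_trans_effect
  A <- B <- rep(0, n)
  i <- arch == "cis_only"; A[i] <- sgn[i] * e; B[i] <- A[i]
  i <- arch == "trans_only"; A[i] <- sgn[i] * e; B[i] <- 0
  i <- arch == "enhancing"; B[i] <- sgn[i] * 0.5; A[i] <- sgn[i] * 1.5
  i <- arch == "compensating"; B[i] <- sgn[i] * 2.5; A[i] <- sgn[i] * 1.5
  i <- arch == "fully_compensatory"; A[i] <- 0; B[i] <- sgn[i] * e
  i <- arch == "cis"; A[i] <- parent_ratio_log2[i]; B[i] <- A[i]
  # category vocabulary of the classifier
  truth_category <- c(conserved = "conserved", cis = "cis_only",
                      cis_only = "cis_only", trans_only = "trans_only",
                      enhancing = "cis_and_trans",
                      compensating = "cis_and_trans",
                      fully_compensatory = "cis_and_trans")[arch]

  # apply the planted parental divergence of explicit architectures to the
  # expression means as well (cis and trans effects move parental totals)
  for (k in which(arch %in% c("cis_only", "trans_only", "enhancing",
                              "compensating"))) {
    r <- 2^(A[k] / 2)
    mrna[k, "P1"] <- base[k] * r
    mrna[k, "P2"] <- base[k] / r
    mrna[k, "F1"] <- (mrna[k, "P1"] + mrna[k, "P2"]) / 2
  }

  # --- counts for every genotype x assay x replicate -----------------
  genotypes <- c("P1", "P2", "F1")
  assays <- c("mrna_input", "m6a_ip", "polysome")
  reps <- seq_len(design$replicates)
  meta <- expand.grid(replicate = reps, assay = assays,
                      genotype = genotypes, stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_%s_r%d", meta$genotype, meta$assay,
                            meta$replicate)
  sheet <- sample_sheet(meta$sample_id, meta$genotype, meta$assay,
                        meta$replicate)
  counts <- matrix(0L, n, nrow(meta),
                   dimnames = list(gene_ids, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    g <- meta$genotype[j]
    mu <- switch(meta$assay[j],
      mrna_input = mrna[, g],
      polysome = mrna[, g] * te[, g],
      m6a_ip = mrna[, g] * (0.1 + m6a[, g] / 4))
    lib <- stats::runif(1, design$lib_factor_range[1],
                        design$lib_factor_range[2])
    counts[, j] <- stats::rnbinom(n, mu = pmax(mu * lib, 1e-8),
                                  size = 1 / disp)
  }
  em <- expression_matrix(counts, sheet)

  # --- peaks ----------------------------------------------------------
  seg_names <- names(design$segment_fractions)
  seg_draw <- sample(seg_names, n, replace = TRUE,
                     prob = design$segment_fractions)
  summit <- rep(NA_real_, n)
  seg_actual <- rep(NA_character_, n)
  half <- 100  # matches the default 200-nt codon window
  for (k in which(modified)) {
    dr <- draw_segment_position(models[[k]], seg_draw[k], half)
    summit[k] <- dr$genomic
    seg_actual[k] <- dr$segment
  }
  make_rep <- function(g, rep_id, false_genes) {
    idx <- which(modified & m6a[, g] > 0)
    s <- summit[idx]
    start <- s - design$peak_halfwidth +
      sample(-design$peak_jitter:design$peak_jitter, length(idx), TRUE)
    end <- s + design$peak_halfwidth +
      sample(-design$peak_jitter:design$peak_jitter, length(idx), TRUE)
    start <- pmin(start, s - 5); end <- pmax(end, s + 6)
    fe <- m6a[idx, g] * exp(stats::rnorm(length(idx), 0, 0.05))
    df <- data.frame(chrom = "chr1", start = start, end = end,
                     name = paste0(gene_ids[idx], "_pk"),
                     fold_enrichment = fe, summit = s,
                     qvalue = 1e-6, replicate = rep_id,
                     stringsAsFactors = FALSE)
    if (length(false_genes)) {
      fs <- vapply(false_genes, function(k) {
        m <- models[[k]]
        tx_pos_to_genomic(m$exons, m$strand,
                          sample.int(m$mature_length, 1) - 1)
      }, numeric(1))
      df <- rbind(df, data.frame(
        chrom = "chr1", start = fs - design$peak_halfwidth,
        end = fs + design$peak_halfwidth,
        name = paste0(gene_ids[false_genes], "_fp"),
        fold_enrichment = stats::rlnorm(length(fs),
                                        design$m6a_level_meanlog,
                                        design$m6a_level_sdlog),
        summit = fs, qvalue = 1e-4, replicate = rep_id,
        stringsAsFactors = FALSE))
    }
    df <- df[order(df$chrom, df$start), ]
    rownames(df) <- NULL
    df
  }
  peaks <- list()
  for (g in genotypes) {
    n_true <- sum(modified & m6a[, g] > 0)
    n_false <- round(design$false_peak_frac * n_true)
    unmod <- which(!modified)
    fp <- if (length(unmod) >= 2 * n_false && n_false > 0)
      sample(unmod, 2 * n_false) else integer(0)
    fp1 <- fp[seq_len(length(fp) %/% 2)]
    fp2 <- setdiff(fp, fp1)
    peaks[[g]] <- list(make_rep(g, 1L, fp1), make_rep(g, 2L, fp2))
  }

  # --- allele-specific counts ----------------------------------------
  pr_b <- 2^B / (1 + 2^B)
  allele_rows <- list(); parental_rows <- list()
  for (a in assays) {
    tot <- stats::rpois(n, design$allelic_depth)
    a1 <- stats::rbinom(n, tot, pr_b)
    allele_rows[[a]] <- data.frame(gene_id = gene_ids, assay = a,
                                   a1_count = a1, a2_count = tot - a1,
                                   stringsAsFactors = FALSE)
    p1 <- stats::rpois(n, design$allelic_depth * 2^(A / 2))
    p2 <- stats::rpois(n, design$allelic_depth * 2^(-A / 2))
    parental_rows[[a]] <- data.frame(gene_id = gene_ids, assay = a,
                                     p1_count = p1, p2_count = p2,
                                     stringsAsFactors = FALSE)
  }

  truth <- data.frame(
    gene_id = gene_ids,
    pattern_mrna = pat_mrna, pattern_m6a = pat_m6a, pattern_te = pat_te,
    hp_parent = hp_parent,
    cis_trans = truth_category, A_log2 = A, B_log2 = B,
    m6a_modified = modified, m6a_level_f1 = m6a[, "F1"],
    segment = seg_actual,
    te_ratio = te[, "F1"] / ((te[, "P1"] + te[, "P2"]) / 2),
    parent_diverged_mrna = abs(log2(mrna[, "P1"] / mrna[, "P2"])) > 1e-9,
    row.names = NULL, stringsAsFactors = FALSE)

  allele_counts <- do.call(rbind, allele_rows)
  parental_snp_counts <- do.call(rbind, parental_rows)
  rownames(allele_counts) <- rownames(parental_snp_counts) <- NULL
  structure(list(counts = em, models = models, peaks = peaks,
                 allele_counts = allele_counts,
                 parental_snp_counts = parental_snp_counts,
                 truth = truth, design = design,
                 means = list(mrna = mrna, te = te, m6a = m6a)),
            class = "SyntheticRun")
}

#' Write a synthetic run as a loadable fixture directory
#'
#' Emits the run in the package's external formats: `samples.tsv`,
#' `counts.tsv`, `models.gff3`, `peaks_<genotype>_rep<k>.tsv`,
#' `allele_counts.tsv`, `parental_snp_counts.tsv`, and `truth.tsv`.
#'
#' @param run a `"SyntheticRun"` from [simulate_run()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  utils::write.table(run$counts$samples, p("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_counts(run$counts, p("counts.tsv"))
  write_gene_models(run$models, p("models.gff3"))
  for (g in names(run$peaks)) {
    for (k in seq_along(run$peaks[[g]])) {
      write_peaks(run$peaks[[g]][[k]],
                  p(sprintf("peaks_%s_rep%d.tsv", g, k)))
    }
  }
  write_allele_counts(run$allele_counts, p("allele_counts.tsv"))
  utils::write.table(run$parental_snp_counts, p("parental_snp_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$truth, p("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a fixture directory written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return A list shaped like a `"SyntheticRun"` (without `design`
#'   and `means`; `truth` is `NULL` when absent).
#' @export
read_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  sheet <- read_sample_sheet(p("samples.tsv"))
  em <- read_counts(p("counts.tsv"), sheet)
  models <- read_gene_models(p("models.gff3"))
  peaks <- list()
  for (g in unique(sheet$genotype)) {
    files <- Sys.glob(p(sprintf("peaks_%s_rep*.tsv", g)))
    if (length(files)) {
      peaks[[g]] <- lapply(seq_along(sort(files)), function(k)
        read_peaks(sort(files)[k], replicate = k))
    }
  }
  truth <- if (file.exists(p("truth.tsv")))
    utils::read.delim(p("truth.tsv"), stringsAsFactors = FALSE) else NULL
  parental <- if (file.exists(p("parental_snp_counts.tsv")))
    utils::read.delim(p("parental_snp_counts.tsv"),
                      stringsAsFactors = FALSE) else NULL
  structure(list(counts = em, models = models, peaks = peaks,
                 allele_counts = read_allele_counts(p("allele_counts.tsv")),
                 parental_snp_counts = parental, truth = truth),
            class = "SyntheticRun")
}
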
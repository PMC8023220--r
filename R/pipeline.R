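#' Run the full three-layer heterosis analysis
#'
#' Executes the stages in dependency order on an in-memory run (from
#' [simulate_run()] or [read_fixture()]): quantification (FPKM, expressed
#' filter, TE, consensus peaks, gene m6A levels), differential testing of
#' all four contrasts per layer (F1 vs P1, F1 vs P2, P1 vs P2, and F1 vs
#' the mid-parent value), heterosis classification with layer summaries
#' and parental contributions, allele-specific bias and cis/trans
#' classification per assay, and ECDF-percentile k-means integration of
#' the non-additive gene union.  Idempotent given `cfg$rng_seed`.
#'
#' @param run a list with `counts` ([expression_matrix()] spanning all
#'   genotypes and assays), `models`, `peaks` (genotype -> list of two
#'   replicate peak tables), `allele_counts`, and `parental_snp_counts`.
#' @param cfg a [run_config()].
#' @param annotation optional named list (set id -> gene ids) for
#'   per-cluster enrichment.
#' @return A list of class `"HeteromicsResult"` with elements `fpkm`,
#'   `expressed`, `te`, `peaks` (annotated consensus per genotype),
#'   `m6a_levels`, `segment_distribution`, `differential` (per layer, per
#'   contrast), `heterosis` (calls/summary/parental contribution per
#'   layer), `allelic` (bias + cis/trans per assay), `integration`, and
#'   `report` (flat named vector of counts and settings).
#' @export
run_all <- function(run, cfg = run_config(), annotation = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  em <- run$counts
  need_assays <- c("mrna_input", "polysome")
  missing_assay <- setdiff(need_assays, unique(em$samples$assay))
  if (length(missing_assay)) {
    stop("missing assay(s): ", paste(missing_assay, collapse = ", "))
  }

  ## ---- quantify ----------------------------------------------------
  res <- list()
  res$fpkm <- stage("quantify", compute_fpkm(em, run$models))
  res$expressed <- expressed_filter(res$fpkm, cfg$fpkm_min)
  res$te <- stage("quantify", compute_te(res$fpkm, res$expressed))

  res$peaks <- list(); res$m6a_levels <- list()
  for (g in names(run$peaks)) {
    cp <- stage("consensus",
                consensus_peaks(run$peaks[[g]][[1]], run$peaks[[g]][[2]]))
    cp <- annotate_peaks(cp, run$models, cfg$window_nt)
    res$peaks[[g]] <- cp
    res$m6a_levels[[g]] <- gene_m6a_level(cp)
  }
  if (!is.null(res$peaks$F1) && nrow(res$peaks$F1)) {
    res$segment_distribution <- segment_distribution(res$peaks$F1)
  }

  ## ---- differential ------------------------------------------------
  sub_assay <- function(a) em_subset(em, em$samples$assay == a)
  input_em <- sub_assay("mrna_input")
  poly_em <- sub_assay("polysome")

  mrna_diff <- stage("differential", list(
    f1_vs_p1 = nb_test(input_em, c("F1", "P1"), cfg),
    f1_vs_p2 = nb_test(input_em, c("F1", "P2"), cfg),
    p1_vs_p2 = nb_test(input_em, c("P1", "P2"), cfg),
    f1_vs_mpv = mpv_contrast(input_em, cfg)))

  te_diff <- stage("differential", list(
    f1_vs_p1 = te_test(poly_em, input_em, c("F1", "P1"), cfg, res$expressed),
    f1_vs_p2 = te_test(poly_em, input_em, c("F1", "P2"), cfg, res$expressed),
    p1_vs_p2 = te_test(poly_em, input_em, c("P1", "P2"), cfg, res$expressed),
    f1_vs_mpv = te_test(poly_em, input_em, c("F1", "MPV"), cfg,
                        res$expressed)))

  lev_vec <- function(g) {
    lv <- res$m6a_levels[[g]]
    if (is.null(lv)) stop("no peaks for genotype ", g)
    stats::setNames(lv$m6a_level, lv$gene_id)
  }
  m6a_universe <- rownames(em$counts)
  m6a_diffs <- NULL
  if (all(c("P1", "P2", "F1") %in% names(res$m6a_levels))) {
    l1 <- lev_vec("P1"); l2 <- lev_vec("P2"); lf <- lev_vec("F1")
    fill <- function(v) {
      out <- stats::setNames(rep(0, length(m6a_universe)), m6a_universe)
      out[names(v)] <- v
      out
    }
    v1 <- fill(l1); v2 <- fill(l2); vf <- fill(lf)
    mpv_lev <- (v1 + v2) / 2
    m6a_diffs <- stage("differential", list(
      f1_vs_p1 = m6a_diff(vf, v1, cfg, m6a_universe),
      f1_vs_p2 = m6a_diff(vf, v2, cfg, m6a_universe),
      p1_vs_p2 = m6a_diff(v1, v2, cfg, m6a_universe),
      f1_vs_mpv = m6a_diff(vf, mpv_lev, cfg, m6a_universe)))
  }
  res$differential <- list(mrna = mrna_diff, te = te_diff, m6a = m6a_diffs)

  ## ---- heterosis ---------------------------------------------------
  sfs <- size_factors(input_em$counts)
  norm_in <- sweep(input_em$counts, 2, sfs, "/")
  geno <- input_em$samples$genotype
  mrna_values <- cbind(
    P1 = rowMeans(norm_in[, geno == "P1", drop = FALSE]),
    P2 = rowMeans(norm_in[, geno == "P2", drop = FALSE]),
    F1 = rowMeans(norm_in[, geno == "F1", drop = FALSE]))

  te_values <- res$te[, c("P1", "P2", "F1")]

  layer_heterosis <- function(d, values) {
    calls <- classify_heterosis(d$f1_vs_mpv, d$f1_vs_p1, d$f1_vs_p2,
                                d$p1_vs_p2, values)
    list(calls = calls, summary = summarize_layer(calls),
         parental = parental_contribution(calls, d$p1_vs_p2))
  }
  res$heterosis <- stage("heterosis", list(
    mrna = layer_heterosis(mrna_diff, mrna_values),
    te = layer_heterosis(te_diff, te_values)))
  if (!is.null(m6a_diffs)) {
    m6a_values <- cbind(P1 = v1, P2 = v2, F1 = vf)
    res$heterosis$m6a <- stage("heterosis",
                               layer_heterosis(m6a_diffs, m6a_values))
  }

  ## ---- allelic -----------------------------------------------------
  res$allelic <- list()
  assays_present <- intersect(unique(run$allele_counts$assay),
                              c("mrna_input", "m6a_ip", "polysome"))
  for (a in assays_present) {
    fa <- run$allele_counts[run$allele_counts$assay == a, ]
    bias <- stage("allelic", allelic_bias_test(fa, cfg$alpha))
    ct <- NULL
    if (!is.null(run$parental_snp_counts)) {
      pa <- run$parental_snp_counts[run$parental_snp_counts$assay == a, ]
      if (nrow(pa)) {
        ct <- stage("allelic",
                    classify_cis_trans(pa, fa, cfg$alpha))
      }
    }
    res$allelic[[a]] <- list(
      bias = bias,
      bias_counts = c(total = sum(bias$biased, na.rm = TRUE),
                      a1_higher = sum(bias$direction == "a1_higher",
                                      na.rm = TRUE),
                      a2_higher = sum(bias$direction == "a2_higher",
                                      na.rm = TRUE)),
      cis_trans = ct,
      cis_trans_table = if (!is.null(ct)) cis_trans_table(ct) else NULL)
  }

  ## ---- integrate ---------------------------------------------------
  non_add_genes <- function(layer) {
    h <- res$heterosis[[layer]]
    if (is.null(h)) return(character())
    h$calls$gene_id[!is.na(h$calls$pattern) & h$calls$pattern != "additive"]
  }
  union_genes <- Reduce(union, lapply(c("mrna", "te", "m6a"), non_add_genes))
  res$integration <- NULL
  if (length(union_genes) >= cfg$k_clusters) {
    val_or_zero <- function(v) ifelse(is.na(v) | !is.finite(v), 0, v)
    tri <- cbind(
      mrna = ecdf_percentile(val_or_zero(mrna_values[union_genes, "F1"])),
      m6a = if (!is.null(m6a_diffs))
        ecdf_percentile(val_or_zero(
          res$differential$m6a$f1_vs_p1$level_a[
            match(union_genes, res$differential$m6a$f1_vs_p1$gene_id)]))
      else NULL,
      te = ecdf_percentile(val_or_zero(res$te[union_genes, "F1"])))
    rownames(tri) <- union_genes
    km <- stage("integrate",
                kmeans_cluster(tri, cfg$k_clusters, cfg$rng_seed))
    enrich <- NULL
    if (!is.null(annotation)) {
      universe <- rownames(em$counts)[rowSums(res$expressed) > 0]
      enrich <- lapply(seq_along(km$sizes), function(cl) {
        genes <- intersect(names(km$cluster)[km$cluster == cl], universe)
        if (!length(genes)) return(NULL)
        set_enrichment(genes, annotation, universe,
                       seed = cfg$rng_seed + cl)
      })
    }
    res$integration <- list(percentiles = tri, clusters = km,
                            enrichment = enrich)
  }

  res$config <- cfg
  res$report <- build_report(res, cfg)
  class(res) <- "HeteromicsResult"
  res
}

# flat key/value summary re-derivable from the stage outputs
build_report <- function(res, cfg) {
  rep <- c(
    fc_threshold = cfg$fc_threshold, alpha = cfg$alpha,
    fpkm_min = cfg$fpkm_min, window_nt = cfg$window_nt,
    k_clusters = cfg$k_clusters, seed = cfg$rng_seed)
  for (g in names(res$peaks)) {
    rep[paste0("consensus_peaks_", g)] <- nrow(res$peaks[[g]])
    rep[paste0("m6a_genes_", g)] <- nrow(res$m6a_levels[[g]])
  }
  if (!is.null(res$segment_distribution)) {
    sd <- res$segment_distribution
    rep[paste0("segment_frac_F1_", names(sd))] <- round(sd, 4)
  }
  for (col in colnames(res$expressed)) {
    rep[paste0("expressed_", col)] <- sum(res$expressed[, col])
  }
  for (layer in names(res$differential)) {
    d <- res$differential[[layer]]
    if (is.null(d)) next
    for (ct in names(d)) {
      rep[paste0("differential_", layer, "_", ct)] <-
        sum(d[[ct]]$significant, na.rm = TRUE)
    }
  }
  for (layer in names(res$heterosis)) {
    h <- res$heterosis[[layer]]
    for (p in names(h$summary$counts)) {
      rep[paste0("heterosis_", layer, "_", p)] <- h$summary$counts[[p]]
    }
    rep[paste0("heterosis_", layer, "_pct_non_additive")] <-
      h$summary$pct_non_additive
    rep[paste0("parental_contribution_", layer, "_pct")] <-
      h$parental$percent
  }
  for (a in names(res$allelic)) {
    bc <- res$allelic[[a]]$bias_counts
    rep[paste0("allelic_bias_", a, "_", names(bc))] <- bc
    tb <- res$allelic[[a]]$cis_trans_table
    if (!is.null(tb)) {
      rep[paste0("cis_trans_", a, "_", tb$category)] <- tb$n
    }
  }
  if (!is.null(res$integration)) {
    rep["clusters"] <- length(res$integration$clusters$sizes)
    rep[paste0("cluster_size_", seq_along(res$integration$clusters$sizes))] <-
      res$integration$clusters$sizes
  }
  rep
}

#' Write the run report as a flat key/value TSV
#'
#' @param res a `"HeteromicsResult"` from [run_all()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(res, path) {
  df <- data.frame(key = names(res$report),
                   value = as.numeric(res$report),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.HeteromicsResult <- function(x, ...) {
  cat("heteromics run\n")
  for (layer in names(x$heterosis)) {
    s <- x$heterosis[[layer]]$summary
    cat(sprintf("  %-5s non-additive %d/%d (%.1f%%), up %d, down %d\n",
                layer, s$non_additive, s$n_classified,
                s$pct_non_additive, s$up, s$down))
  }
  if (!is.null(x$integration)) {
    cat("  clusters:", paste(x$integration$clusters$sizes, collapse = " "),
        "\n")
  }
  invisible(x)
}
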
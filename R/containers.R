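#' Construct a sample sheet
#'
#' Validates per-sample metadata for a hybrid/parent multi-assay experiment.
#' Each row describes one sequencing library.
#'
#' @param sample_id character vector of unique library identifiers.
#' @param genotype one of `"P1"`, `"P2"`, `"F1"` per sample.
#' @param assay one of `"mrna_input"`, `"m6a_ip"`, `"polysome"` per sample.
#' @param replicate positive integer replicate index within
#'   (genotype, assay).
#' @return A `data.frame` with class `"sample_sheet"`.
#' @export
sample_sheet <- function(sample_id, genotype, assay, replicate) {
  genotype <- as.character(genotype)
  assay <- as.character(assay)
  replicate <- as.integer(replicate)
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  bad_g <- setdiff(unique(genotype), c("P1", "P2", "F1"))
  if (length(bad_g)) stop("unknown genotype: ", paste(bad_g, collapse = ", "))
  bad_a <- setdiff(unique(assay), c("mrna_input", "m6a_ip", "polysome"))
  if (length(bad_a)) stop("unknown assay: ", paste(bad_a, collapse = ", "))
  if (any(is.na(replicate)) || any(replicate < 1L)) {
    stop("replicate must be a positive integer")
  }
  out <- data.frame(sample_id = sample_id, genotype = genotype,
                    assay = assay, replicate = replicate,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_sheet", "data.frame")
  out
}

#' Read a sample sheet from TSV
#'
#' Expects columns `sample_id`, `genotype`, `assay`, `replicate`.
#'
#' @param path path to a tab-separated file.
#' @return A validated [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "genotype", "assay", "replicate")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("sample sheet ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  sample_sheet(df$sample_id, df$genotype, df$assay, df$replicate)
}

#' Construct an expression matrix
#'
#' Bundles a genes x samples count matrix with its sample metadata, the
#' substrate for quantification and differential testing.  Counts must be
#' non-negative finite integers; gene identifiers must be unique.
#'
#' @param counts integer matrix, genes in rows, samples in columns; rownames
#'   are gene ids, colnames are sample ids.
#' @param samples a [sample_sheet()] whose `sample_id` matches
#'   `colnames(counts)` (order is taken from the matrix).
#' @return An object of class `"ExpressionMatrix"`: a list with elements
#'   `counts` and `samples`.
#' @export
expression_matrix <- function(counts, samples) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene_ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  if (!all(colnames(counts) %in% samples$sample_id)) {
    stop("sample(s) absent from sample sheet: ",
         paste(setdiff(colnames(counts), samples$sample_id), collapse = ", "))
  }
  storage.mode(counts) <- "numeric"
  if (any(!is.finite(counts))) stop("counts contain non-finite values")
  if (any(counts < 0)) stop("counts contain negative values")
  if (any(counts != round(counts))) stop("counts must be integers")
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$samples$genotype, x$samples$assay)
  print(tab)
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Subset an ExpressionMatrix to selected samples
#'
#' @param em an [expression_matrix()].
#' @param keep logical or integer index over samples, or sample ids.
#' @return The subsetted `ExpressionMatrix`.
#' @export
em_subset <- function(em, keep) {
  if (is.character(keep)) keep <- match(keep, em$samples$sample_id)
  expression_matrix(em$counts[, keep, drop = FALSE],
                    em$samples[keep, , drop = FALSE])
}

#' Run configuration
#'
#' Central container for the thresholds applied across the pipeline, so a
#' single choice of significance rule flows through every stage.
#'
#' @param fc_threshold minimum fold change (linear scale) called
#'   differential; default 1.5.
#' @param alpha significance cutoff on the (adjusted) p-value; default 0.01.
#' @param fpkm_min minimum mean-replicate FPKM for a gene to count as
#'   expressed; default 1.
#' @param window_nt width in nt of the windows centred on the start and stop
#'   codons used for peak segment assignment; must be even; default 200.
#' @param k_clusters number of k-means clusters for the three-layer
#'   integration; default 8.
#' @param rng_seed integer seed governing every stochastic step.
#' @param multiple_testing `"bh_fdr"` (Benjamini-Hochberg adjusted p against
#'   `alpha`) or `"raw_p"` (unadjusted p against `alpha`).
#' @return A list with class `"RunConfig"`.
#' @export
run_config <- function(fc_threshold = 1.5, alpha = 0.01, fpkm_min = 1.0,
                       window_nt = 200L, k_clusters = 8L, rng_seed = 1L,
                       multiple_testing = c("bh_fdr", "raw_p")) {
  multiple_testing <- match.arg(multiple_testing)
  stopifnot(fc_threshold >= 1, alpha > 0, alpha < 1, fpkm_min >= 0,
            k_clusters >= 1)
  window_nt <- as.integer(window_nt)
  if (window_nt %% 2L != 0L) stop("window_nt must be even")
  structure(list(fc_threshold = fc_threshold, alpha = alpha,
                 fpkm_min = fpkm_min, window_nt = window_nt,
                 k_clusters = as.integer(k_clusters),
                 rng_seed = as.integer(rng_seed),
                 multiple_testing = multiple_testing),
            class = "RunConfig")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; absent keys take the
#' defaults.  `overrides` (e.g. parsed command-line flags) take precedence
#' over file values.
#'
#' @param path path to a YAML key/value file, or `NULL` for pure defaults.
#' @param overrides named list overriding file values.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}
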
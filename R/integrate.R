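#' ECDF percentile transformation of one layer
#'
#' Each gene's value is replaced by the fraction of genes with a value
#' less than or equal to it (the empirical cumulative distribution
#' function evaluated at the value); ties share a percentile and the
#' maximum maps to 1.  Genes lacking a value for the layer should be set
#' to 0 by the caller before transformation.
#'
#' @param values numeric vector (optionally named) of per-gene layer
#'   values; must be finite.
#' @return Percentiles in (0, 1], same length and names as `values`.
#' @export
ecdf_percentile <- function(values) {
  if (length(values) < 2) stop("need >= 2 values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (length(unique(values)) == 1) {
    warning("all layer values identical; percentiles degenerate to 1")
    return(stats::setNames(rep(1, length(values)), names(values)))
  }
  pct <- stats::ecdf(values)(values)
  names(pct) <- names(values)
  pct
}

# k-means++ seeding: first center uniform, then each next center drawn
# with probability proportional to the squared distance to the nearest
# chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1, prob = prob)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' K-means clustering of percentile triplets
#'
#' Euclidean k-means with k-means++ initialization, best of `restarts`
#' runs by total within-cluster sum of squares; deterministic given
#' `seed`.  Cluster labels are renumbered in decreasing cluster size.
#'
#' @param triplets numeric matrix (genes x layers) of percentiles, gene
#'   ids as rownames.
#' @param k number of clusters (default 8).
#' @param seed integer RNG seed.
#' @param restarts number of seeded runs (default 100).
#' @return A list with `cluster` (named integer vector in `1..k`),
#'   `centers` (k x layers, in the relabeled order), `tot_withinss`, and
#'   `sizes`.
#' @export
kmeans_cluster <- function(triplets, k = 8, seed = 17, restarts = 100) {
  x <- as.matrix(triplets)
  if (k > nrow(x)) stop("k exceeds the number of genes")
  if (k < 1) stop("k must be >= 1")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_centers(x, k)
    centers <- centers[!duplicated(centers), , drop = FALSE]
    fit <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = 100,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  ord <- order(-tabulate(best$cluster, nbins = nrow(best$centers)))
  relabel <- match(seq_along(ord), ord)
  cluster <- relabel[best$cluster]
  names(cluster) <- rownames(x)
  list(cluster = cluster,
       centers = best$centers[ord, , drop = FALSE],
       tot_withinss = best$tot.withinss,
       sizes = tabulate(cluster, nbins = length(ord)))
}

#' Permutation-corrected gene-set enrichment for a cluster
#'
#' Per annotation set, the raw p-value is the hypergeometric upper tail
#' of the observed overlap between the cluster and the set within the
#' universe.  The family-corrected p-value is the fraction of `n_perm`
#' random same-size draws from the universe whose minimum raw p over all
#' sets is at most the observed raw p (min-p correction).  A set is
#' significant at corrected p < 0.001.
#'
#' @param cluster_genes character vector of gene ids (subset of
#'   `universe`).
#' @param annotation named list: set id -> character vector of gene ids.
#' @param universe character vector of all candidate gene ids.
#' @param n_perm number of permutations (>= 1000).
#' @param seed integer RNG seed.
#' @param sig_threshold corrected-p cutoff (default 0.001).
#' @return A `data.frame`: `set_id, set_size, overlap, p_raw, p_adj_perm,
#'   significant`, one row per set with nonzero universe overlap.
#' @export
set_enrichment <- function(cluster_genes, annotation, universe,
                           n_perm = 1000, seed = 17,
                           sig_threshold = 0.001) {
  if (n_perm < 1000) stop("n_perm must be >= 1000")
  if (!all(cluster_genes %in% universe)) {
    stop("cluster genes must be a subset of the universe")
  }
  ann <- lapply(annotation, intersect, universe)
  ann <- ann[lengths(ann) > 0]
  if (!length(ann)) {
    return(data.frame(set_id = character(), set_size = integer(),
                      overlap = integer(), p_raw = numeric(),
                      p_adj_perm = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  N <- length(universe); n <- length(cluster_genes)
  m <- lengths(ann)
  hyper_p <- function(genes) {
    ov <- vapply(ann, function(s) length(intersect(s, genes)), integer(1))
    p <- stats::phyper(ov - 1, m, N - m, length(genes), lower.tail = FALSE)
    list(ov = ov, p = p)
  }
  obs <- hyper_p(cluster_genes)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  # membership matrix for fast permutation overlaps
  memb <- vapply(ann, function(s) universe %in% s,
                 logical(length(universe)))
  min_p <- vapply(seq_len(n_perm), function(i) {
    draw <- sample.int(N, n)
    ov <- colSums(memb[draw, , drop = FALSE])
    min(stats::phyper(ov - 1, m, N - m, n, lower.tail = FALSE))
  }, numeric(1))
  p_adj <- vapply(obs$p, function(p) mean(min_p <= p), numeric(1))
  data.frame(set_id = names(ann), set_size = as.integer(m),
             overlap = as.integer(obs$ov), p_raw = as.numeric(obs$p),
             p_adj_perm = p_adj, significant = p_adj < sig_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a two-column set annotation (set_id, gene_id) TSV
#'
#' @param path path to the TSV file.
#' @return Named list: set id -> character vector of gene ids.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("set_id", "gene_id")
  if (!all(need %in% names(df))) {
    stop("annotation ", path, " must have columns set_id and gene_id")
  }
  split(df$gene_id, df$set_id)
}
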
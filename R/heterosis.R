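#' Percentage rounded half away from zero to one decimal
#'
#' @param part,whole non-negative counts with `0 <= part <= whole` and
#'   `whole > 0`.
#' @return `100 * part / whole` rounded half away from zero to one
#'   decimal place.
#' @export
percent_round <- function(part, whole) {
  if (any(whole == 0)) stop("percent_round: whole must be > 0")
  if (any(part < 0 | part > whole)) stop("percent_round: need 0 <= part <= whole")
  x <- 100 * part / whole
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

#' Classify per-gene heterotic patterns
#'
#' A gene whose hybrid value does not differ significantly from the
#' mid-parent value is additive.  Otherwise, with HPv/LPv the values of
#' the higher/lower parent for that gene: AHP when the hybrid is
#' significantly above the higher parent; BLP when significantly below
#' the lower parent; HP when above MPV and not significantly different
#' from the higher parent; LP when below MPV and not significantly
#' different from the lower parent.  The residual genes (significant
#' against both parents yet between them) are binned to the nearer parent
#' on the log scale.
#'
#' @param mpv_res,f1_vs_p1,f1_vs_p2,p1_vs_p2 differential results for one
#'   layer, each a `data.frame` with `gene_id` and `significant`, where
#'   the F1-containing contrasts have F1 as the first (numerator) side.
#' @param values matrix or `data.frame`, genes x `c("P1","P2","F1")`, of
#'   per-genotype layer summaries (mean normalized counts, m6A level, or
#'   TE) used to orient directions and pick the higher parent.
#' @return A `data.frame`: `gene_id, pattern, direction` with pattern in
#'   `additive/AHP/HP/LP/BLP` (NA when any contrast or value is missing)
#'   and direction in `up/down/none`.
#' @export
classify_heterosis <- function(mpv_res, f1_vs_p1, f1_vs_p2, p1_vs_p2,
                               values) {
  values <- as.matrix(values)
  genes <- rownames(values)
  sig_of <- function(res) res$significant[match(genes, res$gene_id)]
  s_mpv <- sig_of(mpv_res)
  s_p1 <- sig_of(f1_vs_p1)
  s_p2 <- sig_of(f1_vs_p2)
  v1 <- values[, "P1"]; v2 <- values[, "P2"]; vf <- values[, "F1"]
  complete <- !(is.na(s_mpv) | is.na(s_p1) | is.na(s_p2) |
                  is.na(v1) | is.na(v2) | is.na(vf))
  hp_is_p1 <- v1 >= v2
  hpv <- pmax(v1, v2); lpv <- pmin(v1, v2)
  mpv <- (v1 + v2) / 2
  sig_hp <- ifelse(hp_is_p1, s_p1, s_p2)
  sig_lp <- ifelse(hp_is_p1, s_p2, s_p1)

  pattern <- rep(NA_character_, length(genes))
  pattern[complete & !s_mpv] <- "additive"
  non_add <- complete & s_mpv
  eps <- 1e-9
  nearer_hp <- abs(log(vf + eps) - log(hpv + eps)) <=
    abs(log(vf + eps) - log(lpv + eps))
  is_ahp <- non_add & sig_hp & vf > hpv
  is_blp <- non_add & !is_ahp & sig_lp & vf < lpv
  is_hp <- non_add & !is_ahp & !is_blp & vf > mpv & !sig_hp
  is_lp <- non_add & !is_ahp & !is_blp & !is_hp & vf < mpv & !sig_lp
  residual <- non_add & !is_ahp & !is_blp & !is_hp & !is_lp
  pattern[is_ahp] <- "AHP"
  pattern[is_blp] <- "BLP"
  pattern[is_hp] <- "HP"
  pattern[is_lp] <- "LP"
  pattern[residual & nearer_hp] <- "HP"
  pattern[residual & !nearer_hp] <- "LP"
  n_na <- sum(!complete)
  if (n_na) message("classify_heterosis: ", n_na,
                    " gene(s) unclassified (incomplete contrasts)")
  direction <- ifelse(is.na(pattern), NA_character_,
                      ifelse(pattern == "additive", "none",
                             ifelse(pattern %in% c("AHP", "HP"),
                                    "up", "down")))
  data.frame(gene_id = genes, pattern = pattern, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize a layer's heterosis calls
#'
#' @param calls `data.frame` from [classify_heterosis()].
#' @return A list with per-pattern `counts`, the non-additive total, the
#'   up (`AHP+HP`) and down (`LP+BLP`) counts, and percentages of the
#'   non-additive total via [percent_round()] (`NA` when there are no
#'   non-additive genes), plus `pct_non_additive` of all classified genes.
#' @export
summarize_layer <- function(calls) {
  cl <- calls$pattern[!is.na(calls$pattern)]
  if (!length(cl)) stop("no classified genes")
  pats <- c("additive", "AHP", "HP", "LP", "BLP")
  counts <- vapply(pats, function(p) sum(cl == p), integer(1))
  non_add <- sum(counts[c("AHP", "HP", "LP", "BLP")])
  up <- counts[["AHP"]] + counts[["HP"]]
  down <- counts[["LP"]] + counts[["BLP"]]
  pct <- if (non_add > 0) {
    c(vapply(c("AHP", "HP", "LP", "BLP"),
             function(p) percent_round(counts[[p]], non_add), numeric(1)),
      up = percent_round(up, non_add), down = percent_round(down, non_add))
  } else {
    stats::setNames(rep(NA_real_, 6), c("AHP", "HP", "LP", "BLP", "up", "down"))
  }
  list(counts = counts, non_additive = non_add, up = up, down = down,
       pct_of_non_additive = pct,
       pct_non_additive = percent_round(non_add, length(cl)),
       n_classified = length(cl))
}

#' Parental contribution to non-additive variation
#'
#' Fraction of a layer's non-additive genes whose parents also differ
#' significantly from each other: the hybrid's departure from the
#' mid-parent value is then attributable to parental divergence.
#'
#' @param calls `data.frame` from [classify_heterosis()] for the layer.
#' @param p1_vs_p2 differential result for the parent-parent contrast on
#'   the same layer.
#' @return A list with `non_additive`, `overlap`, and `percent`
#'   ([percent_round()]; `NA` when there are no non-additive genes).
#' @export
parental_contribution <- function(calls, p1_vs_p2) {
  non_add <- !is.na(calls$pattern) & calls$pattern != "additive"
  sig_pp <- p1_vs_p2$significant[match(calls$gene_id, p1_vs_p2$gene_id)]
  overlap <- sum(non_add & !is.na(sig_pp) & sig_pp)
  n <- sum(non_add)
  list(non_additive = n, overlap = overlap,
       percent = if (n > 0) percent_round(overlap, n) else NA_real_)
}
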
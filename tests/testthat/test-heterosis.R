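# build minimal differential-result frames for classification tests
dres <- function(genes, sig) {
  data.frame(gene_id = genes, significant = sig, stringsAsFactors = FALSE)
}

test_that("percentages round half away from zero to one decimal", {
  expect_equal(percent_round(487, 11964), 4.1)
  expect_equal(percent_round(10654, 11964), 89.1)
  expect_equal(percent_round(1, 3), 33.3)
  expect_equal(percent_round(1, 16), 6.3)  # 6.25 rounds up, not to even
  expect_equal(percent_round(0, 10), 0)
  expect_error(percent_round(1, 0), "whole")
  expect_error(percent_round(5, 3))
})

test_that("heterosis patterns follow the significance decision rule", {
  genes <- c("add", "ahp", "hp", "lp", "blp", "mid", "na1")
  values <- cbind(P1 = c(100, 100, 400, 400, 100, 400, 100),
                  P2 = c(100, 100, 100, 100, 100, 100, 100),
                  F1 = c(100, 300, 400, 100, 50, 300, 100))
  rownames(values) <- genes
  mpv <- dres(genes, c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, NA))
  # F1-vs-P1 significance (P1 is the higher parent except for add/ahp/blp)
  f1p1 <- dres(genes, c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE))
  f1p2 <- dres(genes, c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  pp <- dres(genes, c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE))
  calls <- suppressMessages(
    classify_heterosis(mpv, f1p1, f1p2, pp, values))
  expect_equal(calls$pattern,
               c("additive", "AHP", "HP", "LP", "BLP", "HP", NA))
  expect_equal(calls$direction,
               c("none", "up", "up", "down", "down", "up", NA))
  # relabeling parents preserves every call
  values_sw <- values[, c("P2", "P1", "F1")]
  colnames(values_sw) <- c("P1", "P2", "F1")
  calls_sw <- suppressMessages(
    classify_heterosis(mpv, f1p2, f1p1, pp, values_sw))
  expect_equal(calls_sw$pattern, calls$pattern)
})

test_that("calls move monotonically with the hybrid value on the noise-free path", {
  # deterministic significance from expected values: difference is
  # "significant" iff the means differ by >= 1.5-fold
  sig_fc <- function(a, b) pmax(a, b) / pmin(a, b) >= 1.5
  p1 <- 400; p2 <- 100; mpv <- 250
  f1_grid <- seq(10, 1000, by = 5)
  order_rank <- c(BLP = 1, LP = 2, additive = 3, HP = 4, AHP = 5)
  pats <- vapply(f1_grid, function(f1) {
    g <- "g"
    values <- matrix(c(p1, p2, f1), 1,
                     dimnames = list(g, c("P1", "P2", "F1")))
    calls <- classify_heterosis(
      dres(g, sig_fc(f1, mpv)), dres(g, sig_fc(f1, p1)),
      dres(g, sig_fc(f1, p2)), dres(g, sig_fc(p1, p2)), values)
    calls$pattern
  }, character(1))
  expect_true(all(diff(order_rank[pats]) >= 0))
  expect_setequal(unique(pats), names(order_rank))
})

test_that("layer summaries reproduce the reference percentage arithmetic", {
  mk_calls <- function(ahp, hp, lp, blp, add = 0) {
    data.frame(gene_id = sprintf("g%d", seq_len(ahp + hp + lp + blp + add)),
               pattern = rep(c("AHP", "HP", "LP", "BLP", "additive"),
                             c(ahp, hp, lp, blp, add)),
               stringsAsFactors = FALSE)
  }
  # translational efficiency layer: 1805 up, 740 down
  s_te <- summarize_layer(mk_calls(900, 905, 370, 370))
  expect_equal(s_te$up, 1805)
  expect_equal(unname(s_te$pct_of_non_additive["up"]), 70.9)
  expect_equal(unname(s_te$pct_of_non_additive["down"]), 29.1)
  # mRNA layer: 666 up, 783 down of 1449
  s_mrna <- summarize_layer(mk_calls(333, 333, 391, 392))
  expect_equal(unname(s_mrna$pct_of_non_additive["down"]), 54.0)
  expect_equal(unname(s_mrna$pct_of_non_additive["up"]), 46.0)
  # all additive: percentages undefined
  s_add <- summarize_layer(mk_calls(0, 0, 0, 0, add = 10))
  expect_true(all(is.na(s_add$pct_of_non_additive)))
  expect_equal(s_add$non_additive, 0)
})

test_that("parental contribution reproduces the reference overlap fractions", {
  mk <- function(n_non_add, n_overlap) {
    genes <- sprintf("g%d", seq_len(n_non_add))
    calls <- data.frame(gene_id = genes, pattern = "AHP",
                        stringsAsFactors = FALSE)
    pp <- dres(genes, seq_len(n_non_add) <= n_overlap)
    parental_contribution(calls, pp)
  }
  expect_equal(mk(4826, 3085)$percent, 63.9)  # m6A layer
  expect_equal(mk(1449, 525)$percent, 36.2)   # mRNA layer
  expect_equal(mk(2545, 83)$percent, 3.3)     # TE layer
  expect_equal(mk(10, 0)$percent, 0)
})
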
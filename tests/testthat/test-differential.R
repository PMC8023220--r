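test_that("size factors follow median-of-ratios and its symmetries", {
  counts <- matrix(c(10L, 100L, 50L, 10L, 100L, 50L), 3,
                   dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(counts)), c(1, 1))
  counts2 <- cbind(a = c(10L, 100L, 50L), b = c(20L, 200L, 100L))
  rownames(counts2) <- paste0("g", 1:3)
  sf <- size_factors(counts2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  set.seed(42)
  mixed <- matrix(rnbinom(400, mu = 50, size = 5), 100)
  mixed <- sweep(mixed, 2, c(1, 2, 0.5, 1.5), "*")
  storage.mode(mixed) <- "integer"
  dimnames(mixed) <- list(paste0("g", 1:100), paste0("s", 1:4))
  expect_equal(unname(size_factors(mixed)), bf_size_factors(mixed),
               tolerance = 1e-12)
  # no gene nonzero everywhere -> total-count fallback, logged
  sparse <- matrix(c(5L, 0L, 0L, 10L), 2,
                   dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_message(sfb <- size_factors(sparse), "total-count")
  expect_equal(unname(sfb[2] / sfb[1]), 2)
})

test_that("NB test is null-calibrated, symmetric, and BH-monotone", {
  set.seed(501)
  n <- 2000
  mu <- rlnorm(n, log(200), 1)
  em <- make_em(cbind(nb_counts(n, mu, 3), nb_counts(n, mu, 3)),
                c("P1", "P2"), nrep = 3)
  r <- nb_test(em, c("P1", "P2"))
  # type-I error within 0.5-1.5x nominal at alpha = 0.05
  expect_gte(mean(r$p < 0.05, na.rm = TRUE), 0.03)
  expect_lte(mean(r$p < 0.05, na.rm = TRUE), 0.07)
  expect_false(any(r$significant, na.rm = TRUE) &&
                 mean(r$significant, na.rm = TRUE) > 0.01)
  # contrast swap negates log2fc and preserves p
  r2 <- nb_test(em, c("P2", "P1"))
  expect_equal(r$log2fc, -r2$log2fc)
  expect_equal(r$p, r2$p)
  # BH: monotone in p and bounded by [p, 1]
  ok <- !is.na(r$p)
  o <- order(r$p[ok])
  expect_true(all(diff(r$p_adj[ok][o]) >= -1e-12))
  expect_true(all(r$p_adj[ok] >= r$p[ok] - 1e-12))
  expect_true(all(r$p_adj[ok] <= 1))
})

test_that("NB test finds planted fold changes and estimates them well", {
  set.seed(502)
  n <- 2000
  mu <- rlnorm(n, log(300), 0.8)
  # 4-fold changes at mean 200, dispersion 0.05, balanced in direction
  # so median-of-ratios normalization stays centred
  planted <- 1:200
  up <- 1:100; down <- 101:200
  mu_a <- mu; mu_a[up] <- 800; mu_a[down] <- 200
  mu_b <- mu; mu_b[up] <- 200; mu_b[down] <- 800
  disp <- rep(0.1, n); disp[planted] <- 0.05
  cts <- cbind(sapply(1:3, function(j) rnbinom(n, mu = mu_a, size = 1 / disp)),
               sapply(1:3, function(j) rnbinom(n, mu = mu_b, size = 1 / disp)))
  em <- make_em(cts, c("P1", "P2"), nrep = 3)
  r <- nb_test(em, c("P1", "P2"))
  expect_gte(mean(r$significant[planted], na.rm = TRUE), 0.95)
  # identical groups elsewhere: near-zero median fold change
  expect_lt(abs(median(r$log2fc[-planted], na.rm = TRUE)), 0.05)
  # planted |log2 fold change| of 2 recovered with small median error
  expect_lt(median(abs(r$log2fc[up] - 2)), 0.25)
  expect_lt(median(abs(r$log2fc[down] + 2)), 0.25)
})

test_that("NB test agrees with DESeq2 as an independent reference", {
  skip_if_not_installed("DESeq2")
  set.seed(503)
  n <- 400
  mu <- rlnorm(n, log(200), 1)
  mu_a <- mu; mu_a[1:40] <- mu[1:40] * 3
  cts <- cbind(sapply(1:3, function(j) rnbinom(n, mu = mu_a, size = 10)),
               sapply(1:3, function(j) rnbinom(n, mu = mu, size = 10)))
  em <- make_em(cts, c("P1", "P2"), nrep = 3)
  r <- nb_test(em, c("P1", "P2"))
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      em$counts, data.frame(g = factor(rep(c("A", "B"), each = 3))), ~g)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    dres <- DESeq2::results(dds, contrast = c("g", "A", "B"))
  })
  keep <- !is.na(r$p) & !is.na(dres$pvalue)
  expect_gte(cor(r$p[keep], dres$pvalue[keep], method = "spearman"), 0.8)
  expect_gte(cor(r$log2fc[keep], dres$log2FoldChange[keep]), 0.9)
})

test_that("MPV contrast is null when the hybrid sits at the mid-parent", {
  set.seed(504)
  n <- 500
  mu <- rlnorm(n, log(300), 0.5)
  p1 <- nb_counts(n, mu * 1.5, 3, 0.05)
  p2 <- nb_counts(n, mu * 0.5, 3, 0.05)
  f1 <- nb_counts(n, mu, 3, 0.05)   # exactly the mid-parent mean
  em <- make_em(cbind(p1, p2, f1), c("P1", "P2", "F1"), nrep = 3)
  r <- mpv_contrast(em)
  expect_lte(mean(r$significant, na.rm = TRUE), 0.02)
  # parent relabeling leaves the MPV results unchanged
  sw <- em
  sw$samples$genotype <- c(rep("P2", 3), rep("P1", 3), rep("F1", 3))
  r2 <- mpv_contrast(sw)
  expect_equal(r$p, r2$p)
  expect_equal(r$log2fc, r2$log2fc)
})

test_that("MPV contrast detects a hybrid 3x above the mid-parent", {
  set.seed(505)
  n <- 1000
  mu <- rlnorm(n, log(300), 0.5)
  planted <- 1:100
  mu_f <- mu; mu_f[planted] <- mu[planted] * 3
  em <- make_em(cbind(nb_counts(n, mu, 3, 0.05), nb_counts(n, mu, 3, 0.05),
                      nb_counts(n, mu_f, 3, 0.05)),
                c("P1", "P2", "F1"), nrep = 3)
  r <- mpv_contrast(em)
  expect_gte(mean(r$significant[planted], na.rm = TRUE), 0.90)
})

test_that("TE test is null-calibrated and normalization invariant", {
  set.seed(506)
  n <- 2000
  mu <- rlnorm(n, log(200), 1)
  te <- rlnorm(n, 0, 0.2)
  poly <- make_em(cbind(nb_counts(n, mu * te, 3), nb_counts(n, mu * te, 3)),
                  c("P1", "P2"), "polysome", 3)
  inp <- make_em(cbind(nb_counts(n, mu, 3), nb_counts(n, mu, 3)),
                 c("P1", "P2"), "mrna_input", 3)
  r <- te_test(poly, inp, c("P1", "P2"))
  expect_gte(mean(r$p < 0.05, na.rm = TRUE), 0.025)
  expect_lte(mean(r$p < 0.05, na.rm = TRUE), 0.075)
  # doubling every polysome library leaves calls unchanged
  poly2 <- poly
  poly2$counts <- poly2$counts * 2L
  r2 <- te_test(poly2, inp, c("P1", "P2"))
  expect_equal(r$significant, r2$significant)
})

test_that("TE test recovers a planted 2.5-fold efficiency shift", {
  set.seed(507)
  n <- 1000
  mu <- rlnorm(n, log(500), 0.5)
  te_a <- rep(1, n); te_a[1:100] <- 2.5
  # CV ~10% multiplicative noise around the planted means
  poly <- make_em(cbind(sapply(1:3, function(j) rpois(n, mu * te_a * exp(rnorm(n, 0, 0.1)))),
                        sapply(1:3, function(j) rpois(n, mu * exp(rnorm(n, 0, 0.1))))),
                  c("P1", "P2"), "polysome", 3)
  inp <- make_em(cbind(sapply(1:3, function(j) rpois(n, mu * exp(rnorm(n, 0, 0.1)))),
                       sapply(1:3, function(j) rpois(n, mu * exp(rnorm(n, 0, 0.1))))),
                 c("P1", "P2"), "mrna_input", 3)
  # per-gene detection power of the test itself, at the unadjusted
  # p < 0.01 cutoff of the configuration's raw-p mode
  r <- te_test(poly, inp, c("P1", "P2"),
               run_config(multiple_testing = "raw_p"))
  expect_gte(mean(r$significant[1:100], na.rm = TRUE), 0.90)
  expect_lte(mean(r$significant[-(1:100)], na.rm = TRUE), 0.02)
})

test_that("m6A differential uses presence and level-ratio thresholds", {
  cfg <- run_config()
  r <- m6a_diff(c(ga = 6, gb = 6, gc = 9), c(gb = 4.5, gc = 4, gd = 3),
                cfg)
  get <- function(g, col) r[[col]][r$gene_id == g]
  expect_true(get("ga", "significant"))          # gain: 6 vs unmodified
  expect_equal(get("ga", "direction"), "gain")
  expect_false(get("gb", "significant"))         # 6 vs 4.5: ratio 1.33
  expect_true(get("gc", "significant"))          # 9 vs 4: ratio 2.25
  expect_equal(get("gd", "direction"), "loss")
})
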
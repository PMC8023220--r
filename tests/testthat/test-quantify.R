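models2 <- function() {
  structure(list(
    ga = gene_model("ga", "chr1", "+", rbind(c(0, 2000)), 0, 2000),
    gb = gene_model("gb", "chr1", "+", rbind(c(3000, 4000)), 3000, 4000)),
    class = "GeneModels")
}

test_that("FPKM follows the direct formula and its invariances", {
  sheet <- make_sheet("P1", nrep = 2)
  counts <- matrix(c(100L, 999900L, 200L, 1999800L), 2,
                   dimnames = list(c("ga", "gb"), sheet$sample_id))
  em <- expression_matrix(counts, sheet)
  f <- compute_fpkm(em, models2())
  # count 100, length 2000, library 1e6 -> 50
  expect_equal(f$fpkm["ga", 1], 50)
  # library scaling invariance: sample 2 = 2x sample 1
  expect_equal(f$fpkm[, 1], f$fpkm[, 2])
  # zero count -> zero FPKM
  counts["ga", 1] <- 0L
  f0 <- compute_fpkm(expression_matrix(counts, sheet), models2())
  expect_equal(f0$fpkm["ga", 1], 0)
  # count proportional to length -> equal FPKM
  cl <- matrix(c(200L, 100L), 2, 2,
               dimnames = list(c("ga", "gb"), sheet$sample_id))
  # ga length 2000 with 200 counts, gb length 1000 with 100 counts
  fl <- compute_fpkm(expression_matrix(cl, sheet), models2())
  expect_equal(fl$fpkm["ga", 1], fl$fpkm["gb", 1])
  # zero-total sample is a hard error
  cz <- matrix(0L, 2, 2, dimnames = dimnames(counts))
  expect_error(compute_fpkm(expression_matrix(cz, sheet), models2()),
               "zero total")
})

test_that("expressed filter uses the mean over replicates", {
  f <- structure(list(
    fpkm = matrix(c(0.8, 0, 1.4, 0), 2,
                  dimnames = list(c("ga", "gb"), c("s1", "s2"))),
    samples = make_sheet("P1", nrep = 2)), class = "FpkmMatrix")
  ex <- expressed_filter(f, 1)
  expect_true(ex["ga", "P1.mrna_input"])   # mean 1.1
  expect_false(ex["gb", "P1.mrna_input"])  # all zero
  ex0 <- expressed_filter(f, 0)
  expect_true(all(ex0))
})

test_that("TE is the polysome/input FPKM ratio gated by expression", {
  sheet <- rbind(make_sheet("P1", "mrna_input", 2),
                 make_sheet("P1", "polysome", 2))
  fpkm <- matrix(c(10, 0.4, 10, 0.4, 20, 2, 20, 2), 2,
                 dimnames = list(c("ga", "gb"), sheet$sample_id))
  f <- structure(list(fpkm = fpkm, samples = sheet), class = "FpkmMatrix")
  ex <- expressed_filter(f, 1)
  te <- compute_te(f, ex, "P1")
  expect_equal(te["ga", "P1"], 2)
  expect_true(is.na(te["gb", "P1"]))  # input below threshold
  fpkm["ga", 3:4] <- 0               # polysome zero, input expressed
  f$fpkm <- fpkm
  te0 <- compute_te(f, expressed_filter(f, 1), "P1")
  expect_equal(te0["ga", "P1"], 0)
})

test_that("consensus peaks form union intervals from overlapping pairs", {
  p1 <- data.frame(chrom = "chr1", start = 100, end = 300, name = "a",
                   fold_enrichment = 4, summit = 200, qvalue = 1e-5,
                   replicate = 1L, stringsAsFactors = FALSE)
  p2 <- p1; p2$replicate <- 2L
  expect_equal(consensus_peaks(p1, p2)[, c("start", "end")],
               data.frame(start = 100, end = 300))
  p2$start <- 250; p2$end <- 400; p2$summit <- 300
  cp <- consensus_peaks(p1, p2)
  expect_equal(cp$start, 100)
  expect_equal(cp$end, 400)
  p2$start <- 500; p2$end <- 600; p2$summit <- 550
  expect_equal(nrow(consensus_peaks(p1, p2)), 0)
})

test_that("consensus matches the brute-force oracle and is symmetric", {
  set.seed(301)
  for (rep in 1:3) {
    r1 <- random_peaks(40, replicate = 1L)
    r2 <- random_peaks(35, replicate = 2L)
    got <- consensus_peaks(r1, r2)
    want <- bf_consensus(r1, r2)
    expect_equal(got, want, ignore_attr = TRUE)
    swapped <- consensus_peaks(r2, r1)
    expect_equal(got[, c("chrom", "start", "end", "m6a_level")],
                 swapped[, c("chrom", "start", "end", "m6a_level")])
    # each input peak used at most once
    expect_lte(nrow(got), min(nrow(r1), nrow(r2)))
  }
})

test_that("segment assignment honors codon-window priority", {
  m <- plus_model()  # stop codon at transcript position 799
  # 80 nt downstream of the stop codon, inside the 3'UTR -> "stop"
  g80 <- 2500 + 80  # genomic: 3'UTR starts at 2500
  expect_equal(assign_segment(g80, m, 200), "stop")
  # 150 nt into the 300-nt 3'UTR -> outside the window -> "utr3"
  expect_equal(assign_segment(2500 + 150, m, 200), "utr3")
  # exactly window/2 from the stop codon: inclusive -> "stop";
  # one base further -> "utr3"
  expect_equal(assign_segment(2599, m, 200), "stop")
  expect_equal(assign_segment(2600, m, 200), "utr3")
  # intron and intergenic
  expect_equal(assign_segment(1300, m, 200), "intron")
  expect_equal(assign_segment(50, m, 200), "intergenic")
  expect_equal(assign_segment(50, NULL, 200), "intergenic")
})

test_that("segment assignment equals a brute-force scan over all positions", {
  for (m in list(plus_model(), minus_model())) {
    positions <- c(seq(995, 2805))  # spans exons, introns, flanks
    got <- vapply(positions, function(s) assign_segment(s, m, 200),
                  character(1))
    want <- vapply(positions, function(s) bf_segment(m, s, 200),
                   character(1))
    expect_identical(got, want)
  }
})

test_that("gene m6A level is the max over consensus peaks", {
  peaks <- data.frame(chrom = "chr1", start = c(1, 100, 200),
                      end = c(50, 150, 250), summit = c(10, 120, 220),
                      m6a_level = c(5, 3, 7),
                      gene_id = c("ga", "gb", "gb"),
                      segment = "utr3", stringsAsFactors = FALSE)
  lv <- gene_m6a_level(peaks)
  expect_equal(lv$m6a_level[lv$gene_id == "ga"], 5)
  expect_equal(lv$m6a_level[lv$gene_id == "gb"], 7)
  expect_equal(lv$n_peaks[lv$gene_id == "gb"], 2L)
  none <- peaks[0, ]
  expect_equal(nrow(gene_m6a_level(none)), 0)
})

test_that("segment distribution is a normalized fraction table", {
  peaks <- data.frame(segment = rep("utr3", 10))
  expect_equal(segment_distribution(peaks), c(utr3 = 1.0))
  peaks2 <- data.frame(segment = c(rep("utr3", 7), rep("stop", 2), "cds"))
  d <- segment_distribution(peaks2)
  expect_equal(sum(d), 1, tolerance = 1e-9)
  expect_equal(unname(d["utr3"]), 0.7)
  expect_error(segment_distribution(peaks2[0, , drop = FALSE]), "no peaks")
})
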
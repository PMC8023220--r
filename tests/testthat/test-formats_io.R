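test_that("count table round-trips through write/read unchanged", {
  sheet <- make_sheet(c("P1", "P2"), nrep = 1)
  counts <- matrix(c(5L, 0L, 12L, 7L), 2,
                   dimnames = list(c("ga", "gb"), sheet$sample_id))
  em <- expression_matrix(counts, sheet)
  f1 <- tempfile(); f2 <- tempfile()
  write_counts(em, f1)
  em2 <- read_counts(f1, sheet)
  expect_equal(dim(em2), c(2L, 2L))
  expect_identical(em2$counts, em$counts)
  write_counts(em2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("count reader rejects malformed input naming the offender", {
  sheet <- make_sheet(c("P1", "P2"), nrep = 1)
  f <- tempfile()
  writeLines(c("gene_id\tP1_mrna_input_r1\tmystery",
               "ga\t3\t4"), f)
  expect_error(read_counts(f, sheet), "mystery")
  writeLines(c(paste("gene_id", sheet$sample_id[1], sheet$sample_id[2],
                     sep = "\t"),
               "ga\t3\t-4"), f)
  err <- expect_error(read_counts(f, sheet))
  expect_match(conditionMessage(err), "ga")
  expect_match(conditionMessage(err), sheet$sample_id[2])
})

test_that("GFF3 gene models parse with correct UTR orientation", {
  models <- structure(list(gplus = plus_model(), gminus = minus_model()),
                      class = "GeneModels")
  f <- tempfile(fileext = ".gff3")
  write_gene_models(models, f)
  back <- read_gene_models(f)
  expect_setequal(names(back), c("gplus", "gminus"))
  for (g in names(models)) {
    expect_equal(back[[g]]$exons, models[[g]]$exons)
    expect_equal(back[[g]]$cds_start, models[[g]]$cds_start)
    expect_equal(back[[g]]$cds_end, models[[g]]$cds_end)
    expect_equal(back[[g]]$mature_length, 1100)
  }
  # minus strand: 5'UTR comes from the high-coordinate side
  gm <- back$gminus
  expect_true(all(gm$utr5[, 1] >= gm$cds_end))
  expect_true(all(gm$utr3[, 2] <= gm$cds_start))
  # manual arithmetic on the hand-built geometry
  expect_equal(gm$tx_start_codon, 200)
  expect_equal(gm$tx_stop_codon, 799)
  expect_equal(sum(gm$utr5[, 2] - gm$utr5[, 1]), 200)
})

test_that("single-exon gene with CDS spanning the exon has empty UTRs", {
  m <- gene_model("g1", "chr1", "+", rbind(c(100, 400)), 100, 400)
  expect_equal(nrow(m$utr5), 0)
  expect_equal(nrow(m$utr3), 0)
  expect_equal(m$tx_start_codon, 0)
  expect_equal(m$tx_stop_codon, 299)
})

test_that("genes lacking usable CDS are excluded with a warning", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t101\t400\t.\t+\t.\tID=gok",
    "chr1\tx\tmRNA\t101\t400\t.\t+\t.\tID=gok_T;Parent=gok",
    "chr1\tx\texon\t101\t400\t.\t+\t.\tID=gok_T:e1;Parent=gok_T",
    "chr1\tx\tCDS\t101\t400\t.\t+\t.\tID=gok_T:c;Parent=gok_T",
    "chr1\tx\tgene\t501\t900\t.\t+\t.\tID=gnone",
    "chr1\tx\tmRNA\t501\t900\t.\t+\t.\tID=gnone_T;Parent=gnone",
    "chr1\tx\texon\t501\t900\t.\t+\t.\tID=gnone_T:e1;Parent=gnone_T"), f)
  expect_warning(models <- read_gene_models(f), "gnone")
  expect_named(models, "gok")
})

test_that("peak reader computes summits and rejects bad rows", {
  f <- tempfile()
  writeLines(c("chrom\tstart\tend\tname\tfold_enrichment\tsummit_offset\tqvalue",
               "chr1\t100\t300\tp1\t4.5\t50\t0.001"), f)
  p <- read_peaks(f)
  expect_equal(p$summit, 150)
  writeLines("chrom\tstart\tend\tname\tfold_enrichment\tsummit_offset\tqvalue",
             f)
  expect_equal(nrow(read_peaks(f)), 0)
  writeLines(c("chrom\tstart\tend\tname\tfold_enrichment\tsummit_offset\tqvalue",
               "chr1\t100\t300\tp1\t4.5\t50\t0.001",
               "chr1\t100\t300\tp2\t4.5\t250\t0.001"), f)
  expect_error(read_peaks(f), "line 3")
})

test_that("run configuration validates and reads YAML with overrides", {
  cfg <- run_config()
  expect_equal(cfg$fc_threshold, 1.5)
  expect_equal(cfg$alpha, 0.01)
  expect_equal(cfg$window_nt, 200L)
  expect_error(run_config(window_nt = 201), "even")
  expect_error(run_config(alpha = 1.2))
  f <- tempfile(fileext = ".yaml")
  writeLines(c("fc_threshold: 2.0", "alpha: 0.05"), f)
  cfg2 <- read_run_config(f, overrides = list(alpha = 0.001))
  expect_equal(cfg2$fc_threshold, 2.0)
  expect_equal(cfg2$alpha, 0.001)
  writeLines("nonsense: 1", f)
  expect_error(read_run_config(f), "nonsense")
})

test_that("sample sheet and allele table validation reject bad values", {
  expect_error(sample_sheet(c("a", "a"), "P1", "mrna_input", 1), "duplicate")
  expect_error(sample_sheet("a", "XX", "mrna_input", 1), "genotype")
  f <- tempfile()
  writeLines(c("gene_id\tassay\ta1_count\ta2_count",
               "ga\tmrna_input\t5\t-2"), f)
  expect_error(read_allele_counts(f), "ga")
})
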
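test_that("site_level and call_methylated follow their definitions", {
  expect_equal(site_level(3, 1), 0.75)
  expect_equal(site_level(0, 12), 0)
  expect_equal(site_level(27, 0), 1)
  expect_true(is.na(site_level(0, 0)))
  expect_error(site_level(-1, 2), "non-negative")

  # mode "any": a single unconverted read is enough
  expect_true(call_methylated(1, 26, mode = "any")$is_methylated)
  expect_false(call_methylated(0, 0, mode = "any")$is_methylated)

  # binomial mode against an independently summed exact tail
  tail_3_27 <- sum(dbinom(3:27, 27, 0.005))
  got <- call_methylated(3, 24, conversion_failure_rate = 0.005,
                         alpha = 0.05, correct = "none")
  expect_equal(got$p_value, tail_3_27, tolerance = 1e-12)
  expect_equal(got$is_methylated, tail_3_27 <= 0.05)
  expect_false(call_methylated(0, 27, correct = "none",
                               alpha = 0.05)$is_methylated)
  expect_error(call_methylated(1, 1, conversion_failure_rate = 1),
               "conversion_failure_rate")
  expect_error(call_methylated(1, 1, alpha = 0), "alpha")
})

# genome: ACGTACGT -> CG sites at +2, -3, +6, -7
.fix_genome <- c(chr1 = "ACGTACGT")

test_that("extract_counts counts informative bases on the correct strand", {
  sites <- enumerate_cytosines(.fix_genome)
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, c(chr1 = 8L), list(
    list(qname = "r1", flag = 0L, chrom = "chr1", pos = 1L,
         seq = "ACGTACGT", xg = "CT"),
    list(qname = "r2", flag = 0L, chrom = "chr1", pos = 1L,
         seq = "ATGTATGT", xg = "CT"),
    list(qname = "r3", flag = 16L, chrom = "chr1", pos = 1L,
         seq = "ACGTAAAT", xg = "GA")))
  ct <- extract_counts(sam, sites)
  plus2 <- ct[ct$pos == 2L & ct$strand == "+", ]
  expect_equal(plus2$n_meth, 1L)   # r1 shows C
  expect_equal(plus2$n_unmeth, 1L) # r2 shows T
  expect_equal(plus2$level, 0.5)
  # GA read: G at -3 methylated, A at -7 converted
  minus3 <- ct[ct$pos == 3L & ct$strand == "-", ]
  expect_equal(c(minus3$n_meth, minus3$n_unmeth), c(1L, 0L))
  minus7 <- ct[ct$pos == 7L & ct$strand == "-", ]
  expect_equal(c(minus7$n_meth, minus7$n_unmeth), c(0L, 1L))
})

test_that("CT-only input leaves reverse-strand sites uncovered", {
  sites <- enumerate_cytosines(.fix_genome)
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, c(chr1 = 8L), list(
    list(qname = "r1", flag = 0L, chrom = "chr1", pos = 1L,
         seq = "ACGTACGT", xg = "CT")))
  ct <- extract_counts(sam, sites)
  expect_true(all(!ct[ct$strand == "-", ][["covered"]]))
  expect_true(all(ct[ct$strand == "+" & ct$context == "CG", ][["covered"]]))
})

test_that("MAPQ and duplicate filters drop reads; mate overlap counts once", {
  sites <- enumerate_cytosines(.fix_genome)
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, c(chr1 = 8L), list(
    list(qname = "low", flag = 0L, chrom = "chr1", pos = 1L,
         seq = "ACGTACGT", xg = "CT", mapq = 5L),
    list(qname = "dup", flag = 1024L, chrom = "chr1", pos = 1L,
         seq = "ACGTACGT", xg = "CT"),
    # proper pair, both mates over site +2: mate1 C at qual 40, mate2 T at qual 2
    list(qname = "pair", flag = 99L, chrom = "chr1", pos = 1L,
         seq = "ACGT", qual = "IIII", xg = "CT"),
    list(qname = "pair", flag = 147L, chrom = "chr1", pos = 1L,
         seq = "ATGT", qual = "####", xg = "CT")))
  ct <- extract_counts(sam, sites)
  plus2 <- ct[ct$pos == 2L & ct$strand == "+", ]
  expect_equal(plus2$n_meth, 1L)   # high-quality mate base wins, counted once
  expect_equal(plus2$n_unmeth, 0L)
  ct_keepdup <- extract_counts(sam, sites, skip_duplicates = FALSE,
                               mapq_min = 0)
  plus2b <- ct_keepdup[ct_keepdup$pos == 2L & ct_keepdup$strand == "+", ]
  expect_equal(plus2b$n_meth, 3L)  # low-mapq + duplicate + pair
})

test_that("bisulfite strand falls back to FLAG inference without XG", {
  sites <- enumerate_cytosines(.fix_genome)
  sam <- tempfile(fileext = ".sam")
  # no XG tag: forward unpaired read -> CT; reverse -> GA
  hdr <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:8")
  recs <- c("f\t0\tchr1\t1\t60\t8M\t=\t1\t0\tACGTACGT\tIIIIIIII",
            "r\t16\tchr1\t1\t60\t8M\t=\t1\t0\tACGTACGT\tIIIIIIII")
  writeLines(c(hdr, recs), sam)
  ct <- extract_counts(sam, sites)
  expect_equal(ct[ct$pos == 2L & ct$strand == "+", ][["n_meth"]], 1L)
  expect_equal(ct[ct$pos == 3L & ct$strand == "-", ][["n_meth"]], 1L)
})

test_that("reference-name mismatch is reported", {
  sites <- enumerate_cytosines(.fix_genome)
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, c(chrZ = 8L), list(
    list(qname = "r", flag = 0L, chrom = "chrZ", pos = 1L,
         seq = "ACGTACGT", xg = "CT")))
  expect_error(extract_counts(sam, sites), "chrZ")
})

test_that("coverage_summary reports rates, levels and both mC denominators", {
  counts <- data.table::data.table(
    chrom = "c1", pos = c(2L, 6L, 10L, 14L), strand = "+",
    context = c("CG", "CG", "CHH", "CHH"),
    n_meth = c(2L, 8L, 0L, 0L), n_unmeth = c(8L, 2L, 10L, 0L),
    n_other = 0L)
  counts$level <- site_level(counts$n_meth, counts$n_unmeth)
  counts$covered <- counts$n_meth + counts$n_unmeth > 0
  counts$is_methylated <- c(TRUE, TRUE, FALSE, FALSE)
  cs <- coverage_summary(counts)
  cg <- cs[cs$context == "CG", ]
  expect_equal(cg$coverage_rate, 1)
  expect_equal(cg$mean_level, 0.5)
  expect_equal(cg$mc_frac_covered, 1)
  chh <- cs[cs$context == "CHH", ]
  expect_equal(chh$coverage_rate, 0.5)
  expect_equal(chh$mc_frac_covered, 0)
  # per-class summary via features
  feats <- data.table::data.table(chrom = "c1", start = 1L, end = 8L,
                                  te_class = "LTR")
  cs2 <- coverage_summary(counts, feats)
  expect_true(any(cs2$group_type == "te_class" & cs2$group == "LTR"))
  expect_equal(cs2[cs2$group == "LTR" & cs2$context == "CG", ][["n_total"]], 2L)
})

test_that("count tables round-trip and recompute derived columns", {
  cmp <- small_comparison(5L, genome_length = 16000L,
                          n_spikes = c(CG = 0L, CHG = 0L, CHH = 0L))
  p <- tempfile(fileext = ".tsv")
  write_count_table(cmp$a, p)
  back <- read_count_table(p)
  expect_equal(back$n_meth, cmp$a$n_meth)
  expect_equal(back$level, cmp$a$level)
  expect_error(read_count_table(
    {f <- tempfile(); writeLines("chrom\tpos\tstrand", f); f}),
    "missing column")
})
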
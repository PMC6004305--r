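test_that("pearson_chi2 matches the closed form and textbook oracle", {
  expect_equal(pearson_chi2(10, 0, 0, 10)$chi2, 20)
  res <- pearson_chi2(5, 5, 5, 5)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  # degenerate margins
  dg <- pearson_chi2(0, 0, 3, 4)
  expect_true(dg$degenerate)
  expect_equal(dg$p, 1)
  expect_error(pearson_chi2(-1, 2, 3, 4), "non-negative")

  # independent oracle: expected-count computation via chisq.test
  set.seed(11)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 20) + 1L, 2)
    got <- pearson_chi2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    want <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(got$chi2, unname(want$statistic), tolerance = 1e-9)
    expect_equal(got$p, want$p.value, tolerance = 1e-9)
  }
})

test_that("candidate chains follow the gap, span and site-count rules", {
  ms <- data.table::data.table(chrom = "c", pos = c(100L, 250L, 400L, 560L, 700L),
                               meth_A = TRUE, meth_B = FALSE)
  cand <- build_candidate_regions(ms)
  expect_equal(nrow(cand), 1L)
  expect_equal(c(cand$start, cand$end, cand$span), c(100L, 700L, 601L))
  expect_equal(cand$n_sites_A, 5L)

  # gap of 250 splits; singleton spans fail the length floor
  ms2 <- data.table::data.table(chrom = "c", pos = c(100L, 350L),
                                meth_A = TRUE, meth_B = TRUE)
  expect_equal(nrow(build_candidate_regions(ms2, min_sites = 1)), 0L)

  # five sites inside 30 bp: span below 40 -> discarded
  ms3 <- data.table::data.table(chrom = "c", pos = c(100L, 107L, 114L, 121L, 128L),
                                meth_A = TRUE, meth_B = FALSE)
  expect_equal(nrow(build_candidate_regions(ms3)), 0L)

  # exact gap == 200 breaks the chain (criterion is strict <200)
  ms4 <- data.table::data.table(chrom = "c", pos = c(100L, 300L),
                                meth_A = TRUE, meth_B = TRUE)
  expect_equal(nrow(build_candidate_regions(ms4, min_sites = 1L, min_len = 1L)), 2L)
  expect_equal(nrow(build_candidate_regions(ms, max_gap = 150)), 0L)
})

test_that("candidate set equals the exhaustive chain enumerator on random instances", {
  set.seed(202)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    ms <- data.table::data.table(
      chrom = sample(c("c1", "c2"), n, replace = TRUE),
      pos = sample.int(4000L, n),
      meth_A = runif(n) < 0.7, meth_B = runif(n) < 0.7)
    ms <- unique(ms, by = c("chrom", "pos"))
    ms <- ms[ms$meth_A | ms$meth_B, ]
    got <- build_candidate_regions(ms, min_sites = 2)
    want <- oracle_chain_enumerate(ms, min_sites = 2)
    expect_equal(as.data.frame(got[, c("chrom", "start", "end", "span")]),
                 as.data.frame(want))
  }
})

test_that("region pooling and the strict coverage rule behave as specified", {
  mk <- function(n_meth, n_unmeth, pos) data.table::data.table(
    chrom = "c", pos = pos, strand = "+", context = "CG",
    n_meth = n_meth, n_unmeth = n_unmeth,
    covered = n_meth + n_unmeth > 0, is_methylated = n_meth > 0)
  cand <- data.table::data.table(chrom = "c", start = 100L, end = 200L)
  a <- mk(c(30L, 20L), c(30L, 20L), c(120L, 180L))
  b <- mk(c(5L, 5L), c(45L, 45L), c(120L, 180L))
  rc <- region_counts(cand, a, b)
  expect_equal(rc$level_A, 0.5)
  expect_equal(rc$level_B, 0.1)
  expect_equal(rc$depth_A, 50)
  # mean depth exactly 10 must fail the strict "> 10" rule inside call_dmrs
  a10 <- mk(c(5L, 5L), c(5L, 5L), c(120L, 180L))
  rc10 <- region_counts(cand, a10, b)
  expect_equal(rc10$depth_A, 10)
  expect_false(rc10$depth_A > 10)
})

test_that("fold change uses the pseudo-floor at zero levels and direction flips with order", {
  expect_equal(level_fold_change(0.5, 0.1, 100, 100), 5)
  # zero low level floored at 1/(reads+1)
  expect_equal(level_fold_change(0.5, 0, 100, 99), 0.5 / (1 / 100))
  expect_equal(classify_hyper_hypo(0.1, 0.5), "hyper")
  expect_equal(classify_hyper_hypo(0.5, 0.1), "hypo")
  # antisymmetry
  expect_false(classify_hyper_hypo(0.2, 0.6) == classify_hyper_hypo(0.6, 0.2))
})

test_that("call_dmrs composes the criteria: constructed case and identical samples", {
  mk <- function(levels, pos, depth = 27L) {
    n_meth <- as.integer(round(levels * depth))
    data.table::data.table(
      chrom = "c", pos = pos, strand = "+", context = "CG",
      n_meth = n_meth, n_unmeth = depth - n_meth,
      level = n_meth / depth, covered = TRUE, is_methylated = n_meth >= 3L)
  }
  pos <- c(100L, 250L, 400L, 560L, 700L)
  a <- mk(rep(0.5, 5), pos)
  b <- mk(rep(0.1, 5), pos)
  d <- call_dmrs(a, b, "CG")
  expect_equal(nrow(d), 1L)
  expect_equal(c(d$start, d$end, d$span), c(100L, 700L, 601L))
  expect_equal(d$direction, "hypo")
  expect_true(d$fold_change >= 2 && d$p <= 0.05)
  # identical samples: fold change 1 -> nothing called
  expect_equal(nrow(call_dmrs(a, a, "CG")), 0L)
  expect_error(call_dmrs(a, b, "CHH"), "no sites of context")
})

test_that("raising thresholds never increases the number of DMRs", {
  cmp <- small_comparison(31L)
  base <- nrow(call_dmrs(cmp$a, cmp$b, "CG"))
  expect_lte(nrow(call_dmrs(cmp$a, cmp$b, "CG", min_fold = 3)), base)
  expect_lte(nrow(call_dmrs(cmp$a, cmp$b, "CG", alpha = 0.01)), base)
  expect_lte(nrow(call_dmrs(cmp$a, cmp$b, "CG", min_sites = 10)), base)
})

test_that("DMR calling is deterministic and the audit finds no violations", {
  cmp <- small_comparison(17L)
  d1 <- rbindlist(lapply(c("CG", "CHG", "CHH"), function(cx)
    call_dmrs(cmp$a, cmp$b, cx)))
  d2 <- rbindlist(lapply(c("CG", "CHG", "CHH"), function(cx)
    call_dmrs(cmp$a, cmp$b, cx)))
  expect_identical(d1, d2)
  expect_gt(nrow(d1), 0L)
  aud <- audit_dmrs(d1, cmp$a, cmp$b)
  expect_true(all(aud$ok_all))
})

test_that("DMR-feature association resolves zones with body > up2k > down2k priority", {
  feats <- data.table::data.table(chrom = "c", start = 2001L, end = 3000L,
                                  strand = "+", feature_id = "g1")
  dmrs <- data.table::data.table(
    chrom = "c", start = c(2501L, 101L, 8001L), end = c(2600L, 200L, 8100L),
    context = "CG", level_A = 0.5, level_B = 0.1, direction = "hypo")
  res <- associate_dmrs(dmrs, feats)
  expect_equal(res$dmrs$association, c("body", "up2k", "none"))
  expect_equal(res$dmrs$assoc_feature[1:2], c("g1", "g1"))
  # minus-strand gene: genomic-right flank becomes up2k
  featsm <- data.table::data.table(chrom = "c", start = 2001L, end = 3000L,
                                   strand = "-", feature_id = "g1")
  resm <- associate_dmrs(data.table::data.table(
    chrom = "c", start = 3001L, end = 3100L, context = "CG"), featsm)
  expect_equal(resm$dmrs$association, "up2k")
  zs <- dmr_zone_summary(res)
  expect_equal(zs[zs$zone == "body", ][["n_dmrs"]], 1L)
  expect_equal(zs[zs$zone == "none", ][["n_dmrs"]], 1L)
})

test_that("a DMR overlapping body and flank of different genes counts once by priority", {
  feats <- data.table::data.table(chrom = "c",
                                  start = c(2001L, 5001L), end = c(3000L, 6000L),
                                  strand = "+", feature_id = c("g1", "g2"))
  # overlaps g1 body, g1 down2k and g2 up2k
  dmr <- data.table::data.table(chrom = "c", start = 2900L, end = 3200L,
                                context = "CG")
  res <- associate_dmrs(dmr, feats)
  expect_equal(res$dmrs$association, "body")
  expect_equal(nrow(res$associations), 3L)   # every overlap recorded
  zs <- dmr_zone_summary(res)
  expect_equal(sum(zs$n_dmrs), 1L)
})
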
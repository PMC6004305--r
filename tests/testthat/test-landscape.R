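mk_counts <- function(pos, context, level, chrom = "c1", strand = "+",
                      depth = 10L) {
  n_meth <- as.integer(round(level * depth))
  data.table::data.table(
    chrom = chrom, pos = as.integer(pos), strand = strand, context = context,
    n_meth = n_meth, n_unmeth = depth - n_meth, n_other = 0L,
    level = n_meth / depth, covered = TRUE,
    is_methylated = n_meth > 0L)
}

test_that("global fractions use covered-site denominators per context", {
  ct <- mk_counts(c(10, 20, 30, 40), "CG", c(0.9, 0.8, 0.9, 0))
  gf <- global_fractions(ct)
  expect_equal(gf[gf$context == "CG", ][["frac_covered"]], 0.75)
  ct0 <- mk_counts(c(10, 20), "CHH", c(0, 0))
  gf0 <- global_fractions(ct0)
  expect_equal(gf0[gf0$context == "CHH", ][["frac_covered"]], 0)
})

test_that("level histogram bins are right-closed width 0.1 over methylated sites", {
  h <- level_histogram(mk_counts(1:3 * 10, "CG", c(0.95, 0.92, 0.91),
                                 depth = 100L), "CG")
  expect_equal(h$proportions[10], 1)
  expect_equal(sum(h$proportions), 1)
  h2 <- level_histogram(mk_counts(1:3 * 10, "CHH", c(0.15, 0.35, 0.95),
                                  depth = 100L), "CHH")
  expect_equal(h2$proportions[c(2, 4, 10)], rep(1 / 3, 3))
  expect_equal(sum(h2$proportions), 1)
  # exact bin boundary 0.1 falls in bin (0, 0.1]
  h3 <- level_histogram(mk_counts(10, "CG", 0.1, depth = 10L), "CG")
  expect_equal(h3$proportions[1], 1)
  # empty input -> NA proportions
  expect_true(all(is.na(level_histogram(
    mk_counts(10, "CG", 0), "CG")$proportions)))
})

test_that("neighborhood composition matrices have unit column sums", {
  ct <- mk_counts(c(10, 20), "CHH", c(0.5, 0))
  ct$neighborhood <- c("AAAACGAAA", "TTTTCATTT")
  nc <- neighborhood_composition(ct, "CHH")
  expect_equal(unname(colSums(nc$C)), rep(1, 9))
  expect_equal(unname(nc$C["C", 5]), 1)   # centre is always C
  expect_equal(unname(nc$mC["G", 6]), 1)  # only the methylated site has +1 G
  # identical populations give identical matrices
  ct2 <- ct; ct2$is_methylated <- TRUE
  nc2 <- neighborhood_composition(ct2, "CHH")
  expect_equal(nc2$C, nc2$mC)
})

test_that("metagene bins place hand-positioned sites correctly", {
  feats <- data.table::data.table(chrom = "c1", start = 2001L, end = 3000L,
                                  strand = "+", feature_id = "g1")
  ct <- mk_counts(1951, "CG", 0.6)
  pr <- metagene_profile(ct, feats, context = "CG")
  hit <- pr[pr$n_sites > 0, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$zone, "up2k")
  expect_equal(hit$bin, 20L)         # closest upstream bin to the TSS
  expect_equal(hit$mean_level, 0.6)
  # strand flip: the same site lands in downstream bin 1
  feats$strand <- "-"
  pr2 <- metagene_profile(ct, feats, context = "CG")
  hit2 <- pr2[pr2$n_sites > 0, ]
  expect_equal(hit2$zone, "down2k")
  expect_equal(hit2$bin, 1L)
  # empty bins are NA-flagged, not zero-filled
  expect_true(all(is.na(pr[pr$n_sites == 0, ][["mean_level"]])))
})

test_that("constant methylation yields constant non-empty bins and the pooled-mean identity holds", {
  set.seed(42)
  feats <- data.table::data.table(chrom = "c1", start = c(3001L, 9001L),
                                  end = c(5000L, 10500L),
                                  strand = c("+", "-"),
                                  feature_id = c("g1", "g2"))
  pos <- sort(sample(1:13000, 600))
  ct <- mk_counts(pos, "CG", 0.5, depth = 10L)
  pr <- metagene_profile(ct, feats, context = "CG")
  expect_true(all(abs(pr$mean_level[pr$n_sites > 0] - 0.5) < 1e-12))

  # site-count-weighted mean over body bins == direct mean over body sites
  ct$level <- runif(length(pos))
  ct$is_methylated <- TRUE
  pr2 <- metagene_profile(ct, feats, context = "CG")
  body <- pr2[pr2$zone == "body" & pr2$n_sites > 0, ]
  weighted <- sum(body$mean_level * body$n_sites) / sum(body$n_sites)
  ab <- assign_zone_bins(ct[, c("chrom", "pos")], feats)
  direct <- mean(ct$level[ab[ab$zone == "body", ][["xid"]]])
  expect_equal(weighted, direct, tolerance = 1e-9)
})

test_that("strand flip reverses the full bin order exactly", {
  set.seed(7)
  feats <- data.table::data.table(chrom = "c1", start = 5001L, end = 7000L,
                                  strand = "+", feature_id = "g")
  pos <- sort(sample(2500:9500, 400))
  ct <- mk_counts(pos, "CG", 0.5, depth = 10L)
  ct$level <- runif(400)
  pr_f <- metagene_profile(ct, feats, context = "CG")
  feats$strand <- "-"
  pr_r <- metagene_profile(ct, feats, context = "CG")
  # meta_bin k on + equals meta_bin 61-k on -
  expect_equal(pr_f$mean_level, rev(pr_r$mean_level))
  expect_equal(pr_f$n_sites, rev(pr_r$n_sites))
})

test_that("expression classes partition RPKM and stratified profiles work", {
  expect_equal(as.character(expression_classes(c(0, 1, 1.5, 10, 50, 100, 500))),
               c("none", "none", "low", "low", "medium", "high", "high"))
  expect_error(expression_classes(-1), "non-negative")

  feats <- data.table::data.table(chrom = "c1", start = c(1001L, 9001L),
                                  end = c(3000L, 11000L), strand = "+",
                                  feature_id = c("gA", "gB"))
  pos <- seq(1001L, 11000L, by = 50L)
  ct <- mk_counts(pos, "CHG", 0.4, depth = 10L)
  expr <- data.table::data.table(gene_id = c("gA", "gB"), rpkm = c(0.5, 200))
  pr <- expression_stratified_profiles(ct, feats, expr, context = "CHG")
  expect_setequal(unique(pr$expr_class), c("none", "high"))
  # unmatched genes are dropped with a message
  expr2 <- expr[1, ]
  expect_message(
    pr2 <- expression_stratified_profiles(ct, feats, expr2, context = "CHG"),
    "dropped")
  expect_setequal(unique(pr2$expr_class), "none")
  expect_error(expression_stratified_profiles(
    ct, feats, data.table::data.table(gene_id = "zz", rpkm = 1)),
    "no gene id matched")
})
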
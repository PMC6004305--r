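test_that("config validation rejects impossible settings", {
  expect_error(sim_config(p_meth = c(CG = 1.2, CHG = 0.5, CHH = 0.1)), "p_meth")
  expect_error(sim_config(conversion_failure_rate = 1), "conversion_failure_rate")
  expect_error(sim_config(spike_len = c(10L, 500L)), "spike_len")
  expect_error(sim_config(stages = "only_one"), "two stages")
})

test_that("genome simulation is deterministic, correctly sized and packable", {
  cfg <- sim_config(genome_length = 40000L, n_chroms = 2L, n_genes = 4L,
                    n_tes = 6L, gene_len = c(800L, 1500L),
                    te_len = c(200L, 800L), seed = 9L)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_equal(nrow(g1$genes), 4L)
  expect_equal(nrow(g1$tes), 6L)
  expect_true(all(g1$tes$te_class %in% c("LTR", "LINE", "SINE", "simple")))
  # features are disjoint with >= 2 kb clearance within each chromosome
  feats <- rbind(g1$genes[, 1:4], g1$tes[, 1:4])
  data.table::setorder(feats, chrom, start)
  gaps <- feats[, start[-1] - end[-length(end)], by = chrom]$V1
  expect_true(all(gaps > 2000L))
  # realised GC within 3 binomial SE of the target
  gc <- mean(strsplit(as.character(g1$genome[[1]]), "")[[1]] %in% c("C", "G"))
  expect_lt(abs(gc - 0.35), 3 * sqrt(0.35 * 0.65 / 20000))
  # infeasible packing errors out with a suggestion
  expect_error(simulate_genome(sim_config(genome_length = 10000L, n_chroms = 1L,
                                          n_genes = 10L, n_tes = 0L,
                                          seed = 1L)),
               "infeasible packing")
})

test_that("methylome truth follows context probabilities and spike arithmetic", {
  cmp <- small_comparison(23L, genome_length = 40000L)
  tr <- cmp$truth$sites
  # zero CHH probability -> all CHH baseline levels zero
  cfg0 <- sim_config(genome_length = 20000L, n_chroms = 1L, n_genes = 2L,
                     n_tes = 2L, n_deg_up = 1L, n_deg_down = 1L,
                     p_meth = c(CG = 0.81, CHG = 0.64, CHH = 0),
                     n_spikes = c(CG = 0L, CHG = 0L, CHH = 0L), seed = 2L)
  g0 <- simulate_genome(cfg0)
  t0 <- simulate_methylome(enumerate_cytosines(g0$genome), cfg0)
  expect_true(all(t0$sites[t0$sites$context == "CHH", ][["level_stage1"]] == 0))

  # hypo spike: stage2 truth equals stage1 / fold inside the interval
  sp <- cmp$truth$spikes[cmp$truth$spikes$context == "CG", ][1, ]
  inside <- tr[tr$chrom == sp$chrom & tr$pos >= sp$start & tr$pos <= sp$end &
                 tr$context == "CG", ]
  expect_true(nrow(inside) >= 5L)
  expect_equal(inside$level_stage2, inside$level_stage1 / sp$fold)
  # outside any spike, the two stages share the baseline
  spk <- cmp$truth$spikes
  out1 <- tr[tr$chrom == spk$chrom[1] & tr$pos > max(spk$end) + 1000L, ]
  expect_equal(out1$level_stage1, out1$level_stage2)
  # realised mCG fraction within 3 SE of the configured probability
  cg <- tr[tr$context == "CG", ]
  frac <- mean(cg$level_stage1 > 0)
  expect_lt(abs(frac - 0.81), 3 * sqrt(0.81 * 0.19 / nrow(cg)))
  # spikes are pairwise disjoint
  data.table::setkey(spk, chrom, start, end)
  ov <- data.table::foverlaps(spk, spk, nomatch = NULL)
  expect_equal(nrow(ov), nrow(spk))  # only self-overlaps
})

test_that("count simulation hits the exact edge cases and converges with depth", {
  cfg <- sim_config(genome_length = 20000L, n_chroms = 1L, n_genes = 2L,
                    n_tes = 2L, n_deg_up = 1L, n_deg_down = 1L,
                    conversion_failure_rate = 0,
                    n_spikes = c(CG = 0L, CHG = 0L, CHH = 0L), seed = 4L)
  g <- simulate_genome(cfg)
  sites <- enumerate_cytosines(g$genome)
  truth <- simulate_methylome(sites, cfg)
  # force degenerate truths (NA-context sites stay unmethylated)
  truth$sites[, level_stage1 := ifelse(!is.na(context) & context == "CG", 1, 0)]
  ct <- simulate_counts(truth, "stage1", call = FALSE)
  cg <- ct[ct$context == "CG" & ct$covered, ]
  expect_true(all(cg$n_unmeth == 0L))
  nn <- ct[ct$context != "CG" & !is.na(ct$context) & ct$covered, ]
  expect_true(all(nn$n_meth == 0L))

  # law of large numbers at depth 1000
  cfg2 <- sim_config(genome_length = 20000L, n_chroms = 1L, n_genes = 2L,
                     n_tes = 2L, n_deg_up = 1L, n_deg_down = 1L,
                     depth_mean = 1000, conversion_failure_rate = 0,
                     n_spikes = c(CG = 0L, CHG = 0L, CHH = 0L), seed = 4L)
  truth2 <- simulate_methylome(sites, cfg2)
  truth2$sites[, level_stage1 := 0.5]
  ct2 <- simulate_counts(truth2, "stage1", call = FALSE)
  expect_lt(abs(mean(ct2$level) - 0.5), 0.002)
  expect_error(simulate_counts(truth, "nope"), "unknown stage")
})

test_that("per-site level error shrinks from 27x to 270x depth", {
  base <- sim_config(genome_length = 20000L, n_chroms = 1L, n_genes = 2L,
                     n_tes = 2L, n_deg_up = 1L, n_deg_down = 1L,
                     n_spikes = c(CG = 0L, CHG = 0L, CHH = 0L), seed = 6L)
  g <- simulate_genome(base)
  sites <- enumerate_cytosines(g$genome)
  truth <- simulate_methylome(sites, base)
  err <- function(depth) {
    cfg <- base; cfg$depth_mean <- depth
    t2 <- truth; t2$config <- cfg
    ct <- simulate_counts(t2, "stage1", call = FALSE)
    keep <- ct$covered & !is.na(ct$context)
    mean(abs(ct$level[keep] - truth$sites$level_stage1[keep]))
  }
  expect_gt(err(27), err(270))
})

test_that("read simulation is consistent with its own count emission and with extraction", {
  cmp <- small_comparison(8L, genome_length = 20000L)
  sam <- tempfile(fileext = ".sam")
  rr <- simulate_reads(cmp$truth, cmp$genome$genome, "stage1", sam)
  ex <- extract_counts(sam, cmp$sites)
  cols <- c("chrom", "pos", "strand", "n_meth", "n_unmeth")
  expect_equal(as.data.frame(ex[, cols, with = FALSE]),
               as.data.frame(rr$counts[, cols, with = FALSE]))
  # SAM is well-formed for samtools-compatible parsers (header + proper pairs)
  lines <- readLines(sam, n = 5L)
  expect_true(grepl("^@HD", lines[1]))
  expect_error(simulate_reads(
    {t <- cmp$truth; t$config$insert_size <- 150L; t},
    cmp$genome$genome, "stage1", tempfile()), "insert_size")
})

test_that("expression table honours DEG quotas and class mix invariants", {
  cfg <- sim_config(genome_length = 60000L, n_chroms = 2L, n_genes = 12L,
                    n_tes = 2L, gene_len = c(800L, 1200L),
                    te_len = c(200L, 600L), n_deg_up = 3L, n_deg_down = 2L,
                    seed = 5L)
  g <- simulate_genome(cfg)
  e1 <- simulate_expression(g$genes, cfg)
  e2 <- simulate_expression(g$genes, cfg)
  expect_identical(e1, e2)
  expect_equal(sum(e1$status == "up"), 3L)
  expect_equal(sum(e1$status == "down"), 2L)
  expect_true(all(e1$status == deg_status(e1$log2fc, e1$fdr)))
  expect_true(all(e1$rpkm >= 0))
})

test_that("truth covers every simulated site and the bundle is complete", {
  cfg <- sim_config(genome_length = 20000L, n_chroms = 1L, n_genes = 2L,
                    n_tes = 2L, n_deg_up = 1L, n_deg_down = 1L,
                    n_spikes = c(CG = 1L, CHG = 1L, CHH = 1L), seed = 12L)
  out <- tempfile()
  b <- simulate_bundle(cfg, out)
  expect_equal(nrow(b$truth$sites), nrow(b$sites))
  for (st in cfg$stages)
    expect_equal(b$counts[[st]]$pos, b$truth$sites$pos)
  expect_true(all(file.exists(unlist(b$paths))))
  # siRNA loci are 24 nt and the spike-enriched fraction lands inside spikes
  expect_true(all(b$sirna$end - b$sirna$start + 1L == 24L))
  tj <- jsonlite::read_json(b$paths$truth)
  expect_equal(length(tj$spikes), nrow(b$truth$spikes))
})
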
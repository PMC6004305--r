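# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive results by the most literal route available
# (per-position scans, exhaustive window enumeration) so they cannot share a
# bug with the vectorised implementations they check.

library(data.table)

# Naive two-strand re-scan of one sequence: per-position loop, no shared code
# with enumerate_cytosines().
oracle_scan_contexts <- function(s, chrom = "chr") {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  ch[!(ch %in% names(comp))] <- "N"
  n <- length(ch)
  pos <- integer(2L * n); strand <- character(2L * n); ctx <- character(2L * n)
  k <- 0L
  ctx_of <- function(b2, b3) {
    if (b2 == "G") "CG"
    else if (b2 == "N") NA_character_
    else if (b3 == "G") "CHG"
    else if (b3 == "N") NA_character_
    else "CHH"
  }
  for (i in seq_len(n)) {
    if (ch[i] == "C") {
      b2 <- if (i + 1L <= n) ch[i + 1L] else "N"
      b3 <- if (i + 2L <= n) ch[i + 2L] else "N"
      k <- k + 1L; pos[k] <- i; strand[k] <- "+"; ctx[k] <- ctx_of(b2, b3)
    }
    if (ch[i] == "G") {
      b2 <- if (i - 1L >= 1L) comp[[ch[i - 1L]]] else "N"
      b3 <- if (i - 2L >= 1L) comp[[ch[i - 2L]]] else "N"
      k <- k + 1L; pos[k] <- i; strand[k] <- "-"; ctx[k] <- ctx_of(b2, b3)
    }
  }
  if (k == 0L)
    return(data.table(chrom = character(), pos = integer(),
                      strand = character(), context = character()))
  out <- data.table(chrom = chrom, pos = pos[1:k], strand = strand[1:k],
                    context = ctx[1:k])
  setorder(out, chrom, pos, strand)
  out
}

random_seq <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Exhaustive enumerator of maximal <max_gap chains over sorted methylated
# sites: checks every window [i, j] for internal gaps, boundary maximality,
# span bounds and the per-sample site minimum.
oracle_chain_enumerate <- function(ms, max_gap = 200, min_len = 40,
                                   max_len = 10000, min_sites = 5) {
  ms <- as.data.table(ms)
  out <- list()
  for (cc in unique(ms$chrom)) {
    sub <- ms[chrom == cc][order(pos)]
    p <- sub$pos
    n <- length(p)
    for (i in seq_len(n)) for (j in i:n) {
      if (j > i && any(diff(p[i:j]) >= max_gap)) next
      left_max <- i == 1L || (p[i] - p[i - 1L]) >= max_gap
      right_max <- j == n || (p[j + 1L] - p[j]) >= max_gap
      if (!left_max || !right_max) next
      span <- p[j] - p[i] + 1L
      if (span < min_len || span > max_len) next
      if (max(sum(sub$meth_A[i:j]), sum(sub$meth_B[i:j])) < min_sites) next
      out[[length(out) + 1L]] <- data.table(chrom = cc, start = p[i],
                                            end = p[j], span = span)
    }
  }
  if (!length(out))
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), span = integer()))
  res <- rbindlist(out)
  setorder(res, chrom, start)
  res
}

# Minimal SAM writer for hand-built alignment fixtures.
write_test_sam <- function(path, chrom_lens, records) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lens), chrom_lens))
  lines <- vapply(records, function(r) {
    paste(r$qname, r$flag, r$chrom, r$pos,
          if (!is.null(r$mapq)) r$mapq else 60L,
          paste0(nchar(r$seq), "M"), "=",
          if (!is.null(r$pnext)) r$pnext else r$pos, 0L,
          r$seq,
          if (!is.null(r$qual)) r$qual else strrep("I", nchar(r$seq)),
          paste0("XG:Z:", r$xg), sep = "\t")
  }, character(1L))
  ord <- order(vapply(records, function(r) r$chrom, character(1L)),
               vapply(records, function(r) r$pos, numeric(1L)))
  writeLines(c(hdr, lines[ord]), path)
  path
}

# Small simulated two-sample comparison used by several DMR tests.
small_comparison <- function(seed, genome_length = 20000L,
                             n_spikes = c(CG = 2L, CHG = 1L, CHH = 1L)) {
  cfg <- sim_config(genome_length = genome_length, n_chroms = 1L,
                    n_genes = 2L, n_tes = 2L, gene_len = c(800L, 1500L),
                    te_len = c(200L, 800L), n_deg_up = 1L, n_deg_down = 1L,
                    n_spikes = n_spikes, spike_len = c(200L, 1000L),
                    seed = seed)
  g <- simulate_genome(cfg)
  sites <- enumerate_cytosines(g$genome)
  truth <- simulate_methylome(sites, cfg)
  list(cfg = cfg, genome = g, sites = sites, truth = truth,
       a = simulate_counts(truth, "stage1"),
       b = simulate_counts(truth, "stage2"))
}

# Lazily built default-scale bundle (the study-condition regime), shared by
# the landscape-scale tests to keep the suite fast.
.bundle_cache <- new.env(parent = emptyenv())
default_bundle <- function(seed = 1L, coupling = FALSE) {
  key <- paste0("b", seed, "_", coupling)
  if (is.null(.bundle_cache[[key]])) {
    cfg <- sim_config(seed = seed, expression_coupling = coupling)
    .bundle_cache[[key]] <- simulate_bundle(cfg, tempfile(), reads = FALSE)
  }
  .bundle_cache[[key]]
}
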
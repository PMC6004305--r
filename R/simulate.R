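#' Simulation configuration
#'
#' Defaults emulate the study regime this package targets: a 200-kb toy
#' genome, per-context methylated-site probabilities 0.81 (CG), 0.64 (CHG)
#' and 0.05 (CHH), bimodal high site levels for CG/CHG versus broad 0.1-0.4
#' levels for CHH, Poisson sequencing depth with mean 27, bisulfite
#' conversion-failure rate 0.005, 125-bp paired reads, and stage-specific
#' spiked DMRs with >= 2-fold effects.
#'
#' @param genome_length Total genome size in bp (default 200000).
#' @param n_chroms Number of sequences (default 2).
#' @param gc GC fraction (default 0.35).
#' @param n_genes,gene_len Gene count and length range (bp).
#' @param n_tes,te_len,te_classes TE count, length range, class mix.
#' @param p_meth Named per-context methylated-site probabilities.
#' @param level_mix_high Mixture weight of the high (>0.9-centred) component
#'   for CG and CHG site levels.
#' @param depth_mean Poisson mean sequencing depth (default 27).
#' @param conversion_failure_rate Unmethylated-C non-conversion probability.
#' @param seq_error_rate Flat substitution error on the methylation signal
#'   (default 0).
#' @param stages Stage names; the first is the baseline, spikes are applied
#'   to the later stage(s).
#' @param n_spikes Named per-context spiked-DMR counts.
#' @param spike_fold Spike effect size (level ratio, default 2.5).
#' @param spike_len Spike span range in bp (default 200-2000).
#' @param spike_direction Named per-context direction of the spiked stage
#'   relative to baseline ("hypo" divides, "hyper" multiplies with an
#'   additive fallback where the product would exceed 1).
#' @param expression_coupling Couple CHG gene-body truth to expression class
#'   (unexpressed vs expressed body levels below).
#' @param chg_body_unexpressed,chg_body_expressed CHG body truth levels used
#'   when `expression_coupling = TRUE`.
#' @param expr_class_mix Proportions of none/low/medium/high expression.
#' @param n_deg_up,n_deg_down Numbers of up-/down-regulated DEGs.
#' @param n_sirna,sirna_dmr_frac 24-nt siRNA locus count and the fraction
#'   placed inside spiked DMRs.
#' @param read_len,insert_size Read geometry (125-bp paired, 300-bp insert).
#' @param seed Integer master seed.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 200000L, n_chroms = 2L, gc = 0.35,
                       n_genes = 20L, gene_len = c(1000L, 3000L),
                       n_tes = 30L, te_len = c(200L, 2000L),
                       te_classes = c(LTR = 0.4, LINE = 0.25, SINE = 0.2,
                                      simple = 0.15),
                       p_meth = c(CG = 0.81, CHG = 0.64, CHH = 0.05),
                       level_mix_high = c(CG = 0.7, CHG = 0.55),
                       depth_mean = 27,
                       conversion_failure_rate = 0.005,
                       seq_error_rate = 0,
                       stages = c("stage1", "stage2"),
                       n_spikes = c(CG = 20L, CHG = 10L, CHH = 10L),
                       spike_fold = 2.5,
                       spike_len = c(200L, 2000L),
                       spike_direction = c(CG = "hypo", CHG = "hypo",
                                           CHH = "hyper"),
                       expression_coupling = FALSE,
                       chg_body_unexpressed = 0.3,
                       chg_body_expressed = 0.05,
                       expr_class_mix = c(none = 0.25, low = 0.25,
                                          medium = 0.25, high = 0.25),
                       n_deg_up = 5L, n_deg_down = 3L,
                       n_sirna = 300L, sirna_dmr_frac = 0.3,
                       read_len = 125L, insert_size = 300L,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (any(cfg$p_meth < 0 | cfg$p_meth > 1)) stop("p_meth must be in [0,1]")
  if (cfg$conversion_failure_rate < 0 || cfg$conversion_failure_rate >= 1)
    stop("conversion_failure_rate must be in [0,1)")
  if (cfg$spike_len[1] < 40 || cfg$spike_len[2] > 10000)
    stop("spike_len must lie within [40, 10000]")
  if (length(cfg$stages) < 2L) stop("need at least two stages")
  structure(cfg, class = "sim_config")
}

.subseed <- function(seed, k) (as.integer(seed) * 97L + k) %% 2147483629L

#' Simulate a toy genome with gene and TE annotations
#'
#' Random sequences at the configured GC fraction; genes and TEs placed
#' non-overlapping with >= 2 kb clearance between features (so every gene has
#' clean up2k/down2k zones where the chromosome allows), random strands, TE
#' classes drawn from the configured mix.
#'
#' @param cfg A [sim_config()].
#' @return List: `genome` ([Biostrings::DNAStringSet]), `genes` and `tes`
#'   (data.tables with `chrom`, `start`, `end` (1-based inclusive), `strand`,
#'   `feature_id`; TEs also `te_class`).
#' @export
simulate_genome <- function(cfg) {
  set.seed(.subseed(cfg$seed, 1L))
  chrom_len <- as.integer(cfg$genome_length / cfg$n_chroms)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  probs <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2, G = cfg$gc / 2,
             T = (1 - cfg$gc) / 2)
  seqs <- vapply(chroms, function(ch)
    paste(sample(names(probs), chrom_len, replace = TRUE, prob = probs),
          collapse = ""), character(1L))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms

  n_feat <- cfg$n_genes + cfg$n_tes
  kind <- c(rep("gene", cfg$n_genes), rep("te", cfg$n_tes))
  lens <- integer(n_feat)
  lens[kind == "gene"] <- sample(cfg$gene_len[1]:cfg$gene_len[2], cfg$n_genes,
                                 replace = TRUE)
  lens[kind == "te"] <- sample(cfg$te_len[1]:cfg$te_len[2], cfg$n_tes,
                               replace = TRUE)
  ord <- sample.int(n_feat)
  kind <- kind[ord]; lens <- lens[ord]
  # round-robin assignment to chromosomes, then sequential packing with
  # >= 2 kb gaps (clearance for flank zones)
  chrom_of <- rep(chroms, length.out = n_feat)
  feats <- rbindlist(lapply(chroms, function(ch) {
    sel <- chrom_of == ch
    k <- sum(sel)
    if (k == 0L) return(NULL)
    l <- lens[sel]
    min_gap <- 2000L
    need <- sum(l) + (k + 1L) * min_gap
    if (need > chrom_len)
      stop("infeasible packing on ", ch, ": need ", need, " bp > ", chrom_len,
           " bp; reduce n_genes/n_tes or feature lengths")
    slack <- chrom_len - need
    cuts <- sort(sample.int(slack + 1L, k + 1L, replace = TRUE) - 1L)
    extra <- diff(c(0L, cuts))
    gaps <- min_gap + extra[seq_len(k)]
    starts <- cumsum(gaps) + cumsum(c(0L, l[-k])) + 1L
    data.table(chrom = ch, start = starts, end = starts + l - 1L,
               strand = sample(c("+", "-"), k, replace = TRUE),
               kind = kind[sel])
  }))
  genes <- feats[kind == "gene"][, feature_id := sprintf("gene%03d", .I)]
  tes <- feats[kind == "te"][, feature_id := sprintf("te%03d", .I)]
  tes[, te_class := sample(names(cfg$te_classes), .N, replace = TRUE,
                           prob = cfg$te_classes)]
  genes[, kind := NULL]; tes[, kind := NULL]
  list(genome = genome, genes = genes[], tes = tes[])
}

.draw_levels <- function(context, n, cfg) {
  if (n == 0L) return(numeric())
  switch(context,
    CG = {
      hi <- runif(n) < cfg$level_mix_high[["CG"]]
      ifelse(hi, rbeta(n, 40, 2), rbeta(n, 4, 2))
    },
    CHG = {
      hi <- runif(n) < cfg$level_mix_high[["CHG"]]
      ifelse(hi, rbeta(n, 40, 2), rbeta(n, 2, 2))
    },
    CHH = 0.1 + 0.3 * rbeta(n, 2, 2),
    stop("unknown context ", context))
}

#' Simulate stage-specific true methylation levels with spiked DMRs
#'
#' Each context site is methylated with its configured probability; methylated
#' sites draw a level from the context's distribution, unmethylated sites are
#' 0. Stage 1 is the baseline; later stages copy it and then spiked DMR
#' intervals (disjoint, each containing at least `min_sites` context sites)
#' scale their levels by the configured fold ("hypo" divides, "hyper"
#' multiplies; where a product would exceed 1 an additive shift of
#' `(fold - 1) x` the context's mean methylated level is used, capped at 1).
#' With `expression_coupling`, CHG sites in unexpressed gene bodies are set to
#' the elevated truth level and in expressed bodies to the low one.
#'
#' @param sites Cytosine report.
#' @param cfg A [sim_config()].
#' @param genes Gene table (required for expression coupling).
#' @param unexpressed_ids Gene ids treated as unexpressed for coupling.
#' @param min_sites Minimum context sites per spike (default 5).
#' @return List of class `truth_set`: `sites` (report plus one
#'   `level_<stage>` column per stage), `spikes` (`chrom`, `start`, `end`,
#'   `context`, `fold`, `direction`), `config` (the `sim_config`).
#' @export
simulate_methylome <- function(sites, cfg, genes = NULL,
                               unexpressed_ids = NULL, min_sites = 5L) {
  set.seed(.subseed(cfg$seed, 2L))
  tr <- copy(as.data.table(sites))
  tr[, true_level := 0]
  for (cx in c("CG", "CHG", "CHH")) {
    idx <- which(tr$context == cx)
    m <- idx[runif(length(idx)) < cfg$p_meth[[cx]]]
    set(tr, m, "true_level", .draw_levels(cx, length(m), cfg))
  }
  if (isTRUE(cfg$expression_coupling)) {
    if (is.null(genes) || is.null(unexpressed_ids))
      stop("expression_coupling needs genes and unexpressed_ids")
    ab <- .overlap_sites_features(tr, genes)
    chg <- ab[tr$context[xid] == "CHG"]
    unexp <- genes$feature_id[chg$yid] %in% unexpressed_ids
    set(tr, chg$xid[unexp], "true_level", cfg$chg_body_unexpressed)
    set(tr, chg$xid[!unexp], "true_level", cfg$chg_body_expressed)
  }

  # spike placement: disjoint intervals with enough context sites
  chrom_lens <- tr[, .(len = max(pos)), by = chrom]
  spikes <- list()
  taken <- data.table(chrom = character(), start = integer(), end = integer())
  for (cx in names(cfg$n_spikes)) {
    k <- cfg$n_spikes[[cx]]
    placed <- 0L
    tries <- 0L
    while (placed < k && tries < 200L * max(k, 1L)) {
      tries <- tries + 1L
      ch <- chrom_lens[sample.int(nrow(chrom_lens), 1L)]
      w <- sample(cfg$spike_len[1]:cfg$spike_len[2], 1L)
      if (ch$len <= w) next
      s <- sample.int(ch$len - w, 1L)
      e <- s + w - 1L
      if (nrow(taken[chrom == ch$chrom & start <= e & end >= s])) next
      nctx <- tr[chrom == ch$chrom & pos >= s & pos <= e & context == cx, .N]
      if (nctx < min_sites) next
      taken <- rbind(taken, data.table(chrom = ch$chrom, start = s, end = e))
      spikes[[length(spikes) + 1L]] <- data.table(
        chrom = ch$chrom, start = s, end = e, context = cx,
        fold = cfg$spike_fold,
        direction = cfg$spike_direction[[cx]])
      placed <- placed + 1L
    }
    if (placed < k)
      message("simulate_methylome: placed ", placed, "/", k, " ", cx,
              " spikes (genome too crowded)")
  }
  spikes <- if (length(spikes)) rbindlist(spikes) else
    data.table(chrom = character(), start = integer(), end = integer(),
               context = character(), fold = numeric(), direction = character())

  st1 <- cfg$stages[1L]
  tr[, (paste0("level_", st1)) := true_level]
  mean_meth <- tr[true_level > 0, .(mu = mean(true_level)), by = context]
  for (st in cfg$stages[-1L]) {
    lv <- tr$true_level
    if (nrow(spikes)) for (i in seq_len(nrow(spikes))) {
      sp <- spikes[i]
      idx <- which(tr$chrom == sp$chrom & tr$pos >= sp$start &
                     tr$pos <= sp$end & tr$context == sp$context)
      if (sp$direction == "hypo") {
        lv[idx] <- lv[idx] / sp$fold
      } else {
        mu <- mean_meth[context == sp$context, mu]
        prod_ok <- lv[idx] * sp$fold <= 1
        lv[idx] <- ifelse(prod_ok, lv[idx] * sp$fold,
                          pmin(1, lv[idx] + (sp$fold - 1) * mu))
      }
    }
    tr[, (paste0("level_", st)) := lv]
  }
  tr[, true_level := NULL]
  structure(list(sites = tr[], spikes = spikes[], config = cfg),
            class = "truth_set")
}

#' Simulate per-site bisulfite count tables
#'
#' Per site: depth ~ Poisson(`depth_mean`); methylated-read count ~
#' Binomial(depth, p) with
#' `p = level (1 - seq_error_rate) + (1 - level) conversion_failure_rate`.
#' Deterministic given the config seed and stage.
#'
#' @param truth A `truth_set` from [simulate_methylome()].
#' @param stage Stage name (must match a `level_<stage>` column).
#' @param call Add `is_methylated`/`p_value` with default calling (default
#'   TRUE).
#' @return A count table in the standard dialect.
#' @export
simulate_counts <- function(truth, stage, call = TRUE) {
  cfg <- truth$config
  if (!paste0("level_", stage) %in% names(truth$sites))
    stop("unknown stage: ", stage)
  set.seed(.subseed(cfg$seed, 10L + match(stage, cfg$stages)))
  out <- truth$sites[, .(chrom, pos, strand, context)]
  lv <- truth$sites[[paste0("level_", stage)]]
  n <- nrow(out)
  depth <- rpois(n, cfg$depth_mean)
  p <- lv * (1 - cfg$seq_error_rate) +
    (1 - lv) * cfg$conversion_failure_rate
  nm <- rbinom(n, depth, p)
  out[, `:=`(n_meth = nm, n_unmeth = depth - nm, n_other = 0L)]
  out[, level := site_level(n_meth, n_unmeth)]
  out[, covered := (n_meth + n_unmeth) > 0L]
  if (call) out <- add_meth_calls(out,
                                  conversion_failure_rate = cfg$conversion_failure_rate)
  out[]
}

#' Simulate aligned bisulfite reads (SAM) and their implied counts
#'
#' Emits 125-bp proper read pairs pre-aligned at their true coordinates
#' (directional library: each fragment is original-top "CT" or
#' original-bottom "GA" with equal probability, tagged `XG`). Per fragment
#' and informative cytosine, the methylation state is one Bernoulli draw at
#' the same success probability as [simulate_counts()]; the same draws are
#' aggregated into the returned count table, so a faithful extractor must
#' reproduce it exactly when `seq_error_rate = 0`.
#'
#' @param truth A `truth_set`.
#' @param genome The simulated genome (DNAStringSet).
#' @param stage Stage name.
#' @param sam_path Output SAM path.
#' @param fastq_path Optional FASTQ path (interleaved, original read
#'   orientation); `NULL` skips it.
#' @return List: `sam` (path), `counts` (count table implied by the per-read
#'   draws, with default calls), `n_fragments`.
#' @export
simulate_reads <- function(truth, genome, stage, sam_path,
                           fastq_path = NULL) {
  cfg <- truth$config
  set.seed(.subseed(cfg$seed, 20L + match(stage, cfg$stages)))
  rl <- cfg$read_len
  ins <- cfg$insert_size
  if (ins < 2L * rl)
    stop("insert_size must be >= 2 * read_len (non-overlapping mates)")
  lv_all <- truth$sites[[paste0("level_", stage)]]
  chroms <- names(genome)

  frags <- rbindlist(lapply(chroms, function(ch) {
    L <- Biostrings::width(genome[ch])
    nf <- as.integer(round(L * cfg$depth_mean / (2 * rl)))
    if (L <= ins || nf == 0L) return(NULL)
    data.table(chrom = ch,
               start = sample.int(L - ins + 1L, nf, replace = TRUE),
               bs = sample(c("CT", "GA"), nf, replace = TRUE))
  }))
  setorder(frags, chrom, start, bs)
  frags[, frag_id := .I]
  frags[, `:=`(r1s = start, r2s = start + ins - rl)]

  # incidence of informative sites on fragments (either mate)
  sites <- copy(truth$sites)[, site_id := .I][, lv := lv_all]
  inc_all <- rbindlist(lapply(c("r1s", "r2s"), function(col) {
    rd <- frags[, .(chrom, start = get(col), end = get(col) + rl - 1L,
                    frag_id, bs)]
    setkey(rd, chrom, start, end)
    pt <- sites[, .(chrom, start = pos, end = pos, site_id, strand, lv)]
    ov <- foverlaps(pt, rd, by.x = c("chrom", "start", "end"), nomatch = NULL)
    # y columns keep their names; the point coordinate arrives as i.start
    ov[, .(frag_id, bs, site_id, strand, lv, mate = col, pos = i.start)]
  }))
  inc <- inc_all[(strand == "+" & bs == "CT") | (strand == "-" & bs == "GA")]
  p <- inc$lv * (1 - cfg$seq_error_rate) +
    (1 - inc$lv) * cfg$conversion_failure_rate
  inc[, meth := runif(.N) < p]

  counts <- inc[, .(n_meth = sum(meth), n_unmeth = sum(!meth)), by = site_id]
  ct <- sites[, .(chrom, pos, strand, context, site_id)]
  ct <- merge(ct, counts, by = "site_id", all.x = TRUE)
  ct[is.na(n_meth), `:=`(n_meth = 0L, n_unmeth = 0L)]
  ct[, `:=`(site_id = NULL, n_other = 0L)]
  ct[, level := site_level(n_meth, n_unmeth)]
  ct[, covered := (n_meth + n_unmeth) > 0L]
  ct <- add_meth_calls(ct, conversion_failure_rate = cfg$conversion_failure_rate)
  setorder(ct, chrom, pos, strand)

  # read sequences from the bisulfite-converted reference, then restore
  # unconverted Cs (or Gs on the bottom strand) where the draw was methylated
  conv <- lapply(chroms, function(ch) {
    s <- strsplit(as.character(genome[[ch]]), "", fixed = TRUE)[[1L]]
    list(CT = { x <- s; x[x == "C"] <- "T"; x },
         GA = { x <- s; x[x == "G"] <- "A"; x })
  })
  names(conv) <- chroms

  reads <- rbindlist(lapply(c("r1s", "r2s"), function(col)
    frags[, .(frag_id, chrom, bs, mate = col, start = get(col))]))
  setorder(reads, frag_id, mate)
  reads[, read_id := .I]

  seqs <- character(nrow(reads))
  for (ch in chroms) {
    for (b in c("CT", "GA")) {
      sel <- which(reads$chrom == ch & reads$bs == b)
      if (!length(sel)) next
      cv <- conv[[ch]][[b]]
      m <- matrix(cv[outer(reads$start[sel], 0:(rl - 1L), "+")],
                  nrow = length(sel))
      # restore methylated draws
      key <- reads[sel, .(frag_id, mate, start)][, row := .I]
      sub <- merge(inc[meth == TRUE & bs == b],
                   key, by = c("frag_id", "mate"))
      sub <- sub[sites$chrom[site_id] == ch]
      if (nrow(sub)) {
        coloff <- sub$pos - sub$start + 1L
        keep <- coloff >= 1L & coloff <= rl
        m[cbind(sub$row[keep], coloff[keep])] <- if (b == "CT") "C" else "G"
      }
      seqs[sel] <- apply(m, 1L, paste, collapse = "")
    }
  }
  reads[, seq := seqs]

  # SAM emission
  first <- reads$mate == "r1s"
  ga <- reads$bs == "GA"
  flag <- integer(nrow(reads))
  flag[first & !ga] <- 99L   # paired, proper, mate reverse, first
  flag[!first & !ga] <- 147L
  flag[first & ga] <- 83L
  flag[!first & ga] <- 163L
  mate_start <- ifelse(first, reads$start + ins - rl, reads$start - ins + rl)
  tlen <- ifelse(xor(first, ga), ins, -ins)
  qual <- strrep("I", rl)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chroms,
                   Biostrings::width(genome)[match(chroms, names(genome))]))
  ord <- order(reads$chrom, reads$start, reads$frag_id)
  body <- reads[ord]
  bflag <- flag[ord]
  bmate <- mate_start[ord]
  btlen <- tlen[ord]
  lines <- sprintf("frag%07d\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s\tXG:Z:%s",
                   body$frag_id, bflag, body$chrom, body$start, rl,
                   bmate, btlen, body$seq, qual, body$bs)
  writeLines(c(hdr, lines), sam_path)

  if (!is.null(fastq_path)) {
    rc <- bitwAnd(bflag, 16L) != 0L
    fq_seq <- ifelse(rc, .revcomp_str(body$seq), body$seq)
    mate_no <- ifelse(bitwAnd(bflag, 64L) != 0L, 1L, 2L)
    writeLines(as.vector(rbind(
      sprintf("@frag%07d/%d", body$frag_id, mate_no),
      fq_seq, "+", qual)), fastq_path)
  }
  list(sam = sam_path, counts = ct[], n_fragments = nrow(frags))
}

#' Simulate a gene-expression table
#'
#' RPKM drawn per configured class mix; exactly `n_deg_up` genes get
#' `log2fc > 1, fdr < 0.05` and `n_deg_down` the mirrored down flags, the
#' rest are non-significant.
#'
#' @param genes Gene table.
#' @param cfg A [sim_config()].
#' @return data.table: `gene_id`, `rpkm`, `log2fc`, `fdr`, `status`.
#' @export
simulate_expression <- function(genes, cfg) {
  set.seed(.subseed(cfg$seed, 3L))
  n <- nrow(genes)
  cls <- sample(names(cfg$expr_class_mix), n, replace = TRUE,
                prob = cfg$expr_class_mix)
  rpkm <- numeric(n)
  rpkm[cls == "none"] <- runif(sum(cls == "none"), 0, 1)
  rpkm[cls == "low"] <- runif(sum(cls == "low"), 1.0001, 10)
  rpkm[cls == "medium"] <- runif(sum(cls == "medium"), 10.0001, 99.999)
  rpkm[cls == "high"] <- runif(sum(cls == "high"), 100, 1000)
  if (cfg$n_deg_up + cfg$n_deg_down > n)
    stop("more DEGs requested than genes")
  idx <- sample.int(n, cfg$n_deg_up + cfg$n_deg_down)
  up <- idx[seq_len(cfg$n_deg_up)]
  down <- setdiff(idx, up)
  log2fc <- runif(n, -0.8, 0.8)
  fdr <- runif(n, 0.06, 1)
  log2fc[up] <- runif(length(up), 1.2, 4)
  fdr[up] <- runif(length(up), 0, 0.049)
  log2fc[down] <- runif(length(down), -4, -1.2)
  fdr[down] <- runif(length(down), 0, 0.049)
  data.table(gene_id = genes$feature_id, rpkm = rpkm, log2fc = log2fc,
             fdr = fdr, status = deg_status(log2fc, fdr))
}

#' Simulate 24-nt siRNA loci
#'
#' A configured fraction of loci is centred inside spiked DMR intervals (the
#' RdDM-style enrichment mode); the rest are uniform over the genome.
#'
#' @param truth A `truth_set` (for spike intervals and chromosome sizes).
#' @param cfg A [sim_config()].
#' @return data.table: `chrom`, `start`, `end` (24-nt, 1-based inclusive),
#'   `length`, `abundance`, `in_spike`.
#' @export
simulate_sirna <- function(truth, cfg) {
  set.seed(.subseed(cfg$seed, 4L))
  chrom_lens <- truth$sites[, .(len = max(pos)), by = chrom]
  n <- cfg$n_sirna
  n_spike <- if (nrow(truth$spikes)) round(n * cfg$sirna_dmr_frac) else 0L
  mk <- function(chrom, mid) {
    s <- pmax(1L, as.integer(mid) - 11L)
    data.table(chrom = chrom, start = s, end = s + 23L)
  }
  out <- list()
  if (n_spike > 0L) {
    sp <- truth$spikes[sample.int(nrow(truth$spikes), n_spike, replace = TRUE)]
    mid <- sp$start + as.integer(runif(n_spike) * (sp$end - sp$start + 1L))
    out[[1L]] <- mk(sp$chrom, mid)[, in_spike := TRUE]
  }
  n_bg <- n - n_spike
  if (n_bg > 0L) {
    ch <- chrom_lens[sample.int(nrow(chrom_lens), n_bg, replace = TRUE)]
    mid <- as.integer(runif(n_bg) * (ch$len - 30L)) + 15L
    out[[length(out) + 1L]] <- mk(ch$chrom, mid)[, in_spike := FALSE]
  }
  res <- rbindlist(out)
  res[, `:=`(length = 24L, abundance = rpois(.N, 5) + 1L)]
  setorder(res, chrom, start)
  res[]
}

#' Run the full simulator and write a data bundle
#'
#' Genome, annotations, expression, stage methylomes with spiked DMRs, count
#' tables (and optionally aligned reads) per stage, siRNA loci, and a
#' machine-readable truth set.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created).
#' @param reads Also emit per-stage SAM files (default FALSE).
#' @return List with all simulated objects and the file paths written.
#' @export
simulate_bundle <- function(cfg, outdir, reads = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  g <- simulate_genome(cfg)
  sites <- enumerate_cytosines(g$genome)
  expr <- simulate_expression(g$genes, cfg)
  unexp <- expr[rpkm <= 1, gene_id]
  truth <- simulate_methylome(sites, cfg, genes = g$genes,
                              unexpressed_ids = unexp)
  counts <- lapply(cfg$stages, function(st) simulate_counts(truth, st))
  names(counts) <- cfg$stages
  sirna <- simulate_sirna(truth, cfg)

  paths <- list(genome = file.path(outdir, "genome.fa"),
                genes = file.path(outdir, "genes.bed"),
                tes = file.path(outdir, "tes.bed"),
                cytosine_report = file.path(outdir, "cytosine_report.tsv"),
                expression = file.path(outdir, "expression.tsv"),
                sirna = file.path(outdir, "sirna.bed"),
                truth_sites = file.path(outdir, "truth_sites.tsv"),
                truth = file.path(outdir, "truth.json"))
  Biostrings::writeXStringSet(g$genome, paths$genome)
  .write_bed6 <- function(dt, path, name_col = "feature_id") {
    fwrite(dt[, .(chrom, start = start - 1L, end,
                  name = get(name_col), score = 0L, strand)],
           path, sep = "\t", col.names = FALSE, quote = FALSE)
  }
  .write_bed6(g$genes, paths$genes)
  .write_bed6(copy(g$tes)[, feature_id := paste(feature_id, te_class,
                                                sep = "|")], paths$tes)
  write_cytosine_report(sites, paths$cytosine_report)
  fwrite(expr, paths$expression, sep = "\t", quote = FALSE)
  fwrite(sirna[, .(chrom, start = start - 1L, end,
                   name = sprintf("sirna%04d", .I), score = abundance,
                   strand = "+")],
         paths$sirna, sep = "\t", col.names = FALSE, quote = FALSE)
  fwrite(truth$sites, paths$truth_sites, sep = "\t", quote = FALSE)
  jsonlite::write_json(list(
    config = unclass(cfg),
    spikes = truth$spikes,
    truth_sites_file = basename(paths$truth_sites)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  for (st in cfg$stages) {
    paths[[paste0("counts_", st)]] <- file.path(outdir,
                                                paste0("counts_", st, ".tsv"))
    write_count_table(counts[[st]], paths[[paste0("counts_", st)]])
  }
  sams <- NULL
  if (reads) {
    sams <- lapply(cfg$stages, function(st)
      simulate_reads(truth, g$genome, st,
                     file.path(outdir, paste0("reads_", st, ".sam"))))
    names(sams) <- cfg$stages
    for (st in cfg$stages)
      paths[[paste0("reads_", st)]] <- sams[[st]]$sam
  }
  list(config = cfg, genome = g$genome, genes = g$genes, tes = g$tes,
       sites = sites, expression = expr, truth = truth, counts = counts,
       sirna = sirna, reads = sams, paths = paths)
}

utils::globalVariables(c("frag_id", "r1s", "r2s", "bs", "site_id", "lv",
                         "mate", "row", "in_spike", "mu", "kind", "len",
                         "seq", "read_id"))
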
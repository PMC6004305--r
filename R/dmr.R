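#' Pearson chi-square test on 2x2 contingency tables
#'
#' Closed-form Pearson statistic without continuity correction,
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with the upper-tail p-value at
#' one degree of freedom. A zero margin makes the table degenerate: the
#' statistic is 0 and p = 1, flagged.
#'
#' @param a,b,c,d Cell count vectors (recycled): rows are samples, columns
#'   methylated/unmethylated.
#' @return data.table with `chi2`, `p`, `degenerate`.
#' @examples
#' pearson_chi2(10, 0, 0, 10)  # chi2 = 20
#' @export
pearson_chi2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- as.numeric(rep_len(a, n)); b <- as.numeric(rep_len(b, n))
  c <- as.numeric(rep_len(c, n)); d <- as.numeric(rep_len(d, n))
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  N <- a + b + c + d
  m1 <- a + b; m2 <- c + d; m3 <- a + c; m4 <- b + d
  degenerate <- m1 == 0 | m2 == 0 | m3 == 0 | m4 == 0
  stat <- rep(0, n)
  ok <- !degenerate
  stat[ok] <- N[ok] * (a[ok] * d[ok] - b[ok] * c[ok])^2 /
    (m1[ok] * m2[ok] * m3[ok] * m4[ok])
  p <- rep(1, n)
  p[ok] <- pchisq(stat[ok], df = 1, lower.tail = FALSE)
  data.table(chi2 = stat, p = p, degenerate = degenerate)
}

#' Chain methylated sites into candidate DMR intervals
#'
#' Builds maximal chains of methylated sites (the union over the two samples)
#' in which every adjacent gap is < `max_gap` bp. The chain span runs from its
#' first to its last site, 1-based inclusive. Chains whose span falls below
#' `min_len` are discarded, as are chains with fewer than `min_sites`
#' methylated sites in both samples. Chains longer than `max_len` are flagged
#' `overlong = TRUE` for downstream refinement (see [call_dmrs()]) rather than
#' silently kept.
#'
#' @param meth_sites data.table of union methylated sites of one context:
#'   `chrom`, `pos`, and logical `meth_A`, `meth_B` (site methylated in each
#'   sample).
#' @param max_gap Adjacent-site distance bound, exclusive (default 200).
#' @param min_len,max_len Span bounds in bp, inclusive (defaults 40, 10000).
#' @param min_sites Minimum methylated sites in at least one sample (default 5).
#' @return data.table: `chrom`, `start`, `end` (1-based inclusive), `span`,
#'   `n_sites_union`, `n_sites_A`, `n_sites_B`, `overlong`.
#' @export
build_candidate_regions <- function(meth_sites, max_gap = 200, min_len = 40,
                                    max_len = 10000, min_sites = 5) {
  ms <- as.data.table(meth_sites)
  if (nrow(ms) == 0L)
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      span = integer(), n_sites_union = integer(),
                      n_sites_A = integer(), n_sites_B = integer(),
                      overlong = logical()))
  if (!all(c("meth_A", "meth_B") %in% names(ms)))
    stop("meth_sites needs logical columns meth_A and meth_B")
  setorder(ms, chrom, pos)
  ms[, chain := cumsum(c(TRUE, diff(pos) >= max_gap)), by = chrom]
  cand <- ms[, .(start = min(pos), end = max(pos), n_sites_union = .N,
                 n_sites_A = sum(meth_A), n_sites_B = sum(meth_B)),
             by = .(chrom, chain)]
  cand[, span := end - start + 1L]
  cand <- cand[span >= min_len & pmax(n_sites_A, n_sites_B) >= min_sites]
  cand[, overlong := span > max_len]
  cand[, chain := NULL]
  setorder(cand, chrom, start)
  cand[]
}

# Localise the differential segment(s) of each candidate chain: among the
# chain's union methylated sites covered in both samples, seed sites whose
# per-site Pearson chi-square between the samples has p <= seed_alpha, then
# re-chain the seeds under the same <max_gap rule. A chain wholly composed of
# differential sites yields itself; a chain mixing background with a localised
# effect yields the effect's span, which pooled chain-level testing would
# otherwise dilute below the fold-change criterion. Two-level hysteresis:
# lenient seeds (seed_alpha) do the chaining so a true segment does not
# fragment, but each segment is trimmed to its outermost strict seed
# (seed_alpha_strict) so that isolated boundary noise cannot stretch a
# segment into unchanged background and dilute its pooled fold change.
.differential_segments <- function(sites, cand, max_gap, min_len, max_len,
                                   seed_alpha = 0.05,
                                   seed_alpha_strict = 0.01) {
  if (nrow(cand) == 0L) return(cand[, .(chrom, start, end, span = end - start + 1L)][0L])
  cand2 <- copy(cand)[, cand_id := .I]
  setkey(cand2, chrom, start, end)
  pts <- sites[covered_A & covered_B & (is_methylated_A | is_methylated_B),
               .(chrom, start = pos, end = pos, pos,
                 n_meth_A, n_unmeth_A, n_meth_B, n_unmeth_B)]
  if (nrow(pts) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), span = integer()))
  st <- pearson_chi2(pts$n_meth_A, pts$n_unmeth_A, pts$n_meth_B, pts$n_unmeth_B)
  pts[, seed_p := st$p]
  seeds <- pts[st$p <= seed_alpha & !st$degenerate]
  if (nrow(seeds) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), span = integer()))
  ov <- foverlaps(seeds, cand2[, .(chrom, start, end, cand_id)],
                  by.x = c("chrom", "start", "end"), nomatch = NULL)
  if (nrow(ov) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), span = integer()))
  setorder(ov, cand_id, pos)
  ov[, seg := cumsum(c(TRUE, diff(pos) >= max_gap)), by = cand_id]
  segs <- ov[, {
    strict <- pos[seed_p <= seed_alpha_strict]
    if (length(strict) == 0L)
      list(chrom = character(0), start = integer(0), end = integer(0))
    else
      list(chrom = chrom[1L], start = min(strict), end = max(strict))
  }, by = .(cand_id, seg)]
  segs[, span := end - start + 1L]
  segs <- segs[span >= min_len & span <= max_len]
  segs[, c("cand_id", "seg") := NULL]
  setorder(segs, chrom, start)
  segs[]
}

#' Pool counts over a candidate region
#'
#' Sums methylated/unmethylated read counts over all covered context sites of
#' each sample inside each candidate interval, derives pooled levels and the
#' mean per-site read depth used by the coverage criterion.
#'
#' @param candidates data.table with `chrom`, `start`, `end`.
#' @param counts_a,counts_b Count tables of one context for the two samples.
#' @return `candidates` with `meth_A`, `unmeth_A`, `meth_B`, `unmeth_B`,
#'   `level_A`, `level_B`, `depth_A`, `depth_B` (mean per-site depth; `NA`
#'   when a sample has no covered site in the region).
#' @export
region_counts <- function(candidates, counts_a, counts_b) {
  cand <- copy(as.data.table(candidates))
  if (nrow(cand) == 0L) {
    cand[, `:=`(meth_A = integer(), unmeth_A = integer(), meth_B = integer(),
                unmeth_B = integer(), level_A = numeric(), level_B = numeric(),
                depth_A = numeric(), depth_B = numeric())]
    return(cand)
  }
  cand[, dmr_id := .I]
  pool <- function(counts, suffix) {
    cc <- as.data.table(counts)[covered == TRUE,
                                .(chrom, start = pos, end = pos, n_meth, n_unmeth)]
    setkey(cc, chrom, start, end)
    ov <- foverlaps(cand[, .(chrom, start, end, dmr_id)], cc,
                    by.x = c("chrom", "start", "end"), nomatch = NULL)
    agg <- ov[, .(meth = sum(n_meth), unmeth = sum(n_unmeth), nsite = .N),
              by = dmr_id]
    out <- agg[cand[, .(dmr_id)], on = "dmr_id"]
    out[is.na(meth), `:=`(meth = 0L, unmeth = 0L, nsite = 0L)]
    out[, level := ifelse(meth + unmeth > 0, meth / (meth + unmeth), NA_real_)]
    out[, depth := ifelse(nsite > 0, (meth + unmeth) / nsite, NA_real_)]
    setnames(out, c("meth", "unmeth", "level", "depth"),
             paste0(c("meth_", "unmeth_", "level_", "depth_"), suffix))
    out[, nsite := NULL]
    out
  }
  a <- pool(counts_a, "A")
  b <- pool(counts_b, "B")
  cand <- merge(cand, a, by = "dmr_id")
  cand <- merge(cand, b, by = "dmr_id")
  cand[, dmr_id := NULL]
  cand[]
}

#' Fold change between two pooled methylation levels
#'
#' Ratio of the higher to the lower pooled level. A zero (or undefined) lower
#' level is floored at `1 / (pooled reads of the low sample + 1)` so the ratio
#' stays finite while still demanding strong evidence from the high side.
#'
#' @param level_a,level_b Pooled levels.
#' @param reads_a,reads_b Pooled read totals (`meth + unmeth`) per sample.
#' @return Numeric fold-change vector (>= 1).
#' @export
level_fold_change <- function(level_a, level_b, reads_a, reads_b) {
  hi <- pmax(level_a, level_b)
  lo <- pmin(level_a, level_b)
  lo_reads <- ifelse(level_a <= level_b, reads_a, reads_b)
  floor_lo <- 1 / (lo_reads + 1)
  hi / pmax(lo, floor_lo)
}

#' Hyper/hypo direction of a comparison
#'
#' Direction of the second-listed sample relative to the first: `"hyper"` iff
#' `level_b > level_a`, else `"hypo"`. In a comparison named `"X:Y"`
#' (test:reference), the reference Y is sample A and the test X is sample B,
#' so `"hyper"` means hypermethylated in the test sample.
#'
#' @param level_a,level_b Pooled region levels of the first- and second-listed
#'   samples.
#' @return Character vector `"hyper"`/`"hypo"`.
#' @export
classify_hyper_hypo <- function(level_a, level_b) {
  ifelse(level_b > level_a, "hyper", "hypo")
}

#' Call differentially methylated regions between two samples
#'
#' Implements the five-criterion DMR definition for one sequence context:
#' (a) at least `min_sites` methylated cytosines in at least one sample;
#' (b) mean per-site read depth strictly greater than `min_depth` in both
#' samples; (c) adjacent methylated sites (union of the two samples) less
#' than `max_gap` bp apart; (d) region span between `min_len` and `max_len`
#' bp; (e) methylation-level difference of at least `min_fold` (ratio of
#' pooled levels; `effect = "absdiff"` switches to an absolute difference of
#' at least `min_absdiff`) with a Pearson chi-square p <= `alpha` on the
#' pooled 2x2 counts.
#'
#' Candidate regions are maximal <`max_gap`-gap chains of union methylated
#' sites. Within each chain the tested region is its differential segment:
#' sites whose per-site chi-square between the samples has p <= `seed_alpha`
#' seed sub-chains under the same gap rule, and each seed span (clipped to
#' the length bounds) is then taken through criteria (a)-(e) unchanged. A
#' chain that is differential throughout yields itself; without this
#' localisation, a methylation difference confined to part of a chain — or
#' any effect inside the chromosome-long chains that a densely methylated
#' genome produces — would be pooled against unchanged background and lost
#' below the fold-change criterion.
#'
#' @param counts_a,counts_b Count tables (reference and test sample). Calls
#'   are added with defaults if `is_methylated` is absent.
#' @param context Context to call ("CG", "CHG" or "CHH").
#' @param min_sites,min_depth,max_gap,min_len,max_len,min_fold,alpha
#'   Criterion thresholds (defaults 5, 10, 200, 40, 10000, 2, 0.05).
#' @param seed_alpha Per-site chi-square level used only to localise
#'   differential segments within candidate chains (default 0.05, fixed
#'   independently of `alpha` so that tightening `alpha` can only remove
#'   calls).
#' @param seed_alpha_strict Stricter per-site level to which each segment is
#'   trimmed at its boundaries (default 0.01); lenient seeds chain, strict
#'   seeds delimit.
#' @param effect `"fold"` (default) or `"absdiff"`.
#' @param min_absdiff Absolute-difference threshold when `effect = "absdiff"`
#'   (default 0.2).
#' @param correct `"none"` (default, raw p <= alpha) or `"BH"`.
#' @param merge_cg_strands Merge the two symmetric strands of a CG
#'   dinucleotide into one site (counts summed) before calling; default FALSE
#'   keeps strands separate.
#' @return data.table of DMRs sorted by coordinate: `chrom`, `start`, `end`
#'   (1-based inclusive), `span`, `context`, `n_sites_A`, `n_sites_B`,
#'   pooled `meth_/unmeth_` counts, `level_A`, `level_B`, `depth_A`,
#'   `depth_B`, `fold_change`, `chi2`, `p`, `direction`. The pre-filter
#'   candidate set is attached as `attr(, "candidates")`.
#' @export
call_dmrs <- function(counts_a, counts_b, context,
                      min_sites = 5, min_depth = 10, max_gap = 200,
                      min_len = 40, max_len = 10000, min_fold = 2,
                      alpha = 0.05, seed_alpha = 0.05,
                      seed_alpha_strict = 0.01,
                      effect = c("fold", "absdiff"),
                      min_absdiff = 0.2, correct = c("none", "BH"),
                      merge_cg_strands = FALSE) {
  effect <- match.arg(effect)
  correct <- match.arg(correct)
  ctx <- context
  prep <- function(x) {
    x <- as.data.table(x)
    if (!"is_methylated" %in% names(x)) x <- add_meth_calls(x)
    x <- x[x$context == ctx & !is.na(x$context)]
    if (nrow(x) == 0L) stop("no sites of context ", ctx, " in count table")
    x[, .(chrom, pos, strand, n_meth, n_unmeth,
          covered = (n_meth + n_unmeth) > 0L, is_methylated)]
  }
  a <- prep(counts_a)
  b <- prep(counts_b)
  if (merge_cg_strands && ctx == "CG") {
    merge1 <- function(x) {
      # "-" strand CG site sits 1 bp right of its "+" partner
      x[, pos := ifelse(strand == "-", pos - 1L, pos)]
      x[, .(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth),
            covered = any(covered), is_methylated = any(is_methylated)),
        by = .(chrom, pos)][, strand := "+"][]
    }
    a <- merge1(a)
    b <- merge1(b)
  }
  sites <- merge(a, b, by = c("chrom", "pos", "strand"),
                 suffixes = c("_A", "_B"))
  if (nrow(sites) == 0L)
    stop("count tables share no ", ctx, " sites; were they built from the ",
         "same cytosine report?")

  empty <- data.table(
    chrom = character(), start = integer(), end = integer(), span = integer(),
    context = character(), n_sites_A = integer(), n_sites_B = integer(),
    meth_A = integer(), unmeth_A = integer(), level_A = numeric(),
    depth_A = numeric(), meth_B = integer(), unmeth_B = integer(),
    level_B = numeric(), depth_B = numeric(), fold_change = numeric(),
    chi2 = numeric(), p = numeric(), direction = character())

  ms <- sites[is_methylated_A | is_methylated_B,
              .(chrom, pos, meth_A = is_methylated_A, meth_B = is_methylated_B)]
  chains <- build_candidate_regions(ms, max_gap = max_gap, min_len = min_len,
                                    max_len = max_len, min_sites = min_sites)
  attr_cand <- copy(chains)

  cand <- .differential_segments(sites, chains, max_gap = max_gap,
                                 min_len = min_len, max_len = max_len,
                                 seed_alpha = seed_alpha,
                                 seed_alpha_strict = seed_alpha_strict)
  if (nrow(cand)) {
    # recount methylated sites of each sample within every segment
    cand[, dmr_id := .I]
    mspt <- ms[, .(chrom, start = pos, end = pos, meth_A, meth_B)]
    setkey(mspt, chrom, start, end)
    ovm <- foverlaps(cand[, .(chrom, start, end, dmr_id)], mspt,
                     by.x = c("chrom", "start", "end"), nomatch = NULL)
    nsf <- ovm[, .(n_sites_A = sum(meth_A), n_sites_B = sum(meth_B)),
               by = dmr_id]
    cand <- merge(cand, nsf, by = "dmr_id", all.x = TRUE)
    cand[is.na(n_sites_A), `:=`(n_sites_A = 0L, n_sites_B = 0L)]
    cand <- cand[pmax(n_sites_A, n_sites_B) >= min_sites]
    cand[, dmr_id := NULL]
  }
  if (nrow(cand) == 0L) {
    out <- empty
    setattr(out, "candidates", attr_cand)
    return(out)
  }

  cand <- region_counts(cand, a, b)
  cand <- cand[!is.na(depth_A) & !is.na(depth_B) &
                 depth_A > min_depth & depth_B > min_depth]
  if (nrow(cand) == 0L) {
    out <- empty
    setattr(out, "candidates", attr_cand)
    return(out)
  }
  cand[, fold_change := level_fold_change(level_A, level_B,
                                          meth_A + unmeth_A, meth_B + unmeth_B)]
  st <- pearson_chi2(cand$meth_A, cand$unmeth_A, cand$meth_B, cand$unmeth_B)
  cand[, `:=`(chi2 = st$chi2, p = st$p)]
  if (correct == "BH") cand[, p := p.adjust(p, method = "BH")]
  keep <- if (effect == "fold") cand$fold_change >= min_fold else
    abs(cand$level_A - cand$level_B) >= min_absdiff
  out <- cand[keep & cand$p <= alpha]
  out[, `:=`(context = ctx,
             direction = classify_hyper_hypo(level_A, level_B))]
  setcolorder(out, c("chrom", "start", "end", "span", "context",
                     "n_sites_A", "n_sites_B"))
  setorder(out, chrom, start)
  setattr(out, "candidates", attr_cand)
  out[]
}

#' Associate DMRs with gene/TE zones
#'
#' Assigns every DMR to each (feature, zone) it overlaps by at least 1 bp,
#' where the zones of a stranded feature are its body, the 2-kb region
#' upstream of its 5' end (`up2k`) and the 2-kb region downstream of its 3'
#' end (`down2k`). For the per-DMR summary label, zone priority is
#' body > up2k > down2k.
#'
#' @param dmrs DMR table from [call_dmrs()] (needs `chrom`, `start`, `end`;
#'   `context` carried through when present).
#' @param features Stranded feature table (`chrom`, `start`, `end`, `strand`,
#'   optional `feature_id`).
#' @param flank Flank width (default 2000).
#' @return List with `associations` (one row per DMR x feature x zone overlap:
#'   `dmr_id`, `feature_id`, `zone`) and `dmrs` (input with `association`
#'   zone label and `assoc_feature` by priority; `"none"` when no overlap).
#' @export
associate_dmrs <- function(dmrs, features, flank = 2000) {
  dmrs <- copy(as.data.table(dmrs))
  features <- as.data.table(features)
  if (!"feature_id" %in% names(features))
    features <- copy(features)[, feature_id := paste0("feat", .I)]
  dmrs[, dmr_id := .I]
  zones <- rbindlist(list(
    features[, .(chrom, start, end, feature_id, zone = "body")],
    features[, .(chrom,
                 start = ifelse(strand == "+", pmax(1L, start - as.integer(flank)),
                                end + 1L),
                 end = ifelse(strand == "+", start - 1L, end + as.integer(flank)),
                 feature_id, zone = "up2k")],
    features[, .(chrom,
                 start = ifelse(strand == "+", end + 1L,
                                pmax(1L, start - as.integer(flank))),
                 end = ifelse(strand == "+", end + as.integer(flank), start - 1L),
                 feature_id, zone = "down2k")]
  ))
  zones <- zones[end >= start]
  if (nrow(dmrs) == 0L || nrow(zones) == 0L) {
    dmrs[, `:=`(association = character(0), assoc_feature = character(0))]
    return(list(associations = data.table(dmr_id = integer(),
                                          feature_id = character(),
                                          zone = character(),
                                          context = character()),
                dmrs = dmrs))
  }
  setkey(zones, chrom, start, end)
  ov <- foverlaps(dmrs[, .(chrom, start, end, dmr_id)], zones,
                  by.x = c("chrom", "start", "end"), nomatch = NULL)
  assoc <- ov[, .(dmr_id, feature_id, zone)]
  if ("context" %in% names(dmrs))
    assoc[, context := dmrs$context[dmr_id]]
  prio <- c(body = 1L, up2k = 2L, down2k = 3L)
  best <- assoc[order(dmr_id, prio[zone])][, .SD[1L], by = dmr_id]
  dmrs[, association := "none"]
  dmrs[, assoc_feature := NA_character_]
  dmrs[best$dmr_id, `:=`(association = best$zone, assoc_feature = best$feature_id)]
  list(associations = assoc[], dmrs = dmrs[])
}

#' Context-by-zone DMR count summary
#'
#' Counts DMRs per context and zone using the per-DMR priority label
#' (body > up2k > down2k), mirroring the usual "up2k / gene body / down2k"
#' partitioning of DMR tallies.
#'
#' @param assoc Result of [associate_dmrs()].
#' @return data.table: `context`, `zone` (up2k/body/down2k/none), `n_dmrs`.
#' @export
dmr_zone_summary <- function(assoc) {
  d <- assoc$dmrs
  if (!"context" %in% names(d)) d[, context := NA_character_]
  grid <- CJ(context = unique(d$context),
             zone = c("up2k", "body", "down2k", "none"))
  tab <- d[, .(n_dmrs = .N), by = .(context, zone = association)]
  out <- merge(grid, tab, by = c("context", "zone"), all.x = TRUE)
  out[is.na(n_dmrs), n_dmrs := 0L]
  out[]
}

#' Independent five-criterion audit of emitted DMRs
#'
#' Post-hoc checker, deliberately written against the raw count tables rather
#' than the caller's internals: for every emitted DMR it re-verifies
#' (a) methylated-site count, (b) mean depth, (c) adjacent methylated-site
#' gaps, (d) span bounds and (e) fold change with a [stats::chisq.test()]
#' p-value (no continuity correction).
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param counts_a,counts_b The count tables the DMRs were called from.
#' @param min_sites,min_depth,max_gap,min_len,max_len,min_fold,alpha The
#'   thresholds used for calling.
#' @return data.table with one row per DMR and logical columns `ok_a`..`ok_e`
#'   plus `ok_all`.
#' @export
audit_dmrs <- function(dmrs, counts_a, counts_b,
                       min_sites = 5, min_depth = 10, max_gap = 200,
                       min_len = 40, max_len = 10000, min_fold = 2,
                       alpha = 0.05) {
  dmrs <- as.data.table(dmrs)
  ca <- as.data.table(counts_a)
  cb <- as.data.table(counts_b)
  if (!"is_methylated" %in% names(ca)) ca <- add_meth_calls(ca)
  if (!"is_methylated" %in% names(cb)) cb <- add_meth_calls(cb)
  res <- lapply(seq_len(nrow(dmrs)), function(i) {
    d <- dmrs[i]
    sa <- ca[chrom == d$chrom & pos >= d$start & pos <= d$end &
               context == d$context]
    sb <- cb[chrom == d$chrom & pos >= d$start & pos <= d$end &
               context == d$context]
    na <- sum(sa$is_methylated)
    nb <- sum(sb$is_methylated)
    ok_a <- max(na, nb) >= min_sites
    da <- sum(sa$n_meth + sa$n_unmeth) / sum((sa$n_meth + sa$n_unmeth) > 0)
    db <- sum(sb$n_meth + sb$n_unmeth) / sum((sb$n_meth + sb$n_unmeth) > 0)
    ok_b <- is.finite(da) && is.finite(db) && da > min_depth && db > min_depth
    union_pos <- sort(unique(c(sa$pos[sa$is_methylated], sb$pos[sb$is_methylated])))
    ok_c <- length(union_pos) <= 1L || all(diff(union_pos) < max_gap)
    spanlen <- d$end - d$start + 1L
    ok_d <- spanlen >= min_len && spanlen <= max_len
    mA <- sum(sa$n_meth); uA <- sum(sa$n_unmeth)
    mB <- sum(sb$n_meth); uB <- sum(sb$n_unmeth)
    lA <- mA / (mA + uA); lB <- mB / (mB + uB)
    fc <- level_fold_change(lA, lB, mA + uA, mB + uB)
    pv <- tryCatch(
      stats::chisq.test(matrix(c(mA, uA, mB, uB), nrow = 2, byrow = TRUE),
                        correct = FALSE)$p.value,
      warning = function(w)
        suppressWarnings(stats::chisq.test(
          matrix(c(mA, uA, mB, uB), nrow = 2, byrow = TRUE),
          correct = FALSE)$p.value),
      error = function(e) 1)
    ok_e <- fc >= min_fold && !is.na(pv) && pv <= alpha
    data.table(dmr_id = i, ok_a = ok_a, ok_b = ok_b, ok_c = ok_c,
               ok_d = ok_d, ok_e = ok_e)
  })
  out <- rbindlist(res)
  if (nrow(out)) out[, ok_all := ok_a & ok_b & ok_c & ok_d & ok_e]
  out[]
}

#' Write DMRs as a BED-like TSV
#'
#' Tab-separated report with 1-based inclusive coordinates and all call
#' statistics; deterministic column order and formatting.
#'
#' @param dmrs DMR table (optionally with association columns).
#' @param path Output path.
#' @export
write_dmr_table <- function(dmrs, path) {
  fwrite(as.data.table(dmrs), path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

utils::globalVariables(c("is_methylated_A", "is_methylated_B", "covered_A",
                         "covered_B", "meth", "unmeth", "nsite", "depth",
                         "seed_p", "seg", "cand_id",
                         "ok_a", "ok_b", "ok_c", "ok_d", "ok_e", "ok_all",
                         "n_sites_union", "n_dmrs"))
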
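#' Genome-wide methylated-site fractions per context
#'
#' The headline methylome summary: per context, the fraction of covered
#' cytosine sites called methylated (mCG/CG, mCHG/CHG, mCHH/CHH), plus an
#' overall mC/C row. Both denominators are reported: covered sites
#' (`frac_covered`) and all enumerable sites (`frac_all`).
#'
#' @param counts Count table with `is_methylated` (default calls added if
#'   absent).
#' @return data.table with one row per context plus `"all"`: `context`,
#'   `n_sites`, `n_covered`, `n_methylated`, `frac_covered`, `frac_all`.
#'   Fractions are `NA` when a context has no covered site.
#' @export
global_fractions <- function(counts) {
  counts <- as.data.table(counts)
  if (!"is_methylated" %in% names(counts)) counts <- add_meth_calls(counts)
  cc <- counts[!is.na(context)]
  per <- cc[, .(n_sites = .N, n_covered = sum(covered),
                n_methylated = sum(is_methylated)), by = context]
  tot <- cc[, .(context = "all", n_sites = .N, n_covered = sum(covered),
                n_methylated = sum(is_methylated))]
  out <- rbind(per, tot)
  out[, frac_covered := ifelse(n_covered > 0, n_methylated / n_covered, NA_real_)]
  out[, frac_all := n_methylated / n_sites]
  setorder(out, context)
  out[]
}

#' Methylation-level histogram of methylated sites
#'
#' Distribution of site methylation levels over methylated sites of one
#' context, in ten right-closed bins of width 0.1 over (0, 1]. Level 0 cannot
#' occur (a methylated site has `n_meth >= 1`).
#'
#' @param counts Count table with calls.
#' @param context One of "CG", "CHG", "CHH".
#' @return List with `context`, `bin_edges` (length 11) and `proportions`
#'   (length 10, sums to 1 when any methylated site exists, otherwise all NA).
#' @export
level_histogram <- function(counts, context) {
  ctx <- context
  counts <- as.data.table(counts)
  if (!"is_methylated" %in% names(counts)) counts <- add_meth_calls(counts)
  lv <- counts[context == ctx & is_methylated == TRUE, level]
  edges <- seq(0, 1, by = 0.1)
  if (length(lv) == 0L)
    return(list(context = ctx, bin_edges = edges,
                proportions = rep(NA_real_, 10L)))
  bins <- findInterval(lv, edges, left.open = TRUE, rightmost.closed = FALSE)
  bins[bins > 10L] <- 10L  # guard exact 1.0 fp wobble
  props <- tabulate(bins, nbins = 10L) / length(lv)
  list(context = ctx, bin_edges = edges, proportions = props)
}

#' 9-bp neighbourhood base composition of C vs mC populations
#'
#' Per sequence context, compares the base composition of the 9-bp reference
#' window (cytosine at position 5, read 5'->3' on the cytosine's strand)
#' between all covered cytosines (C population) and the methylated subset
#' (mC population).
#'
#' @param counts Count table carrying the `neighborhood` column (join the
#'   cytosine report first if needed) and calls.
#' @param context Context to analyse.
#' @return List with two 4 x 9 frequency matrices `C` and `mC` (rows A, C, G,
#'   T; columns positions -4..+4); each column sums to 1 over non-N bases.
#' @export
neighborhood_composition <- function(counts, context) {
  ctx <- context
  counts <- as.data.table(counts)
  if (!"neighborhood" %in% names(counts))
    stop("counts must carry the 'neighborhood' column from the cytosine report")
  if (!"is_methylated" %in% names(counts)) counts <- add_meth_calls(counts)
  comp <- function(nb) {
    if (length(nb) == 0L)
      return(matrix(NA_real_, 4, 9, dimnames = list(c("A","C","G","T"), NULL)))
    m <- matrix(unlist(strsplit(nb, "", fixed = TRUE), use.names = FALSE),
                ncol = 9L, byrow = TRUE)
    freq <- sapply(seq_len(9L), function(j) {
      b <- m[, j]
      b <- b[b != "N"]
      if (!length(b)) return(rep(NA_real_, 4L))
      tabulate(factor(b, levels = c("A","C","G","T")), nbins = 4L) / length(b)
    })
    rownames(freq) <- c("A", "C", "G", "T")
    freq
  }
  pop_c <- counts[context == ctx & covered == TRUE]
  pop_mc <- pop_c[is_methylated == TRUE]
  list(context = ctx, C = comp(pop_c$neighborhood), mC = comp(pop_mc$neighborhood))
}

# ---------------------------------------------------------------------------
# Metagene geometry (shared with siRNA positional profiles)

#' Assign positions to up2k / body / down2k metagene bins
#'
#' Maps genomic point positions onto the metagene coordinate system of a
#' stranded feature set: `flank/bin` fixed-width upstream bins, `body_bins`
#' proportional body bins, and `flank/bin` downstream bins, all oriented
#' 5'->3' relative to the feature (upstream bin `flank/bin` is adjacent to
#' the start of the feature; downstream bin 1 is adjacent to its end).
#'
#' @param positions data.table with `chrom`, `pos` (1-based points).
#' @param features data.table with `chrom`, `start`, `end` (1-based
#'   inclusive), `strand`, and an id column `feature_id` (created from row
#'   number if absent).
#' @param flank Flank width in bp (default 2000); must be divisible by `bin`.
#' @param bin Flank bin width in bp (default 100).
#' @param body_bins Number of proportional body bins (default 20).
#' @return data.table of (position, feature) incidences: `xid` (row in
#'   `positions`), `feature_id`, `zone` ("up2k"/"body"/"down2k"), `bin`
#'   (1-based within zone).
#' @export
assign_zone_bins <- function(positions, features, flank = 2000, bin = 100,
                             body_bins = 20) {
  if (flank %% bin != 0) stop("flank must be divisible by bin")
  positions <- as.data.table(positions)
  features <- as.data.table(features)
  if (!"feature_id" %in% names(features))
    features[, feature_id := paste0("feat", .I)]
  if (!all(features$strand %in% c("+", "-")))
    stop("features must be stranded (+/-)")
  nb_flank <- as.integer(flank / bin)

  win <- copy(features)
  win[, `:=`(wstart = pmax(1L, start - as.integer(flank)),
             wend = end + as.integer(flank))]
  p <- GenomicRanges::GRanges(positions$chrom,
                              IRanges::IRanges(positions$pos, positions$pos))
  f <- GenomicRanges::GRanges(win$chrom, IRanges::IRanges(win$wstart, win$wend))
  h <- GenomicRanges::findOverlaps(p, f, ignore.strand = TRUE)
  if (length(h) == 0L)
    return(data.table(xid = integer(), feature_id = character(),
                      zone = character(), bin = integer()))
  inc <- data.table(xid = S4Vectors::queryHits(h), yid = S4Vectors::subjectHits(h))
  inc[, `:=`(pos = positions$pos[xid],
             fs = features$start[yid], fe = features$end[yid],
             fstrand = features$strand[yid],
             feature_id = features$feature_id[yid])]
  inc[, width := fe - fs + 1L]

  up <- inc$pos < inc$fs
  dn <- inc$pos > inc$fe
  body <- !up & !dn
  zone <- character(nrow(inc))
  bidx <- integer(nrow(inc))

  plus <- inc$fstrand == "+"
  # upstream of coordinate-start
  z_up_plus <- up & plus          # genomic-left flank, 5' flank
  z_up_minus <- dn & !plus        # genomic-right flank is 5' flank on "-"
  z_dn_plus <- dn & plus
  z_dn_minus <- up & !plus

  zone[z_up_plus | z_up_minus] <- "up2k"
  zone[z_dn_plus | z_dn_minus] <- "down2k"
  zone[body] <- "body"

  # distance from the 5' edge of each flank window, 0-based
  w <- integer(nrow(inc))
  w[z_up_plus] <- inc$pos[z_up_plus] - (inc$fs[z_up_plus] - as.integer(flank))
  w[z_up_minus] <- (inc$fe[z_up_minus] + as.integer(flank)) - inc$pos[z_up_minus]
  w[z_dn_plus] <- inc$pos[z_dn_plus] - inc$fe[z_dn_plus] - 1L
  w[z_dn_minus] <- inc$fs[z_dn_minus] - 1L - inc$pos[z_dn_minus]
  fl <- z_up_plus | z_up_minus | z_dn_plus | z_dn_minus
  bidx[fl] <- w[fl] %/% as.integer(bin) + 1L

  # body: proportional position in [0,1) from the coordinate-left edge; the
  # "-" strand takes the exact mirror bin so strand flips reverse bins exactly
  if (any(body)) {
    relv <- (inc$pos[body] - inc$fs[body]) / inc$width[body]
    bfwd <- pmin(as.integer(floor(relv * body_bins)) + 1L, body_bins)
    bidx[body] <- ifelse(plus[body], bfwd, body_bins + 1L - bfwd)
  }
  out <- data.table(xid = inc$xid, feature_id = inc$feature_id,
                    zone = zone, bin = bidx)
  # positions upstream of chromosome start were clipped out by wstart pmax,
  # but a pos can still fall in a truncated flank; bins are valid by geometry
  out[zone != "body" & bin >= 1L & bin <= nb_flank | zone == "body"]
}

#' Metagene methylation profile
#'
#' Average methylation level in metagene bins (20 x 100-bp upstream, 20
#' proportional body, 20 x 100-bp downstream by default) over a stranded
#' feature set, pooling covered sites across features (site-weighted). Bins
#' with no covered site carry `NA` means and `n_sites = 0` rather than zeros.
#'
#' @param counts Count table (one sample).
#' @param features Stranded feature table (`chrom`, `start`, `end`, `strand`,
#'   optional `feature_id`).
#' @param context Optional single context to restrict to; default profiles
#'   each context separately.
#' @param flank,bin,body_bins Geometry; see [assign_zone_bins()].
#' @return data.table: `context`, `zone`, `bin`, `meta_bin` (1..60 plotting
#'   index), `mean_level` (covered-site denominator), `mean_level_allsites`
#'   (level summed over covered sites / all sites in bin), `n_sites`
#'   (covered), `n_sites_total`.
#' @export
metagene_profile <- function(counts, features, context = NULL, flank = 2000,
                             bin = 100, body_bins = 20) {
  counts <- as.data.table(counts)
  if (!is.null(context)) {
    ctx_sel <- context
    counts <- counts[counts$context %in% ctx_sel]
  } else {
    counts <- counts[!is.na(counts$context)]
  }
  ab <- assign_zone_bins(counts[, .(chrom, pos)], features, flank, bin, body_bins)
  nb_flank <- as.integer(flank / bin)
  grid <- CJ(context = unique(counts$context),
             zone = c("up2k", "body", "down2k"), bin = seq_len(
               max(nb_flank, body_bins)))[
    (zone %in% c("up2k", "down2k") & bin <= nb_flank) |
      (zone == "body" & bin <= body_bins)]
  if (nrow(ab)) {
    sub <- counts[ab$xid, .(context, level, covered)]
    sub[, `:=`(zone = ab$zone, bin = ab$bin)]
    agg <- sub[, .(
      mean_level = if (any(covered)) mean(level[covered]) else NA_real_,
      mean_level_allsites = if (any(covered)) sum(level[covered]) / .N else NA_real_,
      n_sites = sum(covered), n_sites_total = .N),
      by = .(context, zone, bin)]
    out <- merge(grid, agg, by = c("context", "zone", "bin"), all.x = TRUE)
  } else {
    out <- grid[, `:=`(mean_level = NA_real_, mean_level_allsites = NA_real_,
                       n_sites = 0L, n_sites_total = 0L)]
  }
  set(out, which(is.na(out$n_sites)), "n_sites", 0L)
  set(out, which(is.na(out$n_sites_total)), "n_sites_total", 0L)
  out[, meta_bin := fifelse(zone == "up2k", bin,
                    fifelse(zone == "body", nb_flank + bin,
                            nb_flank + body_bins + bin))]
  setorder(out, context, meta_bin)
  out[]
}

#' Expression classes from RPKM
#'
#' Partition of `[0, Inf)`: none (RPKM <= 1), low (1, 10], medium (10, 100),
#' high (>= 100).
#'
#' @param rpkm Numeric vector.
#' @return Factor with levels none < low < medium < high.
#' @export
expression_classes <- function(rpkm) {
  if (any(rpkm < 0, na.rm = TRUE)) stop("rpkm must be non-negative")
  lab <- ifelse(rpkm <= 1, "none",
         ifelse(rpkm <= 10, "low",
         ifelse(rpkm < 100, "medium", "high")))
  factor(lab, levels = c("none", "low", "medium", "high"))
}

#' Metagene profiles stratified by gene expression class
#'
#' Genes are partitioned by RPKM ([expression_classes()]) and profiled per
#' class with [metagene_profile()]. Genes absent from the expression table are
#' dropped with a message.
#'
#' @param counts Count table.
#' @param features Gene table with `feature_id` matching `gene_id` in
#'   `expression`.
#' @param expression data.table with `gene_id` and `rpkm`.
#' @param ... Passed to [metagene_profile()].
#' @return data.table as [metagene_profile()] plus `expr_class`.
#' @export
expression_stratified_profiles <- function(counts, features, expression, ...) {
  features <- as.data.table(features)
  expression <- as.data.table(expression)
  if (!"feature_id" %in% names(features))
    stop("features need a 'feature_id' column to match expression gene_id")
  expression[, gene_id := trimws(gene_id)]
  features[, feature_id := trimws(feature_id)]
  matched <- features[feature_id %in% expression$gene_id]
  n_drop <- nrow(features) - nrow(matched)
  if (nrow(matched) == 0L) stop("no gene id matched between features and expression")
  if (n_drop > 0L)
    message(n_drop, " gene(s) without expression record dropped")
  matched[, class_label := expression_classes(
    expression$rpkm[match(feature_id, expression$gene_id)])]
  rbindlist(lapply(levels(matched$class_label), function(cl) {
    sub <- matched[class_label == cl]
    if (nrow(sub) == 0L) return(NULL)
    pr <- metagene_profile(counts, sub, ...)
    pr[, expr_class := cl][]
  }))
}

utils::globalVariables(c("..context", "expr_class", "fs", "fe", "fstrand",
                         "wstart", "wend", "m", "u", "meta_bin",
                         "mean_level_allsites", "n_sites_total"))
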
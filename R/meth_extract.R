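#' Per-site methylation level
#'
#' Fraction of informative reads retaining C: `n_meth / (n_meth + n_unmeth)`.
#' `NA` (undefined) where the site is uncovered.
#'
#' @param n_meth,n_unmeth Non-negative integer vectors.
#' @return Numeric vector in `[0,1]`, `NA` where `n_meth + n_unmeth == 0`.
#' @export
site_level <- function(n_meth, n_unmeth) {
  if (any(n_meth < 0) || any(n_unmeth < 0))
    stop("counts must be non-negative")
  tot <- n_meth + n_unmeth
  ifelse(tot > 0, n_meth / tot, NA_real_)
}

#' Call binary methylated sites
#'
#' Default mode `"binomial"` tests, per covered site, whether `n_meth`
#' unconverted reads exceed what bisulfite conversion failure alone would
#' produce: upper-tail `P(X >= n_meth)` for
#' `X ~ Binomial(n_meth + n_unmeth, conversion_failure_rate)`. p-values are
#' BH-adjusted across sites by default (`correct = "BH"`, the usual practice
#' for genome-scale site calling; `correct = "none"` tests each site at raw
#' `alpha`). The default FDR level is 0.01: in methylomes where a large share
#' of sites is truly methylated the BH threshold is generous, and a 5% FDR
#' would contaminate the mC-site set by enough to visibly inflate the
#' smallest per-context mC fractions (CHH, a few percent); 1% keeps the
#' contamination an order of magnitude below them. Mode `"any"` calls a site
#' methylated whenever `n_meth >= 1`.
#'
#' @param n_meth,n_unmeth Integer count vectors.
#' @param conversion_failure_rate Probability an unmethylated C escapes
#'   conversion (default 0.005). Must lie in `[0, 1)`.
#' @param alpha Significance (or FDR) level, default 0.01.
#' @param mode `"binomial"` (default) or `"any"`.
#' @param correct p-value adjustment across sites: `"BH"` (default) or `"none"`.
#' @return data.table with `is_methylated` (FALSE for uncovered sites) and
#'   `p_value` (raw upper-tail probability; `NA` for uncovered sites or in
#'   mode `"any"`).
#' @export
call_methylated <- function(n_meth, n_unmeth,
                            conversion_failure_rate = 0.005,
                            alpha = 0.01,
                            mode = c("binomial", "any"),
                            correct = c("BH", "none")) {
  mode <- match.arg(mode)
  correct <- match.arg(correct)
  if (conversion_failure_rate < 0 || conversion_failure_rate >= 1)
    stop("conversion_failure_rate must be in [0, 1)")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  tot <- n_meth + n_unmeth
  covered <- tot > 0
  if (mode == "any")
    return(data.table(is_methylated = covered & n_meth >= 1,
                      p_value = NA_real_))
  pv <- rep(NA_real_, length(tot))
  pv[covered] <- pbinom(n_meth[covered] - 1L, tot[covered],
                        conversion_failure_rate, lower.tail = FALSE)
  padj <- pv
  if (correct == "BH") padj[covered] <- p.adjust(pv[covered], method = "BH")
  data.table(is_methylated = covered & n_meth >= 1 & !is.na(padj) & padj <= alpha,
             p_value = pv)
}

# ---------------------------------------------------------------------------
# Alignment parsing

.as_sorted_bam <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(path)[[1L]]
  so <- hdr$text[["@HD"]]
  if (!is.null(so) && any(grepl("^SO:", so)) &&
      !any(grepl("SO:coordinate", so))) {
    dest <- tempfile()
    path <- Rsamtools::sortBam(path, dest)
  }
  path
}

# Bisulfite strand per read: XG tag ("CT"/"GA") when present, else inferred
# from FLAG assuming a directional library (mate1/unpaired reverse -> GA).
.read_bsstrand <- function(flag, xg) {
  bs <- rep(NA_character_, length(flag))
  if (!is.null(xg)) bs <- as.character(xg)
  need <- is.na(bs)
  if (any(need)) {
    rev <- bitwAnd(flag[need], 16L) != 0L
    mate2 <- bitwAnd(flag[need], 128L) != 0L
    # mate2 of a fragment aligns opposite to mate1
    bs[need] <- ifelse(xor(rev, mate2), "GA", "CT")
  }
  bs
}

#' Extract per-site methylation counts from bisulfite alignments
#'
#' Counts, for every cytosine in `sites`, the informative read bases: at a
#' "+" site, reads from the original-top (CT) bisulfite strand contribute C as
#' methylated and T as unmethylated; at a "-" site, original-bottom (GA)
#' strand reads contribute G as methylated and A as unmethylated. Any other
#' base goes to `n_other`. The bisulfite strand of a read is taken from its
#' `XG` tag when present, else inferred from the FLAG assuming a directional
#' library. Duplicate-flagged reads and reads below `mapq_min` are skipped.
#' Where the two mates of a pair overlap a site, the mate with the higher base
#' quality at that site is counted once.
#'
#' @param alignments Path to a SAM or BAM file, coordinate-sorted against the
#'   same reference as `sites` (SAM input is converted/sorted on the fly).
#' @param sites Cytosine report ([enumerate_cytosines()]).
#' @param mapq_min Minimum mapping quality (default 10).
#' @param skip_duplicates Drop duplicate-flagged reads (default TRUE).
#' @return A count table: `sites` columns plus `n_meth`, `n_unmeth`,
#'   `n_other`, `level` (`NA` when uncovered) and `covered`.
#' @export
extract_counts <- function(alignments, sites, mapq_min = 10,
                           skip_duplicates = TRUE) {
  stopifnot(is.data.frame(sites))
  bam <- .as_sorted_bam(alignments)
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]
  refs <- names(hdr$targets)
  unmatched <- setdiff(refs, unique(sites$chrom))
  if (length(unmatched))
    stop("alignment reference name(s) not present in cytosine report: ",
         paste(unmatched, collapse = ", "))

  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isDuplicate = if (skip_duplicates) FALSE else NA)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "seq", "qual", "cigar"),
    tag = "XG", flag = flags, mapqFilter = mapq_min)
  b <- Rsamtools::scanBam(bam, param = param)[[1L]]

  n_reads <- length(b$pos)
  site_dt <- as.data.table(sites)[, .(chrom, pos, strand)]
  if (n_reads == 0L) return(.finish_counts(sites, site_dt[0L]))

  bs <- .read_bsstrand(b$flag, b$tag$XG)

  # project query sequence/quality into reference space (handles I/D/S)
  simple <- grepl("^[0-9]+M$", b$cigar)
  seq_ref <- b$seq
  qual_ref <- b$qual
  if (!all(simple)) {
    seq_ref[!simple] <- GenomicAlignments::sequenceLayer(
      b$seq[!simple], b$cigar[!simple], from = "query", to = "reference")
    qual_ref[!simple] <- GenomicAlignments::sequenceLayer(
      b$qual[!simple], b$cigar[!simple], from = "query", to = "reference")
  }
  wid <- Biostrings::width(seq_ref)
  long <- data.table(
    qname = rep(b$qname, wid),
    chrom = rep(as.character(b$rname), wid),
    bsstrand = rep(bs, wid),
    pos = sequence(wid) - 1L + rep(b$pos, wid),
    base = unlist(strsplit(as.character(seq_ref), "", fixed = TRUE),
                  use.names = FALSE),
    bsq = unlist(lapply(as.character(qual_ref), function(q)
      as.integer(charToRaw(q))), use.names = FALSE) - 33L
  )
  long <- long[base != "-"]

  # keep only bases at cytosine sites, matched to the informative bs strand
  hits <- merge(long, site_dt, by = c("chrom", "pos"))
  hits <- hits[(strand == "+" & bsstrand == "CT") |
               (strand == "-" & bsstrand == "GA")]
  # overlapping-mate dedup: one observation per fragment per site,
  # highest base quality wins
  setorder(hits, chrom, pos, strand, qname, -bsq)
  hits <- unique(hits, by = c("chrom", "pos", "strand", "qname"))

  hits[, `:=`(
    m = (strand == "+" & base == "C") | (strand == "-" & base == "G"),
    u = (strand == "+" & base == "T") | (strand == "-" & base == "A"))]
  agg <- hits[, .(n_meth = sum(m), n_unmeth = sum(u),
                  n_other = sum(!m & !u)), by = .(chrom, pos, strand)]
  .finish_counts(sites, agg)
}

.finish_counts <- function(sites, agg) {
  out <- as.data.table(sites)
  out <- merge(out, agg, by = c("chrom", "pos", "strand"), all.x = TRUE)
  for (col in c("n_meth", "n_unmeth", "n_other"))
    set(out, which(is.na(out[[col]])), col, 0L)
  out[, level := site_level(n_meth, n_unmeth)]
  out[, covered := (n_meth + n_unmeth) > 0L]
  setorder(out, chrom, pos, strand)
  out[]
}

#' Add binary methylation calls to a count table
#'
#' Convenience wrapper: runs [call_methylated()] on a count table and appends
#' `is_methylated` and `p_value` columns.
#'
#' @param counts Count table from [extract_counts()] or the simulator.
#' @param ... Passed to [call_methylated()].
#' @return The count table with call columns added (by reference semantics
#'   avoided; a copy is returned).
#' @export
add_meth_calls <- function(counts, ...) {
  counts <- copy(as.data.table(counts))
  calls <- call_methylated(counts$n_meth, counts$n_unmeth, ...)
  counts[, `:=`(is_methylated = calls$is_methylated, p_value = calls$p_value)]
  counts[]
}

#' Coverage and methylation summary by chromosome, feature class and context
#'
#' For each chromosome x context (and, when `features` is supplied, each
#' feature class x context), reports the fraction of cytosine sites with at
#' least one informative read, the mean methylation level over covered sites,
#' and the methylated-site fraction under both denominators (covered sites,
#' all sites).
#'
#' @param counts Count table with `is_methylated` (added if absent with
#'   default calling).
#' @param features Optional data.table of intervals with columns `chrom`,
#'   `start`, `end` (1-based inclusive) and a class column named by
#'   `class_col` (e.g. gene part "CDS"/"intron" or TE class).
#' @param class_col Name of the class column in `features`.
#' @return Tidy data.table: `group_type`, `group`, `context`, `n_total`,
#'   `n_covered`, `coverage_rate`, `mean_level`, `mc_frac_covered`,
#'   `mc_frac_all`.
#' @export
coverage_summary <- function(counts, features = NULL, class_col = "te_class") {
  counts <- as.data.table(counts)
  if (!"is_methylated" %in% names(counts)) counts <- add_meth_calls(counts)
  per_chrom <- counts[!is.na(context),
    .(n_total = .N, n_covered = sum(covered), coverage_rate = mean(covered),
      mean_level = if (any(covered)) mean(level[covered]) else NA_real_,
      mc_frac_covered = if (any(covered)) mean(is_methylated[covered]) else NA_real_,
      mc_frac_all = mean(is_methylated)),
    by = .(group = chrom, context)][, group_type := "chromosome"]
  out <- list(per_chrom)
  if (!is.null(features)) {
    features <- as.data.table(features)
    if (!class_col %in% names(features))
      stop("features lack class column '", class_col, "'")
    bad <- features[end < start]
    if (nrow(bad)) stop("feature interval with end < start")
    fo <- .overlap_sites_features(counts, features)
    if (nrow(fo)) {
      fo[, group := features[[class_col]][yid]]
      sub <- counts[fo$xid]
      sub[, group := fo$group]
      per_class <- sub[!is.na(context),
        .(n_total = .N, n_covered = sum(covered), coverage_rate = mean(covered),
          mean_level = if (any(covered)) mean(level[covered]) else NA_real_,
          mc_frac_covered = if (any(covered)) mean(is_methylated[covered]) else NA_real_,
          mc_frac_all = mean(is_methylated)),
        by = .(group, context)][, group_type := class_col]
      out <- c(out, list(per_class))
    }
  }
  rbindlist(out, use.names = TRUE)[]
}

# point-in-interval overlaps: returns data.table(xid = site row, yid = feature row)
.overlap_sites_features <- function(sites, features) {
  s <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  f <- GenomicRanges::GRanges(features$chrom,
                              IRanges::IRanges(features$start, features$end))
  h <- GenomicRanges::findOverlaps(s, f, ignore.strand = TRUE)
  data.table(xid = S4Vectors::queryHits(h), yid = S4Vectors::subjectHits(h))
}

#' Write / read a per-sample count table
#'
#' TSV dialect shared by all downstream modules: `chrom`, `pos` (1-based),
#' `strand`, `context`, `n_meth`, `n_unmeth`, `level`, `is_methylated`.
#'
#' @param counts Count table.
#' @param path TSV path.
#' @export
write_count_table <- function(counts, path) {
  keep <- intersect(c("chrom", "pos", "strand", "context", "n_meth",
                      "n_unmeth", "n_other", "level", "is_methylated",
                      "p_value"), names(counts))
  fwrite(as.data.table(counts)[, keep, with = FALSE], path, sep = "\t",
         na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = list(character = "chrom"))
  req <- c("chrom", "pos", "strand", "context", "n_meth", "n_unmeth")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("count table '", path, "' missing column(s): ",
         paste(miss, collapse = ", "))
  if (!"level" %in% names(dt)) dt[, level := site_level(n_meth, n_unmeth)]
  dt[, covered := (n_meth + n_unmeth) > 0L]
  dt[]
}
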
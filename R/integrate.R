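#' Differential-expression status from thresholds
#'
#' `"up"` iff `log2fc > lfc` and `fdr < q`; `"down"` iff `log2fc < -lfc` and
#' `fdr < q`; otherwise `"ns"`.
#'
#' @param log2fc,fdr Numeric vectors.
#' @param lfc Log2 fold-change threshold (default 1).
#' @param q FDR threshold (default 0.05).
#' @return Character vector in `{"up","down","ns"}`.
#' @export
deg_status <- function(log2fc, fdr, lfc = 1, q = 0.05) {
  ifelse(!is.na(log2fc) & !is.na(fdr) & fdr < q & log2fc > lfc, "up",
  ifelse(!is.na(log2fc) & !is.na(fdr) & fdr < q & log2fc < -lfc, "down", "ns"))
}

#' Intersect DMR-associated genes with differentially expressed genes
#'
#' Per context, counts genes that carry at least one associated DMR and are
#' differentially expressed, with up/down breakdown, and tabulates the
#' cross-context overlap of DMR-related DEG sets.
#'
#' @param assoc Result of [associate_dmrs()] (its `associations` table must
#'   carry `context`), or the `associations` data.table itself.
#' @param deg data.table with `gene_id`, `log2fc`, `fdr` (and optionally a
#'   precomputed `status` column).
#' @param lfc,q Thresholds passed to [deg_status()].
#' @return List: `counts` (per context: `n_dmr_genes`, `n_deg`, `n_up`,
#'   `n_down`), `genes` (per context character vectors of DMR-related DEG
#'   ids), `venn` (per combination of contexts, the number of DMR-related
#'   DEGs shared by exactly that set).
#' @export
dmr_deg_intersection <- function(assoc, deg, lfc = 1, q = 0.05) {
  a <- if (is.list(assoc) && !is.data.frame(assoc)) assoc$associations else assoc
  a <- as.data.table(a)
  if (!"context" %in% names(a))
    stop("associations need a 'context' column")
  deg <- copy(as.data.table(deg))
  deg[, gene_id := trimws(tolower(gene_id))]
  a <- copy(a)[, feature_id := trimws(tolower(feature_id))]
  if (length(intersect(unique(a$feature_id), unique(deg$gene_id))) == 0L)
    stop("gene id universes of DMR associations and DEG table do not intersect")
  if (!"status" %in% names(deg))
    deg[, status := deg_status(log2fc, fdr, lfc, q)]

  ctxs <- sort(unique(a$context))
  gene_sets <- lapply(ctxs, function(cx)
    sort(unique(a[context == cx, feature_id])))
  names(gene_sets) <- ctxs
  deg_ids <- deg[status != "ns", gene_id]
  up_ids <- deg[status == "up", gene_id]
  down_ids <- deg[status == "down", gene_id]

  counts <- rbindlist(lapply(ctxs, function(cx) {
    g <- gene_sets[[cx]]
    data.table(context = cx,
               n_dmr_genes = length(g),
               n_deg = length(intersect(g, deg_ids)),
               n_up = length(intersect(g, up_ids)),
               n_down = length(intersect(g, down_ids)))
  }))
  genes <- lapply(gene_sets, function(g) intersect(g, deg_ids))

  # Venn-style membership over contexts, restricted to DMR-related DEGs
  all_genes <- unique(unlist(genes))
  venn <- data.table()
  if (length(all_genes)) {
    memb <- sapply(ctxs, function(cx) all_genes %in% genes[[cx]])
    memb <- matrix(memb, ncol = length(ctxs),
                   dimnames = list(NULL, ctxs))
    key <- apply(memb, 1L, function(r) paste(ctxs[r], collapse = "&"))
    venn <- as.data.table(table(key))
    setnames(venn, c("contexts", "n_genes"))
  }
  list(counts = counts, genes = genes, venn = venn)
}

#' Positional abundance of 24-nt siRNA loci around features
#'
#' Counts siRNA loci (midpoint assignment) in the up2k / body / down2k
#' metagene bins of a stranded feature set, using the same geometry as
#' [metagene_profile()].
#'
#' @param sirna data.table with `chrom`, `start`, `end` (1-based inclusive)
#'   and optionally `length` (else `end - start + 1`).
#' @param features Stranded feature table.
#' @param flank,bin,body_bins Geometry; see [assign_zone_bins()].
#' @param length_class Keep only loci of this length (default 24; `NULL`
#'   keeps all).
#' @return data.table: `zone`, `bin`, `meta_bin`, `n_loci`.
#' @export
sirna_positional_abundance <- function(sirna, features, flank = 2000,
                                       bin = 100, body_bins = 20,
                                       length_class = 24) {
  s <- copy(as.data.table(sirna))
  if (!"length" %in% names(s)) s[, length := end - start + 1L]
  if (!is.null(length_class)) s <- s[length == length_class]
  nb_flank <- as.integer(flank / bin)
  grid <- CJ(zone = c("up2k", "body", "down2k"),
             bin = seq_len(max(nb_flank, body_bins)))[
    (zone %in% c("up2k", "down2k") & bin <= nb_flank) |
      (zone == "body" & bin <= body_bins)]
  if (nrow(s)) {
    mid <- s[, .(chrom, pos = as.integer((start + end) %/% 2L))]
    ab <- assign_zone_bins(mid, features, flank, bin, body_bins)
    tab <- ab[, .(n_loci = .N), by = .(zone, bin)]
    out <- merge(grid, tab, by = c("zone", "bin"), all.x = TRUE)
  } else {
    out <- grid[, n_loci := NA_integer_]
  }
  out[is.na(n_loci), n_loci := 0L]
  out[, meta_bin := fifelse(zone == "up2k", bin,
                    fifelse(zone == "body", nb_flank + bin,
                            nb_flank + body_bins + bin))]
  setorder(out, meta_bin)
  out[]
}

#' siRNA loci inside hyper- vs hypomethylated DMRs
#'
#' Counts (locus, DMR) overlap pairs per DMR direction and context; a locus
#' overlapping several DMRs counts once per DMR.
#'
#' @param sirna Locus table (`chrom`, `start`, `end`).
#' @param dmrs DMR table with `direction` and `context`.
#' @return data.table with the full direction x context grid and `n_loci`.
#' @export
sirna_dmr_overlap <- function(sirna, dmrs) {
  s <- as.data.table(sirna)
  d <- as.data.table(dmrs)
  grid <- CJ(direction = c("hyper", "hypo"),
             context = sort(unique(c(d$context, c("CG", "CHG", "CHH")))))
  if (nrow(s) == 0L || nrow(d) == 0L)
    return(grid[, n_loci := 0L][])
  dd <- d[, .(chrom, start, end, direction, context)]
  setkey(dd, chrom, start, end)
  ov <- foverlaps(s[, .(chrom, start, end)], dd,
                  by.x = c("chrom", "start", "end"), nomatch = NULL)
  tab <- ov[, .(n_loci = .N), by = .(direction, context)]
  out <- merge(grid, tab, by = c("direction", "context"), all.x = TRUE)
  out[is.na(n_loci), n_loci := 0L]
  out[]
}

utils::globalVariables(c("length", "mid", "n_loci", "is_methylated_A",
                         "n_dmr_genes", "n_deg", "n_up", "n_down"))
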
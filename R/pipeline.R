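#' Read gene/TE features from BED or GFF3
#'
#' Uses rtracklayer for parsing; returns the package's 1-based inclusive
#' feature table. BED names of the form `id|class` populate `te_class`.
#'
#' @param path BED or GFF3 file.
#' @return data.table: `chrom`, `start`, `end`, `strand`, `feature_id`
#'   (+ `te_class` when encoded).
#' @export
read_features <- function(path) {
  gr <- rtracklayer::import(path)
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)))
  md <- S4Vectors::mcols(gr)
  nm <- if ("name" %in% names(md)) as.character(md$name)
        else if ("ID" %in% names(md)) as.character(md$ID)
        else sprintf("feat%05d", seq_len(nrow(dt)))
  dt[, feature_id := nm]
  if (any(grepl("|", nm, fixed = TRUE))) {
    parts <- tstrsplit(nm, "|", fixed = TRUE)
    dt[, feature_id := parts[[1L]]]
    dt[, te_class := parts[[2L]]]
  }
  dt[strand == "*", strand := "+"]
  dt[]
}

#' Pipeline configuration
#'
#' Bundles sample names, comparison pairs (ordered "test:reference" strings),
#' input paths and all module thresholds. Round-trips losslessly through YAML
#' with [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param samples Named character vector or list mapping sample name ->
#'   count-table path (or in-memory count tables when calling
#'   [run_pipeline()] directly).
#' @param comparisons Character vector like `"stage2:stage1"`.
#' @param genome,features,tes,expression,sirna Optional input paths.
#' @param outdir Output directory.
#' @param thresholds Named list of DMR criteria; defaults: `min_sites` 5,
#'   `min_depth` 10, `max_gap` 200, `min_len` 40, `max_len` 10000,
#'   `min_fold` 2, `alpha` 0.05.
#' @param contexts Contexts to call (default CG, CHG, CHH).
#' @param flank,bin,body_bins Metagene geometry.
#' @param seed Integer seed recorded in the manifest.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(samples, comparisons, genome = NULL,
                            features = NULL, tes = NULL, expression = NULL,
                            sirna = NULL, outdir = "results",
                            thresholds = list(), contexts = c("CG", "CHG", "CHH"),
                            flank = 2000, bin = 100, body_bins = 20,
                            seed = 1L) {
  defaults <- list(min_sites = 5, min_depth = 10, max_gap = 200,
                   min_len = 40, max_len = 10000, min_fold = 2, alpha = 0.05)
  thr <- utils::modifyList(defaults, thresholds)
  if (any(unlist(thr) <= 0)) stop("thresholds must be positive")
  sample_names <- names(samples)
  if (is.null(sample_names) || any(sample_names == ""))
    stop("samples must be named")
  for (cmp in comparisons) {
    pair <- strsplit(cmp, ":", fixed = TRUE)[[1L]]
    if (length(pair) != 2L || !all(pair %in% sample_names))
      stop("comparison '", cmp, "' does not reference two declared samples")
  }
  structure(list(samples = samples, comparisons = comparisons,
                 genome = genome, features = features, tes = tes,
                 expression = expression, sirna = sirna, outdir = outdir,
                 thresholds = thr, contexts = contexts, flank = flank,
                 bin = bin, body_bins = body_bins, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  # named atomic vectors lose their names as YAML sequences; write a map
  cfg$samples <- as.list(cfg$samples)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, c(
    list(samples = unlist(x$samples), comparisons = x$comparisons),
    x[setdiff(names(x), c("samples", "comparisons", "thresholds"))],
    list(thresholds = x$thresholds)))
}

#' Validate pipeline inputs
#'
#' Checks existence of declared files, reference-name consistency between the
#' genome/cytosine universe and count tables and feature files, coordinate
#' sanity (intervals within chromosome bounds), and required count-table
#' columns. All failures are collected, not just the first.
#'
#' @param config A `pipeline_config` with path-valued inputs.
#' @return data.table with columns `input`, `problem` (zero rows when clean).
#' @export
validate_inputs <- function(config) {
  fails <- list()
  note <- function(input, problem)
    fails[[length(fails) + 1L]] <<- data.table(input = input, problem = problem)

  chrom_lens <- NULL
  if (!is.null(config$genome)) {
    if (!file.exists(config$genome)) {
      note(config$genome, "genome FASTA not found")
    } else {
      g <- tryCatch(read_genome(config$genome), error = function(e) e)
      if (inherits(g, "error")) note(config$genome, conditionMessage(g))
      else chrom_lens <- setNames(Biostrings::width(g), names(g))
    }
  }
  req_cols <- c("chrom", "pos", "strand", "context", "n_meth", "n_unmeth")
  for (nm in names(config$samples)) {
    p <- config$samples[[nm]]
    if (!is.character(p)) next
    if (!file.exists(p)) { note(p, "count table not found"); next }
    hd <- names(fread(p, nrows = 0L))
    miss <- setdiff(req_cols, hd)
    if (length(miss))
      note(p, paste0("missing column(s): ", paste(miss, collapse = ", ")))
    else if (!is.null(chrom_lens)) {
      ct <- fread(p, select = c("chrom", "pos"))
      badc <- setdiff(unique(ct$chrom), names(chrom_lens))
      if (length(badc))
        note(p, paste0("unknown chrom(s): ", paste(badc, collapse = ", ")))
      oob <- ct[chrom %in% names(chrom_lens)][pos > chrom_lens[chrom] | pos < 1L]
      if (nrow(oob))
        note(p, paste0(nrow(oob), " position(s) outside chromosome bounds"))
    }
  }
  for (fpath in c(config$features, config$tes, config$sirna)) {
    if (is.null(fpath)) next
    if (!file.exists(fpath)) { note(fpath, "feature file not found"); next }
    ft <- tryCatch(read_features(fpath), error = function(e) e)
    if (inherits(ft, "error")) { note(fpath, conditionMessage(ft)); next }
    if (!is.null(chrom_lens)) {
      badc <- setdiff(unique(ft$chrom), names(chrom_lens))
      if (length(badc))
        note(fpath, paste0("unknown chrom(s): ", paste(badc, collapse = ", ")))
      oob <- which(ft$chrom %in% names(chrom_lens) &
                     ft$end > chrom_lens[ft$chrom])
      for (i in oob)
        note(fpath, paste0("line ", i, ": interval beyond chromosome end"))
    }
  }
  if (!is.null(config$expression)) {
    if (!file.exists(config$expression)) {
      note(config$expression, "expression table not found")
    } else {
      hd <- names(fread(config$expression, nrows = 0L))
      miss <- setdiff(c("gene_id", "rpkm"), hd)
      if (length(miss))
        note(config$expression,
             paste0("missing column(s): ", paste(miss, collapse = ", ")))
    }
  }
  if (length(fails)) rbindlist(fails) else
    data.table(input = character(), problem = character())
}

.stage_fail <- function(stage, e)
  stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
       call. = FALSE)

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — cytosine context, count loading,
#' landscape summaries, per-comparison DMR calling and association, and
#' (when inputs are present) DEG/siRNA integration — writing every table as
#' TSV under `config$outdir` plus a JSON manifest with the config hash, seed
#' and per-output row counts and checksums. Outputs are byte-deterministic
#' for a fixed config.
#'
#' @param config A [pipeline_config()]. `samples` may map to count-table
#'   paths or in-memory count tables.
#' @param validate Run [validate_inputs()] first and abort on failures
#'   (default TRUE when all inputs are paths).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, validate = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  all_paths <- all(vapply(config$samples, is.character, logical(1L)))
  if (validate && all_paths) {
    rep <- validate_inputs(config)
    if (nrow(rep))
      stop("input validation failed:\n",
           paste0("  ", rep$input, ": ", rep$problem, collapse = "\n"),
           call. = FALSE)
  }
  outputs <- list()
  emit <- function(dt, name) {
    p <- file.path(outdir, paste0(name, ".tsv"))
    fwrite(dt, p, sep = "\t", na = "NA", quote = FALSE)
    outputs[[name]] <<- list(path = p, rows = nrow(dt))
    p
  }

  counts <- tryCatch({
    lapply(config$samples, function(x)
      if (is.character(x)) read_count_table(x) else as.data.table(x))
  }, error = function(e) .stage_fail("extract", e))
  counts <- lapply(counts, function(ct)
    if ("is_methylated" %in% names(ct)) ct else add_meth_calls(ct))

  features <- if (!is.null(config$features)) {
    if (is.character(config$features)) read_features(config$features)
    else as.data.table(config$features)
  } else NULL
  tes <- if (!is.null(config$tes)) {
    if (is.character(config$tes)) read_features(config$tes)
    else as.data.table(config$tes)
  } else NULL

  # landscape stage
  tryCatch({
    for (nm in names(counts)) {
      emit(global_fractions(counts[[nm]]), paste0("global_fractions_", nm))
      hist_tab <- rbindlist(lapply(config$contexts, function(cx) {
        h <- level_histogram(counts[[nm]], cx)
        data.table(context = cx, bin_lo = head(h$bin_edges, -1L),
                   bin_hi = tail(h$bin_edges, -1L), proportion = h$proportions)
      }))
      emit(hist_tab, paste0("level_histogram_", nm))
      if (!is.null(features))
        emit(metagene_profile(counts[[nm]], features, flank = config$flank,
                              bin = config$bin, body_bins = config$body_bins),
             paste0("metagene_genes_", nm))
      if (!is.null(tes))
        emit(metagene_profile(counts[[nm]], tes, flank = config$flank,
                              bin = config$bin, body_bins = config$body_bins),
             paste0("metagene_tes_", nm))
    }
  }, error = function(e) .stage_fail("landscape", e))

  # DMR stage
  thr <- config$thresholds
  dmr_results <- list()
  tryCatch({
    for (cmp in config$comparisons) {
      pair <- strsplit(cmp, ":", fixed = TRUE)[[1L]]
      test <- pair[1L]; ref <- pair[2L]
      dmrs <- rbindlist(lapply(config$contexts, function(cx)
        call_dmrs(counts[[ref]], counts[[test]], cx,
                  min_sites = thr$min_sites, min_depth = thr$min_depth,
                  max_gap = thr$max_gap, min_len = thr$min_len,
                  max_len = thr$max_len, min_fold = thr$min_fold,
                  alpha = thr$alpha)), use.names = TRUE)
      tag <- gsub(":", "_vs_", cmp, fixed = TRUE)
      if (!is.null(features) && nrow(dmrs)) {
        assoc <- associate_dmrs(dmrs, features, flank = config$flank)
        dmrs <- assoc$dmrs
        emit(dmr_zone_summary(assoc), paste0("dmr_zone_summary_", tag))
        dmr_results[[cmp]] <- assoc
      } else {
        dmr_results[[cmp]] <- list(associations = NULL, dmrs = dmrs)
      }
      emit(dmrs, paste0("dmrs_", tag))
    }
  }, error = function(e) .stage_fail("dmr", e))

  # integration stage
  tryCatch({
    if (!is.null(config$expression)) {
      expr <- if (is.character(config$expression)) fread(config$expression)
              else as.data.table(config$expression)
      for (cmp in names(dmr_results)) {
        a <- dmr_results[[cmp]]$associations
        if (is.null(a) || nrow(a) == 0L) next
        res <- dmr_deg_intersection(a, expr)
        tag <- gsub(":", "_vs_", cmp, fixed = TRUE)
        emit(res$counts, paste0("dmr_deg_counts_", tag))
        if (nrow(res$venn)) emit(res$venn, paste0("dmr_deg_venn_", tag))
      }
      if (!is.null(features))
        emit(rbindlist(lapply(names(counts), function(nm)
          expression_stratified_profiles(counts[[nm]], features, expr,
                                         flank = config$flank,
                                         bin = config$bin,
                                         body_bins = config$body_bins)[
            , sample := nm]), use.names = TRUE),
          "metagene_by_expression")
    }
    if (!is.null(config$sirna)) {
      sirna <- if (is.character(config$sirna)) {
        s <- read_features(config$sirna)
        s[, length := end - start + 1L][]
      } else as.data.table(config$sirna)
      if (!is.null(features))
        emit(sirna_positional_abundance(sirna, features,
                                        flank = config$flank, bin = config$bin,
                                        body_bins = config$body_bins),
             "sirna_gene_profile")
      if (!is.null(tes))
        emit(sirna_positional_abundance(sirna, tes, flank = config$flank,
                                        bin = config$bin,
                                        body_bins = config$body_bins),
             "sirna_te_profile")
      for (cmp in names(dmr_results)) {
        tag <- gsub(":", "_vs_", cmp, fixed = TRUE)
        emit(sirna_dmr_overlap(sirna, dmr_results[[cmp]]$dmrs),
             paste0("sirna_dmr_overlap_", tag))
      }
    }
  }, error = function(e) .stage_fail("integrate", e))

  # manifest
  cfg_path <- file.path(outdir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  manifest <- list(
    package = "methscape",
    version = as.character(utils::packageVersion("methscape")),
    seed = config$seed,
    config = basename(cfg_path),
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = lapply(names(outputs), function(nm) list(
      name = nm, path = basename(outputs[[nm]]$path),
      rows = outputs[[nm]]$rows,
      md5 = unname(tools::md5sum(outputs[[nm]]$path)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

utils::globalVariables(c("problem", "bin_lo", "bin_hi", "proportion",
                         "sample"))
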
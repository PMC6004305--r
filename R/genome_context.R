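#' Classify cytosine sequence context
#'
#' Assigns the CG / CHG / CHH context of a cytosine from the two bases that
#' follow it 5'->3' on its own strand (H = A, C or T). A cytosine followed
#' immediately by G is CG regardless of the third base; otherwise both
#' followers are needed, and an N or missing follower makes the context `NA`.
#'
#' @param b1,b2,b3 Character vectors (recycled): the base at the site (must be
#'   "C"), the next base, and the next-next base on the cytosine's strand.
#'   Use "N" for positions that run off the sequence end.
#' @return Character vector with values "CG", "CHG", "CHH" or `NA`.
#' @examples
#' classify_context("C", "G", "A")  # CG
#' classify_context("C", "A", "G")  # CHG
#' classify_context("C", "T", "N")  # NA
#' @export
classify_context <- function(b1, b2, b3) {
  n <- max(length(b1), length(b2), length(b3))
  b1 <- rep_len(toupper(b1), n)
  b2 <- rep_len(toupper(b2), n)
  b3 <- rep_len(toupper(b3), n)
  if (any(b1 != "C"))
    stop("classify_context: first base must be 'C' (got '",
         b1[which(b1 != "C")[1L]], "')")
  ctx <- rep(NA_character_, n)
  ctx[b2 == "G"] <- "CG"
  h2 <- b2 %in% c("A", "C", "T")
  ctx[h2 & b3 == "G"] <- "CHG"
  ctx[h2 & b3 %in% c("A", "C", "T")] <- "CHH"
  ctx
}

.complement <- function(x) chartr("ACGTN", "TGCAN", x)

.revcomp_str <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(.complement(s), "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Read a reference genome from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that normalises record
#' names to the first whitespace-delimited token.
#'
#' @param path Path to a (optionally gzipped) FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  g <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("malformed FASTA '", path, "': ",
                                         conditionMessage(e)))
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# Enumerate cytosines of a single sequence (character scalar), both strands.
.enumerate_one <- function(s, chrom, iupac_to_n = TRUE) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  bad <- !(ch %in% c("A", "C", "G", "T", "N"))
  if (any(bad)) {
    if (!iupac_to_n)
      stop("sequence '", chrom, "' contains non-ACGTN base '",
           ch[which(bad)[1L]], "' at position ", which(bad)[1L])
    ch[bad] <- "N"
  }
  n <- length(ch)
  if (n == 0L) return(NULL)
  pad <- c(rep("N", 4L), ch, rep("N", 4L))

  nb_matrix <- function(idx) {
    # ref position i maps to pad index i+4; window i-4..i+4 -> pad[i..i+8]
    matrix(pad[outer(idx, 0:8, "+")], nrow = length(idx))
  }
  collapse_rows <- function(m) do.call(paste0, as.data.frame(m))

  out <- list()
  fwd <- which(ch == "C")
  if (length(fwd)) {
    b2 <- pad[fwd + 5L]
    b3 <- pad[fwd + 6L]
    out[[1L]] <- data.table(
      chrom = chrom, pos = fwd, strand = "+",
      context = classify_context("C", b2, b3),
      neighborhood = collapse_rows(nb_matrix(fwd))
    )
  }
  rev <- which(ch == "G")
  if (length(rev)) {
    b2 <- .complement(pad[rev + 3L])
    b3 <- .complement(pad[rev + 2L])
    m <- nb_matrix(rev)
    m <- matrix(.complement(m[, 9:1, drop = FALSE]), nrow = nrow(m))
    out[[2L]] <- data.table(
      chrom = chrom, pos = rev, strand = "-",
      context = classify_context("C", b2, b3),
      neighborhood = collapse_rows(m)
    )
  }
  rbindlist(out)
}

#' Enumerate every cytosine in a genome with strand and context
#'
#' Scans both strands of each sequence and emits one row per cytosine
#' (reference C on "+", reference G on "-"), with its CG/CHG/CHH context read
#' 5'->3' on the cytosine's own strand and a 9-base neighbourhood (cytosine at
#' position 5, N-padded at sequence ends, reverse-complemented for "-" sites).
#' Non-ACGTN IUPAC codes are mapped to N (or rejected with
#' `iupac_to_n = FALSE`); any context touching an N is `NA` and is excluded
#' from downstream denominators.
#'
#' @param genome A [Biostrings::DNAStringSet], a named character vector of
#'   sequences, or a path to a FASTA file.
#' @param iupac_to_n Map non-ACGTN bases to N (default) instead of erroring.
#' @return A [data.table::data.table] with columns `chrom`, `pos` (1-based
#'   forward-reference coordinate of the C), `strand`, `context`,
#'   `neighborhood`, sorted by (chrom, pos, strand).
#' @examples
#' enumerate_cytosines(c(chr1 = "CCGG"))
#' @export
enumerate_cytosines <- function(genome, iupac_to_n = TRUE) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome(genome)
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else if (is.character(genome)) {
    seqs <- genome
  } else stop("genome must be a DNAStringSet, named character vector, or FASTA path")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("genome sequences must be named")
  res <- rbindlist(lapply(names(seqs), function(nm)
    .enumerate_one(seqs[[nm]], nm, iupac_to_n)))
  if (nrow(res) == 0L)
    return(data.table(chrom = character(), pos = integer(), strand = character(),
                      context = character(), neighborhood = character()))
  setorder(res, chrom, pos, strand)
  res[]
}

#' Write / read a cytosine report
#'
#' The cytosine report is the TSV interchange format consumed by the count
#' extractor and the simulator: columns `chrom`, `pos` (1-based), `strand`,
#' `context`, `neighborhood`.
#'
#' @param sites data.table from [enumerate_cytosines()].
#' @param path Output (input) TSV path.
#' @return `write_cytosine_report` returns `path` invisibly;
#'   `read_cytosine_report` returns a data.table.
#' @export
write_cytosine_report <- function(sites, path) {
  fwrite(sites, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_cytosine_report
#' @export
read_cytosine_report <- function(path) {
  req <- c("chrom", "pos", "strand", "context", "neighborhood")
  dt <- fread(path, sep = "\t", colClasses = list(character = "chrom"))
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("cytosine report '", path, "' missing column(s): ",
         paste(miss, collapse = ", "))
  dt
}
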
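#' File interfaces
#'
#' Thin readers/writers for the plain-text formats the pipeline
#' exchanges: FASTA (via Biostrings), 4-column bedGraph, BED, and TSV
#' tables.  Coordinates in all files are 0-based half-open.
#'
#' @name io
NULL

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a coverage vector as bedGraph
#'
#' Adjacent equal values are collapsed into intervals (0-based,
#' half-open), zero runs omitted.
#'
#' @param cov numeric coverage vector (index = 0-based position + 1).
#' @param path output path.
#' @param chrom contig name.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(cov, path, chrom = "chr") {
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  keep <- r$values != 0
  df <- data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
                   value = r$values[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph into a coverage vector
#'
#' @param path bedGraph file (chrom, start, end, value).
#' @param length contig length; default = max end.
#' @return numeric vector (index = 0-based position + 1).
#' @export
read_bedgraph <- function(path, length = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  if (is.null(length)) length <- max(df$end)
  cov <- numeric(length)
  for (i in seq_len(nrow(df)))
    cov[(df$start[i] + 1L):df$end[i]] <- df$value[i]
  cov
}

#' Write intervals as BED
#'
#' @param df data.frame with `start`, `end` (0-based half-open) and
#'   optionally `name`.
#' @param path output path.
#' @param chrom contig name.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, chrom = "chr") {
  out <- data.frame(chrom = chrom, start = df$start, end = df$end,
                    name = if ("name" %in% names(df)) df$name else ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write and read TSV tables with headers
#'
#' @param df data.frame.
#' @param path file path.
#' @return `path` (write) or data.frame (read).
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write a motif model as a MEME-minimal-format text block
#'
#' @param model a `MotifModel`.
#' @param path output path.
#' @param name motif name in the file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(model, path, name = "motif1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: +", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", BASES, model$background),
                     collapse = " "), "",
               sprintf("MOTIF %s", name),
               sprintf(
                 "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                 model$width)), con)
  for (j in seq_len(model$width))
    writeLines(paste(sprintf("%.6f", model$theta[, j]), collapse = "  "),
               con)
  invisible(path)
}

#' Read a MEME-minimal-format motif into a `MotifModel`
#'
#' @param path MEME-format file (first motif is read).
#' @return `MotifModel` (without EM-fit fields).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bgl <- grep("^Background letter frequencies", lines)
  bg <- rep(0.25, 4L)
  if (length(bgl)) {
    toks <- strsplit(trimws(lines[bgl[1] + 1L]), "\\s+")[[1]]
    bg <- as.numeric(toks[seq(2, 8, by = 2)])
  }
  hdr <- grep("^letter-probability matrix", lines)[1]
  w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[hdr]))
  mat <- t(vapply(lines[(hdr + 1L):(hdr + w)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]), numeric(4L)))
  theta <- t(mat)
  rownames(theta) <- BASES
  cons <- paste(BASES[apply(theta, 2L, which.max)], collapse = "")
  structure(list(width = w, theta = theta, background = bg,
                 gamma = NA_real_, consensus = cons,
                 information_content =
                   sum(theta * log2(sweep(theta, 1L, bg, "/"))),
                 loglik = NA_real_, ll_trace = numeric(0),
                 hits = NULL),
            class = "MotifModel")
}

#' Naive local-maximum peak caller (synthetic-data plumbing only)
#'
#' Calls positions whose strand-summed coverage is a local maximum over
#' a sliding window and exceeds a threshold.  Provided so synthetic
#' coverage can be turned into peak positions for round-trip tests; it
#' mirrors no published peak-calling algorithm.
#'
#' @param fwd,rev per-strand coverage vectors.
#' @param min_height minimum strand-summed height.
#' @param min_distance minimum distance between called peaks.
#' @return integer vector of 0-based peak positions.
#' @export
call_peaks_naive <- function(fwd, rev, min_height = 10,
                             min_distance = 100L) {
  tot <- fwd + rev
  cand <- which(tot >= min_height)
  if (length(cand) == 0L) return(integer(0))
  ord <- cand[order(-tot[cand])]
  picked <- integer(0)
  for (p in ord) {
    if (all(abs(p - picked) >= min_distance)) picked <- c(picked, p)
  }
  sort(picked) - 1L
}
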
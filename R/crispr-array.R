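#' CRISPR array representation and cas2-flank preparation
#'
#' Functions to parse CRISPR arrays (alternating identical repeats and
#' variable spacers, spacer 1 leader-proximal) and to prepare the
#' cas2-downstream flank sequences used for boxA motif screening:
#' extraction of a fixed-length flank 3' of cas2, trimming at the first
#' recurring 15-mer (the likely start of the CRISPR array), and discarding
#' flanks that lack a repeat or trim to under 20 bp.
#'
#' All genomic coordinates are 0-based, half-open (BED convention).
#'
#' @name crispr_array
NULL

#' Extract the flank downstream of a cas2 gene
#'
#' Returns the `length` bp immediately 3' of a cas2 gene, read in the
#' gene's orientation.  For a minus-strand cas2 this is the reverse
#' complement of the region upstream (in genome coordinates) of the gene
#' start.  The flank is truncated, and flagged, at contig ends.
#'
#' @param genome character string; contig sequence.
#' @param start,end 0-based half-open interval of the cas2 gene.
#' @param strand `"+"` or `"-"`.
#' @param length flank length in bp (default 300).
#' @return list with `seq` (character), `truncated` (logical).
#' @export
extract_cas2_flank <- function(genome, start, end, strand, length = 300L) {
  L <- nchar(genome)
  if (start < 0L || end > L || start >= end)
    stop_input("cas2 interval [%d,%d) outside contig of length %d",
               start, end, L)
  if (!strand %in% c("+", "-")) stop_input("strand must be '+' or '-'")
  if (strand == "+") {
    to <- min(end + length, L)
    seq <- slice0(genome, end, to)
    truncated <- (to - end) < length
  } else {
    from <- max(start - length, 0L)
    seq <- revcomp(slice0(genome, from, start))
    truncated <- (start - from) < length
  }
  list(seq = seq, truncated = truncated)
}

#' Offset of the first recurring 15-mer
#'
#' Finds the smallest offset p (0-based) such that the 15-mer starting at
#' p occurs again, exactly, at some later offset in the same sequence.
#' 15-mers containing N never match.  CRISPR repeats are direct repeats,
#' so only same-strand recurrence is considered.
#'
#' @param seq character string over A/C/G/T/N.
#' @param width repeat width (default 15).
#' @return 0-based offset, or `NA_integer_` if no 15-mer recurs.
#' @export
find_first_repeat15 <- function(seq, width = 15L) {
  km <- kmers(seq, width)
  if (length(km) == 0L) return(NA_integer_)
  ok <- !grepl("N", km, fixed = TRUE)
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  hit <- which(ok & dup)
  if (length(hit) == 0L) return(NA_integer_)
  hit[1L] - 1L
}

#' Trim a cas2 flank at the first 15-bp repeat and classify it
#'
#' The flank is trimmed to the prefix preceding the first recurring
#' 15-mer (the putative start of the CRISPR array).  Flanks with no
#' recurring 15-mer get status `"no_repeat"`; flanks trimmed to fewer
#' than `min_len` bp get `"too_short"`; the rest are `"kept"`.
#'
#' @param seq raw flank sequence.
#' @param min_len minimum kept length (default 20).
#' @return list with `raw`, `trimmed`, `status`, `repeat_offset`.
#' @export
trim_and_filter <- function(seq, min_len = 20L) {
  p <- find_first_repeat15(seq)
  if (is.na(p)) {
    return(list(raw = seq, trimmed = NA_character_, status = "no_repeat",
                repeat_offset = NA_integer_))
  }
  trimmed <- substr(seq, 1L, p)
  status <- if (p >= min_len) "kept" else "too_short"
  list(raw = seq, trimmed = trimmed, status = status, repeat_offset = p)
}

#' Parse a CRISPR array from a genomic region
#'
#' Locates non-overlapping, leftmost-greedy exact occurrences of the
#' repeat sequence; spacers are the maximal segments strictly between
#' consecutive repeats, numbered from the leader-proximal end (spacer 1
#' closest to the leader).  For a minus-strand array pass the reverse
#' complement of the genomic region so that the leader-proximal repeat
#' comes first.
#'
#' @param region character string containing the array.
#' @param repeat_seq the (identical) repeat sequence.
#' @param array_id identifier stored on the result.
#' @param max_mismatch mismatch budget for a degenerate terminal repeat
#'   (applies to the last occurrence only; default 0 = exact everywhere).
#' @return object of class `CrisprArray`: list with `array_id`,
#'   `repeat_seq`, `spacers` (data.frame: index, seq, start, end; 0-based
#'   half-open, region coordinates), `repeat_starts`.
#' @export
parse_array <- function(region, repeat_seq, array_id = "array",
                        max_mismatch = 0L) {
  hits <- Biostrings::matchPattern(repeat_seq, Biostrings::DNAString(region),
                                   max.mismatch = max_mismatch)
  st <- IRanges::start(hits) - 1L    # to 0-based
  if (max_mismatch > 0L && length(st) > 0L) {
    # only the terminal occurrence may be degenerate: keep exact hits plus,
    # if distinct, the right-most inexact hit
    exact <- IRanges::start(Biostrings::matchPattern(
      repeat_seq, Biostrings::DNAString(region))) - 1L
    inexact <- setdiff(st, exact)
    st <- sort(unique(c(exact, if (length(inexact)) max(inexact))))
  }
  # leftmost-greedy non-overlapping selection
  keep <- integer(0)
  last_end <- -1L
  for (s in sort(st)) {
    if (s >= last_end) {
      keep <- c(keep, s)
      last_end <- s + nchar(repeat_seq)
    }
  }
  if (length(keep) < 2L)
    stop_input("parse_array: fewer than 2 repeat occurrences (%d found)",
               length(keep))
  w <- nchar(repeat_seq)
  sp_start <- keep[-length(keep)] + w
  sp_end <- keep[-1L]
  nonempty <- sp_end > sp_start
  sp_start <- sp_start[nonempty]; sp_end <- sp_end[nonempty]
  spacers <- data.frame(
    index = seq_along(sp_start),
    seq = substring(region, sp_start + 1L, sp_end),
    start = sp_start, end = sp_end,
    stringsAsFactors = FALSE)
  structure(list(array_id = array_id, repeat_seq = repeat_seq,
                 spacers = spacers, repeat_starts = keep),
            class = "CrisprArray")
}

#' @export
print.CrisprArray <- function(x, ...) {
  cat(sprintf("CrisprArray '%s': %d spacers, repeat %s (%d bp)\n",
              x$array_id, nrow(x$spacers), x$repeat_seq,
              nchar(x$repeat_seq)))
  invisible(x)
}

#' Extract the flank at the cas2-distal end of an array
#'
#' For screening CRISPR arrays suspected to be oriented opposite to cas2
#' (as in type II-C systems): returns `length` bp adjacent to the
#' cas2-distal end of the array, oriented toward the array, i.e. the
#' reverse complement of the genomic segment downstream of the array.
#'
#' @param genome contig sequence.
#' @param start,end 0-based half-open array interval.
#' @param strand strand on which cas2 and leader sit upstream of the
#'   array (`"+"`: distal end is `end`; `"-"`: distal end is `start`).
#' @param length flank length (default 300).
#' @return list with `seq`, `truncated`.
#' @export
extract_opposite_flank <- function(genome, start, end, strand = "+",
                                   length = 300L) {
  L <- nchar(genome)
  if (start < 0L || end > L || start >= end)
    stop_input("array interval [%d,%d) outside contig of length %d",
               start, end, L)
  if (strand == "+") {
    to <- min(end + length, L)
    seq <- revcomp(slice0(genome, end, to))
    truncated <- (to - end) < length
  } else {
    from <- max(start - length, 0L)
    seq <- slice0(genome, from, start)
    truncated <- (start - from) < length
  }
  list(seq = seq, truncated = truncated)
}
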
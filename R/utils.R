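#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   readDNAStringSet writeXStringSet matchPattern
#' @importFrom IRanges IRanges reduce findOverlaps start end width
#' @importFrom S4Vectors mcols
#' @importFrom stats rmultinom rpois runif setNames
#' @importFrom utils read.table write.table
NULL

#' Reverse complement of a DNA string
#'
#' Thin character-level wrapper around [Biostrings::reverseComplement()].
#'
#' @param x single character string over A/C/G/T/N.
#' @return reverse complement as a character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Derived per-stage RNG stream: keeps stages independent under one master
# seed.  Result stays below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.double(seed) * 7919 + 104729 * stage) %% 2147483647)
}

# 0-based half-open slice of a genome string: genome[start, end)
slice0 <- function(genome, start, end) {
  substr(genome, start + 1L, end)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# All w-mers of a sequence as a character vector (offsets 0-based).
kmers <- function(seq, w) {
  L <- nchar(seq)
  if (L < w) return(character(0))
  starts <- seq_len(L - w + 1L)
  substring(seq, starts, starts + w - 1L)
}

# Encode A/C/G/T as 1..4; anything else (incl. N) as NA so it never matches.
encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
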
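#' Spacer-to-peak assignment via Cascade seed and PAM matching
#'
#' Cascade (the type I-E effector) binds chromosomal off-target sites with
#' very limited base pairing: a protospacer-adjacent motif (PAM, here AWG,
#' i.e. AAG or ATG) plus the PAM-proximal "seed" of the crRNA spacer.
#' ChIP-seq binding regions are therefore matched to spacers using two
#' modes:
#'
#' * `PAM_SEED5` — a PAM (AAG/ATG) immediately 5' of an exact match to
#'   spacer positions 1-5;
#' * `SEED5_78` — an exact match to spacer positions 1-5 and 7-8 (any base
#'   at position 6), with no PAM required.
#'
#' A peak is assigned a spacer only when exactly one spacer identity
#' matches anywhere in its region.
#'
#' @name spacer_assignment
NULL

#' Build fixed-width regions around peak positions
#'
#' Each input peak position p yields the width-bp window centered on p.
#' Overlapping or abutting windows on the same contig are merged and the
#' floor of the merged-interval midpoint becomes the "peak center" used
#' for coverage readout.  Regions are clipped at contig bounds.
#'
#' @param positions integer vector of 0-based peak positions.
#' @param width odd region width (default 101).
#' @param contig_length optional contig length for clipping.
#' @return data.frame with `start`, `end` (0-based half-open), `center`,
#'   and `n_input` (how many input peaks merged into the region).
#' @export
build_regions <- function(positions, width = 101L, contig_length = NULL) {
  stopifnot(width %% 2L == 1L)
  if (length(positions) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      center = integer(0), n_input = integer(0)))
  half <- (width - 1L) %/% 2L
  ir <- IRanges::IRanges(start = positions - half, width = width)
  merged <- IRanges::reduce(ir, with.revmap = TRUE)
  n_input <- lengths(S4Vectors::mcols(merged)$revmap)
  start <- IRanges::start(merged)
  end <- IRanges::end(merged) + 1L  # half-open
  if (!is.null(contig_length)) {
    start <- pmax(start, 0L)
    end <- pmin(end, contig_length)
  } else {
    start <- pmax(start, 0L)
  }
  data.frame(start = start, end = end,
             center = (start + end) %/% 2L,
             n_input = n_input)
}

# Match one fixed pattern (vector of codes 1..4, NA = wildcard position)
# at every offset of an encoded sequence.  Returns 0-based offsets.
# Encoded-sequence NAs (N bases) never match.
match_coded <- function(enc, pat) {
  L <- length(enc); w <- length(pat)
  if (L < w) return(integer(0))
  n_off <- L - w + 1L
  ok <- rep(TRUE, n_off)
  for (j in seq_len(w)) {
    if (is.na(pat[j])) next       # wildcard column
    x <- enc[j:(j + n_off - 1L)]
    ok <- ok & !is.na(x) & x == pat[j]
  }
  which(ok) - 1L
}

# complement of encoded bases (A=1 <-> T=4, C=2 <-> G=3); NA stays NA
rc_coded <- function(enc) 5L - rev(enc)

# Precompile the per-spacer encoded search patterns for both modes and
# strands.  Done once per spacer set; matching a region is then pure
# integer comparison.
compile_patterns <- function(spacers, pams = c("AAG", "ATG")) {
  spacers <- as_spacer_df(spacers)
  if (any(nchar(spacers$seq) < 8L))
    stop_input("all spacers must be >= 8 nt (position 1-5 seed + 7-8)")
  pam_enc <- lapply(pams, encode_dna)
  pats <- list()
  for (i in seq_len(nrow(spacers))) {
    sp <- spacers$seq[i]
    id <- spacers$spacer_id[i]
    seed5 <- encode_dna(substr(sp, 1L, 5L))
    seed578 <- c(seed5, NA_integer_, encode_dna(substr(sp, 7L, 8L)))
    for (k in seq_along(pams)) {
      fwdpat <- c(pam_enc[[k]], seed5)
      pats[[length(pats) + 1L]] <- list(id = id, mode = "PAM_SEED5",
                                        strand = "+", pam = pams[k],
                                        pat = fwdpat)
      pats[[length(pats) + 1L]] <- list(id = id, mode = "PAM_SEED5",
                                        strand = "-", pam = pams[k],
                                        pat = rc_coded(fwdpat))
    }
    pats[[length(pats) + 1L]] <- list(id = id, mode = "SEED5_78",
                                      strand = "+", pam = NA_character_,
                                      pat = seed578)
    pats[[length(pats) + 1L]] <- list(id = id, mode = "SEED5_78",
                                      strand = "-", pam = NA_character_,
                                      pat = rc_coded(seed578))
  }
  list(spacers = spacers, patterns = pats)
}

match_compiled <- function(enc_region, compiled) {
  ids <- character(0); modes <- character(0); strands <- character(0)
  offs <- integer(0); pam_out <- character(0)
  for (p in compiled$patterns) {
    off <- match_coded(enc_region, p$pat)
    if (length(off)) {
      ids <- c(ids, rep(p$id, length(off)))
      modes <- c(modes, rep(p$mode, length(off)))
      strands <- c(strands, rep(p$strand, length(off)))
      offs <- c(offs, off)
      pam_out <- c(pam_out, rep(p$pam, length(off)))
    }
  }
  data.frame(spacer_id = ids, mode = modes, strand = strands,
             offset = offs, pam = pam_out, stringsAsFactors = FALSE)
}

#' Find seed/PAM matches of spacers within a region sequence
#'
#' Scans both strands of `region_seq` for the two Cascade match modes.
#' All hits are returned; a `PAM_SEED5` hit does not suppress an
#' overlapping `SEED5_78` hit for a different spacer.  Offsets are
#' 0-based positions of the match start on the forward strand of the
#' region (for minus-strand hits, the leftmost base of the matched
#' segment in forward coordinates).  N bases never match.
#'
#' @param region_seq region sequence (character).
#' @param spacers data.frame with columns `spacer_id` and `seq`
#'   (spacer position 1 = PAM-proximal 5' end), or a character vector
#'   (names used as ids).
#' @param pams allowed PAM 3-mers (default AAG/ATG, the AWG consensus).
#' @return data.frame: `spacer_id`, `mode` (`PAM_SEED5`/`SEED5_78`),
#'   `strand`, `offset`, `pam` (`NA` for SEED5_78 hits).
#' @export
find_matches <- function(region_seq, spacers, pams = c("AAG", "ATG")) {
  compiled <- compile_patterns(spacers, pams)
  res <- match_compiled(encode_dna(region_seq), compiled)
  res[order(res$offset, res$spacer_id, res$mode, res$strand), ,
      drop = FALSE]
}

# Normalize spacer input to a data.frame(spacer_id, seq); spacers with
# identical sequence collapse to a single candidate identity so exact
# duplicates cannot force spurious ambiguity.
as_spacer_df <- function(spacers, collapse_duplicates = TRUE) {
  if (is.character(spacers)) {
    ids <- names(spacers)
    if (is.null(ids)) ids <- paste0("spacer", seq_along(spacers))
    spacers <- data.frame(spacer_id = ids, seq = unname(spacers),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("spacer_id", "seq") %in% names(spacers)))
  spacers$seq <- toupper(spacers$seq)
  if (collapse_duplicates) spacers <- spacers[!duplicated(spacers$seq), ,
                                              drop = FALSE]
  spacers
}

#' Collect the spacers of one or more CRISPR arrays into a table
#'
#' @param arrays list of `CrisprArray` objects (or a single one).
#' @return data.frame with `spacer_id` (`"<array_id>:<index>"`), `array_id`,
#'   `index`, `seq`.
#' @export
spacer_table <- function(arrays) {
  if (inherits(arrays, "CrisprArray")) arrays <- list(arrays)
  do.call(rbind, lapply(arrays, function(a) {
    data.frame(spacer_id = paste0(a$array_id, ":", a$spacers$index),
               array_id = a$array_id, index = a$spacers$index,
               seq = a$spacers$seq, stringsAsFactors = FALSE)
  }))
}

#' Assign spacers to peak regions
#'
#' For each region, the candidate set is the set of distinct spacer
#' identities with at least one match (either mode, either strand)
#' anywhere in the region.  Status is `unique` (exactly one candidate,
#' the assignment), `unassigned` (none) or `ambiguous` (several).
#'
#' @param regions data.frame from [build_regions()].
#' @param genome contig sequence the regions index into.
#' @param spacers spacer table (see [find_matches()]).
#' @param pams allowed PAM 3-mers.
#' @return data.frame: regions plus `status`, `spacer_id` (NA unless
#'   unique), `candidates` (comma-separated), `n_candidates`, and
#'   `provenance` (`direct_unique` for unique rows).  Attribute
#'   `summary` holds total and uniquely assigned counts.
#' @export
assign_peaks <- function(regions, genome, spacers, pams = c("AAG", "ATG")) {
  compiled <- compile_patterns(spacers, pams)
  n <- nrow(regions)
  status <- character(n); sid <- rep(NA_character_, n)
  cands <- character(n); ncand <- integer(n)
  for (i in seq_len(n)) {
    seq <- slice0(genome, regions$start[i], regions$end[i])
    m <- match_compiled(encode_dna(seq), compiled)
    cc <- sort(unique(m$spacer_id))
    ncand[i] <- length(cc)
    cands[i] <- paste(cc, collapse = ",")
    if (length(cc) == 1L) {
      status[i] <- "unique"; sid[i] <- cc
    } else if (length(cc) == 0L) status[i] <- "unassigned"
    else status[i] <- "ambiguous"
  }
  out <- cbind(regions,
               data.frame(status = status, spacer_id = sid,
                          candidates = cands, n_candidates = ncand,
                          provenance = ifelse(status == "unique",
                                              "direct_unique", NA_character_),
                          stringsAsFactors = FALSE))
  attr(out, "summary") <- c(total = n,
                            unique = sum(status == "unique"),
                            ambiguous = sum(status == "ambiguous"),
                            unassigned = sum(status == "unassigned"))
  out
}
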
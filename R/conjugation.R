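#' Pooled-conjugation interference quantification
#'
#' Reads from a pooled plasmid-transfer assay are assigned to
#' protospacer-containing plasmids by exact match to a 10-nt tag within
#' each protospacer.  Plasmids with fewer than 50 reads in the
#' interference-free (Delta-cascade) recipient in either replicate are
#' discarded.  Normalized conjugation efficiency doubly normalizes each
#' count: first to the Delta-cascade count for the same plasmid, then to
#' the same ratio for a control plasmid lacking a protospacer, expressed
#' in percent.
#'
#' @name conjugation
NULL

#' Select unique 10-nt tags within protospacers
#'
#' The default tag is the centered 10-mer of each protospacer.  On a
#' collision (within the set or with the optional control sequence), the
#' window is shifted outward one base at a time (left, then right, then
#' two left, ...) until all tags are unique.  Protospacers with identical
#' sequence are collapsed to a single reference identity first.
#'
#' @param protospacers named character vector or data.frame with `id`,
#'   `seq`; each sequence >= `tag_length` nt.
#' @param tag_length tag width (default 10).
#' @param control_seq optional control-construct sequence tags must also
#'   avoid.
#' @return data.frame: `id`, `seq`, `tag`, `tag_offset` (0-based).
#' @export
select_tags <- function(protospacers, tag_length = 10L,
                        control_seq = NULL) {
  if (is.character(protospacers))
    protospacers <- data.frame(id = names(protospacers),
                               seq = unname(protospacers),
                               stringsAsFactors = FALSE)
  stopifnot(all(c("id", "seq") %in% names(protospacers)))
  protospacers <- protospacers[!duplicated(protospacers$seq), , drop = FALSE]
  if (any(nchar(protospacers$seq) < tag_length))
    stop_input("all protospacers must be >= %d nt", tag_length)
  forbidden <- character(0)
  if (!is.null(control_seq)) forbidden <- kmers(control_seq, tag_length)
  n <- nrow(protospacers)
  tags <- character(n); offs <- integer(n)
  taken <- forbidden
  for (i in seq_len(n)) {
    s <- protospacers$seq[i]
    L <- nchar(s)
    center <- (L - tag_length) %/% 2L
    deltas <- c(0L, as.vector(rbind(-seq_len(L), seq_len(L))))
    cand_off <- center + deltas
    cand_off <- cand_off[cand_off >= 0L & cand_off <= L - tag_length]
    placed <- FALSE
    for (o in cand_off) {
      tg <- substr(s, o + 1L, o + tag_length)
      others <- unlist(lapply(protospacers$seq[-i], kmers, w = tag_length))
      if (!(tg %in% taken) && !(tg %in% others)) {
        tags[i] <- tg; offs[i] <- o; taken <- c(taken, tg)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop_input("no unique %d-mer tag available for protospacer '%s'",
                 tag_length, protospacers$id[i])
  }
  data.frame(id = protospacers$id, seq = protospacers$seq, tag = tags,
             tag_offset = offs, stringsAsFactors = FALSE)
}

#' Count reads per protospacer by exact tag match
#'
#' A read increments a protospacer's count iff exactly one tag occurs as
#' an exact substring of the read in either orientation (the read as
#' sequenced or its reverse complement).  Reads matching zero or several
#' tags are tallied, not silently dropped.
#'
#' @param reads character vector of read sequences, or a path to a
#'   FASTQ/FASTA file (read with [Biostrings::readDNAStringSet()]).
#' @param refs tag table from [select_tags()].
#' @return list: `counts` (named integer per protospacer id),
#'   `unmatched`, `multi_tag` (read tallies).
#' @export
count_reads <- function(reads, refs) {
  if (length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", reads)) "fastq" else "fasta"
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = fmt))
  }
  stopifnot(!anyDuplicated(refs$tag))
  nr <- length(reads)
  hit <- matrix(FALSE, nrow = nr, ncol = nrow(refs))
  for (j in seq_len(nrow(refs))) {
    tg <- refs$tag[j]
    hit[, j] <- grepl(tg, reads, fixed = TRUE) |
      grepl(revcomp(tg), reads, fixed = TRUE)
  }
  nhit <- rowSums(hit)
  counts <- integer(nrow(refs))
  one <- nhit == 1L
  if (any(one)) {
    idx <- max.col(hit[one, , drop = FALSE])
    tb <- tabulate(idx, nbins = nrow(refs))
    counts <- tb
  }
  list(counts = stats::setNames(as.integer(counts), refs$id),
       unmatched = sum(nhit == 0L),
       multi_tag = sum(nhit > 1L))
}

#' Drop plasmids with too few interference-free reads
#'
#' A protospacer plasmid is retained iff it has at least `threshold`
#' reads in the `control_sample` (Delta-cascade) in every replicate;
#' exactly `threshold` reads is retained.  The control plasmid is always
#' retained.
#'
#' @param counts long data.frame with `protospacer_id`, `sample`,
#'   `replicate`, `count`.
#' @param threshold minimum read count (default 50).
#' @param control_sample name of the interference-free sample.
#' @param control_id id of the no-protospacer control plasmid.
#' @return list: `counts` (filtered table), `dropped` (ids).
#' @export
filter_low <- function(counts, threshold = 50L,
                       control_sample = "dcascade",
                       control_id = "control") {
  cc <- counts[counts$sample == control_sample, , drop = FALSE]
  if (nrow(cc) == 0L) stop_input("no rows for sample '%s'", control_sample)
  keep_tab <- tapply(cc$count, cc$protospacer_id,
                     function(x) all(x >= threshold))
  keep_ids <- names(keep_tab)[keep_tab]
  keep_ids <- union(keep_ids, control_id)
  dropped <- setdiff(unique(counts$protospacer_id), keep_ids)
  list(counts = counts[counts$protospacer_id %in% keep_ids, , drop = FALSE],
       dropped = dropped)
}

#' Normalized conjugation efficiency (%)
#'
#' eff(p, strain, rep) = (count(p, strain, rep) / count(p, dcascade,
#' rep)) / (count(control, strain, rep) / count(control, dcascade, rep))
#' * 100.  The control plasmid therefore scores exactly 100% in every
#' sample, and per-sample depth rescaling leaves efficiencies unchanged.
#'
#' @param counts filtered long table (see [filter_low()]).
#' @param control_sample interference-free sample name.
#' @param control_id control-plasmid id.
#' @return data.frame: `protospacer_id`, `sample`, `replicate`,
#'   `efficiency` (percent), plus per-protospacer/sample `min`/`max`
#'   range across replicates in attribute `"range"`.
#' @export
normalize_efficiency <- function(counts, control_sample = "dcascade",
                                 control_id = "control") {
  key <- function(id, s, r) paste(id, s, r, sep = "\r")
  lut <- stats::setNames(counts$count,
                         key(counts$protospacer_id, counts$sample,
                             counts$replicate))
  strains <- setdiff(unique(counts$sample), control_sample)
  ids <- unique(counts$protospacer_id)
  reps <- sort(unique(counts$replicate))
  rows <- list()
  for (s in strains) for (r in reps) {
    ctrl_num <- lut[[key(control_id, s, r)]]
    ctrl_den <- lut[[key(control_id, control_sample, r)]]
    if (is.null(ctrl_num) || is.null(ctrl_den) || ctrl_num == 0 ||
        ctrl_den == 0)
      stop_input("zero or missing control-plasmid count in %s rep %d", s, r)
    for (p in ids) {
      num <- lut[[key(p, s, r)]]
      den <- lut[[key(p, control_sample, r)]]
      if (is.null(num) || is.null(den)) next
      if (den == 0)
        stop_input("zero %s count for '%s' rep %d (filter first)",
                   control_sample, p, r)
      rows[[length(rows) + 1L]] <- data.frame(
        protospacer_id = p, sample = s, replicate = r,
        efficiency = (num / den) / (ctrl_num / ctrl_den) * 100,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  rng <- do.call(rbind, lapply(split(out, list(out$protospacer_id,
                                               out$sample), drop = TRUE),
                               function(d) data.frame(
                                 protospacer_id = d$protospacer_id[1],
                                 sample = d$sample[1],
                                 min = min(d$efficiency),
                                 max = max(d$efficiency),
                                 stringsAsFactors = FALSE)))
  rownames(rng) <- NULL
  attr(out, "range") <- rng
  out
}
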
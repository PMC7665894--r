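# Independent brute-force oracles and shared (memoized) fixtures.

# character-level reverse complement, independent of the package helper
rc_chr <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(x, "")[[1]]]), collapse = "")
}

# Brute-force matcher: enumerate every offset x strand x spacer x mode
# with plain substring comparisons.  Kept deliberately naive.
oracle_find_matches <- function(region, spacers, pams = c("AAG", "ATG")) {
  if (is.character(spacers))
    spacers <- data.frame(spacer_id = names(spacers),
                          seq = unname(spacers), stringsAsFactors = FALSE)
  spacers <- spacers[!duplicated(spacers$seq), , drop = FALSE]
  rows <- list()
  L <- nchar(region)
  eq_exact <- function(a, b) {
    a == b && !grepl("N", a, fixed = TRUE)
  }
  for (i in seq_len(nrow(spacers))) {
    sp <- spacers$seq[i]
    seed5 <- substr(sp, 1, 5)
    p78 <- substr(sp, 7, 8)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") region else rc_chr(region)
      for (o in 0:(L - 1)) {
        # PAM_SEED5: 3-mer PAM then seed5 starting at o (0-based on s)
        if (o + 8 <= L) {
          pam <- substr(s, o + 1, o + 3)
          if (pam %in% pams &&
              eq_exact(substr(s, o + 4, o + 8), seed5)) {
            fo <- if (strand == "+") o else L - (o + 8)
            rows[[length(rows) + 1]] <- data.frame(
              spacer_id = spacers$spacer_id[i], mode = "PAM_SEED5",
              strand = strand, offset = fo, pam = pam,
              stringsAsFactors = FALSE)
          }
        }
        # SEED5_78: seed5, any base, positions 7-8, starting at o
        if (o + 8 <= L) {
          if (eq_exact(substr(s, o + 1, o + 5), seed5) &&
              substr(s, o + 6, o + 6) %in% c("A", "C", "G", "T") &&
              eq_exact(substr(s, o + 7, o + 8), p78)) {
            fo <- if (strand == "+") o else L - (o + 8)
            rows[[length(rows) + 1]] <- data.frame(
              spacer_id = spacers$spacer_id[i], mode = "SEED5_78",
              strand = strand, offset = fo, pam = NA_character_,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(spacer_id = character(0), mode = character(0),
                      strand = character(0), offset = integer(0),
                      pam = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# O(L^2) all-pairs recurring 15-mer oracle
oracle_first_repeat15 <- function(seq, width = 15) {
  L <- nchar(seq)
  if (L < 2 * width) {
    # still possible to have overlapping recurrence when L >= width + 1
  }
  for (p in 0:(L - width)) {
    a <- substr(seq, p + 1, p + width)
    if (grepl("N", a, fixed = TRUE)) next
    if (p + width <= L - 1) {
      for (q in (p + 1):(L - width)) {
        if (substr(seq, q + 1, q + width) == a) return(p)
      }
    }
  }
  NA_integer_
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# memoized fixtures (shared across test files)
.fixtures <- new.env(parent = emptyenv())

fixture_sim_small <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- make_crispr_genome(sim_config(
      seed = 7L, genome_length = 30000L,
      arrays = list(array_spec("A", 3L), array_spec("B", 3L)),
      offtargets_per_spacer = 2L))
  }
  .fixtures$small
}

fixture_sim_profile <- function() {
  if (is.null(.fixtures$profile)) {
    .fixtures$profile <- make_crispr_genome(sim_config(
      seed = 3L, genome_length = 120000L,
      arrays = list(array_spec("CRISPR-I", 8L),
                    array_spec("CRISPR-II", 23L)),
      offtargets_per_spacer = 3L))
  }
  .fixtures$profile
}

fixture_assigned_profile <- function() {
  if (is.null(.fixtures$assigned)) {
    sim <- fixture_sim_profile()
    reg <- build_regions(sim$sites$center,
                         contig_length = nchar(sim$genome))
    .fixtures$assigned <- assign_peaks(reg, sim$genome, sim$spacers)
  }
  .fixtures$assigned
}
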
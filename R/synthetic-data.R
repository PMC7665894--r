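#' Synthetic data emulating Rho termination along CRISPR arrays
#'
#' The generator builds a genome carrying CRISPR arrays and planted
#' Cascade off-target sites (PAM + 5-nt seed constructs), simulates
#' per-spacer crRNA abundance under a survival model of Rho termination
#' (with or without BoxA-mediated antitermination), produces
#' strand-resolved ChIP-like coverage with counting noise, multinomial
#' pooled-conjugation read counts, and genus flank sets with a planted
#' boxA-like motif.  Every stage returns ground truth for
#' parameter-recovery tests.
#'
#' @name synthetic_data
NULL

#' Specification of one synthetic CRISPR array
#'
#' @param array_id identifier.
#' @param n_spacers number of spacers (>= 1).
#' @param spacer_length spacer length in bp (>= 8).
#' @param repeat_seq repeat sequence; `NULL` draws a random repeat.
#' @param repeat_length repeat length when drawn.
#' @param leader_length leader length upstream of the first repeat.
#' @param boxa_seq boxA element planted in the leader.
#' @param boxa_offset distance (bp) from boxA start to the first repeat.
#' @return list of class `array_spec`.
#' @export
array_spec <- function(array_id, n_spacers, spacer_length = 32L,
                       repeat_seq = NULL, repeat_length = 29L,
                       leader_length = 100L,
                       boxa_seq = "TGCTCTTTAACA", boxa_offset = 40L) {
  stopifnot(n_spacers >= 1L, spacer_length >= 8L,
            boxa_offset >= nchar(boxa_seq),
            leader_length >= boxa_offset)
  n_spacers <- as.integer(n_spacers)
  spacer_length <- as.integer(spacer_length)
  structure(list(array_id = array_id, n_spacers = n_spacers,
                 spacer_length = spacer_length, repeat_seq = repeat_seq,
                 repeat_length = repeat_length,
                 leader_length = leader_length, boxa_seq = boxa_seq,
                 boxa_offset = boxa_offset),
            class = "array_spec")
}

#' Simulation configuration
#'
#' Defaults emulate the two-array layout of the studied type I-E system:
#' a short first array and a 23-spacer second array whose leader-distal
#' spacers are the ones lost to premature termination when boxA is
#' mutated.
#'
#' @param seed master RNG seed; per-stage streams are derived from it.
#' @param genome_length genome size in bp.
#' @param arrays list of [array_spec()]s.
#' @param offtargets_per_spacer planted off-target sites per spacer.
#' @param pams PAM 3-mers used for planted sites (AWG consensus).
#' @param fidelity_78 probability that planted positions 7-8 copy the
#'   spacer (1 = always, giving both match modes at each site).
#' @param depth expected reads per fully-transcribed site.
#' @param noise counting-noise family, `"poisson"` or `"none"`.
#' @param background_rate per-strand per-position background rate.
#' @param unique_seeds make all spacer seeds (positions 1-5) distinct so
#'   planted sites are mutually distinguishable.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 60000L,
                       arrays = list(
                         array_spec("CRISPR-I", n_spacers = 8L),
                         array_spec("CRISPR-II", n_spacers = 23L)),
                       offtargets_per_spacer = 2L,
                       pams = c("AAG", "ATG"),
                       fidelity_78 = 1,
                       depth = 200,
                       noise = "poisson",
                       background_rate = 0.5,
                       unique_seeds = TRUE) {
  stopifnot(genome_length > 0L, offtargets_per_spacer >= 0L,
            fidelity_78 >= 0, fidelity_78 <= 1)
  structure(list(seed = seed, genome_length = genome_length,
                 arrays = arrays,
                 offtargets_per_spacer = offtargets_per_spacer,
                 pams = pams, fidelity_78 = fidelity_78, depth = depth,
                 noise = noise, background_rate = background_rate,
                 unique_seeds = unique_seeds),
            class = "sim_config")
}

# Build the sequence of one array and bookkeeping offsets (array-local,
# 0-based): leader with embedded boxA, then R S1 R S2 ... Sn R.
build_array_seq <- function(spec, spacer_seqs) {
  leader <- random_dna(spec$leader_length)
  boxa_start <- spec$leader_length - spec$boxa_offset
  substr(leader, boxa_start + 1L,
         boxa_start + nchar(spec$boxa_seq)) <- spec$boxa_seq
  rep_seq <- spec$repeat_seq
  if (is.null(rep_seq)) rep_seq <- random_dna(spec$repeat_length)
  body <- paste0(rep_seq,
                 paste(vapply(spacer_seqs,
                              function(s) paste0(s, rep_seq), ""),
                       collapse = ""))
  w <- nchar(rep_seq); sl <- nchar(spacer_seqs[1])
  sp_start <- spec$leader_length + w + (seq_along(spacer_seqs) - 1L) *
    (w + sl)
  list(seq = paste0(leader, body), repeat_seq = rep_seq,
       boxa_start = boxa_start,
       spacer_starts = sp_start,
       length = spec$leader_length + nchar(body))
}

#' Generate a synthetic genome with CRISPR arrays and planted off-targets
#'
#' Arrays are placed on the forward strand with margins; for every spacer,
#' `offtargets_per_spacer` sites are planted in the background, each a
#' PAM 3-mer immediately 5' of spacer positions 1-5 (exact), positions
#' 7-8 copied with probability `fidelity_78`, remaining positions random,
#' on a random strand.  Planted sites are non-overlapping, at least
#' 160 bp apart, and (when `unique_seeds`) each site's 101-bp window
#' matches exactly one spacer identity, verified against the package's
#' own matcher and re-randomized on collision.
#'
#' @param config a [sim_config()].
#' @return list of class `crispr_sim`: `genome` (character), `arrays`
#'   (list: per array the `CrisprArray`-style info plus genomic
#'   coordinates), `spacers` (table with `spacer_id`, `array_id`,
#'   `index`, `seq`), `sites` (ground-truth table: `chrom`, `start`
#'   0-based, `strand`, `spacer_id`, `pam`, `construct`, `center`),
#'   `config`.
#' @export
make_crispr_genome <- function(config = sim_config()) {
  set.seed(derive_seed(config$seed, 1L))
  n_total <- sum(vapply(config$arrays, function(a) a$n_spacers, 0L))
  # spacer seeds (positions 1-5) distinct across all arrays by default
  if (config$unique_seeds) {
    all5 <- expand.grid(rep(list(c("A", "C", "G", "T")), 5L),
                        stringsAsFactors = FALSE)
    pool <- do.call(paste0, all5)
    seeds <- sample(pool, n_total)
  } else {
    seeds <- vapply(seq_len(n_total), function(i) random_dna(5L), "")
  }
  k <- 0L
  spacer_rows <- list(); built <- list()
  for (a in config$arrays) {
    sp <- vapply(seq_len(a$n_spacers), function(i) {
      k_i <- k + i
      paste0(seeds[k_i], random_dna(a$spacer_length - 5L))
    }, "")
    k <- k + a$n_spacers
    b <- build_array_seq(a, sp)
    b$spec <- a; b$spacer_seqs <- sp
    built[[a$array_id]] <- b
  }
  # place arrays sequentially with 1 kb margins
  pos <- 1000L
  genome <- random_dna(config$genome_length)
  arrays_out <- list()
  occupied <- IRanges::IRanges()   # intervals sites must avoid (1-based)
  for (id in names(built)) {
    b <- built[[id]]
    if (pos + b$length + 1000L > config$genome_length)
      stop_input("genome_length %d too small for arrays", config$genome_length)
    substr(genome, pos + 1L, pos + b$length) <- b$seq
    spacers <- data.frame(
      index = seq_along(b$spacer_seqs), seq = b$spacer_seqs,
      start = pos + b$spacer_starts,
      end = pos + b$spacer_starts + nchar(b$spacer_seqs),
      stringsAsFactors = FALSE)
    arrays_out[[id]] <- list(
      array_id = id, start = pos, end = pos + b$length, strand = "+",
      leader_start = pos, leader_end = pos + b$spec$leader_length,
      boxa_start = pos + b$boxa_start,
      boxa_end = pos + b$boxa_start + nchar(b$spec$boxa_seq),
      boxa_seq = b$spec$boxa_seq,
      repeat_seq = b$repeat_seq, spacers = spacers)
    occupied <- c(occupied,
                  IRanges::IRanges(pos + 1L - 200L, pos + b$length + 200L))
    pos <- pos + b$length + 1000L
    spacer_rows[[id]] <- data.frame(
      spacer_id = paste0(id, ":", spacers$index), array_id = id,
      index = spacers$index, seq = spacers$seq, stringsAsFactors = FALSE)
  }
  spacer_tab <- do.call(rbind, spacer_rows)
  rownames(spacer_tab) <- NULL

  # plant off-target sites
  n_sites <- nrow(spacer_tab) * config$offtargets_per_spacer
  sites <- NULL
  if (n_sites > 0L) {
    clen <- 3L + max(nchar(spacer_tab$seq))
    min_gap <- 160L
    starts <- integer(0)
    tries <- 0L
    while (length(starts) < n_sites) {
      tries <- tries + 1L
      if (tries > 200L * n_sites)
        stop_input("could not place %d sites in %d bp (capacity error)",
                   n_sites, config$genome_length)
      cand <- sample.int(config$genome_length - clen - 120L, 1L) + 60L
      iv <- IRanges::IRanges(cand - min_gap, cand + clen + min_gap)
      if (length(IRanges::findOverlaps(iv, occupied)) > 0L) next
      starts <- c(starts, cand)
      occupied <- c(occupied, iv)
    }
    site_rows <- list()
    idx <- 0L
    for (r in seq_len(nrow(spacer_tab))) {
      for (j in seq_len(config$offtargets_per_spacer)) {
        idx <- idx + 1L
        sp <- spacer_tab$seq[r]
        pam <- sample(config$pams, 1L)
        tail_len <- nchar(sp) - 5L
        tail <- random_dna(tail_len)
        if (tail_len >= 3L && stats::runif(1) < config$fidelity_78)
          substr(tail, 2L, 3L) <- substr(sp, 7L, 8L)
        construct <- paste0(pam, substr(sp, 1L, 5L), tail)
        strand <- sample(c("+", "-"), 1L)
        planted <- if (strand == "+") construct else revcomp(construct)
        st <- starts[idx]
        substr(genome, st + 1L, st + nchar(planted)) <- planted
        site_rows[[idx]] <- data.frame(
          chrom = "chr", start = st, strand = strand,
          spacer_id = spacer_tab$spacer_id[r], pam = pam,
          construct = construct,
          center = st + nchar(planted) %/% 2L,
          stringsAsFactors = FALSE)
      }
    }
    sites <- do.call(rbind, site_rows)
    rownames(sites) <- NULL
    if (config$unique_seeds) {
      scrubbed <- scrub_site_windows(genome, sites, spacer_tab, config$pams)
      genome <- scrubbed$genome
      sites <- scrubbed$sites
    }
  } else {
    sites <- data.frame(chrom = character(0), start = integer(0),
                        strand = character(0), spacer_id = character(0),
                        pam = character(0), construct = character(0),
                        center = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(genome = genome, arrays = arrays_out,
                 spacers = spacer_tab, sites = sites, config = config),
            class = "crispr_sim")
}

# Re-randomize each planted site's window (background plus the
# construct's free tail positions, keeping PAM, seed 1-5 and positions
# 7-8) until the window matches exactly its own spacer identity.
scrub_site_windows <- function(genome, sites, spacer_tab, pams) {
  compiled <- compile_patterns(spacer_tab, pams)
  for (i in seq_len(nrow(sites))) {
    st <- sites$start[i]
    clen <- nchar(sites$construct[i])
    ctr <- sites$center[i]
    for (attempt in 1:25) {
      ws <- max(ctr - 50L, 0L); we <- min(ctr + 51L, nchar(genome))
      m <- match_compiled(encode_dna(slice0(genome, ws, we)), compiled)
      cand <- unique(m$spacer_id)
      if (length(cand) == 1L && cand == sites$spacer_id[i]) break
      if (attempt == 25L)
        stop_input("could not make site %d uniquely matchable", i)
      for (p in ws:(we - 1L)) {
        if (p >= st && p < st + clen) next
        substr(genome, p + 1L, p + 1L) <- sample(c("A", "C", "G", "T"), 1L)
      }
      # free tail positions (1-based within construct): after PAM+seed5,
      # sparing 7-8 which carry the planted fidelity
      cst <- sites$construct[i]
      free <- setdiff(seq(9L, clen), c(3L + 7L, 3L + 8L))
      for (cp in free)
        substr(cst, cp, cp) <- sample(c("A", "C", "G", "T"), 1L)
      sites$construct[i] <- cst
      planted <- if (sites$strand[i] == "+") cst else revcomp(cst)
      substr(genome, st + 1L, st + clen) <- planted
    }
  }
  list(genome = genome, sites = sites)
}

#' Rho termination model along a CRISPR array
#'
#' Transcription initiating at the leader survives each inter-spacer
#' interval j with probability 1 - rho[j]; BoxA-mediated Nus-factor
#' antitermination lowers the hazard to `rho_protected`.  An optional
#' internal promoter adds initiation at spacer `internal_promoter_at`,
#' propagated downstream under the same survival process.
#'
#' @param rho per-interval termination probabilities (length = number of
#'   spacers; rho[j] acts between spacer j and j+1), all in \[0,1\].
#' @param boxa_intact logical; use `rho_protected` when TRUE.
#' @param rho_protected hazards under antitermination (default rho/10).
#' @param internal_promoter_at optional spacer index with added
#'   initiation.
#' @param internal_amount initiation amount a_k >= 0 at that spacer.
#' @return list of class `termination_model`.
#' @export
termination_model <- function(rho, boxa_intact = FALSE,
                              rho_protected = rho / 10,
                              internal_promoter_at = NULL,
                              internal_amount = 0) {
  stopifnot(all(rho >= 0 & rho <= 1),
            all(rho_protected >= 0 & rho_protected <= 1),
            length(rho_protected) == length(rho),
            internal_amount >= 0)
  structure(list(rho = rho, boxa_intact = boxa_intact,
                 rho_protected = rho_protected,
                 internal_promoter_at = internal_promoter_at,
                 internal_amount = internal_amount),
            class = "termination_model")
}

#' Per-spacer crRNA abundance under the termination survival model
#'
#' abundance_i = A0 * prod_(j<i) (1 - rho_j), plus the internal-promoter
#' contribution a_k * prod_(k<=j<i) (1 - rho_j) for spacers i >= k.
#'
#' @param model a [termination_model()].
#' @param n_spacers number of spacers (default `length(model$rho)`).
#' @param A0 initiation amount at the leader promoter.
#' @return numeric abundance vector of length `n_spacers`.
#' @export
simulate_crrna_abundance <- function(model, n_spacers = length(model$rho),
                                     A0 = 1) {
  rho <- if (model$boxa_intact) model$rho_protected else model$rho
  stopifnot(length(rho) >= n_spacers - 1L)
  surv <- cumprod(c(1, 1 - rho))        # surv[i] = prod_{j<i}(1-rho_j)
  ab <- A0 * surv[seq_len(n_spacers)]
  k <- model$internal_promoter_at
  if (!is.null(k) && model$internal_amount > 0) {
    extra <- numeric(n_spacers)
    for (i in k:n_spacers) {
      s <- if (i == k) 1 else prod(1 - rho[k:(i - 1L)])
      extra[i] <- model$internal_amount * s
    }
    ab <- ab + extra
  }
  ab
}

#' Simulate strand-resolved ChIP coverage over planted sites
#'
#' Each planted site gets a 60-bp symmetric footprint on both strands
#' whose strand-summed center height has expectation
#' `depth * abundance(spacer)`; background positions draw from a uniform
#' low-rate process.  With `noise = "poisson"` every position is an
#' independent Poisson draw around its expectation; `"none"` returns the
#' expectations themselves.
#'
#' @param sim a `crispr_sim` (or any list with `genome` and `sites`).
#' @param abundance named numeric vector, spacer_id -> relative crRNA
#'   abundance (A0 scale).
#' @param depth expected strand-summed reads at a site with abundance 1.
#' @param noise `"poisson"` or `"none"`.
#' @param background_rate expected background per strand per position.
#' @param footprint footprint width in bp.
#' @param library_size if set, the expected coverage is rescaled so each
#'   strand's expectations sum to `library_size`, emulating relative
#'   (per-library-normalized) coverage: removing signal (e.g. deleting
#'   an array) then inflates the remaining sites, as sequencing depth
#'   redistributes.
#' @param seed RNG seed for the draw.
#' @return list with numeric vectors `fwd` and `rev` (index = 0-based
#'   position + 1).
#' @export
simulate_chip_coverage <- function(sim, abundance,
                                   depth = sim$config$depth,
                                   noise = sim$config$noise,
                                   background_rate = sim$config$background_rate,
                                   footprint = 60L, library_size = NULL,
                                   seed = 1L) {
  set.seed(derive_seed(seed, 3L))
  L <- nchar(sim$genome)
  mu <- rep(background_rate, L)
  half <- footprint %/% 2L
  for (i in seq_len(nrow(sim$sites))) {
    sp <- sim$sites$spacer_id[i]
    if (!sp %in% names(abundance))
      stop_input("no abundance for spacer '%s'", sp)
    ctr <- sim$sites$center[i]
    from <- max(ctr - half, 0L) + 1L
    to <- min(ctr + half, L - 1L) + 1L
    mu[from:to] <- mu[from:to] + depth * abundance[[sp]] / 2
  }
  if (!is.null(library_size)) mu <- mu * (library_size / sum(mu))
  if (noise == "poisson") {
    fwd <- stats::rpois(L, mu); rev <- stats::rpois(L, mu)
  } else {
    fwd <- mu; rev <- mu
  }
  list(fwd = as.numeric(fwd), rev = as.numeric(rev))
}

#' Simulate pooled-conjugation read counts
#'
#' Emulates a pooled plasmid-transfer assay read out by amplicon
#' sequencing: a Delta-cascade recipient (no interference) samples the
#' pool proportions directly; interference-proficient recipients sample
#' proportions multiplied by per-protospacer transfer efficiencies.  A
#' control plasmid without a protospacer (efficiency 1) is always
#' included.  Counts are multinomial with `depth` reads per sample and
#' replicate.
#'
#' @param eff_wt named efficiencies in \[0,1\] for the boxA-intact
#'   recipient, one per protospacer.
#' @param eff_mut efficiencies for the boxA-mutant recipient (default
#'   `eff_wt`).
#' @param depth reads per sample.
#' @param proportions pool proportions (default uniform over
#'   protospacers + control).
#' @param n_replicates replicates per sample (default 2).
#' @param seed RNG seed.
#' @return data.frame: `protospacer_id` (including `"control"`),
#'   `sample` (`dcascade`, `boxA_wt`, `boxA_mut`), `replicate`, `count`.
#' @export
simulate_conjugation_counts <- function(eff_wt, eff_mut = eff_wt,
                                        depth = 1e5, proportions = NULL,
                                        n_replicates = 2L, seed = 1L) {
  stopifnot(all(eff_wt >= 0 & eff_wt <= 1), all(eff_mut >= 0 & eff_mut <= 1),
            !is.null(names(eff_wt)), identical(names(eff_wt), names(eff_mut)))
  set.seed(derive_seed(seed, 4L))
  ids <- c(names(eff_wt), "control")
  if (is.null(proportions)) proportions <- rep(1 / length(ids), length(ids))
  stopifnot(length(proportions) == length(ids))
  eff <- list(dcascade = rep(1, length(ids)),
              boxA_wt = c(unname(eff_wt), 1),
              boxA_mut = c(unname(eff_mut), 1))
  rows <- list()
  for (s in names(eff)) {
    p <- proportions * eff[[s]]
    p <- p / sum(p)
    for (r in seq_len(n_replicates)) {
      cnt <- as.integer(stats::rmultinom(1L, size = depth, prob = p))
      rows[[length(rows) + 1L]] <- data.frame(
        protospacer_id = ids, sample = s, replicate = r, count = cnt,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expand per-protospacer counts into synthetic amplicon reads
#'
#' Noiseless tag embedding for round-trip tests of the read counter:
#' each read is the full protospacer (hence its tag) embedded in random
#' flanking sequence.  The control plasmid gets a fixed synthetic
#' control sequence.
#'
#' @param counts data.frame for a single sample/replicate with
#'   `protospacer_id` and `count`.
#' @param refs data.frame `id`, `seq` of protospacers (see
#'   [select_tags()]); `"control"` handled internally.
#' @param read_length read length (default 75).
#' @param control_seq sequence embedded for control-plasmid reads.
#' @param seed RNG seed.
#' @return character vector of reads, in shuffled order.
#' @export
counts_to_reads <- function(counts, refs, read_length = 75L,
                            control_seq = NULL, seed = 1L) {
  set.seed(derive_seed(seed, 5L))
  if (is.null(control_seq)) control_seq <- random_dna(32L)
  seqs <- c(stats::setNames(refs$seq, refs$id), control = control_seq)
  reads <- character(0)
  for (i in seq_len(nrow(counts))) {
    id <- counts$protospacer_id[i]
    n <- counts$count[i]
    if (n == 0L) next
    insert <- seqs[[id]]
    pad <- read_length - nchar(insert)
    stopifnot(pad >= 0L)
    left <- sample.int(pad + 1L, n, replace = TRUE) - 1L
    reads <- c(reads, vapply(left, function(l) {
      paste0(random_dna(l), insert, random_dna(pad - l))
    }, ""))
  }
  sample(reads)
}

#' Generate a genus flank set with a planted boxA-like motif
#'
#' Emulates the cas2-downstream flank collection of a phylogenetic boxA
#' screen: each flank is random sequence optionally carrying one exact
#' motif instance upstream of a planted 15-bp tandem repeat pair (the
#' start of a CRISPR array, which the trimming step removes).
#'
#' @param n number of flanks (one per genus).
#' @param motif planted motif string.
#' @param planting_fraction fraction of flanks carrying the motif;
#'   exactly `round(n * planting_fraction)` are planted.
#' @param flank_length flank length (default 300).
#' @param repeat_scheme `"all"` (every flank gets a tandem 15-bp repeat),
#'   `"planted_only"`, or `"none"`.
#' @param repeat_offset fixed repeat offset, or `NULL` for random in
#'   \[140, flank_length - 31\].
#' @param seed RNG seed.
#' @return data.frame: `genus`, `source_id`, `seq`, `motif_offset`
#'   (0-based; NA if unplanted), `repeat_offset` (NA if none).
#' @export
make_cas2_flank_set <- function(n = 187L, motif = "TGCTCTTTAACA",
                                planting_fraction = 52 / 187,
                                flank_length = 300L,
                                repeat_scheme = c("all", "planted_only",
                                                  "none"),
                                repeat_offset = NULL, seed = 1L) {
  repeat_scheme <- match.arg(repeat_scheme)
  stopifnot(nchar(motif) <= flank_length)
  set.seed(derive_seed(seed, 6L))
  n_planted <- round(n * planting_fraction)
  planted <- sort(sample.int(n, n_planted))
  w <- nchar(motif)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    seq <- random_dna(flank_length)
    is_planted <- i %in% planted
    put_repeat <- switch(repeat_scheme, all = TRUE,
                         planted_only = is_planted, none = FALSE)
    roff <- NA_integer_
    if (put_repeat) {
      roff <- if (is.null(repeat_offset))
        sample(140:(flank_length - 31L), 1L) else repeat_offset
      r15 <- random_dna(15L)
      # the repeat's last base must differ from the base preceding the
      # planting site, else the window one position upstream also
      # recurs and the trim point shifts left of the planted offset
      if (roff >= 1L) {
        prev <- substr(seq, roff, roff)
        while (substr(r15, 15L, 15L) == prev) r15 <- random_dna(15L)
      }
      substr(seq, roff + 1L, roff + 30L) <- paste0(r15, r15)
    }
    moff <- NA_integer_
    if (is_planted) {
      hi <- if (put_repeat) roff - w else flank_length - w
      moff <- sample.int(hi + 1L, 1L) - 1L
      substr(seq, moff + 1L, moff + w) <- motif
    }
    rows[[i]] <- data.frame(
      genus = sprintf("Genus%03d", i), source_id = sprintf("g%03d_1", i),
      seq = seq, motif_offset = moff, repeat_offset = roff,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
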
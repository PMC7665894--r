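#' boxA motif discovery upstream of CRISPR arrays
#'
#' A ZOOPS ("zero or one occurrence per sequence")
#' expectation-maximization motif finder over fixed-width position
#' probability matrices, run on the given strand only, with PWM scanning
#' and an end-to-end screen that deduplicates input genera, prepares
#' cas2 flanks, and reports per-genus motif calls.
#'
#' @name boxa_discovery
NULL

BASES <- c("A", "C", "G", "T")

#' Keep one record per genus
#'
#' Deterministic stand-in for arbitrary per-genus selection: the record
#' with the lexicographically first `source_id` within each genus.
#'
#' @param records data.frame with `genus` and `source_id` columns.
#' @return data.frame with one row per genus, ordered by genus.
#' @export
dedupe_by_genus <- function(records) {
  stopifnot(all(c("genus", "source_id") %in% names(records)))
  if (nrow(records) == 0L) return(records)
  ord <- order(records$genus, records$source_id)
  records <- records[ord, , drop = FALSE]
  out <- records[!duplicated(records$genus), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# encode sequences, reject non-ACGT
encode_set <- function(seqs) {
  enc <- lapply(seqs, encode_dna)
  if (any(vapply(enc, anyNA, TRUE)))
    stop_input("motif discovery requires A/C/G/T-only sequences")
  enc
}

# log motif-vs-background score of every window of one encoded sequence
window_llr <- function(enc, log_theta, log_bg) {
  L <- length(enc); w <- ncol(log_theta)
  n_off <- L - w + 1L
  llr <- numeric(n_off)
  for (j in seq_len(w)) {
    x <- enc[j:(j + n_off - 1L)]
    llr <- llr + log_theta[x, j] - log_bg[x]
  }
  llr
}

# Shared precomputation for a set of encoded sequences: pad to a common
# length with sentinel code 5 (contributes 0 and is masked), and cache,
# per motif column j, the gather indices of each base within the
# n x m_max window matrix.  This makes every EM iteration a handful of
# vectorized gathers.
em_workspace <- function(enc, w) {
  n <- length(enc)
  lens <- lengths(enc)
  L_max <- max(lens)
  m_max <- L_max - w + 1L
  E <- matrix(5L, nrow = n, ncol = L_max)
  for (s in seq_len(n)) E[s, seq_len(lens[s])] <- enc[[s]]
  m_s <- lens - w + 1L
  mask <- outer(m_s, seq_len(m_max), ">=")
  Ej <- vector("list", w)
  base_idx <- vector("list", w)
  for (j in seq_len(w)) {
    Ej[[j]] <- E[, j:(j + m_max - 1L), drop = FALSE]
    base_idx[[j]] <- lapply(1:4, function(b) which(Ej[[j]] == b))
  }
  base_counts_seq <- t(vapply(enc, function(e) tabulate(e, 4L),
                              numeric(4L)))
  list(n = n, w = w, m_s = m_s, m_max = m_max, mask = mask, Ej = Ej,
       base_idx = base_idx, base_counts_seq = base_counts_seq,
       base_counts = colSums(base_counts_seq))
}

em_run <- function(ws, theta0, bg0, gamma0, alpha, max_iter, tol) {
  theta <- theta0; bg <- bg0; gamma <- gamma0
  w <- ws$w; n <- ws$n; m_max <- ws$m_max
  ll_trace <- numeric(0)
  ll_old <- -Inf
  Z <- NULL; q <- NULL
  for (iter in seq_len(max_iter)) {
    lt <- rbind(log(theta), 0)        # row 5 = padding sentinel
    lb <- c(log(bg), 0)
    # E-step: log motif-vs-background ratio of every window
    llr <- matrix(0, nrow = n, ncol = m_max)
    for (j in seq_len(w)) {
      d <- lt[, j] - lb
      llr <- llr + d[ws$Ej[[j]]]
    }
    llr[!ws$mask] <- -Inf
    a <- log(gamma) - log(ws$m_s) + llr
    b <- log1p(-gamma)
    mx <- pmax(apply(a, 1L, max), b)
    ea <- exp(a - mx)
    denom <- rowSums(ea) + exp(b - mx)
    Z <- ea / denom
    q <- rowSums(Z)
    B <- as.numeric(ws$base_counts_seq %*% log(bg))
    ll <- sum(B + mx + log(denom))
    ll_trace <- c(ll_trace, ll)
    # M-step
    cnt <- matrix(alpha, nrow = 4L, ncol = w)
    for (j in seq_len(w)) {
      for (b2 in 1:4)
        cnt[b2, j] <- cnt[b2, j] + sum(Z[ws$base_idx[[j]][[b2]]])
    }
    theta <- sweep(cnt, 2L, colSums(cnt), "/")
    gamma <- min(max(mean(q), 1e-4), 1 - 1e-4)
    motif_counts <- rowSums(cnt) - alpha * w
    bg_counts <- pmax(ws$base_counts - motif_counts, 0) + 1
    bg <- bg_counts / sum(bg_counts)
    if (is.finite(ll_old) && ll - ll_old < tol && iter > 1L) break
    ll_old <- ll
  }
  rownames(theta) <- BASES
  list(theta = theta, bg = bg, gamma = gamma, Z = Z, q = q,
       ll = ll_trace[length(ll_trace)], ll_trace = ll_trace)
}

theta_from_seed <- function(seed_mer, w, weight = 0.5) {
  enc <- encode_dna(seed_mer)
  theta <- matrix((1 - weight) / 3, nrow = 4L, ncol = w)
  theta[cbind(enc, seq_len(w))] <- weight
  theta
}

#' ZOOPS EM motif discovery on the given strand
#'
#' Each sequence carries zero or one motif occurrence (prior gamma,
#' offset uniform).  The E-step computes per-offset occurrence
#' responsibilities under the current position probability matrix,
#' background, and gamma; the M-step re-estimates all three (PWM with
#' pseudo-count `alpha`, background from expected non-motif base
#' counts).  Restarts are seeded from w-mers occurring in the data: half
#' from the most frequent distinct w-mers (strong exact repeats seed
#' reliably), the rest drawn by a seeded RNG.  Every start runs a short
#' burn-in; the most promising are refined to convergence and the best
#' final log-likelihood wins.  The reverse complement strand is never
#' searched.
#'
#' @param seqs character vector of A/C/G/T sequences (>= 2, each >=
#'   `width`).
#' @param width motif width (default 12).
#' @param n_starts number of seeded restarts (default 20).
#' @param max_iter EM iteration cap per start (default 100).
#' @param tol log-likelihood convergence gain (default 1e-6).
#' @param alpha pseudo-count per base in the M-step (default 0.25).
#' @param seed RNG seed for restart selection.
#' @return object of class `MotifModel`: list with `width`, `theta`
#'   (4 x w PPM, rows A/C/G/T), `background`, `gamma`, `consensus`,
#'   `information_content` (bits), `loglik`, `ll_trace` (best start),
#'   `hits` (data.frame: `seq_index`, `offset` 0-based, `posterior`,
#'   `score` log2-odds).
#' @export
discover_motif_zoops <- function(seqs, width = 12L, n_starts = 20L,
                                 max_iter = 100L, tol = 1e-6,
                                 alpha = 0.25, seed = 1L) {
  if (length(seqs) < 2L) stop_input("need >= 2 sequences")
  width <- as.integer(width)
  if (any(nchar(seqs) < width))
    stop_input("all sequences must be >= width (%d)", width)
  enc <- encode_set(seqs)
  ws <- em_workspace(enc, width)
  # candidate seed w-mers: half from the most frequent distinct w-mers
  # (exact recurring motifs seed reliably), the rest by seeded RNG
  all_mers <- unlist(lapply(seqs, kmers, w = width))
  tab <- sort(table(all_mers), decreasing = TRUE)
  mers <- names(tab)
  n_top <- min(ceiling(n_starts / 2), length(mers))
  seeds_top <- mers[seq_len(n_top)]
  set.seed(derive_seed(seed, 7L))
  rest <- setdiff(mers, seeds_top)
  n_rng <- min(n_starts - n_top, length(rest))
  seeds_rng <- if (n_rng > 0L) sample(rest, n_rng) else character(0)
  seed_mers <- c(seeds_top, seeds_rng)
  bg0 <- rep(0.25, 4L)
  # short-run each start, refine the most promising to convergence
  shortfits <- lapply(seed_mers, function(sm)
    em_run(ws, theta_from_seed(sm, width), bg0, gamma0 = 0.3,
           alpha = alpha, max_iter = 5L, tol = tol))
  ord <- order(vapply(shortfits, `[[`, 0, "ll"), decreasing = TRUE)
  best <- NULL
  for (k in utils::head(ord, 3L)) {
    fit <- em_run(ws, shortfits[[k]]$theta, shortfits[[k]]$bg,
                  shortfits[[k]]$gamma, alpha = alpha,
                  max_iter = max_iter, tol = tol)
    fit$ll_trace <- c(shortfits[[k]]$ll_trace, fit$ll_trace)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  theta <- best$theta
  cons <- paste(BASES[apply(theta, 2L, which.max)], collapse = "")
  ic <- sum(theta * log2(sweep(theta, 1L, best$bg, "/")))
  hit_rows <- list()
  for (s in seq_along(enc)) {
    if (best$q[s] > 0.5) {
      o <- which.max(best$Z[s, seq_len(ws$m_s[s])]) - 1L
      win <- enc[[s]][(o + 1L):(o + width)]
      sc <- sum(log2(theta[cbind(win, seq_len(width))]) -
                  log2(best$bg[win]))
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        seq_index = s, offset = o, posterior = best$q[s], score = sc)
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(seq_index = integer(0), offset = integer(0),
               posterior = numeric(0), score = numeric(0))
  structure(list(width = width, theta = theta, background = best$bg,
                 gamma = best$gamma, consensus = cons,
                 information_content = ic, loglik = best$ll,
                 ll_trace = best$ll_trace, hits = hits),
            class = "MotifModel")
}

#' @export
print.MotifModel <- function(x, ...) {
  cat(sprintf("MotifModel: width %d, consensus %s, IC %.2f bits, gamma %.2f\n",
              x$width, x$consensus, x$information_content, x$gamma))
  invisible(x)
}

#' Scan a sequence with a PWM
#'
#' Log2-odds (motif vs background) score at every offset on the given
#' strand; offsets scoring at least `threshold` bits are returned ranked
#' by score.
#'
#' @param seq character sequence (>= model width).
#' @param model a `MotifModel` (or list with `theta`, `background`,
#'   `width`).
#' @param threshold score threshold in bits (default 8).
#' @return data.frame: `offset` (0-based), `score`, sorted by
#'   decreasing score.
#' @export
scan_pwm <- function(seq, model, threshold = 8) {
  enc <- encode_set(list(seq))[[1]]
  if (length(enc) < model$width)
    stop_input("sequence shorter than motif width")
  sc <- window_llr(enc, log2(model$theta), log2(model$background))
  hit <- which(sc >= threshold)
  out <- data.frame(offset = hit - 1L, score = sc[hit])
  out[order(-out$score), , drop = FALSE]
}

#' End-to-end boxA screen over genus flank records
#'
#' Deduplicates to one record per genus, trims each flank at the first
#' recurring 15-mer and discards flanks lacking one or trimmed below
#' 20 bp, then either discovers a motif by ZOOPS EM on the kept trimmed
#' flanks or scans them with a supplied PWM.  Flanks of genera listed in
#' `reversed_genera` (e.g. type II-C systems with arrays oriented
#' opposite to cas2) are expected to have been extracted from the
#' opposite array end by the caller; they pass through the same rules.
#'
#' @param records data.frame with `genus`, `source_id`, `seq`.
#' @param pwm optional `MotifModel` to scan with instead of running EM.
#' @param width,n_starts,seed EM parameters (see
#'   [discover_motif_zoops()]).
#' @param scan_threshold bits threshold for PWM scanning.
#' @return list: `report` (per genus: `genus`, `status`, `trimmed_length`,
#'   `hit_offset`, `score`), `model` (the MotifModel used or learned),
#'   `summary` (n_input, n_genera, n_kept, n_with_motif).
#' @export
screen_boxa <- function(records, pwm = NULL, width = 12L, n_starts = 20L,
                        seed = 1L, scan_threshold = 8) {
  n_input <- nrow(records)
  recs <- dedupe_by_genus(records)
  trims <- lapply(recs$seq, trim_and_filter)
  status <- vapply(trims, `[[`, "", "status")
  tlen <- vapply(trims, function(t)
    if (is.na(t$trimmed)) NA_integer_ else nchar(t$trimmed), 0L)
  kept <- which(status == "kept")
  report <- data.frame(genus = recs$genus, status = status,
                       trimmed_length = tlen,
                       hit_offset = NA_integer_, score = NA_real_,
                       stringsAsFactors = FALSE)
  model <- pwm
  if (length(kept) >= 2L) {
    kept_seqs <- vapply(trims[kept], `[[`, "", "trimmed")
    usable <- kept[nchar(kept_seqs) >= width]
    kept_seqs <- kept_seqs[nchar(kept_seqs) >= width]
    if (is.null(pwm)) {
      model <- discover_motif_zoops(kept_seqs, width = width,
                                    n_starts = n_starts, seed = seed)
      h <- model$hits
      report$hit_offset[usable[h$seq_index]] <- h$offset
      report$score[usable[h$seq_index]] <- h$score
    } else {
      for (i in seq_along(kept_seqs)) {
        h <- scan_pwm(kept_seqs[i], pwm, threshold = scan_threshold)
        if (nrow(h) > 0L) {
          report$hit_offset[usable[i]] <- h$offset[1]
          report$score[usable[i]] <- h$score[1]
        }
      }
    }
  }
  list(report = report, model = model,
       summary = c(n_input = n_input, n_genera = nrow(recs),
                   n_kept = length(kept),
                   n_with_motif = sum(!is.na(report$hit_offset))))
}
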
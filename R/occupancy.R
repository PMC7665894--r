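#' Peak-center occupancy, replicate scaling, and ratio-based refinement
#'
#' Occupancy at a binding site is read out as the strand-summed coverage
#' at the peak center.  Replicates are put on a common scale by
#' multiplying the second replicate by a constant equating the summed
#' values over the analyzed peak set.  Comparing a strain in which one
#' array is deleted against the wild type gives per-peak
#' deletion:reference ratios that resolve peaks matched by spacers from
#' both arrays: sites driven by the deleted array collapse to background
#' (both replicate ratios below 0.2), sites driven by the other array do
#' not (both ratios above 1.0).
#'
#' @name occupancy
NULL

#' Strand-summed coverage at a peak center
#'
#' @param fwd,rev per-strand coverage vectors (index = 0-based position
#'   + 1); positions beyond the vectors read as 0.
#' @param center 0-based peak-center position(s).
#' @return numeric value(s): `fwd[center] + rev[center]`.
#' @export
peak_center_value <- function(fwd, rev, center) {
  at <- function(v, i) {
    out <- rep(0, length(i))
    ok <- i >= 0L & i < length(v)
    out[ok] <- v[i[ok] + 1L]
    out[is.na(out)] <- 0
    out
  }
  at(fwd, center) + at(rev, center)
}

#' Build an occupancy matrix over peak centers
#'
#' @param centers 0-based peak-center positions.
#' @param tracks named list of samples, each a list with `fwd` and `rev`
#'   coverage vectors.
#' @return numeric matrix, rows = peaks, columns = samples.
#' @export
occupancy_matrix <- function(centers, tracks) {
  m <- vapply(tracks, function(t) peak_center_value(t$fwd, t$rev, centers),
              numeric(length(centers)))
  m <- matrix(m, nrow = length(centers),
              dimnames = list(NULL, names(tracks)))
  m
}

#' Scale a second replicate to match the first
#'
#' Multiplies every value of replicate 2 by c = sum(rep1)/sum(rep2) over
#' the analyzed peak set, so the summed values for the replicates agree.
#'
#' @param rep1,rep2 peak-center values over the same peak set.
#' @return list with `scaled` (rep2 * c) and `constant` c.
#' @export
scale_replicates <- function(rep1, rep2) {
  s2 <- sum(rep2)
  if (!is.finite(s2) || s2 <= 0)
    stop_input("replicate 2 sums to %g; cannot scale", s2)
  c0 <- sum(rep1) / s2
  list(scaled = rep2 * c0, constant = c0)
}

# deletion:reference ratio with a pseudo-count applied only when the
# denominator is zero (stabilizes background sites at low coverage
# without altering threshold behaviour at realistic depth)
del_ratio <- function(num, den) {
  z <- den == 0
  r <- num / den
  r[z] <- (num[z] + 1) / (den[z] + 1)
  r
}

#' Refine ambiguous peak assignments using array-deletion ChIP data
#'
#' For each still-ambiguous peak, the per-replicate ratio of
#' deletion-strain to reference-strain peak-center coverage is computed.
#' If both ratios fall below `lower` the candidate set is restricted to
#' spacers of the deleted array; if both exceed `upper` it is restricted
#' to spacers of the other array(s).  A peak becomes `unique`
#' (provenance `ratio_refined`) iff exactly one candidate survives;
#' discordant replicates leave the peak untouched.  Already-unique peaks
#' are never modified.
#'
#' @param peaks assignment table from [assign_peaks()].
#' @param occ_ref,occ_del n x 2 matrices of peak-center values for the
#'   reference and deletion strains (columns = replicates, already
#'   sum-scaled; see [scale_replicates()]).
#' @param spacer_arrays named character vector, spacer_id -> array_id.
#' @param deleted_array array_id deleted in the deletion strain.
#' @param lower,upper ratio thresholds (defaults 0.2 and 1.0).
#' @return `peaks` with refined `status`, `spacer_id`, `candidates`,
#'   `provenance`, plus `ratio_rep1`, `ratio_rep2`.
#' @export
deletion_refinement <- function(peaks, occ_ref, occ_del, spacer_arrays,
                                deleted_array, lower = 0.2, upper = 1.0) {
  n <- nrow(peaks)
  stopifnot(nrow(occ_ref) == n, nrow(occ_del) == n,
            ncol(occ_ref) == 2L, ncol(occ_del) == 2L)
  r1 <- del_ratio(occ_del[, 1L], occ_ref[, 1L])
  r2 <- del_ratio(occ_del[, 2L], occ_ref[, 2L])
  peaks$ratio_rep1 <- r1
  peaks$ratio_rep2 <- r2
  for (i in seq_len(n)) {
    if (peaks$status[i] != "ambiguous") next
    cand <- strsplit(peaks$candidates[i], ",", fixed = TRUE)[[1]]
    arr <- spacer_arrays[cand]
    if (any(is.na(arr)))
      stop_input("candidate spacer without array label at peak %d", i)
    keep <- if (r1[i] < lower && r2[i] < lower) {
      cand[arr == deleted_array]
    } else if (r1[i] > upper && r2[i] > upper) {
      cand[arr != deleted_array]
    } else cand
    if (length(keep) == 1L) {
      peaks$status[i] <- "unique"
      peaks$spacer_id[i] <- keep
      peaks$candidates[i] <- keep
      peaks$n_candidates[i] <- 1L
      peaks$provenance[i] <- "ratio_refined"
    }
  }
  attr(peaks, "summary") <- c(
    total = n, unique = sum(peaks$status == "unique"),
    ratio_refined = sum(peaks$provenance %in% "ratio_refined"),
    ambiguous = sum(peaks$status == "ambiguous"),
    unassigned = sum(peaks$status == "unassigned"))
  peaks
}

#' Per-spacer normalized occupancy-ratio profile
#'
#' For each uniquely assigned peak the mutant:reference occupancy ratio
#' is computed per replicate (on sum-scaled values) and averaged; ratios
#' are normalized to the mean ratio over peaks assigned to spacers of
#' `reference_array`, then averaged per spacer.  Under premature Rho
#' termination of one array, the profile stays near 1 for leader-proximal
#' spacers and decays beyond the point where the mutant loses
#' antitermination protection.
#'
#' @param peaks assignment table with `status` and `spacer_id`.
#' @param occ_mut,occ_ref n x 2 matrices of peak-center values (mutant
#'   and reference strains, sum-scaled replicates).
#' @param spacer_arrays named vector spacer_id -> array_id.
#' @param reference_array array whose peaks define the normalization
#'   (value 1 on average by construction).
#' @return data.frame: `spacer_id`, `array_id`, `n_peaks`, `ratio`
#'   (normalized mutant/reference).
#' @export
spacer_effect_profile <- function(peaks, occ_mut, occ_ref, spacer_arrays,
                                  reference_array) {
  use <- peaks$status == "unique"
  if (!any(use)) stop_input("no uniquely assigned peaks")
  sid <- peaks$spacer_id[use]
  r <- (del_ratio(occ_mut[use, 1L], occ_ref[use, 1L]) +
          del_ratio(occ_mut[use, 2L], occ_ref[use, 2L])) / 2
  arr <- spacer_arrays[sid]
  ref_peaks <- arr == reference_array
  if (!any(ref_peaks))
    stop_input("no peaks assigned to reference array '%s'", reference_array)
  r_norm <- r / mean(r[ref_peaks])
  agg <- tapply(r_norm, sid, mean)
  npk <- tapply(r_norm, sid, length)
  data.frame(spacer_id = names(agg),
             array_id = unname(spacer_arrays[names(agg)]),
             n_peaks = as.integer(npk[names(agg)]),
             ratio = as.numeric(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Locate a termination change-point in a spacer ratio profile
#'
#' Fits, for every candidate change-point k, a piecewise model in log
#' space (flat at 0 up to k, linear decay after) and returns the k with
#' the smallest residual sum of squares.  Suited to profiles produced by
#' [spacer_effect_profile()] ordered by spacer index.
#'
#' @param ratio numeric profile ordered by spacer index (leader-proximal
#'   first); values must be positive.
#' @return integer index k: last spacer before the decay starts.
#' @export
estimate_changepoint <- function(ratio) {
  stopifnot(all(ratio > 0), length(ratio) >= 3L)
  l <- log(ratio)
  n <- length(l)
  rss <- rep(Inf, n - 1L)
  for (k in seq_len(n - 1L)) {
    x <- seq_len(n - k)
    y <- l[(k + 1L):n]
    slope <- sum(x * y) / sum(x * x)
    rss[k] <- sum(l[seq_len(k)]^2) + sum((y - slope * x)^2)
  }
  which.min(rss)
}
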
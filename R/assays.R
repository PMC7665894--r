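#' Closed-form assay computations
#'
#' Miller-unit beta-galactosidase activity and ChIP-qPCR relative
#' occupancy.
#'
#' @name assays
NULL

#' Beta-galactosidase activity in Miller units
#'
#' activity = 1000 * A420 / (A600 * time * volume).
#'
#' @param a420 reaction absorbance at 420 nm (>= 0).
#' @param a600 culture density at 600 nm (> 0).
#' @param time_min reaction time in minutes (> 0).
#' @param volume_ml culture volume assayed in mL (> 0).
#' @return activity in Miller units (vectorized).
#' @export
miller_units <- function(a420, a600, time_min, volume_ml) {
  if (any(a600 <= 0) || any(time_min <= 0) || any(volume_ml <= 0))
    stop_input("a600, time_min and volume_ml must all be positive")
  if (any(a420 < 0)) stop_input("a420 must be non-negative")
  1000 * a420 / (a600 * time_min * volume_ml)
}

#' ChIP-qPCR relative occupancy
#'
#' Background-subtracted enrichment relative to a control region:
#' each enrichment is the target-region signal divided by the
#' control-region signal; occupancy is the target enrichment minus the
#' mock/background enrichment.
#'
#' @param target target enrichment (fold over control region, > 0).
#' @param background mock/background enrichment (> 0).
#' @return occupancy (vectorized).
#' @export
relative_occupancy <- function(target, background) {
  if (any(target <= 0) || any(background <= 0))
    stop_input("enrichments must be positive")
  target - background
}

#' Efficiency-corrected qPCR enrichment from Cq values
#'
#' enrichment = efficiency^(cq_control - cq_target); with the default
#' amplification efficiency of 2 this is the usual 2^-dCq fold change of
#' the target region over the control region.
#'
#' @param cq_target Cq of the target region.
#' @param cq_control Cq of the control region.
#' @param efficiency per-cycle amplification factor (default 2).
#' @return fold enrichment (vectorized).
#' @export
qpcr_enrichment <- function(cq_target, cq_control, efficiency = 2) {
  if (any(efficiency <= 1)) stop_input("efficiency must exceed 1")
  efficiency^(cq_control - cq_target)
}
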
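test_that("peak-center value sums both strands and defaults to zero", {
  fwd <- c(0, 0, 12, 0); rev <- c(0, 0, 8, 0)
  expect_equal(peak_center_value(fwd, rev, 2L), 20)
  expect_equal(peak_center_value(fwd, rev, 100L), 0)
  expect_equal(peak_center_value(numeric(0), numeric(0), 5L), 0)
  expect_equal(peak_center_value(fwd, rev, c(2L, 3L)), c(20, 0))
})

test_that("replicate scaling equates the summed values", {
  s <- scale_replicates(c(120, 80), c(60, 40))
  expect_equal(s$constant, 2)
  expect_equal(sum(s$scaled), 200)
  # identity when replicates already agree
  s2 <- scale_replicates(c(3, 7), c(3, 7))
  expect_equal(s2$constant, 1)
  expect_identical(s2$scaled, c(3, 7))
  # property: random positive vectors always end with equal sums, and
  # rank order within the replicate is conserved
  set.seed(8)
  for (i in 1:20) {
    a <- runif(30, 1, 100); b <- runif(30, 1, 100)
    sc <- scale_replicates(a, b)
    expect_equal(sum(sc$scaled), sum(a))
    expect_identical(order(sc$scaled), order(b))
  }
  expect_error(scale_replicates(c(1, 2), c(0, 0)), "cannot scale")
})

make_amb_peaks <- function(cands) {
  n <- length(cands)
  data.frame(start = seq(0, by = 200, length.out = n),
             end = seq(101, by = 200, length.out = n),
             center = seq(50, by = 200, length.out = n),
             n_input = 1L, status = "ambiguous", spacer_id = NA_character_,
             candidates = cands,
             n_candidates = lengths(strsplit(cands, ",")),
             provenance = NA_character_, stringsAsFactors = FALSE)
}

test_that("deletion refinement applies the two-threshold rule", {
  sa <- c("I:3" = "I", "I:5" = "I", "II:9" = "II")
  pk <- make_amb_peaks(c("I:5,II:9",   # both ratios < 0.2 -> I:5
                         "I:5,II:9",   # both ratios > 1.0 -> II:9
                         "I:3,I:5",    # both < 0.2 but two I survivors
                         "I:5,II:9"))  # discordant -> unchanged
  occ_ref <- matrix(100, nrow = 4, ncol = 2)
  occ_del <- rbind(c(5, 10), c(150, 200), c(5, 10), c(10, 50))
  out <- deletion_refinement(pk, occ_ref, occ_del, sa, "I")
  expect_identical(out$status, c("unique", "unique", "ambiguous",
                                 "ambiguous"))
  expect_identical(out$spacer_id[1:2], c("I:5", "II:9"))
  expect_identical(out$provenance[1:2], rep("ratio_refined", 2))
  expect_equal(out$ratio_rep1, c(0.05, 1.5, 0.05, 0.1))
  # unique peaks are never touched
  pk2 <- pk; pk2$status <- "unique"; pk2$spacer_id <- "I:5"
  out2 <- deletion_refinement(pk2, occ_ref, occ_del, sa, "I")
  expect_identical(out2$status, pk2$status)
  expect_identical(out2$spacer_id, pk2$spacer_id)
})

test_that("refinement resolves simulated deletion data correctly", {
  sim <- fixture_sim_profile()
  pk <- fixture_assigned_profile()
  sa <- setNames(sim$spacers$array_id, sim$spacers$spacer_id)
  truth <- pk$spacer_id
  other <- vapply(truth, function(s)
    sim$spacers$spacer_id[sim$spacers$array_id != sa[s]][1], "")
  amb <- pk
  amb$status <- "ambiguous"
  amb$candidates <- paste(pmin(truth, other), pmax(truth, other), sep = ",")
  amb$spacer_id <- NA_character_
  amb$n_candidates <- 2L
  amb$provenance <- NA_character_
  ab <- setNames(rep(1, nrow(sim$spacers)), sim$spacers$spacer_id)
  ab_del <- ab * ifelse(grepl("^CRISPR-I:", names(ab)), 0, 1)
  LS <- 2e6
  occ_ref <- occupancy_matrix(amb$center, list(
    r1 = simulate_chip_coverage(sim, ab, depth = 150,
                                library_size = LS, seed = 31),
    r2 = simulate_chip_coverage(sim, ab, depth = 150,
                                library_size = LS, seed = 32)))
  occ_del <- occupancy_matrix(amb$center, list(
    r1 = simulate_chip_coverage(sim, ab_del, depth = 150,
                                library_size = LS, seed = 33),
    r2 = simulate_chip_coverage(sim, ab_del, depth = 150,
                                library_size = LS, seed = 34)))
  occ_ref[, 2] <- scale_replicates(occ_ref[, 1], occ_ref[, 2])$scaled
  occ_del[, 2] <- scale_replicates(occ_del[, 1], occ_del[, 2])$scaled
  out <- deletion_refinement(amb, occ_ref, occ_del, sa, "CRISPR-I")
  # never contradicts ground truth; resolves the overwhelming majority
  resolved <- out$status == "unique"
  expect_true(all(out$spacer_id[resolved] == truth[resolved]))
  expect_gte(mean(resolved & out$spacer_id == truth), 0.95)
})

test_that("effect profile is 1 when mutant equals reference", {
  sim <- fixture_sim_profile()
  pk <- fixture_assigned_profile()
  sa <- setNames(sim$spacers$array_id, sim$spacers$spacer_id)
  occ <- matrix(runif(nrow(pk) * 2, 50, 150), ncol = 2)
  prof <- spacer_effect_profile(pk, occ, occ, sa, "CRISPR-I")
  expect_true(all(abs(prof$ratio - 1) < 1e-12))
  # reference-array normalization invariant holds for any occupancies
  occ2 <- occ * matrix(runif(length(occ), 0.5, 2), ncol = 2)
  prof2 <- spacer_effect_profile(pk, occ2, occ, sa, "CRISPR-I")
  ref_rows <- prof2$array_id == "CRISPR-I"
  w <- prof2$n_peaks[ref_rows]
  expect_equal(sum(prof2$ratio[ref_rows] * w) / sum(w), 1)
})

test_that("change-point estimation finds a planted hazard jump", {
  # clean geometric profile: flat to 8, decay after
  ratio <- c(rep(1, 8), 0.75^(1:15))
  expect_identical(estimate_changepoint(ratio), 8L)
  # noise robustness
  set.seed(41)
  ok <- vapply(1:20, function(i) {
    r <- ratio * exp(rnorm(23, 0, 0.08))
    abs(estimate_changepoint(r) - 8L) <= 1L
  }, TRUE)
  expect_true(all(ok))
})
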
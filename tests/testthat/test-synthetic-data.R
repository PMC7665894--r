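test_that("genome construction plants reconstructible sites", {
  sim <- fixture_sim_small()
  # 2 arrays x 3 spacers x 2 sites
  expect_identical(nrow(sim$sites), 12L)
  for (i in seq_len(nrow(sim$sites))) {
    st <- sim$sites$start[i]
    cst <- sim$sites$construct[i]
    g <- substr(sim$genome, st + 1, st + nchar(cst))
    if (sim$sites$strand[i] == "-") g <- rc_chr(g)
    expect_identical(g, cst)
    expect_true(sim$sites$pam[i] %in% c("AAG", "ATG"))
    expect_identical(substr(cst, 1, 3), sim$sites$pam[i])
    sp <- sim$spacers$seq[sim$spacers$spacer_id == sim$sites$spacer_id[i]]
    expect_identical(substr(cst, 4, 8), substr(sp, 1, 5))
  }
})

test_that("generator is deterministic and honours the empty case", {
  cfg <- sim_config(seed = 19L, genome_length = 20000L,
                    arrays = list(array_spec("X", 2L)),
                    offtargets_per_spacer = 0L)
  s1 <- make_crispr_genome(cfg)
  s2 <- make_crispr_genome(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$spacers, s2$spacers)
  expect_identical(nrow(s1$sites), 0L)
  # arrays still present
  expect_match(s1$genome, s1$arrays$X$repeat_seq, fixed = TRUE)
})

test_that("survival model matches its closed forms", {
  # no termination
  m0 <- termination_model(rep(0, 6))
  expect_equal(simulate_crrna_abundance(m0), rep(1, 6))
  # absorbing termination after spacer 3
  rho <- rep(0, 6); rho[3] <- 1
  m1 <- termination_model(rho)
  ab <- simulate_crrna_abundance(m1)
  expect_equal(ab[1:3], rep(1, 3))
  expect_equal(ab[4:6], rep(0, 3))
  # geometric decay
  m2 <- termination_model(rep(0.1, 8))
  expect_equal(simulate_crrna_abundance(m2), 0.9^(0:7))
  # boxA protection switches to the protected hazard
  m3 <- termination_model(rep(0.2, 5), boxa_intact = TRUE,
                          rho_protected = rep(0, 5))
  expect_equal(simulate_crrna_abundance(m3), rep(1, 5))
  # internal promoter adds propagated initiation
  m4 <- termination_model(rep(0.5, 4), internal_promoter_at = 3,
                          internal_amount = 2)
  ab4 <- simulate_crrna_abundance(m4)
  expect_equal(ab4, c(1, 0.5, 0.25 + 2, 0.125 + 1))
})

test_that("abundance is non-increasing without an internal promoter", {
  set.seed(31)
  for (i in 1:25) {
    rho <- runif(sample(3:30, 1))
    ab <- simulate_crrna_abundance(termination_model(rho))
    expect_true(all(diff(ab) <= 1e-12))
  }
})

test_that("noiseless coverage is proportional to abundance", {
  sim <- fixture_sim_small()
  ab <- setNames(rep(1, nrow(sim$spacers)), sim$spacers$spacer_id)
  ab[sim$sites$spacer_id[1]] <- 4
  ab[sim$sites$spacer_id[3]] <- 1
  cov <- simulate_chip_coverage(sim, ab, depth = 100,
                                noise = "none", background_rate = 0,
                                seed = 2)
  v <- peak_center_value(cov$fwd, cov$rev, sim$sites$center)
  i4 <- sim$sites$spacer_id == sim$sites$spacer_id[1]
  expect_equal(unique(v[i4]), 400)
  expect_equal(v[sim$sites$spacer_id == sim$sites$spacer_id[3]][1], 100)
  # determinism under seed with noise
  c1 <- simulate_chip_coverage(sim, ab, seed = 9)
  c2 <- simulate_chip_coverage(sim, ab, seed = 9)
  expect_identical(c1, c2)
})

test_that("Poisson site coverage matches expectation within 3 SE", {
  sim <- fixture_sim_profile()
  ab <- setNames(rep(1, nrow(sim$spacers)), sim$spacers$spacer_id)
  depth <- 200
  cov <- simulate_chip_coverage(sim, ab, depth = depth,
                                background_rate = 0.5, seed = 13)
  v <- peak_center_value(cov$fwd, cov$rev, sim$sites$center)
  mu <- depth + 2 * 0.5
  se <- sqrt(mu / length(v))
  expect_lt(abs(mean(v) - mu), 3 * se)
})

test_that("conjugation pools conserve depth and recover efficiencies", {
  eff <- setNames(c(1, 1, 1), c("p1", "p2", "p3"))
  cnt <- simulate_conjugation_counts(eff, depth = 2e4, seed = 21)
  sums <- tapply(cnt$count, list(cnt$sample, cnt$replicate), sum)
  expect_true(all(sums == 2e4))
  # null interference: all efficiencies near 100%
  ef <- normalize_efficiency(filter_low(cnt)$counts)
  expect_true(all(abs(ef$efficiency - 100) < 15))
  # full interference drives counts to ~0
  eff0 <- setNames(c(0, 1), c("dead", "live"))
  cnt0 <- simulate_conjugation_counts(eff0, depth = 1e4, seed = 22)
  dead <- cnt0[cnt0$protospacer_id == "dead" & cnt0$sample != "dcascade", ]
  expect_true(all(dead$count == 0))
  # determinism
  expect_identical(cnt, simulate_conjugation_counts(eff, depth = 2e4,
                                                    seed = 21))
})

test_that("Monte-Carlo recovery of a 20% efficiency at high depth", {
  eff <- setNames(c(0.2, 0.6), c("p1", "p2"))
  est <- vapply(1:20, function(s) {
    cnt <- simulate_conjugation_counts(eff, depth = 1e5, seed = 100 + s)
    ef <- normalize_efficiency(filter_low(cnt)$counts)
    mean(ef$efficiency[ef$protospacer_id == "p1" & ef$sample == "boxA_wt"])
  }, 0)
  expect_lt(abs(mean(est) - 20), 2)
})

test_that("flank sets plant the requested number of motifs", {
  fl0 <- make_cas2_flank_set(n = 40, planting_fraction = 0, seed = 3)
  expect_identical(sum(!is.na(fl0$motif_offset)), 0L)
  fl <- make_cas2_flank_set(n = 187, planting_fraction = 52 / 187,
                            seed = 3)
  expect_identical(sum(!is.na(fl$motif_offset)), 52L)
  expect_identical(nrow(fl), 187L)
  # planted motif instances reconstruct exactly
  pl <- fl[!is.na(fl$motif_offset), ]
  for (i in seq_len(nrow(pl))) {
    expect_identical(substr(pl$seq[i], pl$motif_offset[i] + 1,
                            pl$motif_offset[i] + 12), "TGCTCTTTAACA")
  }
  # planted repeat drives the trim point (cross-module round trip)
  fl120 <- make_cas2_flank_set(n = 5, planting_fraction = 0,
                               repeat_offset = 120L, seed = 4)
  for (s in fl120$seq) {
    tf <- trim_and_filter(s)
    expect_identical(tf$status, "kept")
    expect_identical(nchar(tf$trimmed), 120L)
  }
})

test_that("counts expand to reads that the tag counter recovers exactly", {
  set.seed(55)
  ps <- data.frame(id = c("p1", "p2", "p3"),
                   seq = replicate(3, rand_seq(32)),
                   stringsAsFactors = FALSE)
  refs <- select_tags(ps)
  eff <- setNames(c(0.5, 1, 0.1), ps$id)
  cnt <- simulate_conjugation_counts(eff, depth = 2000, seed = 77)
  one <- cnt[cnt$sample == "boxA_wt" & cnt$replicate == 1, ]
  reads <- counts_to_reads(one, refs, read_length = 60,
                           control_seq = rand_seq(32), seed = 78)
  got <- count_reads(reads, refs)
  want <- setNames(one$count[match(refs$id, one$protospacer_id)], refs$id)
  expect_identical(got$counts, want)
  expect_identical(got$multi_tag, 0L)
})
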
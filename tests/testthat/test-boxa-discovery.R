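test_that("genus deduplication keeps the first source id per genus", {
  rec <- data.frame(genus = c("B", "A", "A", "C", "B"),
                    source_id = c("b2", "a2", "a1", "c1", "b1"),
                    seq = "ACGT", stringsAsFactors = FALSE)
  out <- dedupe_by_genus(rec)
  expect_identical(out$genus, c("A", "B", "C"))
  expect_identical(out$source_id, c("a1", "b1", "c1"))
  # already unique -> identity (up to ordering)
  uni <- rec[c(3, 1, 4), ]
  expect_identical(nrow(dedupe_by_genus(uni)), 3L)
  # empty in, empty out
  expect_identical(nrow(dedupe_by_genus(rec[0, ])), 0L)
})

test_that("EM converges to point masses on identical motif copies", {
  set.seed(71)
  ctx_l <- rand_seq(20); ctx_r <- rand_seq(20)
  seqs <- rep(paste0(ctx_l, "TGACTGAC", ctx_r), 10)
  mod <- discover_motif_zoops(seqs, width = 8, n_starts = 4, seed = 2)
  # with every sequence identical, the learned columns are near-pure
  expect_true(all(apply(mod$theta, 2, max) > 0.9))
  expect_true(all(diff(mod$ll_trace) > -1e-6))
})

test_that("a planted motif is recovered from mostly-random flanks", {
  fl <- make_cas2_flank_set(n = 60, motif = "TTGACGGCTAGC",
                            planting_fraction = 0.5, flank_length = 150,
                            repeat_scheme = "none", seed = 14)
  mod <- discover_motif_zoops(fl$seq, width = 12, n_starts = 10, seed = 14)
  expect_identical(mod$consensus, "TTGACGGCTAGC")
  planted <- which(!is.na(fl$motif_offset))
  hits <- mod$hits
  tp <- hits[hits$seq_index %in% planted, ]
  expect_gte(nrow(tp), 0.9 * length(planted))
  # recovered offsets match the planted ground truth
  expect_true(all(tp$offset == fl$motif_offset[tp$seq_index]))
  # false hits are rare
  expect_lte(sum(!(hits$seq_index %in% planted)),
             ceiling(0.05 * (nrow(fl) - length(planted))))
  # log-likelihood is monotone across all recorded iterations
  expect_true(all(diff(mod$ll_trace) > -1e-6))
  # permutation stability: shuffled input order, same model
  set.seed(1)
  perm <- sample(nrow(fl))
  mod2 <- discover_motif_zoops(fl$seq[perm], width = 12, n_starts = 10,
                               seed = 14)
  expect_identical(mod2$consensus, mod$consensus)
  expect_equal(mod2$theta, mod$theta, tolerance = 1e-6)
})

test_that("PWM scanning matches a direct log-odds recomputation", {
  theta <- matrix(0.01 / 3, nrow = 4, ncol = 3,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  theta[1, ] <- 0.99   # near-point masses on AAA
  model <- structure(list(width = 3L, theta = theta,
                          background = rep(0.25, 4)),
                     class = "MotifModel")
  h <- scan_pwm("TTTAAATTT", model, threshold = 4)
  expect_identical(nrow(h), 1L)
  expect_identical(h$offset, 3L)
  expect_equal(h$score, 3 * log2(0.99 / 0.25))
  # threshold above the maximum attainable score: no hits
  expect_identical(nrow(scan_pwm("TTTAAATTT", model, threshold = 10)), 0L)
  # scores equal brute-force per-offset recomputation
  set.seed(3)
  s <- rand_seq(60)
  h2 <- scan_pwm(s, model, threshold = -Inf)
  brute <- vapply(0:(60 - 3), function(o) {
    win <- strsplit(substr(s, o + 1, o + 3), "")[[1]]
    sum(log2(theta[cbind(match(win, c("A", "C", "G", "T")), 1:3)]) -
          log2(0.25))
  }, 0)
  expect_equal(sort(h2$score), sort(brute))
})

test_that("the end-to-end screen reports statuses and motif calls", {
  fl <- make_cas2_flank_set(n = 60, planting_fraction = 26 / 60, seed = 8)
  scr <- screen_boxa(fl, width = 12, n_starts = 8, seed = 8)
  expect_identical(unname(scr$summary["n_genera"]), 60L)
  expect_identical(unname(scr$summary["n_kept"]),
                   sum(scr$report$status == "kept"))
  planted <- !is.na(fl$motif_offset)
  called <- !is.na(scr$report$hit_offset)
  expect_gte(sum(called & planted), 0.9 * sum(planted))
  # determinism
  scr2 <- screen_boxa(fl, width = 12, n_starts = 8, seed = 8)
  expect_identical(scr$report, scr2$report)
  # degenerate: no kept flanks -> clean empty report, no motif step
  none <- make_cas2_flank_set(n = 5, planting_fraction = 0,
                              repeat_scheme = "none", seed = 9)
  scr3 <- screen_boxa(none)
  expect_identical(unname(scr3$summary["n_kept"]), 0L)
  expect_true(all(scr3$report$status == "no_repeat"))
  expect_null(scr3$model)
})

test_that("motif information content reflects planted signal strength", {
  fl <- make_cas2_flank_set(n = 60, planting_fraction = 0.5,
                            flank_length = 150, repeat_scheme = "none",
                            seed = 16)
  mod <- discover_motif_zoops(fl$seq, width = 12, n_starts = 10, seed = 16)
  # IC of the empirical PWM over the planted instances, under the same
  # pseudocount convention, is the attainable ceiling
  planted <- fl[!is.na(fl$motif_offset), ]
  cnt <- matrix(0.25, 4, 12)
  for (i in seq_len(nrow(planted))) {
    win <- strsplit(substr(planted$seq[i], planted$motif_offset[i] + 1,
                           planted$motif_offset[i] + 12), "")[[1]]
    idx <- match(win, c("A", "C", "G", "T"))
    cnt[cbind(idx, 1:12)] <- cnt[cbind(idx, 1:12)] + 1
  }
  theta_p <- sweep(cnt, 2, colSums(cnt), "/")
  ic_p <- sum(theta_p * log2(theta_p / 0.25))
  expect_gte(mod$information_content, 0.9 * ic_p)
})
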
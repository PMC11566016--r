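test_that("zero planted effects give near-zero differentiation; full shift
           separates the conditions pair by pair", {
  # no effect, near-zero noise: pre/post similarity equal across conditions
  s0 <- small_subject(effect_config("Wake", noise_sd = 1e-6))
  sm <- snapshot_matrices(s0)
  rec <- pair_similarity(sm$pre_a, sm$post_b, s0$design$pairs)
  d0 <- differentiation_score(rec)
  # residual wobble comes from the finite-voxel latent bases, not the
  # (near-zero) measurement noise
  expect_lt(abs(d0$diff_score), 0.05)

  # delta_diff = 1: violation postB drops the shared block entirely,
  # so every violation pair's z falls below every nonviolation pair's z
  s1 <- small_subject(effect_config("REM", delta_diff = 1, noise_sd = 1e-6))
  sm1 <- snapshot_matrices(s1)
  rec1 <- pair_similarity(sm1$pre_a, sm1$post_b, s1$design$pairs)
  expect_lt(max(rec1$z[rec1$condition == "violation"]),
            min(rec1$z[rec1$condition == "nonviolation"]))
})

test_that("expected differentiation decreases strictly with delta_diff", {
  diffs <- vapply(c(0, 0.3, 0.6, 0.9), function(dd) {
    s <- small_subject(effect_config("REM", delta_diff = dd, noise_sd = 1e-6),
                       seed = 3)
    sm <- snapshot_matrices(s)
    differentiation_score(
      pair_similarity(sm$pre_a, sm$post_b, s$design$pairs))$diff_score
  }, numeric(1))
  expect_true(all(diff(diffs) < 0))
})

test_that("ground truth records the reactivation and realized shifts", {
  eff <- effect_config("REM", delta_diff = 0.4, kappa = 0.5)
  s <- small_subject(eff, seed = 9)
  gt <- s$ground_truth
  viol <- gt$condition == "violation"
  expect_true(all(is.na(gt$pi[!viol])))
  expect_true(all(gt$pi[viol] >= 0 & gt$pi[viol] <= 1))
  expect_equal(gt$d[viol],
               pmin(pmax(0.4 + 0.5 * (gt$pi[viol] - eff$pred_mean), 0), 1))
  expect_true(all(gt$d[!viol] == 0))
  # deterministic per seed
  s2 <- small_subject(eff, seed = 9)
  expect_identical(s$patterns, s2$patterns)
})

test_that("simulate_subject validates its parameters", {
  expect_error(effect_config("REM", noise_sd = 0), "noise_sd")
  expect_error(effect_config("REM", delta_diff = NaN), "finite")
  expect_error(simulate_subject(small_design(), effect_config("Wake"),
                                n_vox = 10, k_s = 4, k_u = 3, k_n = 3),
               "latent dimension")
})

test_that("cohorts have the right size and reject bad inputs", {
  coh <- simulate_cohort(n_per_group = 2, seed = 4, design = small_design(),
                         n_vox = 60, k_s = 4, k_u = 3, k_n = 3)
  expect_length(coh$subjects, 6L)
  expect_equal(sort(unique(coh$groups)), c("NREM", "REM", "Wake"))
  expect_equal(as.integer(table(coh$groups)), rep(2L, 3))
  expect_error(simulate_cohort(n_per_group = 0), "n_per_group")
  dup <- list(effect_config("REM"), effect_config("REM"))
  expect_error(simulate_cohort(2, effects = dup, seed = 1,
                               design = small_design(), n_vox = 60,
                               k_s = 4, k_u = 3, k_n = 3), "duplicate")
})

test_that("hypnogram generator reproduces its stage targets exactly", {
  tgt <- c(N1 = 6, N2 = 22, N3 = 20, REM = 0, WASO = 8)
  sim <- simulate_hypnogram("NREM", target_minutes = tgt, tib_min = 65,
                            seed = 2)
  arch <- score_architecture(sim$hypnogram)
  expect_equal(unname(arch$minutes[c("N1", "N2", "N3", "REM")]),
               unname(tgt[c("N1", "N2", "N3", "REM")]))
  expect_equal(arch$waso_min, 8)
  expect_equal(arch$tib_min, 65)
  expect_equal(arch$tst_min, 48)

  # REM-group nap classifies as REM
  simr <- simulate_hypnogram("REM", seed = 3)
  expect_equal(classify_nap(simr$hypnogram)$label, "REM")
  # NREM group refuses REM minutes
  expect_error(simulate_hypnogram("NREM",
                                  target_minutes = c(N1 = 2, N2 = 10, N3 = 5,
                                                     REM = 5, WASO = 0),
                                  tib_min = 30, seed = 1), "REM")
})

test_that("spindle counts recover the configured rate", {
  sim <- simulate_hypnogram("REM",
                            target_minutes = c(N1 = 0, N2 = 42, N3 = 0,
                                               REM = 0.5, WASO = 0),
                            tib_min = 50, spindle_rate = c(N2 = 4.3, N3 = 5.1),
                            seed = 8)
  n2 <- sum(sim$spindles$stage == "N2")
  expected <- 4.3 * 42  # 180.6
  expect_lt(abs(n2 - expected), 4 * sqrt(expected))
  dens <- spindle_density(sim$spindles, sim$hypnogram, "N2")
  expect_lt(abs(dens - 4.3), 4 * sqrt(expected) / 42)
})

test_that("rendered BOLD reflects HRF-weighted trial patterns", {
  d <- generate_design(seed = 41, n_runs = 1, pairs_per_run = 4, isi_s = 29)
  d <- generate_post_session(d, 42)
  s <- simulate_subject(d, effect_config("Wake", noise_sd = 1e-8),
                        n_vox = 40, k_s = 4, k_u = 3, k_n = 3,
                        trials = "all", seed = 5)
  rb <- render_bold(s, "roi", run = 1, tr = 1.5, noise_sd = 0)
  # trial onsets sit on the TR grid, so the volume at onset + 4.5 s equals
  # the trial pattern scaled by hrf(4.5): raw extraction aligns exactly
  idx <- which(s$events$run == 1)
  j <- 1L
  raw <- extract_pattern(rb$bold, rb$mask, rb$events$onset[j], tr = 1.5,
                         time_offset = 0)
  expect_gt(cor(raw, s$patterns$roi[idx[j], ]), 0.999)
  # two trials 3 s apart contaminate each other in proportion to HRF overlap
  d2 <- generate_design(seed = 43, n_runs = 1, pairs_per_run = 4)
  d2 <- generate_post_session(d2, 44)
  s2 <- simulate_subject(d2, effect_config("Wake", noise_sd = 1e-8),
                         n_vox = 40, k_s = 4, k_u = 3, k_n = 3,
                         trials = "all", seed = 6)
  rb2 <- render_bold(s2, "roi", run = 1, tr = 1.5, noise_sd = 0)
  raw2 <- extract_pattern(rb2$bold, rb2$mask, rb2$events$onset[1], tr = 1.5,
                          time_offset = 0)
  i2 <- which(s2$events$run == 1)
  expected <- s2$patterns$roi[i2[1], ] * hrf_double_gamma(4.5) +
    s2$patterns$roi[i2[2], ] * hrf_double_gamma(1.5)
  expect_equal(as.numeric(raw2),
               expected +
                 rowSums(sapply(3:length(i2), function(k)
                   s2$patterns$roi[i2[k], ] *
                     hrf_double_gamma(4.5 - (s2$events$onset[i2[k]] -
                                               s2$events$onset[i2[1]])))),
               tolerance = 1e-8)
})
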
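test_that("fisher z matches its closed form and inverts cleanly", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(1.5 / 0.5))
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  for (r in c(-0.9, -0.2, 0, 0.4, 0.99))
    expect_equal(inverse_fisher_z(fisher_z(r)), r, tolerance = 1e-12)
  expect_error(fisher_z(1), "\\|r\\| < 1")
  expect_error(fisher_z(-1.2), "\\|r\\| < 1")
})

test_that("pair similarity handles exact, orthogonal and degenerate toys", {
  pairs <- data.frame(pair_id = c("p1", "p2"),
                      condition = c("violation", "nonviolation"),
                      a_item = c("a1", "a2"), b_item = c("b1", "b2"),
                      stringsAsFactors = FALSE)
  pre_a <- rbind(a1 = c(1, 2, 3), a2 = c(1, 0, 1))
  # b1 identical to a1 -> r = 1, clamped with a warning; b2 reversed
  post_b <- rbind(b1 = c(1, 2, 3), b2 = c(3, 2, 1))
  pre_a2 <- rbind(a1 = c(1, 2, 3), a2 = c(1, 2, 3))
  expect_warning(rec <- pair_similarity(pre_a2, post_b, pairs), "clamped")
  expect_equal(rec$r, c(1, -1))
  expect_true(all(is.finite(rec$z)))
  # zero-variance pattern names the item
  post_b0 <- rbind(b1 = c(1, 2, 3), b2 = c(2, 2, 2))
  expect_error(pair_similarity(pre_a, post_b0, pairs), "b2")
  # mean-centered orthogonal patterns give r ~ 0
  pre_o <- rbind(a1 = c(-1, 1, -1, 1), a2 = c(-1, 1, -1, 1))
  post_o <- rbind(b1 = c(-1, -1, 1, 1), b2 = c(1, 1, -1, -1))
  rec_o <- pair_similarity(pre_o, post_o, pairs)
  expect_equal(rec_o$r, c(0, 0))
})

test_that("similarity is invariant to affine rescaling of a pattern", {
  inst <- random_instance(1)
  rec <- pair_similarity(inst$pre_a, inst$post_b, inst$pairs)
  rec2 <- pair_similarity(inst$pre_a * 3.7 + 2, inst$post_b, inst$pairs)
  expect_equal(rec$r, rec2$r, tolerance = 1e-12)
})

test_that("differentiation score is the difference of condition means", {
  records <- data.frame(
    pair_id = sprintf("p%d", 1:4),
    condition = c("violation", "violation", "nonviolation", "nonviolation"),
    z = c(0.1, 0.3, 0.4, 0.6), stringsAsFactors = FALSE)
  d <- differentiation_score(records)
  expect_equal(d$diff_score, -0.3)
  expect_equal(d$mean_z_violation, 0.2)
  # order invariance
  expect_equal(differentiation_score(records[sample(4), ])$diff_score, -0.3)
  expect_error(differentiation_score(records[records$condition ==
                                               "violation", ]),
               "nonviolation")
})

test_that("similarity pipeline matches a brute-force oracle to 1e-12", {
  for (s in 1:6) {
    inst <- random_instance(100 + s, n_pairs = 6, n_vox = 10)
    rec <- pair_similarity(inst$pre_a, inst$post_b, inst$pairs)
    d <- differentiation_score(rec)
    # brute force straight from the raw patterns
    zs <- sapply(seq_len(nrow(inst$pairs)), function(i)
      atanh(cor(inst$pre_a[inst$pairs$a_item[i], ],
                inst$post_b[inst$pairs$b_item[i], ])))
    viol <- inst$pairs$condition == "violation"
    expect_equal(d$diff_score, mean(zs[viol]) - mean(zs[!viol]),
                 tolerance = 1e-12)

    # b-prediction oracle
    bp <- b_prediction_scores(inst$pre_b, inst$evoked, inst$pairs)
    vp <- inst$pairs[viol, ]
    bp_oracle <- sapply(seq_len(nrow(vp)), function(i)
      mean(c(atanh(cor(inst$pre_b[vp$b_item[i], ],
                       inst$evoked[vp$x_item[i], ])),
             atanh(cor(inst$pre_b[vp$b_item[i], ],
                       inst$evoked[vp$y_item[i], ])))))
    expect_equal(bp$z_pred, bp_oracle, tolerance = 1e-12)

    # coupling oracle
    cp <- coupling_correlation(bp, rec, "violation")
    expect_equal(cp$r_within, cor(bp_oracle, zs[viol]), tolerance = 1e-12)
  }
})

test_that("item-specificity z is negative for planted differentiation and
           near zero for exchangeable B patterns", {
  s <- medium_subject(effect_config("REM", delta_diff = 0.6), seed = 13)
  sm <- snapshot_matrices(s)
  res <- item_specificity_z(sm$pre_a, sm$post_b, s$design$pairs,
                            n_shuffles = 500, seed = 1)
  expect_lt(res$z, -2)
  # removing pairmate-specific structure (shuffling B rows within condition)
  # should give |z| typically small; average over a few shuffle seeds
  zs <- vapply(1:5, function(k) {
    set.seed(200 + k)
    post_b <- sm$post_b
    for (cond in c("violation", "nonviolation")) {
      b_items <- s$design$pairs$b_item[s$design$pairs$condition == cond]
      post_b[b_items, ] <- post_b[sample(b_items), ]
    }
    item_specificity_z(sm$pre_a, post_b, s$design$pairs,
                       n_shuffles = 500, seed = k)$z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 1.5)
  # degenerate: identical B rows -> zero-sd null
  post_b_const <- sm$post_b
  post_b_const[] <- rep(post_b_const[1, ], each = nrow(post_b_const))
  expect_error(
    suppressWarnings(item_specificity_z(sm$pre_a, post_b_const,
                                        s$design$pairs, n_shuffles = 50,
                                        seed = 1)),
    "degenerate|zero")
  # determinism
  res2 <- item_specificity_z(sm$pre_a, sm$post_b, s$design$pairs,
                             n_shuffles = 500, seed = 1)
  expect_identical(res$z, res2$z)
})

test_that("b-prediction scores track the planted reactivation weights", {
  s <- medium_subject(effect_config("REM", pred_sd = 0.1, noise_sd = 1e-6),
                     seed = 17)
  sm <- snapshot_matrices(s)
  bp <- b_prediction_scores(sm$pre_b, sm$evoked, s$design$pairs)
  gt <- s$ground_truth[s$ground_truth$condition == "violation", ]
  m <- merge(bp, gt, by = "pair_id")
  # even with no measurement noise the random latent bases leave a small
  # per-pair wobble in r (finite-voxel mean-centering), so demand a near-
  # perfect rather than exact rank agreement with the planted weights
  expect_gt(cor(m$z_pred, m$pi, method = "spearman"), 0.95)
  expect_gt(cor(m$z_pred, m$pi), 0.95)
  # missing evoked pattern raises with the face name
  viol <- s$design$pairs[s$design$pairs$condition == "violation", ]
  expect_error(b_prediction_scores(sm$pre_b,
                                   sm$evoked[rownames(sm$evoked) !=
                                               viol$x_item[1], ],
                                   s$design$pairs),
               viol$x_item[1])
})

test_that("coupling correlation guards its preconditions", {
  inst <- random_instance(7, n_pairs = 6)
  rec <- pair_similarity(inst$pre_a, inst$post_b, inst$pairs)
  bp <- b_prediction_scores(inst$pre_b, inst$evoked, inst$pairs)
  # constant scores -> zero variance error
  bp0 <- bp; bp0$z_pred <- 1
  expect_error(coupling_correlation(bp0, rec, "violation"), "zero variance")
  # < 3 matched pairs
  expect_error(coupling_correlation(bp[1, , drop = FALSE], rec, "violation"),
               ">= 3")
  # score equal to similarity -> r = 1 under the clamp policy
  sc <- rec[rec$condition == "violation", c("pair_id", "z")]
  names(sc)[2] <- "score"
  expect_warning(cp <- coupling_correlation(sc, rec, "violation"), "clamped")
  expect_equal(cp$r_within, 1)
})

test_that("B-X-Y integration scores behave like the other pair scores", {
  inst <- random_instance(9, n_pairs = 6)
  sc <- bxy_integration_scores(inst$post_b, inst$post_face, inst$pairs)
  viol <- inst$pairs$condition == "violation"
  expect_equal(nrow(sc), sum(viol))
  # identical B and face patterns -> maximal score under clamp policy
  vp <- inst$pairs[viol, ]
  post_faces <- rbind(inst$post_b[vp$b_item, ], inst$post_b[vp$b_item, ])
  rownames(post_faces) <- c(vp$x_item, vp$y_item)
  w <- capture_warnings(
    sc_max <- bxy_integration_scores(inst$post_b, post_faces, inst$pairs))
  expect_true(all(grepl("clamped", w)))
  expect_true(all(sc_max$z_int > 13))
  # generator has no face-binding channel: group-mean B-X-Y coupling ~ 0
  rs <- vapply(1:12, function(k) {
    s <- medium_subject(effect_config("REM", delta_diff = 0.5), seed = 300 + k)
    sm <- snapshot_matrices(s)
    rec <- pair_similarity(sm$pre_a, sm$post_b, s$design$pairs)
    bxy <- bxy_integration_scores(sm$post_b, sm$post_face, s$design$pairs)
    coupling_correlation(bxy, rec, "violation")$z_within
  }, numeric(1))
  expect_lt(abs(mean(rs)) / (sd(rs) / sqrt(length(rs))), 3)
})
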
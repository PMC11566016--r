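# Shared fixtures: small designs and subjects built in code at test time.

# small design (1 run, 8 pairs) with session-2 snapshot runs
small_design <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- generate_design(seed = 11, n_runs = 1, pairs_per_run = 8)
      cache <<- generate_post_session(d, seed = 12)
    }
    cache
  }
})

# full-size design (6 runs, 16 pairs/run) with session 2
full_design <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- generate_design(seed = 21)
      cache <<- generate_post_session(d, seed = 22)
    }
    cache
  }
})

small_subject <- function(effect = effect_config("Wake"), seed = 7, ...) {
  simulate_subject(small_design(), effect, n_vox = 60, k_s = 4, k_u = 3,
                   k_n = 3, seed = seed, ...)
}

# full-size design, reduced voxel count: enough pairs for the randomization
# and coupling analyses at test-friendly speed
medium_subject <- function(effect = effect_config("Wake"), seed = 7, ...) {
  simulate_subject(full_design(), effect, n_vox = 60, k_s = 4, k_u = 3,
                   k_n = 3, seed = seed, ...)
}

# random small-instance snapshot matrices for oracle tests
random_instance <- function(seed, n_pairs = 4L, n_vox = 8L) {
  set.seed(seed)
  pairs <- data.frame(
    pair_id = sprintf("p%02d", seq_len(n_pairs)),
    condition = rep(c("violation", "nonviolation"), length.out = n_pairs),
    a_item = sprintf("a%02d", seq_len(n_pairs)),
    b_item = sprintf("b%02d", seq_len(n_pairs)),
    x_item = NA_character_, y_item = NA_character_,
    stringsAsFactors = FALSE
  )
  viol <- pairs$condition == "violation"
  pairs$x_item[viol] <- sprintf("x%02d", which(viol))
  pairs$y_item[viol] <- sprintf("y%02d", which(viol))
  mk <- function(ids) {
    m <- matrix(rnorm(length(ids) * n_vox), length(ids), n_vox)
    rownames(m) <- ids
    m
  }
  list(pairs = pairs,
       pre_a = mk(pairs$a_item), pre_b = mk(pairs$b_item),
       post_b = mk(pairs$b_item),
       evoked = mk(c(pairs$x_item[viol], pairs$y_item[viol])),
       post_face = mk(c(pairs$x_item[viol], pairs$y_item[viol])))
}
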
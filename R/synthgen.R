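# Synthetic subjects: voxel patterns with planted representational effects,
# optional rendered BOLD time series, and synthetic hypnograms with spindles.
#
# The latent model encodes differentiation as feature reallocation on the
# post-learning B representation: a fraction d of the features B shares with
# A is relinquished and replaced by novel features, while integration adds
# shared-feature weight. B reactivation during violation events mixes the B
# representation into the evoked pattern with per-pair weight pi, and the
# coupling parameter kappa ties pi to the realized differentiation d.

#' Per-group effect configuration for the synthetic generator
#'
#' @param group Group label (e.g. "Wake", "NREM", "REM").
#' @param delta_diff Differentiation shift in [0, 1]: fraction of shared
#'   features relinquished (and novel features acquired) by the post-learning
#'   B representation in the violation condition.
#' @param delta_int Integration shift in [0, 1]: proportional gain on shared
#'   features of the post-learning B representation in the nonviolation
#'   condition.
#' @param pred_mean,pred_sd Mean and sd of the per-pair B-reactivation weight
#'   pi during violation events (drawn from a normal and truncated to
#'   [0, 1]). Reactivation occurs during learning, before the group
#'   manipulation, so these are typically identical across groups.
#' @param kappa Coupling of pi to per-pair differentiation: the realized
#'   per-pair shift is d_p = clip(delta_diff + kappa * (pi_p - pred_mean),
#'   0, 1).
#' @param noise_sd Per-voxel Gaussian measurement noise sd (> 0).
#' @return An object of class \code{remdiff_effect}.
#' @export
effect_config <- function(group, delta_diff = 0, delta_int = 0,
                          pred_mean = 0.35, pred_sd = 0.2,
                          kappa = 0, noise_sd = 1) {
  vals <- c(delta_diff = delta_diff, delta_int = delta_int,
            pred_mean = pred_mean, pred_sd = pred_sd, kappa = kappa,
            noise_sd = noise_sd)
  if (!all(is.finite(vals))) stop("effect parameters must be finite")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  structure(as.list(c(list(group = group), as.list(vals))),
            class = "remdiff_effect")
}

#' Default per-group effect configurations
#'
#' The study conditions emulated by the cohort generator: no representational
#' change in the Wake and NREM groups; in the REM group, violation-condition
#' differentiation (delta_diff = 0.5) coupled to B reactivation
#' (kappa = 1), plus nonviolation-condition integration (delta_int = 0.2).
#' All groups share the same B-reactivation distribution since reactivation
#' happens during learning, before the offline manipulation.
#'
#' @return Named list of \code{remdiff_effect}, one per group.
#' @export
default_group_effects <- function() {
  list(
    Wake = effect_config("Wake"),
    NREM = effect_config("NREM"),
    REM = effect_config("REM", delta_diff = 0.5, delta_int = 0.2, kappa = 1)
  )
}

#' Simulate one subject's voxel patterns from a design and effect config
#'
#' For each pair an orthonormal latent basis is drawn and partitioned into
#' mutually orthogonal blocks: shared features (length \code{k_s}), A-unique
#' and B-unique features (\code{k_u} each), novel features (\code{k_n}; the
#' post-learning drift target), and X/Y face features (\code{k_u} each, for
#' violation pairs). Each block contributes a random direction within its
#' subspace with fixed norm \code{signal_amp * sqrt(k)}, keeping component
#' magnitudes homogeneous across pairs. Item patterns are sums of these
#' components plus per-trial white noise:
#' \itemize{
#'   \item pre-learning A = shared + A-unique
#'   \item pre-learning B = shared + B-unique
#'   \item post-learning B (violation) = (1 - d_p) shared + B-unique +
#'     d_p novel, with d_p = clip(delta_diff + kappa (pi_p - pred_mean), 0, 1)
#'   \item post-learning B (nonviolation) = (1 + delta_int) shared + B-unique
#'   \item violation-evoked = face + pi_p (shared + B-unique)
#'   \item post-learning face = face
#' }
#'
#' @param design A \code{remdiff_design}; if it lacks session-2 snapshot
#'   runs they are added with a seed derived from \code{seed}.
#' @param effect A \code{remdiff_effect}.
#' @param n_vox Voxels per ROI; must be at least the per-pair latent
#'   dimension (\code{k_s + 2 k_u + k_n} plus \code{2 k_u} face features for
#'   violation pairs).
#' @param k_s,k_u,k_n Latent block sizes.
#' @param rois Character vector of ROI labels; latents and noise are drawn
#'   independently per ROI.
#' @param trials \code{"analysis"} generates patterns only for the trials the
#'   similarity analyses consume (snapshots and violation-evoked events);
#'   \code{"all"} generates one pattern for every trial event.
#' @param signal_amp Per-feature loading amplitude (feature weights are
#'   N(0, signal_amp^2)); controls the signal-to-noise of pattern
#'   correlations.
#' @param seed Integer seed; the subject is bit-identical for a fixed seed.
#' @return An object of class \code{remdiff_subject}: list with
#'   \code{design}, \code{group}, \code{effect}, \code{events} (the rows
#'   patterns were generated for), \code{patterns} (named list of
#'   trial-by-voxel matrices, one per ROI), and \code{ground_truth}
#'   (per-pair pi_p and realized d_p).
#' @export
simulate_subject <- function(design, effect, n_vox = 500L, k_s = 8L,
                             k_u = 6L, k_n = 6L, rois = "roi",
                             trials = c("analysis", "all"),
                             signal_amp = 3, seed = 1L) {
  stopifnot(inherits(design, "remdiff_design"), inherits(effect, "remdiff_effect"))
  trials <- match.arg(trials)
  if (!all(is.finite(c(n_vox, k_s, k_u, k_n, signal_amp))))
    stop("non-finite simulation parameters")
  d_lat <- k_s + 2L * k_u + k_n + 2L * k_u  # full basis incl. face blocks
  if (n_vox < d_lat)
    stop("n_vox must be >= the per-pair latent dimension (", d_lat, ")")
  if (!any(design$events$session == 2L)) {
    design <- generate_post_session(design, seed = seed + 1L)
  }
  if (anyDuplicated(rois)) stop("duplicate ROI labels")

  analysis_types <- c("pre_snapshot_A", "pre_snapshot_B", "post_snapshot_B",
                      "post_snapshot_face", "violation_X", "violation_Y")
  ev <- design$events
  if (trials == "analysis") ev <- ev[ev$trial_type %in% analysis_types, ]
  rownames(ev) <- NULL

  pairs <- design$pairs
  n_pairs <- nrow(pairs)

  with_seed(seed, {
    # per-pair reactivation weight and realized differentiation shift
    pi_p <- pmin(pmax(rnorm(n_pairs, effect$pred_mean, effect$pred_sd), 0), 1)
    d_p <- pmin(pmax(effect$delta_diff +
                       effect$kappa * (pi_p - effect$pred_mean), 0), 1)
    d_p[pairs$condition != "violation"] <- 0
    pi_p[pairs$condition != "violation"] <- NA_real_

    patterns <- vector("list", length(rois))
    names(patterns) <- rois
    for (roi in rois) {
      # per-pair orthonormal latent blocks
      comp <- vector("list", n_pairs)
      for (i in seq_len(n_pairs)) {
        viol <- pairs$condition[i] == "violation"
        d_i <- k_s + 2L * k_u + k_n + if (viol) 2L * k_u else 0L
        q <- qr.Q(qr(matrix(rnorm(n_vox * d_i), n_vox, d_i)))
        col <- 0L
        # random direction within the block's subspace, fixed norm
        # signal_amp * sqrt(k): keeps per-pair component magnitudes (and so
        # the planted similarity shifts) homogeneous across pairs
        take <- function(k) {
          idx <- col + seq_len(k); col <<- col + k
          w <- rnorm(k)
          w <- w * signal_amp * sqrt(k) / sqrt(sum(w^2))
          as.numeric(q[, idx, drop = FALSE] %*% w)
        }
        comp[[i]] <- list(
          shared = take(k_s), a_unique = take(k_u), b_unique = take(k_u),
          novel = take(k_n),
          x_face = if (viol) take(k_u) else NULL,
          y_face = if (viol) take(k_u) else NULL
        )
      }
      names(comp) <- pairs$pair_id

      mat <- matrix(NA_real_, nrow(ev), n_vox)
      for (t in seq_len(nrow(ev))) {
        i <- match(ev$pair_id[t], pairs$pair_id)
        cp <- comp[[i]]
        mu <- switch(ev$trial_type[t],
          pre_snapshot_A = ,
          pair_A = cp$shared + cp$a_unique,
          pre_snapshot_B = ,
          pair_B = ,
          restudy_B = cp$shared + cp$b_unique,
          post_snapshot_B =
            if (pairs$condition[i] == "violation")
              (1 - d_p[i]) * cp$shared + cp$b_unique + d_p[i] * cp$novel
            else
              (1 + effect$delta_int) * cp$shared + cp$b_unique,
          violation_X = cp$x_face + pi_p[i] * (cp$shared + cp$b_unique),
          violation_Y = cp$y_face + pi_p[i] * (cp$shared + cp$b_unique),
          post_snapshot_face = {
            face <- if (ev$item_id[t] == pairs$x_item[i]) cp$x_face else cp$y_face
            face
          }
        )
        mat[t, ] <- mu + rnorm(n_vox, sd = effect$noise_sd)
      }
      patterns[[roi]] <- mat
    }

    structure(
      list(design = design, group = effect$group, effect = effect,
           events = ev, patterns = patterns,
           ground_truth = data.frame(pair_id = pairs$pair_id,
                                     condition = pairs$condition,
                                     pi = pi_p, d = d_p,
                                     stringsAsFactors = FALSE),
           params = list(n_vox = n_vox, k_s = k_s, k_u = k_u, k_n = k_n,
                         signal_amp = signal_amp, trials = trials),
           seed = seed),
      class = "remdiff_subject"
    )
  })
}

#' Simulate a cohort of subjects across experimental groups
#'
#' Draws independent subject seeds from the master seed. All subjects share
#' one design realization (the similarity analyses are invariant to the
#' per-participant re-randomization of item assignments, so a shared design
#' does not couple subjects); latent patterns and noise are independent
#' across subjects.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param effects Named list of \code{remdiff_effect}, one per group
#'   (default \code{\link{default_group_effects}}).
#' @param seed Master integer seed.
#' @param design Optional shared \code{remdiff_design}; generated from a
#'   derived seed when NULL.
#' @param ... Passed to \code{\link{simulate_subject}} (n_vox, latent sizes,
#'   rois, trials, signal_amp).
#' @return Object of class \code{remdiff_cohort}: list with \code{subjects},
#'   \code{groups}, \code{design}, \code{seed}.
#' @export
simulate_cohort <- function(n_per_group = 23L, effects = default_group_effects(),
                            seed = 1L, design = NULL, ...) {
  if (n_per_group < 2L) stop("n_per_group must be >= 2")
  labels <- vapply(effects, function(e) e$group, character(1))
  if (anyDuplicated(labels)) stop("duplicate group labels in effects")
  seeds <- derive_seeds(seed, length(effects) * n_per_group + 1L)
  if (is.null(design)) design <- generate_design(seed = seeds[1L])
  if (!any(design$events$session == 2L))
    design <- generate_post_session(design, seed = seeds[1L])
  subjects <- vector("list", length(effects) * n_per_group)
  groups <- character(length(subjects))
  k <- 0L
  for (g in seq_along(effects)) {
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      subjects[[k]] <- simulate_subject(design, effects[[g]],
                                        seed = seeds[k + 1L], ...)
      groups[k] <- labels[g]
    }
  }
  names(subjects) <- sprintf("sub%03d", seq_along(subjects))
  structure(list(subjects = subjects, groups = groups, design = design,
                 seed = seed),
            class = "remdiff_cohort")
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peak ~6 s, undershoot ~16 s,
#' peak-to-undershoot ratio 6), normalized to a maximum of 1.
#'
#' @param t Time in seconds (vector).
#' @param peak,undershoot Gamma shape parameters (rate 1) for the response
#'   and undershoot lobes.
#' @param ratio Response-to-undershoot amplitude ratio.
#' @return HRF values at \code{t}.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  h <- dgamma(t, shape = peak, rate = 1) -
    dgamma(t, shape = undershoot, rate = 1) / ratio
  h[t < 0] <- 0
  tt <- seq(0, 32, by = 0.01)
  hmax <- max(dgamma(tt, shape = peak, rate = 1) -
                dgamma(tt, shape = undershoot, rate = 1) / ratio)
  h / hmax
}

#' Render a subject's trial patterns for one run into a BOLD time series
#'
#' Each trial contributes its ground-truth pattern scaled by the canonical
#' double-gamma HRF sampled at the TR grid, summed over overlapping trials,
#' plus white noise. The returned timeline includes lead-in and tail volumes
#' (defaults 9 and 5) so the discard step of
#' \code{\link{preprocess_run}} is exercised; trial onsets in the returned
#' events table are on the acquisition timeline (design onset +
#' \code{lead_in * tr}).
#'
#' @param subject A \code{remdiff_subject} simulated with
#'   \code{trials = "all"} (every trial in the run needs a pattern).
#' @param roi ROI label present in \code{subject$patterns}.
#' @param run Run number to render.
#' @param tr Repetition time, seconds.
#' @param noise_sd Additive white-noise sd on the rendered volumes.
#' @param lead_in,tail Extra volumes before the first trial and after the
#'   HRF of the last trial has decayed.
#' @param hrf Function of time in seconds returning HRF amplitude.
#' @param seed Seed for the rendering noise.
#' @return List with \code{bold} (4D array, voxels x 1 x 1 x time),
#'   \code{mask} (3D logical), \code{events} (acquisition-timeline onsets),
#'   \code{tr}.
#' @export
render_bold <- function(subject, roi, run, tr = 1.5, noise_sd = 0,
                        lead_in = 9L, tail = 5L, hrf = hrf_double_gamma,
                        seed = 1L) {
  stopifnot(inherits(subject, "remdiff_subject"))
  if (!roi %in% names(subject$patterns)) stop("no patterns for roi ", roi)
  idx <- which(subject$events$run == run)
  if (length(idx) == 0L) stop("no trials for run ", run)
  ev <- subject$events[idx, ]
  pat <- subject$patterns[[roi]][idx, , drop = FALSE]
  n_vox <- ncol(pat)
  run_dur <- max(ev$onset) + max(ev$duration) + 24  # let the HRF decay
  if (run_dur <= 0) stop("non-positive run duration")
  n_task <- ceiling(run_dur / tr)
  n_t <- lead_in + n_task + tail
  vol_times <- (seq_len(n_t) - 1L) * tr
  ev$onset <- ev$onset + lead_in * tr

  y <- matrix(0, n_vox, n_t)
  for (i in seq_len(nrow(ev))) {
    h <- hrf(vol_times - ev$onset[i])
    nz <- which(h != 0)
    if (length(nz) > 0L)
      y[, nz] <- y[, nz] + outer(pat[i, ], h[nz])
  }
  if (noise_sd > 0)
    y <- y + with_seed(seed, matrix(rnorm(length(y), sd = noise_sd), n_vox, n_t))
  list(bold = array(y, dim = c(n_vox, 1L, 1L, n_t)),
       mask = array(TRUE, dim = c(n_vox, 1L, 1L)),
       events = ev, tr = tr)
}

#' Simulate a nap hypnogram with exact per-stage totals, plus spindle events
#'
#' Emits a 30-s-epoch stage sequence whose per-stage minute totals equal the
#' targets exactly: a sleep-latency block of wake, then sleep-stage blocks in
#' the order N1, N2, N3, N2, REM with the wake-after-sleep-onset epochs
#' inserted at interior block boundaries. Spindle events are placed uniformly
#' within N2/N3 epochs at the configured per-minute rates, with Poisson
#' counts.
#'
#' @param group Group label; \code{"NREM"} forbids a positive REM target.
#' @param target_minutes Named vector with entries N1, N2, N3, REM, WASO (all
#'   multiples of 0.5). Defaults emulate typical short (NREM) and long (REM)
#'   daytime naps.
#' @param tib_min Time in bed, minutes; sleep latency is
#'   \code{tib - sum(targets)}.
#' @param spindle_rate Named per-minute spindle rates for N2 and N3.
#' @param seed Integer seed.
#' @return List with \code{hypnogram} (a \code{remdiff_hypnogram}) and
#'   \code{spindles} (data.frame: start_s, duration_s, stage, channel).
#' @export
simulate_hypnogram <- function(group = c("REM", "NREM", "Wake"),
                               target_minutes = NULL, tib_min = NULL,
                               spindle_rate = c(N2 = 4.3, N3 = 5.1),
                               seed = 1L) {
  group <- match.arg(group)
  if (is.null(target_minutes)) {
    target_minutes <- switch(group,
      NREM = c(N1 = 6.5, N2 = 22.5, N3 = 20, REM = 0, WASO = 9),
      REM = c(N1 = 9, N2 = 42, N3 = 22, REM = 16.5, WASO = 14),
      Wake = c(N1 = 0, N2 = 0, N3 = 0, REM = 0, WASO = 0))
  }
  if (is.null(tib_min))
    tib_min <- switch(group, NREM = 65, REM = 114,
                      Wake = sum(target_minutes) + 90)
  need <- c("N1", "N2", "N3", "REM", "WASO")
  if (!all(need %in% names(target_minutes)))
    stop("target_minutes must name ", paste(need, collapse = ", "))
  tm <- target_minutes[need]
  if (any(abs(tm / 0.5 - round(tm / 0.5)) > 1e-9))
    stop("target minutes must be multiples of 0.5 (30-s epochs)")
  if (group == "NREM" && tm[["REM"]] > 0)
    stop("group 'NREM' cannot have REM minutes > 0")
  latency <- tib_min - sum(tm)
  if (latency < 0) stop("targets exceed time in bed")

  n_ep <- function(m) as.integer(round(m / 0.5))
  with_seed(seed, {
    n2a <- n_ep(tm[["N2"]]) %/% 2L
    blocks <- list(rep("N1", n_ep(tm[["N1"]])),
                   rep("N2", n2a),
                   rep("N3", n_ep(tm[["N3"]])),
                   rep("N2", n_ep(tm[["N2"]]) - n2a),
                   rep("REM", n_ep(tm[["REM"]])))
    blocks <- blocks[lengths(blocks) > 0L]
    # WASO split across block boundaries (never before sleep onset)
    w <- n_ep(tm[["WASO"]])
    if (w > 0L && length(blocks) > 0L) {
      slots <- max(length(blocks) - 1L, 1L)
      alloc <- tabulate(sample.int(slots, w, replace = TRUE), nbins = slots)
      out <- list()
      for (b in seq_along(blocks)) {
        out[[length(out) + 1L]] <- blocks[[b]]
        if (b <= slots && alloc[b] > 0L)
          out[[length(out) + 1L]] <- rep("W", alloc[b])
      }
      blocks <- out
    }
    stages <- c(rep("W", n_ep(latency)), unlist(blocks))
    h <- hypnogram(stages)

    spl <- list()
    for (st in c("N2", "N3")) {
      mins <- tm[[st]]
      rate <- if (st %in% names(spindle_rate)) spindle_rate[[st]] else 0
      if (mins > 0 && rate > 0) {
        n <- rpois(1L, rate * mins)
        if (n > 0L) {
          ep <- sample_vec(which(stages == st), n, replace = TRUE)
          dur <- runif(n, 0.5, 1.5)
          start <- (ep - 1L) * 30 + runif(n, 0, 30 - max(dur))
          spl[[st]] <- data.frame(start_s = start, duration_s = dur,
                                  stage = st, channel = "CPz",
                                  stringsAsFactors = FALSE)
        }
      }
    }
    spindles <- if (length(spl) > 0L) do.call(rbind, spl) else
      data.frame(start_s = numeric(), duration_s = numeric(),
                 stage = character(), channel = character(),
                 stringsAsFactors = FALSE)
    rownames(spindles) <- NULL
    list(hypnogram = h, spindles = spindles)
  })
}
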
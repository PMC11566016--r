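# Experimental design: A-B scene pairs with violation / nonviolation
# conditions, interleaved learning sequences, and snapshot runs.

# Per-pair learning templates, written in pair-event units. "AB" is an A trial
# followed immediately by its B pairmate; "AX"/"AY" are violation events in
# which A is followed by a novel face; "B" is a lone restudy presentation.
TEMPLATE_VIOLATION <- c("AB", "AB", "AB", "AX", "B", "AY", "B")
TEMPLATE_NONVIOLATION <- c("AB", "AB", "AB", "B", "B")

#' Generate a statistical-learning design with violation and nonviolation pairs
#'
#' Builds the full session-1 design: scene items are assigned to A-B pairs,
#' pairs are split evenly between the violation and nonviolation conditions
#' within each run, and each run consists of a pre-learning snapshot phase
#' (every A and B scene shown once, in randomized order with the constraint
#' that a pair's B never immediately follows its own A) followed by a learning
#' phase in which each pair's event template (violation:
#' AB-AB-AB-AX-B-AY-B; nonviolation: AB-AB-AB-B-B) is interleaved with the
#' other pairs under a spacing constraint: between two successive events of
#' the same pair there are always between \code{min_gap} and \code{max_gap}
#' intervening pair-events.
#'
#' Trials are presented every 3 s (1 s stimulus + 2 s inter-stimulus
#' interval); onsets are seconds from the start of each run.
#'
#' @param seed Integer seed; the design is bit-identical for a fixed seed.
#' @param n_runs Number of session-1 runs (default 6).
#' @param pairs_per_run Pairs per run, split evenly between conditions
#'   (default 16, i.e. 8 violation + 8 nonviolation).
#' @param min_gap,max_gap Minimum/maximum number of intervening pair-events
#'   between successive events of the same pair (defaults 2 and 20).
#' @param max_attempts Resampling bound per run for the constrained
#'   interleaving before giving up with an error.
#' @param stim_s,isi_s Stimulus duration and inter-stimulus interval, seconds.
#' @return An object of class \code{remdiff_design}: a list with elements
#'   \code{pairs} (one row per pair: pair_id, run, condition, a_item, b_item,
#'   x_item, y_item), \code{items} (item_id, category, subcategory),
#'   \code{events} (one row per trial: run, session, index_in_run, onset,
#'   duration, trial_type, item_id, pair_id, condition, pair_event),
#'   \code{seed} and \code{params}.
#' @export
generate_design <- function(seed, n_runs = 6L, pairs_per_run = 16L,
                            min_gap = 2L, max_gap = 20L,
                            max_attempts = 10000L,
                            stim_s = 1.0, isi_s = 2.0) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  n_runs <- as.integer(n_runs)
  pairs_per_run <- as.integer(pairs_per_run)
  if (n_runs < 1L) stop("n_runs must be >= 1")
  if (pairs_per_run < 2L || pairs_per_run %% 2L != 0L)
    stop("pairs_per_run must be an even integer >= 2")

  with_seed(seed, {
    n_pairs <- n_runs * pairs_per_run
    n_viol <- n_pairs %/% 2L

    scene_ids <- sprintf("scene%03d", seq_len(2L * n_pairs))
    scene_sub <- sample(c("indoor", "outdoor"), 2L * n_pairs, replace = TRUE)

    # randomize scene-to-pair assignment and pair-to-condition assignment
    scene_perm <- sample(scene_ids)
    pair_ids <- sprintf("pair%03d", seq_len(n_pairs))
    cond_by_run <- unlist(lapply(seq_len(n_runs), function(r)
      sample(rep(c("violation", "nonviolation"), each = pairs_per_run %/% 2L))))
    pairs <- data.frame(
      pair_id = pair_ids,
      run = rep(seq_len(n_runs), each = pairs_per_run),
      condition = cond_by_run,
      a_item = scene_perm[seq(1L, 2L * n_pairs, by = 2L)],
      b_item = scene_perm[seq(2L, 2L * n_pairs, by = 2L)],
      x_item = NA_character_,
      y_item = NA_character_,
      stringsAsFactors = FALSE
    )
    viol_idx <- which(pairs$condition == "violation")
    face_ids <- sprintf("face%03d", seq_len(2L * length(viol_idx)))
    face_sub <- sample(c("male", "female"), length(face_ids), replace = TRUE)
    pairs$x_item[viol_idx] <- face_ids[seq(1L, length(face_ids), by = 2L)]
    pairs$y_item[viol_idx] <- face_ids[seq(2L, length(face_ids), by = 2L)]

    items <- rbind(
      data.frame(item_id = scene_ids, category = "scene",
                 subcategory = scene_sub, stringsAsFactors = FALSE),
      data.frame(item_id = face_ids, category = "face",
                 subcategory = face_sub, stringsAsFactors = FALSE)
    )

    events <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
      run_pairs <- pairs[pairs$run == r, ]
      snap <- snapshot_phase_order(run_pairs, max_attempts)
      learn <- learning_phase_trials(run_pairs, min_gap, max_gap, max_attempts)
      trials <- rbind(snap, learn)
      n <- nrow(trials)
      data.frame(
        run = r, session = 1L, index_in_run = seq_len(n) - 1L,
        onset = (seq_len(n) - 1L) * (stim_s + isi_s), duration = stim_s,
        trials, stringsAsFactors = FALSE
      )
    }))
    rownames(events) <- NULL

    structure(
      list(pairs = pairs, items = items, events = events, seed = seed,
           params = list(n_runs = n_runs, pairs_per_run = pairs_per_run,
                         min_gap = min_gap, max_gap = max_gap,
                         stim_s = stim_s, isi_s = isi_s)),
      class = "remdiff_design"
    )
  })
}

# Randomized snapshot-phase order for one run: every A and B scene once,
# with a pair's B never immediately following its own A.
snapshot_phase_order <- function(run_pairs, max_attempts) {
  n <- nrow(run_pairs)
  cand <- data.frame(
    trial_type = rep(c("pre_snapshot_A", "pre_snapshot_B"), each = n),
    item_id = c(run_pairs$a_item, run_pairs$b_item),
    pair_id = rep(run_pairs$pair_id, 2L),
    condition = rep(run_pairs$condition, 2L),
    pair_event = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (attempt in seq_len(max_attempts)) {
    ord <- sample.int(nrow(cand))
    out <- cand[ord, ]
    bad <- out$trial_type[-1L] == "pre_snapshot_B" &
      out$trial_type[-nrow(out)] == "pre_snapshot_A" &
      out$pair_id[-1L] == out$pair_id[-nrow(out)]
    if (!any(bad)) return(out)
  }
  stop("could not order snapshot phase (B-after-own-A constraint) after ",
       max_attempts, " attempts")
}

# Constrained interleaving of one run's pair-event templates. Greedy
# randomized construction with deadlines: at each position a pair is eligible
# if its previous event is at least min_gap+1 positions back; a pair whose
# next event would otherwise overshoot max_gap (or run out of room at the
# tail) is forced. Dead ends trigger a fresh resampling attempt.
interleave_pair_events <- function(templates, min_gap, max_gap, max_attempts) {
  counts0 <- lengths(templates)
  n_pairs <- length(templates)
  total <- sum(counts0)
  for (attempt in seq_len(max_attempts)) {
    remaining <- counts0
    last <- rep(NA_integer_, n_pairs)
    out <- integer(total)
    ok <- TRUE
    for (pos in seq_len(total)) {
      elig <- which(remaining > 0L &
                      (is.na(last) | (pos - last - 1L) >= min_gap))
      if (length(elig) == 0L) { ok <- FALSE; break }
      dl_tail <- total - (min_gap + 1L) * (remaining - 1L)
      dl_gap <- ifelse(is.na(last), .Machine$integer.max, last + max_gap + 1L)
      deadline <- pmin(dl_tail, dl_gap)
      forced <- elig[deadline[elig] <= pos]
      if (length(forced) > 1L) { ok <- FALSE; break }
      pick <- if (length(forced) == 1L) forced else sample_vec(elig, 1L)
      out[pos] <- pick
      remaining[pick] <- remaining[pick] - 1L
      last[pick] <- pos
    }
    if (ok) return(list(seq = out, attempts = attempt))
  }
  stop("could not interleave pair events within spacing bounds [", min_gap,
       ", ", max_gap, "] after ", max_attempts, " attempts")
}

# Expand one run's interleaved pair-event sequence into trials.
learning_phase_trials <- function(run_pairs, min_gap, max_gap, max_attempts) {
  templates <- lapply(run_pairs$condition, function(cond)
    if (cond == "violation") TEMPLATE_VIOLATION else TEMPLATE_NONVIOLATION)
  iv <- interleave_pair_events(templates, min_gap, max_gap, max_attempts)
  used <- integer(nrow(run_pairs))
  rows <- vector("list", length(iv$seq))
  for (e in seq_along(iv$seq)) {
    k <- iv$seq[e]
    used[k] <- used[k] + 1L
    ev <- templates[[k]][used[k]]
    p <- run_pairs[k, ]
    tt_item <- switch(ev,
      AB = list(c("pair_A", "pair_B"), c(p$a_item, p$b_item)),
      AX = list(c("pair_A", "violation_X"), c(p$a_item, p$x_item)),
      AY = list(c("pair_A", "violation_Y"), c(p$a_item, p$y_item)),
      B  = list("restudy_B", p$b_item)
    )
    rows[[e]] <- data.frame(
      trial_type = tt_item[[1L]], item_id = tt_item[[2L]],
      pair_id = p$pair_id, condition = p$condition, pair_event = e,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Append session-2 post-learning snapshot runs to a design
#'
#' Adds two runs: one in which every B scene is shown once in random order
#' (post-learning B snapshots), and one in which every X and Y face from the
#' violation condition is shown once in random order (post-learning face
#' snapshots). Trial timing matches session 1 (1 s stimulus, 2 s ISI).
#'
#' @param design A \code{remdiff_design} from \code{\link{generate_design}}.
#' @param seed Integer seed for the two random orders.
#' @return The design with \code{events} extended by the two session-2 runs.
#' @export
generate_post_session <- function(design, seed) {
  stopifnot(inherits(design, "remdiff_design"))
  viol <- design$pairs[design$pairs$condition == "violation", ]
  if (nrow(viol) > 0L && anyNA(c(viol$x_item, viol$y_item)))
    stop("violation pairs are missing X/Y face items")
  stim_s <- design$params$stim_s
  isi_s <- design$params$isi_s
  with_seed(seed, {
    b_run_id <- design$params$n_runs + 1L
    f_run_id <- design$params$n_runs + 2L
    ord_b <- sample.int(nrow(design$pairs))
    b_run <- data.frame(
      run = b_run_id, session = 2L,
      index_in_run = seq_len(nrow(design$pairs)) - 1L,
      onset = (seq_len(nrow(design$pairs)) - 1L) * (stim_s + isi_s),
      duration = stim_s, trial_type = "post_snapshot_B",
      item_id = design$pairs$b_item[ord_b],
      pair_id = design$pairs$pair_id[ord_b],
      condition = design$pairs$condition[ord_b],
      pair_event = NA_integer_, stringsAsFactors = FALSE
    )
    face_items <- c(rbind(viol$x_item, viol$y_item))
    face_pairs <- rep(viol$pair_id, each = 2L)
    f_run <- if (length(face_items) > 0L) {
      ord_f <- sample.int(length(face_items))
      data.frame(
        run = f_run_id, session = 2L,
        index_in_run = seq_along(face_items) - 1L,
        onset = (seq_along(face_items) - 1L) * (stim_s + isi_s),
        duration = stim_s, trial_type = "post_snapshot_face",
        item_id = face_items[ord_f], pair_id = face_pairs[ord_f],
        condition = "violation", pair_event = NA_integer_,
        stringsAsFactors = FALSE
      )
    } else {
      design$events[0L, ]
    }
    design$events <- rbind(design$events, b_run, f_run)
    rownames(design$events) <- NULL
    design
  })
}

#' Validate a design against its structural invariants
#'
#' Pure function; runs every design check and returns a per-rule report
#' rather than raising. Checks: pair counts per condition and run; session-1
#' trial counts; strictly increasing, evenly spaced onsets; same-pair
#' spacing within the configured bounds; exact per-pair template order;
#' total session-1 B-scene exposure count (6 in both conditions: 1 snapshot
#' + 3 pair presentations + 2 restudies); and the snapshot-phase rule that a
#' pair's B never immediately follows its own A.
#'
#' @param design A \code{remdiff_design}.
#' @return A data.frame of class \code{remdiff_validation} with columns
#'   \code{rule}, \code{pass}, \code{detail} (offending pairs/runs if any).
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "remdiff_design"))
  p <- design$params
  ev <- design$events
  s1 <- ev[ev$session == 1L, ]
  res <- list()
  add <- function(rule, pass, detail = "") {
    res[[length(res) + 1L]] <<- data.frame(
      rule = rule, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }

  tab <- table(design$pairs$run, design$pairs$condition)
  half <- p$pairs_per_run %/% 2L
  add("pairs_per_condition_per_run", all(tab == half),
      if (all(tab == half)) "" else "unbalanced condition assignment")

  expected_n <- 2L * p$pairs_per_run +
    half * (2L * sum(TEMPLATE_VIOLATION != "B") + sum(TEMPLATE_VIOLATION == "B")) +
    half * (2L * sum(TEMPLATE_NONVIOLATION != "B") + sum(TEMPLATE_NONVIOLATION == "B"))
  counts <- tapply(s1$onset, s1$run, length)
  add("session1_trials_per_run", all(counts == expected_n),
      paste0("expected ", expected_n, ", got ",
             paste(unique(counts), collapse = ",")))

  onset_ok <- all(vapply(split(s1$onset, s1$run), function(o)
    all(diff(o) > 0) && all(abs(diff(o) - (p$stim_s + p$isi_s)) < 1e-9),
    logical(1)))
  add("onsets_increasing_evenly_spaced", onset_ok)

  # spacing between successive pair-events of the same pair
  bad_pairs <- character()
  for (r in unique(s1$run)) {
    run_ev <- s1[s1$run == r & !is.na(s1$pair_event), ]
    pe <- run_ev[!duplicated(run_ev$pair_event), c("pair_id", "pair_event")]
    for (pid in unique(pe$pair_id)) {
      pos <- sort(pe$pair_event[pe$pair_id == pid])
      if (length(pos) > 1L) {
        gaps <- diff(pos) - 1L
        if (any(gaps < p$min_gap) || any(gaps > p$max_gap))
          bad_pairs <- c(bad_pairs, pid)
      }
    }
  }
  add("pair_spacing_within_bounds", length(bad_pairs) == 0L,
      paste(unique(bad_pairs), collapse = ","))

  # per-pair template order read off the learning-phase trials
  bad_tmpl <- character()
  for (pid in design$pairs$pair_id) {
    cond <- design$pairs$condition[design$pairs$pair_id == pid]
    tr <- s1[s1$pair_id == pid & !is.na(s1$pair_event), ]
    tr <- tr[order(tr$onset), ]
    seen <- character()
    for (e in unique(tr$pair_event)) {
      tt <- tr$trial_type[tr$pair_event == e]
      seen <- c(seen, if (identical(tt, c("pair_A", "pair_B"))) "AB"
                else if (identical(tt, c("pair_A", "violation_X"))) "AX"
                else if (identical(tt, c("pair_A", "violation_Y"))) "AY"
                else if (identical(tt, "restudy_B")) "B" else "??")
    }
    tmpl <- if (cond == "violation") TEMPLATE_VIOLATION else TEMPLATE_NONVIOLATION
    if (!identical(seen, tmpl)) bad_tmpl <- c(bad_tmpl, pid)
  }
  add("template_order_per_pair", length(bad_tmpl) == 0L,
      paste(bad_tmpl, collapse = ","))

  b_counts <- table(s1$item_id[s1$item_id %in% design$pairs$b_item])
  add("b_exposures_equal_6", all(b_counts == 6L),
      paste(names(b_counts)[b_counts != 6L], collapse = ","))

  snap <- s1[grepl("^pre_snapshot", s1$trial_type), ]
  bad_adj <- character()
  for (r in unique(snap$run)) {
    sr <- snap[snap$run == r, ]
    sr <- sr[order(sr$onset), ]
    n <- nrow(sr)
    hit <- sr$trial_type[-1L] == "pre_snapshot_B" &
      sr$trial_type[-n] == "pre_snapshot_A" & sr$pair_id[-1L] == sr$pair_id[-n]
    if (any(hit)) bad_adj <- c(bad_adj, sr$pair_id[-1L][hit])
  }
  add("snapshot_B_not_after_own_A", length(bad_adj) == 0L,
      paste(bad_adj, collapse = ","))

  if (any(ev$session == 2L)) {
    b_run <- ev[ev$trial_type == "post_snapshot_B", ]
    add("post_B_run_one_trial_per_pair",
        nrow(b_run) == nrow(design$pairs) &&
          setequal(b_run$item_id, design$pairs$b_item))
    f_run <- ev[ev$trial_type == "post_snapshot_face", ]
    viol <- design$pairs[design$pairs$condition == "violation", ]
    add("post_face_run_one_trial_per_face",
        nrow(f_run) == 2L * nrow(viol) &&
          setequal(f_run$item_id, c(viol$x_item, viol$y_item)))
  }

  out <- do.call(rbind, res)
  class(out) <- c("remdiff_validation", "data.frame")
  out
}

# Same-pair spacing gaps (intervening pair-events) over all session-1 runs.
# Used by validation, tests and the acceptance script.
#' Scan a design's learning sequences for same-pair repetition spacings
#'
#' @param design A \code{remdiff_design}.
#' @return Integer vector of all gaps (number of intervening pair-events
#'   between successive events of the same pair) across runs.
#' @export
pair_spacing_gaps <- function(design) {
  s1 <- design$events[design$events$session == 1L &
                        !is.na(design$events$pair_event), ]
  gaps <- integer()
  for (r in unique(s1$run)) {
    run_ev <- s1[s1$run == r, ]
    pe <- run_ev[!duplicated(run_ev$pair_event), c("pair_id", "pair_event")]
    for (pid in unique(pe$pair_id)) {
      pos <- sort(pe$pair_event[pe$pair_id == pid])
      if (length(pos) > 1L) gaps <- c(gaps, diff(pos) - 1L)
    }
  }
  gaps
}

#' @export
print.remdiff_design <- function(x, ...) {
  cat("Statistical-learning design (seed ", x$seed, ")\n", sep = "")
  cat("  pairs: ", nrow(x$pairs), " (",
      sum(x$pairs$condition == "violation"), " violation / ",
      sum(x$pairs$condition == "nonviolation"), " nonviolation) over ",
      x$params$n_runs, " runs\n", sep = "")
  cat("  trials:", nrow(x$events), "across sessions",
      paste(unique(x$events$session), collapse = ","), "\n")
  invisible(x)
}
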
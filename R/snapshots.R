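# Minimal functional post-processing and peak-HRF snapshot extraction.
#
# Volumes are plain 4D arrays (x, y, z, time); masks are 3D logical arrays
# on the same spatial grid. Voxel order everywhere is the ascending linear
# index of the mask in its native array layout, so patterns line up across
# items, phases and runs for a given mask.

#' Discard edge volumes, high-pass filter and z-score a functional run
#'
#' Drops \code{discard_front} leading and \code{discard_back} trailing
#' volumes, removes slow drift per voxel by regressing on a discrete-cosine
#' basis whose frequencies lie below \code{hp_cutoff_hz} (plus an
#' intercept), and z-scores each voxel's residual time series to mean 0,
#' sd 1. The returned \code{time_offset = discard_front * tr} must be passed
#' to \code{\link{extract_pattern}} so onsets stated on the original
#' acquisition timeline stay aligned.
#'
#' @param run4d 4D numeric array (x, y, z, time).
#' @param tr Repetition time, seconds.
#' @param discard_front,discard_back Volumes dropped at the start/end
#'   (defaults 9 and 5).
#' @param hp_cutoff_hz High-pass cutoff in Hz (default 1/128).
#' @param tolerant If TRUE, voxels with zero variance after filtering are
#'   set to all-zero and reported in \code{flagged} instead of raising.
#' @return List with \code{data} (cleaned 4D array), \code{time_offset}
#'   (seconds), \code{tr}, \code{n_volumes}, \code{flagged} (linear indices
#'   of zero-variance voxels, tolerant mode).
#' @export
preprocess_run <- function(run4d, tr, discard_front = 9L, discard_back = 5L,
                           hp_cutoff_hz = 1 / 128, tolerant = FALSE) {
  stopifnot(length(dim(run4d)) == 4L, tr > 0)
  n_total <- dim(run4d)[4L]
  if (n_total <= discard_front + discard_back + 1L)
    stop("run too short: ", n_total, " volumes, need > ",
         discard_front + discard_back + 1L)
  keep <- (discard_front + 1L):(n_total - discard_back)
  n <- length(keep)
  sp <- dim(run4d)[1:3]
  y <- matrix(run4d[, , , keep, drop = FALSE], prod(sp), n)

  # discrete-cosine drift basis: component k has frequency k / (2 N tr)
  k_max <- floor(2 * n * tr * hp_cutoff_hz)
  tt <- seq_len(n) - 1L
  basis <- cbind(1, if (k_max >= 1L)
    sapply(seq_len(k_max), function(k) cos(pi * (2 * tt + 1) * k / (2 * n))))
  resid <- t(qr.resid(qr(basis), t(y)))

  sds <- apply(resid, 1L, sd)
  zero <- which(sds < .Machine$double.eps^0.5)
  if (length(zero) > 0L && !tolerant)
    stop("zero-variance voxel(s) after filtering at linear index ",
         paste(utils::head(zero, 5L), collapse = ","),
         "; use tolerant = TRUE to zero them")
  z <- (resid - rowMeans(resid)) / sds
  if (length(zero) > 0L) z[zero, ] <- 0

  list(data = array(z, dim = c(sp, n)),
       time_offset = discard_front * tr, tr = tr, n_volumes = n,
       flagged = zero)
}

#' Extract a single-volume snapshot pattern at the hemodynamic peak
#'
#' Samples the one volume nearest to \code{onset + peak_offset} on the
#' cleaned run's timeline: the 0-based volume index is
#' \code{round((onset + peak_offset - time_offset) / tr)} with half-up
#' rounding. With a 1.5-s TR and the default 4.5-s peak offset this is
#' exactly 3 volumes after the stimulus volume. Voxels are returned in
#' ascending linear index order of the mask.
#'
#' @param run4d Cleaned 4D array (from \code{\link{preprocess_run}$data}).
#' @param mask 3D logical array on the same spatial grid.
#' @param onset Stimulus onset in seconds on the original acquisition
#'   timeline.
#' @param tr Repetition time, seconds.
#' @param peak_offset Seconds after onset at which to sample (default 4.5).
#' @param time_offset Seconds removed from the front of the run by
#'   preprocessing (\code{discard_front * tr}).
#' @return Numeric vector of mask voxel amplitudes with attributes
#'   \code{volume_index} (0-based index actually sampled).
#' @export
extract_pattern <- function(run4d, mask, onset, tr, peak_offset = 4.5,
                            time_offset = 0) {
  stopifnot(length(dim(run4d)) == 4L)
  if (!identical(dim(run4d)[1:3], dim(mask)[1:3]))
    stop("mask and run have different spatial dimensions")
  vox <- which(mask)
  if (length(vox) == 0L) stop("mask is empty")
  idx0 <- round_half_up((onset + peak_offset - time_offset) / tr)
  n_t <- dim(run4d)[4L]
  if (idx0 < 0L || idx0 >= n_t)
    stop("target volume index ", idx0, " out of range [0, ", n_t - 1L, "]")
  vol <- run4d[, , , idx0 + 1L]
  structure(vol[vox], volume_index = as.integer(idx0))
}

#' Build per-ROI, per-phase snapshot matrices from cleaned runs and events
#'
#' Collects one pattern per item and phase: \code{pre} from the session-1
#' run-start snapshot trials, \code{post} from the session-2 snapshot runs,
#' and \code{violation_evoked} from the violation events (keyed by the face
#' item shown). Raises if any referenced item has a missing or duplicated
#' event for a required phase.
#'
#' @param runs List of cleaned runs, each a list with \code{data} (4D
#'   array), \code{events} (trial table with acquisition-timeline onsets),
#'   \code{tr}, and \code{time_offset}.
#' @param masks Named list of 3D logical mask arrays, one per ROI.
#' @param peak_offset Seconds after onset at which patterns are sampled.
#' @return Named list (per ROI) of named lists (per phase: \code{pre},
#'   \code{post}, \code{violation_evoked}) of item-by-voxel matrices with
#'   item_id rownames.
#' @export
build_snapshot_matrices <- function(runs, masks, peak_offset = 4.5) {
  phase_of <- c(pre_snapshot_A = "pre", pre_snapshot_B = "pre",
                post_snapshot_B = "post", post_snapshot_face = "post",
                violation_X = "violation_evoked",
                violation_Y = "violation_evoked")
  all_ev <- do.call(rbind, lapply(seq_along(runs), function(i) {
    ev <- runs[[i]]$events
    ev$.run_index <- i
    ev
  }))
  all_ev <- all_ev[all_ev$trial_type %in% names(phase_of), ]
  all_ev$.phase <- phase_of[all_ev$trial_type]

  dup <- all_ev[duplicated(all_ev[, c("item_id", ".phase")]), ]
  if (nrow(dup) > 0L)
    stop("duplicate phase events for item(s): ",
         paste(unique(dup$item_id), collapse = ","))

  out <- vector("list", length(masks))
  names(out) <- names(masks)
  for (roi in names(masks)) {
    mats <- list()
    for (ph in unique(all_ev$.phase)) {
      sel <- all_ev[all_ev$.phase == ph, ]
      pats <- lapply(seq_len(nrow(sel)), function(j) {
        rn <- runs[[sel$.run_index[j]]]
        extract_pattern(rn$data, masks[[roi]], sel$onset[j], rn$tr,
                        peak_offset = peak_offset,
                        time_offset = rn$time_offset)
      })
      m <- do.call(rbind, pats)
      rownames(m) <- sel$item_id
      mats[[ph]] <- m
    }
    out[[roi]] <- mats
  }
  out
}

# Snapshot matrices straight from a simulated subject's trial patterns
# (the fast path that bypasses BOLD rendering). Returns, per ROI, the
# item-keyed matrices the similarity analyses consume.
#' Assemble analysis snapshot matrices from a simulated subject
#'
#' @param subject A \code{remdiff_subject}.
#' @param roi ROI label (default: first ROI).
#' @return List of item-by-voxel matrices: \code{pre_a}, \code{pre_b},
#'   \code{post_b}, \code{post_face}, \code{evoked} (violation events keyed
#'   by face item).
#' @export
snapshot_matrices <- function(subject, roi = names(subject$patterns)[1L]) {
  stopifnot(inherits(subject, "remdiff_subject"))
  ev <- subject$events
  pat <- subject$patterns[[roi]]
  if (is.null(pat)) stop("no patterns for roi ", roi)
  grab <- function(types) {
    sel <- which(ev$trial_type %in% types)
    if (length(sel) == 0L) return(NULL)
    m <- pat[sel, , drop = FALSE]
    rownames(m) <- ev$item_id[sel]
    if (anyDuplicated(rownames(m)))
      stop("duplicate events for item(s): ",
           paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ","))
    m
  }
  list(pre_a = grab("pre_snapshot_A"),
       pre_b = grab("pre_snapshot_B"),
       post_b = grab("post_snapshot_B"),
       post_face = grab("post_snapshot_face"),
       evoked = grab(c("violation_X", "violation_Y")))
}
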
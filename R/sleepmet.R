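# Sleep architecture metrics, nap classification, and spindle densities
# from 30-s-epoch hypnograms and spindle-event lists.

STAGE_CODES <- c("W", "N1", "N2", "N3", "REM")
EPOCH_S <- 30

#' Construct a hypnogram
#'
#' A sequence of sleep-stage codes, one per 30-s epoch, with the in-bed
#' interval given as a half-open epoch range: epochs \code{lights_off} to
#' \code{lights_on - 1} (1-based) are in bed.
#'
#' @param stages Character vector over {W, N1, N2, N3, REM}.
#' @param lights_off First in-bed epoch index (default 1).
#' @param lights_on One past the last in-bed epoch (default length + 1).
#' @param artifact Integer indices of artifact epochs (excluded from spindle
#'   density denominators).
#' @return Object of class \code{remdiff_hypnogram}.
#' @export
hypnogram <- function(stages, lights_off = 1L,
                      lights_on = length(stages) + 1L,
                      artifact = integer()) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), STAGE_CODES)
  if (length(bad) > 0L)
    stop("unknown stage code(s): ", paste(bad, collapse = ","))
  if (!(lights_off >= 1L && lights_off <= lights_on &&
          lights_on <= length(stages) + 1L))
    stop("need 1 <= lights_off <= lights_on <= length(stages) + 1")
  structure(list(stages = stages, lights_off = as.integer(lights_off),
                 lights_on = as.integer(lights_on),
                 artifact = as.integer(artifact)),
            class = "remdiff_hypnogram")
}

in_bed_idx <- function(h) seq.int(h$lights_off, h$lights_on - 1L)

#' Score sleep architecture from a hypnogram
#'
#' Computes time in bed (TIB), total sleep time (TST), sleep efficiency
#' (TST/TIB), per-stage minutes (N1, N2, N3, REM, and NREM = N1+N2+N3),
#' wake after sleep onset (WASO: all wake epochs from the first sleep epoch
#' to lights-on, including terminal wake), and per-stage percentages of TST.
#' All epochs are 30 s, so every minute value is a multiple of 0.5.
#' Percentages are NA when there is no sleep.
#'
#' @param h A \code{remdiff_hypnogram}.
#' @return List of class \code{remdiff_sleep_arch}: tib_min, tst_min,
#'   sleep_efficiency, minutes (named: N1, N2, N3, REM, NREM), waso_min,
#'   percent (of TST), waso_percent, sleep_onset_epoch (NA if no sleep).
#' @export
score_architecture <- function(h) {
  stopifnot(inherits(h, "remdiff_hypnogram"))
  if (h$lights_off >= h$lights_on) stop("empty in-bed interval")
  s <- h$stages[in_bed_idx(h)]
  tib <- length(s) * EPOCH_S / 60
  onset <- which(s != "W")[1L]
  mins <- vapply(c("N1", "N2", "N3", "REM"),
                 function(st) sum(s == st) * EPOCH_S / 60, numeric(1))
  mins <- c(mins, NREM = unname(mins["N1"] + mins["N2"] + mins["N3"]))
  tst <- unname(mins["N1"] + mins["N2"] + mins["N3"] + mins["REM"])
  waso <- if (is.na(onset)) 0 else sum(s[onset:length(s)] == "W") * EPOCH_S / 60
  pct <- if (tst > 0) 100 * mins / tst else mins * NA_real_
  structure(list(
    tib_min = tib, tst_min = tst,
    sleep_efficiency = if (tib > 0) tst / tib else NA_real_,
    minutes = mins, waso_min = waso, percent = pct,
    waso_percent = if (tst > 0) 100 * waso / tst else NA_real_,
    sleep_onset_epoch = if (is.na(onset)) NA_integer_
      else h$lights_off + onset - 1L
  ), class = "remdiff_sleep_arch")
}

#' Classify a nap as REM, NREM, or reassigned-to-wake
#'
#' Any REM epoch makes the nap a REM nap. Otherwise, the nap counts as NREM
#' sleep if it contains a consolidated sleep bout -- a run of consecutive
#' non-wake epochs, evaluated within the first \code{window_min} minutes
#' after lights off -- of at least \code{min_consolidated_sleep_min}
#' minutes; naps with only short, fragmented sleep bouts (or none) are
#' reassigned to the wake condition.
#'
#' @param h A \code{remdiff_hypnogram}.
#' @param min_consolidated_sleep_min Minimum consolidated sleep, minutes
#'   (default 10).
#' @param window_min Window after lights off within which the bout is
#'   evaluated (default 30).
#' @return List of class \code{remdiff_nap_label}: label (one of "REM",
#'   "NREM", "WAKE_REASSIGNED"), rationale.
#' @export
classify_nap <- function(h, min_consolidated_sleep_min = 10,
                         window_min = 30) {
  stopifnot(inherits(h, "remdiff_hypnogram"))
  s <- h$stages[in_bed_idx(h)]
  if (any(s == "REM"))
    return(structure(list(label = "REM",
                          rationale = "nap contains REM sleep"),
                     class = "remdiff_nap_label"))
  w <- s[seq_len(min(length(s), window_min * 60 / EPOCH_S))]
  runs <- rle(w != "W")
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  longest_min <- longest * EPOCH_S / 60
  if (longest_min >= min_consolidated_sleep_min) {
    structure(list(label = "NREM",
                   rationale = sprintf(
                     "no REM; consolidated NREM bout of %.1f min >= %.1f min",
                     longest_min, min_consolidated_sleep_min)),
              class = "remdiff_nap_label")
  } else {
    structure(list(label = "WAKE_REASSIGNED",
                   rationale = sprintf(
                     "no REM; longest sleep bout in first %d min was %.1f min < %.1f min",
                     window_min, longest_min, min_consolidated_sleep_min)),
              class = "remdiff_nap_label")
  }
}

#' Spindle density per minute of a sleep stage
#'
#' Number of discrete spindle events in the given stage divided by minutes
#' spent in that stage. Artifact epochs are excluded from the denominator,
#' and events starting within artifact epochs are excluded from the count.
#'
#' @param events Data.frame of spindle events (start_s, duration_s, stage).
#' @param h A \code{remdiff_hypnogram}.
#' @param stage "N2" or "N3".
#' @return Density in events per minute.
#' @export
spindle_density <- function(events, h, stage = c("N2", "N3")) {
  stage <- match.arg(stage)
  stopifnot(inherits(h, "remdiff_hypnogram"))
  idx <- in_bed_idx(h)
  stage_ep <- idx[h$stages[idx] == stage & !(idx %in% h$artifact)]
  mins <- length(stage_ep) * EPOCH_S / 60
  if (mins == 0) stop("no non-artifact ", stage, " epochs")
  if (nrow(events) == 0L) return(0)
  ev <- events[events$stage == stage, , drop = FALSE]
  if (nrow(ev) == 0L) return(0)
  ep_of_event <- floor(ev$start_s / EPOCH_S) + 1L
  sum(ep_of_event %in% stage_ep) / mins
}
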
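# Orchestration: per-subject similarity analyses, cohort-level metric
# tables, and the group-level results report.

#' Run all pattern-similarity analyses for one subject
#'
#' For each ROI: pairmate similarity records, the neural differentiation
#' score, the item-specificity randomization test, the B-prediction
#' coupling, and the B-X-Y integration coupling.
#'
#' @param subject A \code{remdiff_subject} (or any object accepted by
#'   \code{\link{snapshot_matrices}}).
#' @param n_shuffles Shuffles for the randomization test (default 1000).
#' @param seed Seed for the randomization test.
#' @return Named list (per ROI) of lists with elements \code{records},
#'   \code{diff}, \code{itemspec}, \code{prediction}, \code{pred_coupling},
#'   \code{bxy}, \code{bxy_coupling}.
#' @export
analyze_subject <- function(subject, n_shuffles = 1000L, seed = 1L) {
  pairs <- subject$design$pairs
  out <- list()
  for (roi in names(subject$patterns)) {
    sm <- snapshot_matrices(subject, roi)
    records <- pair_similarity(sm$pre_a, sm$post_b, pairs)
    diff <- differentiation_score(records)
    itemspec <- item_specificity_z(sm$pre_a, sm$post_b, pairs,
                                   n_shuffles = n_shuffles, seed = seed)
    prediction <- b_prediction_scores(sm$pre_b, sm$evoked, pairs)
    pred_coupling <- coupling_correlation(prediction, records, "violation")
    bxy <- bxy_integration_scores(sm$post_b, sm$post_face, pairs)
    bxy_coupling <- coupling_correlation(bxy, records, "violation")
    out[[roi]] <- list(records = records, diff = diff, itemspec = itemspec,
                       prediction = prediction,
                       pred_coupling = pred_coupling,
                       bxy = bxy, bxy_coupling = bxy_coupling)
  }
  out
}

#' Per-subject metric table for a simulated cohort
#'
#' Runs \code{\link{analyze_subject}} on every subject and collects the
#' scalar metrics the group-level tests consume.
#'
#' @param cohort A \code{remdiff_cohort}.
#' @param n_shuffles Shuffles for the randomization test.
#' @param seed Master seed; per-subject randomization seeds are derived.
#' @return Data.frame: subject, group, roi, diff_score, mean_z_violation,
#'   mean_z_nonviolation, itemspec_z, pred_coupling_z, bxy_coupling_z.
#' @export
analyze_cohort <- function(cohort, n_shuffles = 1000L, seed = 1L) {
  stopifnot(inherits(cohort, "remdiff_cohort"))
  seeds <- derive_seeds(seed, length(cohort$subjects))
  rows <- list()
  for (i in seq_along(cohort$subjects)) {
    res <- analyze_subject(cohort$subjects[[i]], n_shuffles = n_shuffles,
                           seed = seeds[i])
    for (roi in names(res)) {
      r <- res[[roi]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = names(cohort$subjects)[i], group = cohort$groups[i],
        roi = roi, diff_score = r$diff$diff_score,
        mean_z_violation = r$diff$mean_z_violation,
        mean_z_nonviolation = r$diff$mean_z_nonviolation,
        itemspec_z = r$itemspec$z,
        pred_coupling_z = r$pred_coupling$z_within,
        bxy_coupling_z = r$bxy_coupling$z_within,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-level results report for a cohort metric table
#'
#' Mirrors the structure of the primary analyses: per ROI and per measure
#' (differentiation score, item-specificity z, prediction-differentiation
#' coupling, B-X-Y coupling), the REM-vs-no-REM planned contrast
#' (weights REM -1, NREM 0.5, Wake 0.5), the NREM-vs-Wake contrast
#' (weights 0, -1, 1), and the one-sample follow-up within the REM group
#' (one-tailed in the predicted negative direction for differentiation and
#' coupling measures). Contrast rows share a Bonferroni family across ROIs;
#' follow-ups share a family across the three groups.
#'
#' @param metrics Data.frame from \code{\link{analyze_cohort}}.
#' @param alpha Family-wise alpha (default 0.05).
#' @return Data.frame: roi, measure, test, method, statistic, df, p, d,
#'   family_k, adjusted_alpha, significant.
#' @export
cohort_report <- function(metrics, alpha = 0.05) {
  w_rem <- c(REM = -1, NREM = 0.5, Wake = 0.5)
  w_nrem <- c(REM = 0, NREM = -1, Wake = 1)
  measures <- c("diff_score", "itemspec_z", "pred_coupling_z",
                "bxy_coupling_z")
  rois <- unique(metrics$roi)
  fam_roi <- bonferroni_alpha(alpha, length(rois))
  fam_grp <- bonferroni_alpha(alpha, 3L)
  rows <- list()
  add <- function(roi, measure, test, method, statistic, df, p, d, fam) {
    rows[[length(rows) + 1L]] <<- data.frame(
      roi = roi, measure = measure, test = test, method = method,
      statistic = statistic, df = df, p = p, d = d,
      family_k = fam$k, adjusted_alpha = fam$adjusted_alpha,
      significant = p < fam$adjusted_alpha, stringsAsFactors = FALSE)
  }
  for (roi in rois) {
    mr <- metrics[metrics$roi == roi, ]
    for (ms in measures) {
      vals <- split(mr[[ms]], mr$group)
      ct <- planned_contrast(vals, w_rem)
      add(roi, ms, "contrast_REM_vs_noREM", "planned_contrast",
          ct$t, ct$df, ct$p, ct$d, fam_roi)
      ct2 <- planned_contrast(vals, w_nrem)
      add(roi, ms, "contrast_NREM_vs_Wake", "planned_contrast",
          ct2$t, ct2$df, ct2$p, ct2$d, fam_roi)
      if ("REM" %in% names(vals)) {
        tail <- if (ms == "bxy_coupling_z") "two" else "less"
        ot <- one_sample_test(vals$REM, 0, tail = tail)
        add(roi, ms, "one_sample_REM", ot$method, ot$statistic, ot$df,
            ot$p, ot$d, fam_grp)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate a neural metric with sleep-architecture variables
#'
#' Pearson correlations between a per-subject neural measure and sleep
#' variables (e.g. REM minutes, stage minutes, spindle densities), as used
#' for sleep-differentiation relationships.
#'
#' @param metrics Cohort metric table (one row per subject and ROI).
#' @param sleep Data.frame with a \code{subject} column and numeric sleep
#'   variables.
#' @param measure Metric column to correlate (default "diff_score").
#' @param roi ROI to use.
#' @param groups Groups to include (default nap groups NREM and REM).
#' @return Data.frame: sleep_variable, r, p, n.
#' @export
sleep_correlations <- function(metrics, sleep, measure = "diff_score",
                               roi = unique(metrics$roi)[1L],
                               groups = c("NREM", "REM")) {
  mr <- metrics[metrics$roi == roi & metrics$group %in% groups, ]
  merged <- merge(mr, sleep, by = "subject")
  vars <- setdiff(names(sleep), "subject")
  rows <- lapply(vars, function(v) {
    ct <- correlate(merged[[measure]], merged[[v]])
    data.frame(sleep_variable = v, r = ct$r, p = ct$p, n = ct$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
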
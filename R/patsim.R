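# Pairmate pattern similarity, neural differentiation scores, the
# item-specificity randomization test, B-prediction scores, within-subject
# coupling correlations, and the B-X-Y integration control.

#' Fisher z transform of a correlation coefficient
#'
#' @param r Correlation in (-1, 1).
#' @return atanh(r).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("fisher_z requires |r| < 1")
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher z value.
#' @export
inverse_fisher_z <- function(z) tanh(z)

# Clamp policy for degenerate correlations: |r| = 1 can occur on noise-free
# toy inputs; clamp to +/- (1 - 1e-12) with a warning so the z transform
# stays finite without affecting realistic data.
clamp_r <- function(r) {
  hit <- abs(r) >= 1 - 1e-12
  if (any(hit)) {
    warning("correlation(s) at |r| >= 1 clamped to +/-(1 - 1e-12)")
    r[hit] <- sign(r[hit]) * (1 - 1e-12)
  }
  r
}

# Pearson correlation of two patterns with a zero-variance guard.
pattern_cor <- function(x, y, name_x = "x", name_y = "y") {
  if (sd(x) == 0) stop("zero-variance pattern for item ", name_x)
  if (sd(y) == 0) stop("zero-variance pattern for item ", name_y)
  cor(x, y)
}

#' Pairmate pattern similarity: pre-learning A vs post-learning B
#'
#' For each pair, the Pearson correlation across ROI voxels between the
#' pre-learning snapshot of A and the post-learning snapshot of B, plus its
#' Fisher z transform. Smaller values indicate less neural overlap between
#' the pairmates, i.e. more differentiation.
#'
#' @param pre_a Item-by-voxel matrix of pre-learning A snapshots (item_id
#'   rownames).
#' @param post_b Item-by-voxel matrix of post-learning B snapshots.
#' @param pairs Pair table (as in \code{remdiff_design$pairs}) with columns
#'   pair_id, condition, a_item, b_item.
#' @return Data.frame of class \code{remdiff_similarity}: pair_id,
#'   condition, r, z.
#' @export
pair_similarity <- function(pre_a, post_b, pairs) {
  if (ncol(pre_a) != ncol(post_b))
    stop("pre_a and post_b have different voxel counts")
  missing_a <- setdiff(pairs$a_item, rownames(pre_a))
  missing_b <- setdiff(pairs$b_item, rownames(post_b))
  if (length(missing_a) + length(missing_b) > 0L)
    stop("missing snapshots for item(s): ",
         paste(c(missing_a, missing_b), collapse = ","))
  r <- vapply(seq_len(nrow(pairs)), function(i)
    pattern_cor(pre_a[pairs$a_item[i], ], post_b[pairs$b_item[i], ],
                pairs$a_item[i], pairs$b_item[i]),
    numeric(1))
  out <- data.frame(pair_id = pairs$pair_id, condition = pairs$condition,
                    r = r, z = fisher_z(clamp_r(r)),
                    stringsAsFactors = FALSE)
  class(out) <- c("remdiff_similarity", "data.frame")
  out
}

#' Neural differentiation score from pairmate similarity records
#'
#' Per-condition mean of the Fisher z similarities, and their difference
#' (violation minus nonviolation). Negative scores indicate more
#' violation-related differentiation.
#'
#' @param records A \code{remdiff_similarity} data.frame (or any data.frame
#'   with columns condition and z).
#' @return List of class \code{remdiff_diff}: mean_z_violation,
#'   mean_z_nonviolation, diff_score.
#' @export
differentiation_score <- function(records) {
  for (cond in c("violation", "nonviolation"))
    if (!any(records$condition == cond))
      stop("no similarity records in condition ", cond)
  mv <- mean(records$z[records$condition == "violation"])
  mn <- mean(records$z[records$condition == "nonviolation"])
  structure(list(mean_z_violation = mv, mean_z_nonviolation = mn,
                 diff_score = mv - mn),
            class = "remdiff_diff")
}

#' Item-specificity randomization test of the differentiation score
#'
#' Shuffles the B-to-pair assignment within each task condition (uniform
#' permutations, identity allowed) \code{n_shuffles} times, recomputing the
#' differentiation score each time, and z-scores the observed score against
#' the null's mean and sample SD. Negative z means the observed
#' differentiation is specific to the true pairmate assignment.
#'
#' @param pre_a,post_b Item-by-voxel snapshot matrices.
#' @param pairs Pair table (pair_id, condition, a_item, b_item).
#' @param n_shuffles Number of random permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @return List of class \code{remdiff_itemspec}: observed, null_mean,
#'   null_sd, z, n_shuffles, seed.
#' @export
item_specificity_z <- function(pre_a, post_b, pairs, n_shuffles = 1000L,
                               seed = 1L) {
  conds <- c("violation", "nonviolation")
  for (cond in conds)
    if (sum(pairs$condition == cond) < 2L)
      stop("need >= 2 pairs per condition, have ",
           sum(pairs$condition == cond), " in ", cond)
  # all cross-pair preA/postB Fisher-z similarities within each condition;
  # shuffled scores are then means over permuted matrix entries
  zmat <- lapply(conds, function(cond) {
    p <- pairs[pairs$condition == cond, ]
    a <- t(pre_a[p$a_item, , drop = FALSE])
    b <- t(post_b[p$b_item, , drop = FALSE])
    if (any(apply(a, 2L, sd) == 0) || any(apply(b, 2L, sd) == 0))
      stop("zero-variance pattern among condition ", cond, " items")
    fisher_z(clamp_r(suppressWarnings(cor(a, b))))
  })
  names(zmat) <- conds
  n_c <- vapply(zmat, nrow, integer(1))
  observed <- mean(diag(zmat$violation)) - mean(diag(zmat$nonviolation))
  null <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      pv <- sample.int(n_c[["violation"]])
      pn <- sample.int(n_c[["nonviolation"]])
      mean(zmat$violation[cbind(seq_along(pv), pv)]) -
        mean(zmat$nonviolation[cbind(seq_along(pn), pn)])
    }, numeric(1))
  })
  null_sd <- sd(null)
  if (null_sd == 0) stop("degenerate null: all shuffled scores identical")
  structure(list(observed = observed, null_mean = mean(null),
                 null_sd = null_sd, z = (observed - mean(null)) / null_sd,
                 n_shuffles = n_shuffles, seed = seed),
            class = "remdiff_itemspec")
}

#' Per-pair B-prediction scores from violation-evoked patterns
#'
#' For each violation pair, correlates the pre-learning snapshot of B with
#' the patterns evoked by the X and Y violation events, Fisher-z transforms
#' the two correlations, and averages them into a single B-prediction score
#' quantifying covert reactivation of the expected item.
#'
#' @param pre_b Item-by-voxel matrix of pre-learning B snapshots.
#' @param evoked Item-by-voxel matrix of violation-evoked patterns, keyed by
#'   the face item shown (X or Y).
#' @param pairs Pair table; only violation pairs are used.
#' @return Data.frame: pair_id, z_pred.
#' @export
b_prediction_scores <- function(pre_b, evoked, pairs) {
  vp <- pairs[pairs$condition == "violation", ]
  if (nrow(vp) == 0L) stop("no violation pairs")
  missing <- setdiff(c(vp$x_item, vp$y_item), rownames(evoked))
  if (length(missing) > 0L)
    stop("missing evoked pattern(s) for: ", paste(missing, collapse = ","))
  z_pred <- vapply(seq_len(nrow(vp)), function(i) {
    b <- pre_b[vp$b_item[i], ]
    zx <- fisher_z(clamp_r(pattern_cor(b, evoked[vp$x_item[i], ],
                                       vp$b_item[i], vp$x_item[i])))
    zy <- fisher_z(clamp_r(pattern_cor(b, evoked[vp$y_item[i], ],
                                       vp$b_item[i], vp$y_item[i])))
    mean(c(zx, zy))
  }, numeric(1))
  data.frame(pair_id = vp$pair_id, z_pred = z_pred, stringsAsFactors = FALSE)
}

#' Per-pair B-X-Y integration scores (face-noise control)
#'
#' For each violation pair, correlates the post-learning snapshot of B with
#' the post-learning snapshots of its X and Y faces, Fisher-z transforms,
#' and averages. Used to test the alternative explanation that apparent
#' differentiation reflects face features bound into the B representation.
#'
#' @param post_b Item-by-voxel matrix of post-learning B snapshots.
#' @param post_faces Item-by-voxel matrix of post-learning face snapshots.
#' @param pairs Pair table; only violation pairs are used.
#' @return Data.frame: pair_id, z_int.
#' @export
bxy_integration_scores <- function(post_b, post_faces, pairs) {
  vp <- pairs[pairs$condition == "violation", ]
  if (nrow(vp) == 0L) stop("no violation pairs")
  missing <- setdiff(c(vp$x_item, vp$y_item), rownames(post_faces))
  if (length(missing) > 0L)
    stop("missing face snapshot(s) for: ", paste(missing, collapse = ","))
  z_int <- vapply(seq_len(nrow(vp)), function(i) {
    b <- post_b[vp$b_item[i], ]
    zx <- fisher_z(clamp_r(pattern_cor(b, post_faces[vp$x_item[i], ],
                                       vp$b_item[i], vp$x_item[i])))
    zy <- fisher_z(clamp_r(pattern_cor(b, post_faces[vp$y_item[i], ],
                                       vp$b_item[i], vp$y_item[i])))
    mean(c(zx, zy))
  }, numeric(1))
  data.frame(pair_id = vp$pair_id, z_int = z_int, stringsAsFactors = FALSE)
}

#' Within-subject coupling of a per-pair score with pairmate similarity
#'
#' Pearson correlation across pairs between a per-pair score (e.g. the
#' B-prediction or B-X-Y integration score) and the pairmate Fisher-z
#' similarity, plus its Fisher z transform for group-level analysis.
#'
#' @param per_pair_score Data.frame with pair_id and a single score column.
#' @param records \code{remdiff_similarity} records.
#' @param condition Condition whose similarity values to use (default
#'   "violation").
#' @return List of class \code{remdiff_coupling}: r_within, z_within, n.
#' @export
coupling_correlation <- function(per_pair_score, records,
                                 condition = "violation") {
  rec <- records[records$condition == condition, ]
  merged <- merge(per_pair_score, rec[, c("pair_id", "z")], by = "pair_id")
  if (nrow(merged) < 3L)
    stop("need >= 3 matched pairs in condition ", condition,
         ", have ", nrow(merged))
  score_col <- setdiff(names(per_pair_score), "pair_id")[1L]
  x <- merged[[score_col]]
  y <- merged$z
  if (sd(x) == 0) stop("zero variance in per-pair scores")
  if (sd(y) == 0) stop("zero variance in similarity values")
  r <- cor(x, y)
  structure(list(r_within = r, z_within = fisher_z(clamp_r(r)),
                 n = nrow(merged)),
            class = "remdiff_coupling")
}
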
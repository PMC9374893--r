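# Evaluation in the target (FLAIR) space: DICE overlap after resampling and
# thresholding, volume-binned distribution summaries, and the paired
# comparison between two methods.

#' DICE overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks agree perfectly on absence and
#' score 1 by default (configurable, since low-lesion-load subjects otherwise
#' dominate summaries with arbitrary zeros); empty vs nonempty scores 0.
#' @param a,b binary `volume`s or arrays on the same grid.
#' @param empty_value value when both masks are empty (default 1).
#' @return DICE in `[0, 1]`.
#' @export
dice <- function(a, b, empty_value = 1) {
  av <- as_data3(a) > 0.5
  bv <- as_data3(b) > 0.5
  if (!identical(dim(av), dim(bv))) stop("dice: masks on different grids")
  sa <- sum(av); sb <- sum(bv)
  if (sa + sb == 0L) return(empty_value)
  2 * sum(av & bv) / (sa + sb)
}

#' DICE of a T1-space probability map against a FLAIR-space reference
#'
#' The probabilistic map is resampled (trilinear) into the reference FLAIR
#' grid, thresholded (default 50%), and compared with DICE. Resampling
#' precedes thresholding: probabilities interpolate smoothly, hard masks do
#' not.
#' @param t1_prob probabilistic `volume` on the T1 grid.
#' @param flair_ref binary reference `volume` on the FLAIR grid.
#' @param rigid FLAIR-to-T1 world transform.
#' @param threshold probability cut (default 0.5).
#' @param id,method labels carried into the record.
#' @return An `eval_record` data.frame row: id, method, dice,
#'   lesion_volume_mm3 (of the reference mask).
#' @export
dice_in_flair_space <- function(t1_prob, flair_ref, rigid = rigid_transform(),
                                threshold = 0.5, id = NA_character_,
                                method = NA_character_) {
  stopifnot(is_volume(t1_prob), is_volume(flair_ref))
  # t1 volume sits on the T1 grid; mapping FLAIR->T1 is `rigid`, so sampling
  # the T1 map at FLAIR centers uses the inverse direction
  res <- resample(t1_prob, flair_ref$grid, invert_transform(rigid),
                  mode = "trilinear")
  pred <- res$data >= threshold
  ref <- flair_ref$data > 0.5
  data.frame(id = id, method = method,
             dice = dice(pred, ref),
             lesion_volume_mm3 = sum(ref) * prod(flair_ref$grid$voxel_size),
             stringsAsFactors = FALSE)
}

#' Volume-binned DICE summary
#'
#' Bins records by reference lesion volume (quantile bins) and reports per
#' bin the mean, SD and the 5th-95th percentile envelope of the DICE.
#' @param records data.frame with `dice` and `lesion_volume_mm3` columns.
#' @param n_bins number of quantile bins.
#' @return data.frame: bin, n, volume range, mean, sd, p05, p95.
#' @export
volume_binned_summary <- function(records, n_bins = 5L) {
  stopifnot(nrow(records) > 0L)
  n_bins <- max(1L, min(n_bins, nrow(records)))
  br <- unique(stats::quantile(records$lesion_volume_mm3,
                               probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- if (length(br) > 2L)
    cut(records$lesion_volume_mm3, br, include.lowest = TRUE, labels = FALSE)
  else rep(1L, nrow(records))
  out <- lapply(sort(unique(bin)), function(b) {
    d <- records$dice[bin == b]
    v <- records$lesion_volume_mm3[bin == b]
    data.frame(bin = b, n = length(d),
               vol_min_mm3 = min(v), vol_max_mm3 = max(v),
               mean = mean(d), sd = if (length(d) > 1) stats::sd(d) else 0,
               p05 = unname(stats::quantile(d, 0.05)),
               p95 = unname(stats::quantile(d, 0.95)))
  })
  do.call(rbind, out)
}

#' Paired comparison of two methods' DICE records
#'
#' Classical paired t on per-subject differences, matched by `id`. A
#' zero-variance difference is flagged (`degenerate = TRUE`, t infinite or
#' undefined) rather than silently propagated.
#' @param records_a,records_b data.frames with `id` and `dice`.
#' @return list(t, dof, p, mean_diff, degenerate).
#' @export
paired_compare <- function(records_a, records_b) {
  m <- merge(records_a[, c("id", "dice")], records_b[, c("id", "dice")],
             by = "id", suffixes = c("_a", "_b"))
  if (nrow(m) < 2L) stop("paired_compare: need >= 2 matched subjects")
  d <- m$dice_a - m$dice_b
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd <= 1e-12 * max(abs(md), 1)) {
    return(list(t = if (md == 0) 0 else sign(md) * Inf, dof = n - 1L,
                p = if (md == 0) 1 else 0, mean_diff = md, degenerate = TRUE))
  }
  tstat <- md / (sdd / sqrt(n))
  list(t = tstat, dof = n - 1L,
       p = 2 * stats::pt(-abs(tstat), df = n - 1L),
       mean_diff = md, degenerate = FALSE)
}

#' Threshold-stability report
#'
#' Re-evaluates DICE at several probability thresholds; a report (not an
#' assertion) of how sensitive the overall result is to the cut.
#' @param pairs list of `list(t1_prob, flair_ref, rigid, id)` entries.
#' @param thresholds probability cuts to sweep.
#' @return data.frame: threshold, mean_dice, sd_dice, n.
#' @export
threshold_stability <- function(pairs, thresholds = c(0.3, 0.5, 0.7)) {
  out <- lapply(thresholds, function(th) {
    recs <- do.call(rbind, lapply(pairs, function(p)
      dice_in_flair_space(p$t1_prob, p$flair_ref,
                          p$rigid %||% rigid_transform(), threshold = th,
                          id = p$id %||% NA_character_)))
    data.frame(threshold = th, mean_dice = mean(recs$dice),
               sd_dice = if (nrow(recs) > 1) stats::sd(recs$dice) else 0,
               n = nrow(recs))
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
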
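# The spatially sparse cross-resolution loss and its companions.
#
# The training target lives on a thick-slice FLAIR grid; the model output
# lives on the high-resolution T1 grid. Each FLAIR voxel center is mapped
# (through the rigid registration, possibly composed with an augmentation
# transform) to its nearest T1 voxel; the loss is a plain sum of squared
# differences over exactly those pairs. T1 voxels that no FLAIR center maps
# closest to contribute nothing and receive an exactly zero gradient -- they
# are never given an interpolated surrogate signal. The auxiliary cortical
# ribbon term is a dense squared error on the full T1 grid, weighted 0.001.

default_ribbon_weight <- 0.001

check_map_shapes <- function(map, out_dim, flair_dim) {
  if (!inherits(map, "sampling_map")) stop("map must be a sampling_map")
  if (!identical(as.integer(map$t1_shape), as.integer(out_dim)))
    stop("sampling map T1 shape ", paste(map$t1_shape, collapse = "x"),
         " does not match prediction shape ", paste(out_dim, collapse = "x"))
  if (!identical(as.integer(map$flair_shape), as.integer(flair_dim)))
    stop("sampling map FLAIR shape does not match target shape")
}

as_data3 <- function(x) if (is_volume(x)) x$data else x

#' Spatially sparse lesion loss
#'
#' Sum over sampling-map pairs of squared prediction-target differences.
#' @param out1 prediction on the T1 grid (3D array or `volume`, values in
#'   `[0,1]`).
#' @param flair_wmh binary target on the FLAIR grid.
#' @param map a `sampling_map` built from the same grids/transforms.
#' @param grad also return the gradient w.r.t. `out1` (zero at unsampled
#'   voxels).
#' @return The loss, or (with `grad = TRUE`) `list(loss, grad)`.
#' @export
sparse_lesion_loss <- function(out1, flair_wmh, map, grad = FALSE) {
  p <- as_data3(out1)
  t <- as_data3(flair_wmh)
  check_map_shapes(map, dim(p), dim(t))
  d <- p[map$t1_lin] - t[map$flair_lin]
  loss <- sum(d * d)
  if (!grad) return(loss)
  g <- array(0, dim(p))
  # two FLAIR centers may share a T1 voxel; gradients accumulate (the loss is
  # a sum over FLAIR voxels, so such a voxel legitimately counts twice)
  acc <- rowsum(2 * d, map$t1_lin)
  g[as.integer(rownames(acc))] <- acc
  list(loss = loss, grad = g)
}

#' Dense cortical-ribbon loss (auxiliary task)
#'
#' Voxelwise sum of squared differences over the full T1 grid.
#' @param out2 prediction (ribbon channel); `ribbon` the target mask.
#' @param ribbon target ribbon mask on the same grid.
#' @param grad also return the gradient w.r.t. `out2`.
#' @return The loss, or `list(loss, grad)`.
#' @export
ribbon_loss <- function(out2, ribbon, grad = FALSE) {
  p <- as_data3(out2)
  t <- as_data3(ribbon)
  if (!identical(dim(p), dim(t))) stop("ribbon shapes differ")
  d <- p - t
  loss <- sum(d * d)
  if (!grad) return(loss)
  list(loss = loss, grad = 2 * d)
}

#' Joint training loss: sparse lesion term + weighted ribbon term
#'
#' `total = sparse_lesion + weight * ribbon`, with the published weight 0.001
#' as default.
#' @param out1,out2 model outputs (lesion and ribbon channels) on the T1 grid.
#' @param flair_wmh binary lesion target on the FLAIR grid.
#' @param ribbon ribbon target on the T1 grid.
#' @param map a `sampling_map`.
#' @param weight ribbon weight (default 0.001).
#' @param grad also return gradients for both outputs.
#' @return A `loss_terms` list: `sparse_lesion`, `ribbon`, `total`,
#'   `n_sampled` (and `grad1`, `grad2` when requested).
#' @export
joint_loss <- function(out1, out2, flair_wmh, ribbon, map,
                       weight = default_ribbon_weight, grad = FALSE) {
  sl <- sparse_lesion_loss(out1, flair_wmh, map, grad = grad)
  rl <- ribbon_loss(out2, ribbon, grad = grad)
  if (grad) {
    structure(list(sparse_lesion = sl$loss, ribbon = rl$loss,
                   total = sl$loss + weight * rl$loss,
                   n_sampled = length(map$t1_lin),
                   grad1 = sl$grad, grad2 = weight * rl$grad),
              class = "loss_terms")
  } else {
    structure(list(sparse_lesion = sl, ribbon = rl,
                   total = sl + weight * rl,
                   n_sampled = length(map$t1_lin)),
              class = "loss_terms")
  }
}

#' @export
print.loss_terms <- function(x, ...) {
  cat(sprintf("<loss_terms total %.6g = sparse %.6g + 0.001-weighted ribbon %.6g; %d sampled>\n",
              x$total, x$sparse_lesion, x$ribbon, x$n_sampled))
  invisible(x)
}

#' Dense interpolating baseline loss
#'
#' The straightforward alternative the sparse loss is measured against:
#' trilinearly resample the FLAIR target onto the T1 grid and take the dense
#' squared error over the FLAIR field of view.
#' @param out1 prediction `volume` on the T1 grid.
#' @param flair_wmh binary target `volume` on the FLAIR grid.
#' @param rigid FLAIR-to-T1 world transform.
#' @param grad also return the gradient w.r.t. `out1`.
#' @return The loss, or `list(loss, grad)`.
#' @export
dense_interpolating_loss <- function(out1, flair_wmh, rigid = rigid_transform(),
                                     grad = FALSE) {
  stopifnot(is_volume(out1), is_volume(flair_wmh))
  res <- resample(flair_wmh, out1$grid, rigid, mode = "trilinear")
  fov <- resample(volume(array(1, flair_wmh$grid$shape), flair_wmh$grid),
                  out1$grid, rigid, mode = "nearest")$data > 0
  d <- (out1$data - res$data) * fov
  loss <- sum(d * d)
  if (!grad) return(loss)
  list(loss = loss, grad = 2 * d)
}
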
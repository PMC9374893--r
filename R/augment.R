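# Training-time augmentations: constrained random rigid/affine transforms,
# monotone histogram warping, and simulated lacunes. All are deterministic
# under a fixed seed, and zero-strength settings are exact identities.

#' Augmentation parameters
#'
#' @param max_rotation_deg per-axis rotation bound (scalar or length 3).
#' @param max_translation_mm translation bound in mm.
#' @param axial_only rotate only around the slice (z) axis -- used in FLAIR
#'   space to avoid inter-slice resampling; the T1-space default allows full
#'   3D rotations.
#' @param max_scale relative isotropic scale bound (0 keeps the transform
#'   rigid).
#' @param histogram_knots,histogram_strength monotone intensity-warp control
#'   points and strength.
#' @param lacune_count_range,lacune_radius_range_mm,lacune_intensity_drop
#'   simulated-lacune settings.
#' @return An `augment_params` list.
#' @export
augment_params <- function(max_rotation_deg = 10, max_translation_mm = 5,
                           axial_only = FALSE, max_scale = 0,
                           histogram_knots = 5, histogram_strength = 0.3,
                           lacune_count_range = c(4L, 10L),
                           lacune_radius_range_mm = c(1.5, 3.5),
                           lacune_intensity_drop = 0.8) {
  rot <- rep(max_rotation_deg, length.out = 3)
  if (axial_only) rot[1:2] <- 0
  structure(list(max_rotation_deg = rot,
                 max_translation_mm = max_translation_mm,
                 axial_only = axial_only, max_scale = max_scale,
                 histogram_knots = as.integer(histogram_knots),
                 histogram_strength = histogram_strength,
                 lacune_count_range = as.integer(lacune_count_range),
                 lacune_radius_range_mm = lacune_radius_range_mm,
                 lacune_intensity_drop = lacune_intensity_drop),
            class = "augment_params")
}

rot_axis <- function(axis, theta) {
  c1 <- cos(theta); s1 <- sin(theta)
  m <- diag(4)
  ax <- setdiff(1:3, axis)
  m[ax[1], ax[1]] <- c1; m[ax[2], ax[2]] <- c1
  m[ax[1], ax[2]] <- -s1; m[ax[2], ax[1]] <- s1
  m
}

#' Draw a random constrained affine transform
#'
#' Rotation angles and translations are uniform within their bounds;
#' `axial_only` leaves the slice axis fixed. About a given center (mm) so
#' volumes rotate around their middle rather than the origin.
#' @param params an `augment_params`.
#' @param seed RNG seed (deterministic draw).
#' @param center_mm rotation center.
#' @return A `rigid_transform` (flagged non-rigid when `max_scale > 0`).
#' @export
random_affine <- function(params, seed, center_mm = c(0, 0, 0)) {
  stopifnot(inherits(params, "augment_params"))
  set.seed(seed)
  ang <- stats::runif(3, -params$max_rotation_deg, params$max_rotation_deg) *
    pi / 180
  tr <- stats::runif(3, -params$max_translation_mm, params$max_translation_mm)
  sc <- 1 + stats::runif(1, -params$max_scale, params$max_scale)
  m <- rot_axis(3L, ang[3]) %*% rot_axis(2L, ang[2]) %*% rot_axis(1L, ang[1])
  m[1:3, 1:3] <- m[1:3, 1:3] * sc
  m[1:3, 4] <- tr
  # conjugate by the center so rotation/scale act about center_mm
  pre <- diag(4); pre[1:3, 4] <- -center_mm
  post <- diag(4); post[1:3, 4] <- center_mm
  out <- post %*% m %*% pre
  rigid_transform(out, rigid = params$max_scale == 0)
}

#' Random monotone histogram warp
#'
#' Applies a random monotone piecewise-smooth intensity mapping (a Hyman
#' monotone spline through jittered knots of the intensity range), emulating
#' scanner-to-scanner contrast variation. Rank order of voxel intensities is
#' preserved; strength 0 is the identity.
#' @param vol a `volume` with finite intensities.
#' @param params an `augment_params` (`histogram_knots`, `histogram_strength`).
#' @param seed RNG seed.
#' @return A `volume`.
#' @export
histogram_warp <- function(vol, params, seed) {
  stopifnot(is_volume(vol), inherits(params, "augment_params"))
  if (!all(is.finite(vol$data))) stop("histogram_warp: non-finite intensities")
  if (params$histogram_strength == 0) return(vol)
  set.seed(seed)
  k <- max(3L, params$histogram_knots)
  lo <- min(vol$data); hi <- max(vol$data)
  if (hi <= lo) return(vol)
  xk <- seq(lo, hi, length.out = k)
  # jitter interior knot heights, keep monotone by construction (positive
  # increments), pin the range ends
  inc <- diff(xk) * exp(stats::runif(k - 1, -1, 1) * params$histogram_strength)
  yk <- lo + c(0, cumsum(inc)) / sum(inc) * (hi - lo)
  f <- stats::splinefun(xk, yk, method = "hyman")
  volume(array(f(vol$data), dim(vol$data)), vol$grid)
}

#' Scatter simulated lacunes through the white matter
#'
#' Lowers the intensity inside small smooth-edged patches (centers strictly
#' inside the white-matter mask) toward the CSF level, emulating lacunar
#' cavities that confuse tissue classifiers. Returns the modified image and
#' the ground-truth lacune mask.
#' @param vol T1-like `volume`.
#' @param wm_mask binary white-matter `volume` on the same grid (nonempty).
#' @param params an `augment_params`.
#' @param seed RNG seed.
#' @return `list(volume, lacune_mask)` -- `lacune_mask` is a binary `volume`.
#' @export
scatter_lacunes <- function(vol, wm_mask, params, seed) {
  stopifnot(is_volume(vol), is_volume(wm_mask),
            inherits(params, "augment_params"))
  w <- wm_mask$data > 0.5
  if (!any(w)) stop("scatter_lacunes: empty white-matter mask")
  set.seed(seed)
  cr <- params$lacune_count_range
  k <- if (cr[1] >= cr[2]) cr[1] else sample(cr[1]:cr[2], 1L)
  img <- vol$data
  s <- dim(img)
  vz <- vol$grid$voxel_size
  att <- array(0, s) # attenuation field in [0,1]
  center_mm <- matrix(numeric(0), ncol = 3)
  if (k > 0) {
    wmi <- which(w)
    centers <- wmi[sample.int(length(wmi), k, replace = TRUE)]
    for (v in centers) {
      z <- (v - 1L) %/% (s[1] * s[2])
      rem <- (v - 1L) %% (s[1] * s[2])
      cy <- rem %/% s[1]; cx <- rem %% s[1]
      cmm <- c(cx, cy, z) * vz
      center_mm <- rbind(center_mm, cmm)
      rad <- stats::runif(1, params$lacune_radius_range_mm[1],
                          params$lacune_radius_range_mm[2])
      lo <- pmax(1L, floor((cmm - 2 * rad) / vz) + 1L)
      hi <- pmin(s, ceiling((cmm + 2 * rad) / vz) + 1L)
      xs <- (seq(lo[1], hi[1]) - 1L) * vz[1]
      ys <- (seq(lo[2], hi[2]) - 1L) * vz[2]
      zs <- (seq(lo[3], hi[3]) - 1L) * vz[3]
      d2 <- outer(outer((xs - cmm[1])^2, (ys - cmm[2])^2, "+"),
                  (zs - cmm[3])^2, "+")
      blob <- exp(-(d2 / rad^2)^2)
      blob[blob < 0.05] <- 0
      sub <- att[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
      att[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- pmax(sub, blob)
    }
  }
  att <- att * params$lacune_intensity_drop
  csf <- T1_INTENSITY[["csf"]]
  out <- img * (1 - att) + csf * att
  mask <- array(as.numeric(att > 0.5 * params$lacune_intensity_drop), s)
  rownames(center_mm) <- NULL
  list(volume = volume(out, vol$grid),
       lacune_mask = volume(mask, vol$grid),
       centers_mm = center_mm)
}
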
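# Synthetic paired-resolution phantoms.
#
# A phantom is a small "head": an ellipsoidal brain whose outer 1-3 voxels
# form a cortical ribbon, two ellipsoidal ventricles, and white matter in
# between. Lesions are smooth super-Gaussian blobs (differentiable borders
# mimic partial-volume effects) confined to white matter and placed by class:
# periventricular within 9 mm of the ventricles, juxtacortical against the
# ribbon, deep elsewhere. Rendering reproduces the contrast facts the method
# lives on: on T1 the lesions take gray-matter-like intensity (so no global
# threshold separates lesion from ribbon), on FLAIR they are frankly
# hyperintense; the FLAIR volume is produced by slice-profile integration
# (slab averaging of the high-resolution signal), not nearest-slice sampling.

T1_INTENSITY <- c(bg = 0, wm = 1.0, gm = 0.62, csf = 0.10)
FLAIR_INTENSITY <- c(bg = 0, wm = 0.35, gm = 0.45, csf = 0.05, lesion = 1.0)

#' Generate a ground-truth phantom
#'
#' @param seed integer; the phantom is bit-reproducible given the seed.
#' @param shape high-resolution grid shape (>= c(32, 32, 16)).
#' @param n_lesions_by_class integer vector (periventricular, deep,
#'   juxtacortical) lesion counts.
#' @param lesion_radius_range blob radius range in mm.
#' @param voxel_size mm voxel sizes of the high-resolution grid.
#' @param pv_radius_mm periventricular zone: within this distance of the
#'   ventricles (default 9 mm).
#' @param jc_radius_mm juxtacortical zone: within this distance of the ribbon.
#' @return A `phantom_truth`: `tissue_labels` (volume coded 0 background,
#'   1 white matter, 2 cortex ribbon, 3 ventricle), `lesion_field` (volume in
#'   `[0,1]`, nonzero only in white matter), `grid`, and `lesion_components`
#'   (data.frame of mm centers, radii and classes).
#' @export
make_phantom <- function(seed, shape = c(64L, 64L, 48L),
                         n_lesions_by_class = c(2L, 2L, 1L),
                         lesion_radius_range = c(3, 8),
                         voxel_size = c(1, 1, 1),
                         pv_radius_mm = 9, jc_radius_mm = 4) {
  shape <- as.integer(shape)
  if (any(shape < c(32L, 32L, 16L)))
    stop("phantom shape must be at least 32x32x16")
  g <- grid(shape, voxel_size)
  set.seed(seed)
  ext <- shape * voxel_size
  ctr <- ext / 2
  idx <- grid_indices(g)
  mm <- apply_affine(g$affine, idx)
  # brain ellipsoid; semi-axes, ventricle size and head position vary across
  # subjects to emulate cohort heterogeneity -- without it a desk-scale net
  # can memorize anatomy by position alone and never needs the image
  semi <- ext * (0.42 + stats::runif(3, 0, 0.05))
  jitter <- stats::runif(3, -0.015, 0.015) * ext
  bctr <- ctr + jitter
  r2 <- ((mm[, 1] - bctr[1]) / semi[1])^2 + ((mm[, 2] - bctr[2]) / semi[2])^2 +
        ((mm[, 3] - bctr[3]) / semi[3])^2
  brain <- array(r2 <= 1, shape)
  # ribbon: outer shell of the brain, ~2 voxels thick
  d_out <- edt_sq(!brain, shape, voxel_size)
  ribbon <- brain & array(d_out <= (2 * min(voxel_size))^2 + 1e-9, shape)
  # two ventricle ellipsoids near the center; size varies per subject
  vent <- array(FALSE, shape)
  vscale <- stats::runif(1, 0.85, 1.15)
  for (s in c(-1, 1)) {
    vc <- bctr + c(s * 0.08 * ext[1], 0, 0)
    vs <- ext * c(0.05, 0.13, 0.10) * vscale
    vr2 <- ((mm[, 1] - vc[1]) / vs[1])^2 + ((mm[, 2] - vc[2]) / vs[2])^2 +
           ((mm[, 3] - vc[3]) / vs[3])^2
    vent <- vent | array(vr2 <= 1, shape)
  }
  vent <- vent & brain & !ribbon
  wm <- brain & !ribbon & !vent
  labels <- array(0L, shape)
  labels[wm] <- 1L; labels[ribbon] <- 2L; labels[vent] <- 3L

  d_vent <- array(sqrt(edt_sq(vent, shape, voxel_size)), shape)
  d_rib <- array(sqrt(edt_sq(ribbon, shape, voxel_size)), shape)
  zone_pv <- wm & d_vent <= pv_radius_mm
  zone_jc <- wm & d_rib <= jc_radius_mm & !zone_pv
  zone_deep <- wm & !zone_pv & !zone_jc
  zones <- list(periventricular = zone_pv, deep = zone_deep,
                juxtacortical = zone_jc)
  n <- as.integer(n_lesions_by_class)
  stopifnot(length(n) == 3L, all(n >= 0L))
  counts <- c(periventricular = n[1], deep = n[2], juxtacortical = n[3])

  field <- array(0, shape)
  comps <- list()
  for (cls in names(counts)) {
    if (counts[[cls]] == 0L) next
    zone <- zones[[cls]]
    if (!any(zone))
      stop("no eligible placement voxels for lesion class '", cls, "'")
    # interior distance: placing centers away from the zone border keeps most
    # of each blob inside its nominal region
    margin <- array(sqrt(edt_sq(!zone, shape, voxel_size)), shape)
    margin[!zone] <- 0
    for (j in seq_len(counts[[cls]])) {
      placed <- FALSE
      for (try in 1:100) {
        rad <- stats::runif(1, lesion_radius_range[1], lesion_radius_range[2])
        want <- min(rad, max(margin) * 0.9) / 2^((try - 1) %/% 25)
        elig <- which(zone & margin >= want)
        if (length(elig) == 0L) next
        v <- elig[sample.int(length(elig), 1L)]
        cmm <- mm[v, ]
        # super-Gaussian blob, evaluated on its bounding box only
        lo <- pmax(1L, floor((cmm - 2 * rad) / voxel_size) + 1L)
        hi <- pmin(shape, ceiling((cmm + 2 * rad) / voxel_size) + 1L)
        if (any(lo > hi)) next
        xs <- (seq(lo[1], hi[1]) - 1L) * voxel_size[1]
        ys <- (seq(lo[2], hi[2]) - 1L) * voxel_size[2]
        zs <- (seq(lo[3], hi[3]) - 1L) * voxel_size[3]
        dist2 <- outer(outer((xs - cmm[1])^2, (ys - cmm[2])^2, "+"),
                       (zs - cmm[3])^2, "+")
        blob <- exp(-(dist2 / rad^2)^2)
        blob[blob < 0.01] <- 0
        sub <- field[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
        field[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- pmax(sub, blob)
        comps[[length(comps) + 1L]] <-
          data.frame(x = cmm[1], y = cmm[2], z = cmm[3], radius_mm = rad,
                     class = cls, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place a lesion of class '", cls, "'")
    }
  }
  field[!wm] <- 0 # lesions exist only in white matter
  structure(list(
    tissue_labels = volume(labels, g),
    lesion_field = volume(field, g),
    grid = g,
    lesion_components = if (length(comps)) do.call(rbind, comps)
                        else data.frame(x = numeric(0), y = numeric(0),
                                        z = numeric(0), radius_mm = numeric(0),
                                        class = character(0)),
    pv_radius_mm = pv_radius_mm, jc_radius_mm = jc_radius_mm
  ), class = "phantom_truth")
}

#' Extract a tissue mask from a phantom
#' @param truth a `phantom_truth`.
#' @param tissue one of `"wm"`, `"ribbon"`, `"ventricle"`, `"brain"`.
#' @return Logical array on the truth grid.
#' @export
truth_mask <- function(truth, tissue = c("wm", "ribbon", "ventricle", "brain")) {
  tissue <- match.arg(tissue)
  lab <- truth$tissue_labels$data
  switch(tissue,
         wm = lab == 1L, ribbon = lab == 2L, ventricle = lab == 3L,
         brain = lab > 0L)
}

#' Acquisition settings for rendering a phantom
#'
#' @param contrast `"t1"` (high-resolution, on the truth grid) or `"flair"`
#'   (thick axial slices; `slice_thickness_mm` must exceed `in_plane_mm` and
#'   be an integer multiple of the truth z spacing).
#' @param slice_thickness_mm,n_slices FLAIR slab geometry; `n_slices = NULL`
#'   fits as many slabs as the truth extent holds.
#' @param in_plane_mm in-plane sampling (default: the truth in-plane sizes).
#' @param noise_sd additive Gaussian noise, in units of the [0,1] signal.
#' @param z_offset_mm shift of the slab stack along the slice axis (emulates
#'   the scanner table position; must be a multiple of the truth z spacing).
#'   Varying it across subjects exposes every slab phase to a model trained
#'   on the resulting sparse targets.
#' @param seed noise seed.
#' @return An `acquisition_spec` list.
#' @export
acquisition_spec <- function(contrast = c("t1", "flair"),
                             slice_thickness_mm = 6, n_slices = NULL,
                             in_plane_mm = NULL, noise_sd = 0.02,
                             z_offset_mm = 0, seed = 0L) {
  contrast <- match.arg(contrast)
  structure(list(contrast = contrast, slice_thickness_mm = slice_thickness_mm,
                 n_slices = n_slices, in_plane_mm = in_plane_mm,
                 noise_sd = noise_sd, z_offset_mm = z_offset_mm,
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}

flair_grid_for <- function(truth, spec) {
  vz <- truth$grid$voxel_size
  shape <- truth$grid$shape
  Tm <- spec$slice_thickness_mm
  if (Tm <= max(vz[1:2]))
    stop("flair slice thickness must exceed the in-plane voxel size")
  m <- Tm / vz[3]
  if (abs(m - round(m)) > 1e-9)
    stop("slice thickness must be an integer multiple of the truth z spacing")
  m <- as.integer(round(m))
  nmax <- shape[3] %/% m
  ns <- if (is.null(spec$n_slices)) nmax else as.integer(spec$n_slices)
  if (ns < 1L || ns > nmax)
    stop("n_slices inconsistent with truth extent (max ", nmax, ")")
  ip <- if (is.null(spec$in_plane_mm)) vz[1:2] else rep(spec$in_plane_mm, 2)[1:2]
  nxy <- floor(shape[1:2] * vz[1:2] / ip)
  koff <- (spec$z_offset_mm %||% 0) / vz[3]
  if (abs(koff - round(koff)) > 1e-9)
    stop("z_offset_mm must be a multiple of the truth z spacing")
  k0 <- ((shape[3] - ns * m) %/% 2L) + as.integer(round(koff))
  if (k0 < 0L || k0 + ns * m > shape[3])
    stop("z_offset_mm pushes the slab stack outside the truth extent")
  aff <- diag(c(ip, Tm, 1))
  # voxel centers: slab s center sits at the mean of its m member slices
  aff[3, 4] <- (k0 + (m - 1) / 2) * vz[3]
  # in-plane: first flair center offset so coverage is centered
  aff[1, 4] <- (shape[1] * vz[1] - nxy[1] * ip[1]) / 2 + (ip[1] - vz[1]) / 2
  aff[2, 4] <- (shape[2] * vz[2] - nxy[2] * ip[2]) / 2 + (ip[2] - vz[2]) / 2
  list(grid = grid(c(nxy, ns), c(ip, Tm), aff), m = m, k0 = k0)
}

slab_average <- function(signal_vol, truth, fg) {
  # mean over each slab of the high-res signal, sampled at the FLAIR in-plane
  # centers (pure slab average when in-plane grids coincide)
  g <- fg$grid
  vz <- truth$grid$voxel_size[3]
  acc <- array(0, g$shape)
  for (j in seq_len(fg$m) - 1L) {
    # slab member j: same slab spacing, origin shifted to high-res slice j
    sub_aff <- g$affine
    sub_aff[3, 4] <- (fg$k0 + j) * vz
    sub <- grid(g$shape, g$voxel_size, sub_aff)
    acc <- acc + resample(signal_vol, sub, mode = "trilinear")$data
  }
  volume(acc / fg$m, g)
}

#' Render a phantom under an acquisition
#'
#' T1 contrast: white matter brightest, ribbon and lesions at the same
#' gray-matter level, CSF dark; returned on the truth grid. FLAIR contrast:
#' lesions strictly above white and gray matter, CSF suppressed; the
#' high-resolution signal is averaged within each thick slab and returned on
#' the FLAIR grid together with the (exact) rigid FLAIR-to-T1 transform.
#'
#' @param truth a `phantom_truth`.
#' @param spec an `acquisition_spec`.
#' @return For `"t1"`: a `volume`. For `"flair"`: `list(volume, grid, rigid)`.
#' @export
render <- function(truth, spec) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(spec, "acquisition_spec"))
  lab <- truth$tissue_labels$data
  les <- truth$lesion_field$data
  if (spec$contrast == "t1") {
    base <- array(T1_INTENSITY[["bg"]], dim(lab))
    base[lab == 1L] <- T1_INTENSITY[["wm"]]
    base[lab == 2L] <- T1_INTENSITY[["gm"]]
    base[lab == 3L] <- T1_INTENSITY[["csf"]]
    img <- base * (1 - les) + T1_INTENSITY[["gm"]] * les
    if (spec$noise_sd > 0) {
      set.seed(spec$seed)
      img <- img + array(stats::rnorm(length(img), sd = spec$noise_sd), dim(img))
    }
    return(volume(img, truth$grid))
  }
  base <- array(FLAIR_INTENSITY[["bg"]], dim(lab))
  base[lab == 1L] <- FLAIR_INTENSITY[["wm"]]
  base[lab == 2L] <- FLAIR_INTENSITY[["gm"]]
  base[lab == 3L] <- FLAIR_INTENSITY[["csf"]]
  sig <- base * (1 - les) + FLAIR_INTENSITY[["lesion"]] * les
  fg <- flair_grid_for(truth, spec)
  out <- slab_average(volume(sig, truth$grid), truth, fg)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    out$data <- out$data +
      array(stats::rnorm(length(out$data), sd = spec$noise_sd), dim(out$data))
  }
  list(volume = out, grid = fg$grid, rigid = rigid_transform())
}

#' Clean FLAIR-space lesion training target
#'
#' The ground-truth lesion field is slab-averaged onto the FLAIR grid and
#' thresholded at 0.5; this stands in for an external FLAIR segmenter's
#' output on a clean case.
#' @param truth a `phantom_truth`; `spec` a `"flair"` `acquisition_spec`.
#' @param spec an `acquisition_spec` with flair contrast.
#' @return Binary `volume` on the FLAIR grid.
#' @export
lesion_mask_flair <- function(truth, spec) {
  fg <- flair_grid_for(truth, spec)
  avg <- slab_average(truth$lesion_field, truth, fg)
  volume(array(as.numeric(avg$data >= 0.5), fg$grid$shape), fg$grid)
}

#' Corrupt a FLAIR target mask
#'
#' Emulates the documented failure taxonomy of automatic FLAIR segmenters:
#' `miss_small` deletes small connected components (false negatives),
#' `bright_artifact` adds spurious components outside the true lesions (false
#' positives), `motion` shears a random subset of slices in-plane.
#'
#' @param mask binary `volume` (FLAIR grid).
#' @param mode `"miss_small"`, `"bright_artifact"` or `"motion"`.
#' @param seed RNG seed; output is deterministic given it.
#' @param min_voxels `miss_small`: components strictly smaller than this are
#'   deleted.
#' @param n_artifacts,artifact_radius `bright_artifact` parameters (voxels).
#' @return A binary `volume`.
#' @export
corrupt_target <- function(mask, mode = c("miss_small", "bright_artifact",
                                          "motion"),
                           seed = 0L, min_voxels = 20L, n_artifacts = 3L,
                           artifact_radius = 3L) {
  mode <- match.arg(mode)
  stopifnot(is_volume(mask))
  m <- mask$data > 0.5
  set.seed(seed)
  s <- dim(m)
  out <- m
  if (mode == "miss_small") {
    lab <- label_components(m, s)
    if (max(lab) > 0L) {
      sizes <- tabulate(lab[lab > 0L])
      kill <- which(sizes < min_voxels)
      out[lab %in% kill] <- FALSE
    }
  } else if (mode == "bright_artifact") {
    bg <- which(!m)
    for (i in seq_len(n_artifacts)) {
      v <- bg[sample.int(length(bg), 1L)]
      z <- (v - 1L) %/% (s[1] * s[2])
      rem <- (v - 1L) %% (s[1] * s[2])
      cy <- rem %/% s[1]; cx <- rem %% s[1]
      xs <- pmax(0L, cx - artifact_radius):pmin(s[1] - 1L, cx + artifact_radius)
      ys <- pmax(0L, cy - artifact_radius):pmin(s[2] - 1L, cy + artifact_radius)
      dd <- outer((xs - cx)^2, (ys - cy)^2, "+") <= artifact_radius^2
      out[xs + 1L, ys + 1L, z + 1L][dd] <- TRUE
    }
  } else { # motion: in-plane shear/duplication of a random subset of slices
    zs <- sample(seq_len(s[3]), max(1L, s[3] %/% 2L))
    for (z in zs) {
      k <- sample(c(-3L, -2L, 2L, 3L), 1L)
      sl <- out[, , z]
      shifted <- sl * FALSE
      if (k > 0) shifted[(k + 1):s[1], ] <- sl[1:(s[1] - k), ]
      else shifted[1:(s[1] + k), ] <- sl[(1 - k):s[1], ]
      out[, , z] <- sl | shifted # duplication-style ghosting
    }
  }
  volume(array(as.numeric(out), s), mask$grid)
}
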
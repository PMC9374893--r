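# Shared fixtures: all built in code, deliberately small.

# a random rigid transform with bounded rotation/translation
rand_rigid <- function(seed, max_deg = 15, max_mm = 4) {
  set.seed(seed)
  ang <- runif(3, -max_deg, max_deg) * pi / 180
  rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  m <- diag(4)
  m[1:3, 1:3] <- rz(ang[3]) %*% ry(ang[2]) %*% rx(ang[1])
  m[1:3, 4] <- runif(3, -max_mm, max_mm)
  rigid_transform(m)
}

# brute-force sampling map: for every FLAIR center, nearest T1 center by
# exhaustive world-space distance over all T1 voxels
oracle_sampling_map <- function(flair_grid, t1_grid, rigid) {
  fc <- voxel_centers(flair_grid)
  fc <- t(as_mat4(rigid)[1:3, 1:3] %*% t(fc)) +
    matrix(as_mat4(rigid)[1:3, 4], nrow(fc), 3, byrow = TRUE)
  tc <- voxel_centers(t1_grid)
  ti_all <- sparsewmh:::grid_indices(t1_grid)
  pairs_f <- list(); pairs_t <- list(); dropped <- 0L
  s <- t1_grid$shape
  fi_all <- sparsewmh:::grid_indices(flair_grid)
  for (i in seq_len(nrow(fc))) {
    d2 <- (tc[, 1] - fc[i, 1])^2 + (tc[, 2] - fc[i, 2])^2 + (tc[, 3] - fc[i, 3])^2
    j <- which.min(d2)
    # in-bounds test mirrors the implementation: the continuous index must
    # round inside the grid, i.e. the nearest center must be within half a
    # voxel along each axis (in index space)
    cont <- solve(t1_grid$affine) %*% c(fc[i, ], 1)
    idx <- ceiling(cont[1:3] - 0.5)
    if (any(idx < 0) || any(idx >= s)) { dropped <- dropped + 1L; next }
    pairs_f[[length(pairs_f) + 1L]] <- fi_all[i, ]
    pairs_t[[length(pairs_t) + 1L]] <- ti_all[j, ]
  }
  list(flair_index = do.call(rbind, pairs_f), t1_index = do.call(rbind, pairs_t),
       n_dropped = dropped)
}

as_mat4 <- function(x) sparsewmh:::as_transform_matrix(x)

tiny_phantom <- function(seed = 1, shape = c(32, 32, 24),
                         n = c(1, 1, 1), radius = c(3, 6)) {
  make_phantom(seed, shape = shape, n_lesions_by_class = n,
               lesion_radius_range = radius)
}

as_vol <- function(a, g) volume(array(as.numeric(a), g$shape), g)

mask_vol <- function(truth, tissue)
  as_vol(truth_mask(truth, tissue), truth$grid)
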
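#' @useDynLib sparsewmh, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- Grid ------------------------------------------------------------------

#' Voxel grid geometry
#'
#' A `grid` couples an array shape with its voxel sizes and the affine matrix
#' mapping 0-based voxel indices (i, j, k, 1) to mm (world) coordinates, using
#' the NIfTI world-coordinate convention.
#'
#' @param shape integer vector of length 3, voxel counts per axis.
#' @param voxel_size numeric vector of length 3, voxel edge lengths in mm.
#' @param affine 4x4 matrix mapping voxel index to mm; if `NULL`, a diagonal
#'   affine `diag(voxel_size)` with zero origin is built.
#' @return An object of class `grid`.
#' @examples
#' g <- grid(c(184, 202, 72), c(1, 1, 1.5))
#' @export
grid <- function(shape, voxel_size, affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  cn <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(abs(cn - voxel_size) > 1e-4 * pmax(1, voxel_size)))
    stop("affine column norms do not match voxel_size")
  if (abs(det(affine)) < 1e-12) stop("affine is singular")
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "grid")
}

#' @export
print.grid <- function(x, ...) {
  cat(sprintf("<grid %s @ %s mm>\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  invisible(x)
}

#' The canonical T1 working grid
#'
#' The template-space working grid used for all T1 model inputs and outputs:
#' 184 x 202 x 72 voxels of 1 x 1 x 1.5 mm.
#' @return A `grid`.
#' @export
canonical_grid <- function() grid(c(184L, 202L, 72L), c(1, 1, 1.5))

is_grid <- function(x) inherits(x, "grid")

# ---- RigidTransform --------------------------------------------------------

#' Rigid (or affine) world-coordinate transform
#'
#' Wraps a 4x4 matrix acting on mm coordinates. `rigid = TRUE` enforces an
#' orthonormal rotation block to 1e-6.
#'
#' @param matrix 4x4 numeric matrix.
#' @param rigid enforce orthonormality of the upper-left 3x3 block.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(matrix = diag(4), rigid = TRUE) {
  m <- as.matrix(matrix)
  stopifnot(identical(dim(m), c(4L, 4L)))
  if (any(abs(m[4, ] - c(0, 0, 0, 1)) > 1e-9))
    stop("last row of a transform must be (0,0,0,1)")
  if (rigid) {
    R <- m[1:3, 1:3]
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      stop("rotation block is not orthonormal within 1e-6")
  }
  if (abs(det(m)) < 1e-12) stop("transform is not invertible")
  structure(list(matrix = m, rigid = rigid), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n"); print(signif(x$matrix, 5)); invisible(x)
}

as_transform_matrix <- function(x) {
  if (inherits(x, "rigid_transform")) return(x$matrix)
  m <- as.matrix(x)
  stopifnot(identical(dim(m), c(4L, 4L)))
  m
}

#' Compose transforms (left-to-right application order of the arguments'
#' inverses: `compose_transforms(a, b)` applies `b` first, then `a`).
#' @param ... transforms (rigid_transform objects or 4x4 matrices).
#' @return A `rigid_transform` (rigid flag dropped if any input is non-rigid).
#' @export
compose_transforms <- function(...) {
  ms <- lapply(list(...), as_transform_matrix)
  out <- Reduce(`%*%`, ms)
  rigid <- max(abs(crossprod(out[1:3, 1:3]) - diag(3))) <= 1e-6
  rigid_transform(out, rigid = rigid)
}

#' Invert a transform
#' @param x a `rigid_transform` or 4x4 matrix.
#' @return A `rigid_transform`.
#' @export
invert_transform <- function(x) {
  m <- as_transform_matrix(x)
  rigid_transform(solve(m), rigid = inherits(x, "rigid_transform") && x$rigid)
}

#' Read / write a 4x4 transform as a plain-text matrix file
#'
#' The file holds four whitespace-separated rows; coordinates are mm (world)
#' coordinates in the NIfTI convention.
#' @param path file path.
#' @param x transform to write.
#' @rdname transform_io
#' @export
read_transform <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  rigid <- max(abs(crossprod(m[1:3, 1:3]) - diag(3))) <= 1e-6
  rigid_transform(m, rigid = rigid)
}

#' @rdname transform_io
#' @export
write_transform <- function(x, path) {
  m <- as_transform_matrix(x)
  utils::write.table(format(m, digits = 17), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- Volume ----------------------------------------------------------------

#' A 3D volume with its grid
#'
#' @param data 3D numeric array; its dim must equal `grid$shape`.
#' @param grid a `grid`.
#' @return An object of class `volume`.
#' @export
volume <- function(data, grid) {
  stopifnot(is_grid(grid))
  data <- as.array(data)
  if (!identical(dim(data), grid$shape))
    stop("data shape does not match grid shape")
  structure(list(data = data, grid = grid), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume %s, range [%.4g, %.4g]>\n",
              paste(x$grid$shape, collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "volume")

# ---- Coordinates -----------------------------------------------------------

# 0-based voxel index matrix (N x 3) for all voxels of a grid, fastest-varying
# first axis (R array order).
grid_indices <- function(grid) {
  s <- grid$shape
  cbind(
    rep.int(seq_len(s[1]) - 1L, s[2] * s[3]),
    rep.int(rep(seq_len(s[2]) - 1L, each = s[1]), s[3]),
    rep(seq_len(s[3]) - 1L, each = s[1] * s[2])
  )
}

apply_affine <- function(m, pts) {
  # pts: N x 3; returns N x 3
  out <- pts %*% t(m[1:3, 1:3])
  out[, 1] <- out[, 1] + m[1, 4]
  out[, 2] <- out[, 2] + m[2, 4]
  out[, 3] <- out[, 3] + m[3, 4]
  out
}

#' Voxel-center mm coordinates of every voxel of a grid
#'
#' @param grid a `grid`.
#' @return An N x 3 matrix of mm coordinates, one row per voxel, in R array
#'   order (first index fastest).
#' @export
voxel_centers <- function(grid) {
  stopifnot(is_grid(grid))
  apply_affine(grid$affine, grid_indices(grid))
}

# ---- Sampling map ----------------------------------------------------------

#' Build the FLAIR-to-T1 voxel-center sampling map
#'
#' Every FLAIR voxel center is pushed through `aug o rigid` into T1 world
#' coordinates, converted to a continuous T1 voxel index and rounded to the
#' nearest integer index (ties at exactly .5 round toward the lower index,
#' deterministically). Centers landing outside the T1 grid are dropped and
#' counted. T1 voxels that no FLAIR center maps closest to are simply absent:
#' they receive no training signal.
#'
#' @param flair_grid,t1_grid `grid` objects.
#' @param rigid FLAIR-to-T1 world transform (`rigid_transform` or 4x4 matrix).
#' @param aug optional augmentation transform applied after `rigid`
#'   (identity by default); may be a general affine.
#' @return An object of class `sampling_map`: a list with `flair_index` and
#'   `t1_index` (N x 3 integer matrices of 0-based indices, row i paired with
#'   row i), `flair_lin`/`t1_lin` (1-based linear indices into the arrays),
#'   and `n_dropped`.
#' @export
build_sampling_map <- function(flair_grid, t1_grid, rigid = rigid_transform(),
                               aug = NULL) {
  stopifnot(is_grid(flair_grid), is_grid(t1_grid))
  m <- as_transform_matrix(rigid)
  if (!is.null(aug)) m <- as_transform_matrix(aug) %*% m
  if (abs(det(m)) < 1e-12) stop("sampling-map transform is not invertible")
  fi <- grid_indices(flair_grid)
  world <- apply_affine(m %*% flair_grid$affine, fi)
  cont <- apply_affine(solve(t1_grid$affine), world)
  # round-half-down: ceiling(x - 0.5) gives nearest with .5 -> lower
  ti <- ceiling(cont - 0.5)
  s <- t1_grid$shape
  inb <- ti[, 1] >= 0 & ti[, 1] < s[1] &
         ti[, 2] >= 0 & ti[, 2] < s[2] &
         ti[, 3] >= 0 & ti[, 3] < s[3]
  fi <- fi[inb, , drop = FALSE]
  ti <- ti[inb, , drop = FALSE]
  storage.mode(ti) <- "integer"
  fs <- flair_grid$shape
  structure(list(
    flair_index = fi, t1_index = ti,
    flair_lin = 1L + fi[, 1] + fs[1] * (fi[, 2] + fs[2] * fi[, 3]),
    t1_lin = 1L + ti[, 1] + s[1] * (ti[, 2] + s[2] * ti[, 3]),
    n_dropped = sum(!inb),
    flair_shape = fs, t1_shape = s
  ), class = "sampling_map")
}

#' @export
print.sampling_map <- function(x, ...) {
  cat(sprintf("<sampling_map: %d pairs, %d dropped>\n",
              nrow(x$flair_index), x$n_dropped))
  invisible(x)
}

# ---- Resampling ------------------------------------------------------------

#' Resample a volume onto another grid
#'
#' Each destination voxel center is mapped back through `rigid^-1` into the
#' source grid and interpolated. Voxels falling outside the source field of
#' view are set to 0.
#'
#' @param vol source `volume`.
#' @param dst destination `grid`.
#' @param rigid source-to-destination world transform (identity default).
#' @param mode `"trilinear"` or `"nearest"`.
#' @return A `volume` on `dst`.
#' @export
resample <- function(vol, dst, rigid = rigid_transform(),
                     mode = c("trilinear", "nearest")) {
  stopifnot(is_volume(vol), is_grid(dst))
  mode <- match.arg(mode)
  m <- as_transform_matrix(rigid)
  # dst index -> dst world -> src world -> src continuous index
  a <- solve(vol$grid$affine) %*% solve(m) %*% dst$affine
  cont <- apply_affine(a, grid_indices(dst))
  out <- interp3(vol$data, cont, mode)
  volume(array(out, dst$shape), dst)
}

# continuous-index interpolation (0-based indices), vectorized
interp3 <- function(arr, cont, mode) {
  s <- dim(arr)
  if (mode == "nearest") {
    i <- ceiling(cont - 0.5)
    ok <- i[, 1] >= 0 & i[, 1] < s[1] & i[, 2] >= 0 & i[, 2] < s[2] &
          i[, 3] >= 0 & i[, 3] < s[3]
    out <- numeric(nrow(cont))
    ii <- i[ok, , drop = FALSE]
    out[ok] <- arr[1 + ii[, 1] + s[1] * (ii[, 2] + s[2] * ii[, 3])]
    return(out)
  }
  f <- floor(cont)
  w <- cont - f
  out <- numeric(nrow(cont))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- f[, 1] + dx; iy <- f[, 2] + dy; iz <- f[, 3] + dz
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    ok <- ix >= 0 & ix < s[1] & iy >= 0 & iy < s[2] & iz >= 0 & iz < s[3] & wt > 0
    if (any(ok))
      out[ok] <- out[ok] +
        wt[ok] * arr[1 + ix[ok] + s[1] * (iy[ok] + s[2] * iz[ok])]
  }
  out
}
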
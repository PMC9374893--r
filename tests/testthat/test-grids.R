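test_that("voxel_centers follows the affine exactly", {
  g <- grid(c(2L, 1L, 1L), c(1, 1, 1))
  expect_equal(voxel_centers(g), rbind(c(0, 0, 0), c(1, 0, 0)))

  g2 <- canonical_grid()
  expect_identical(g2$shape, c(184L, 202L, 72L))
  expect_equal(nrow(voxel_centers(g2)), 184 * 202 * 72)

  # random affine: center of (3,4,5) equals the direct matrix product
  set.seed(7)
  R <- as_mat4(rand_rigid(7))
  R[1:3, 1:3] <- R[1:3, 1:3] %*% diag(c(0.9, 1.1, 2.0))
  g3 <- grid(c(6L, 6L, 6L), sqrt(colSums(R[1:3, 1:3]^2)), R)
  cen <- voxel_centers(g3)
  lin <- 1 + 3 + 6 * (4 + 6 * 5)
  expect_equal(cen[lin, ], as.numeric(R %*% c(3, 4, 5, 1))[1:3],
               tolerance = 1e-12)
})

test_that("grid and transform validation reject bad inputs", {
  expect_error(grid(c(2, 2, 2), c(1, 1, 1), diag(c(2, 1, 1, 1))),
               "column norms")
  m <- diag(4); m[1, 1] <- 1.01
  expect_error(rigid_transform(m), "orthonormal")
  s <- diag(4); s[1, 1] <- 0; s[4, 4] <- 1
  expect_error(rigid_transform(s, rigid = FALSE), "invertible")
  expect_error(build_sampling_map(grid(c(4, 4, 4), c(1, 1, 1)),
                                  grid(c(4, 4, 4), c(1, 1, 1)),
                                  rigid_transform(),
                                  aug = matrix(0, 4, 4) + diag(c(0, 1, 1, 1))),
               "invertible")
})

test_that("sampling map: identity pairing when grids coincide", {
  g <- grid(c(5L, 4L, 3L), c(1, 1, 1.5))
  m <- build_sampling_map(g, g, rigid_transform())
  expect_equal(m$n_dropped, 0L)
  expect_equal(m$flair_index, m$t1_index)
  expect_equal(nrow(m$flair_index), prod(g$shape))
  expect_equal(m$flair_lin, seq_len(prod(g$shape)))
})

test_that("sampling map: 6:1 slice anisotropy gives ~1/6 T1 coverage and matches brute force", {
  t1 <- grid(c(8L, 8L, 12L), c(1, 1, 1))
  fl <- grid(c(8L, 8L, 2L), c(1, 1, 6), {
    a <- diag(c(1, 1, 6, 1)); a[3, 4] <- 2.5; a
  })
  m <- build_sampling_map(fl, t1, rigid_transform())
  expect_equal(nrow(m$t1_index) + m$n_dropped, prod(fl$shape))
  # every flair center maps in-bounds here; T1 coverage is 2 of 12 slices
  frac <- length(unique(m$t1_lin)) / prod(t1$shape)
  expect_equal(frac, 2 / 12, tolerance = 1e-12)
  o <- oracle_sampling_map(fl, t1, rigid_transform())
  expect_equal(m$flair_index, o$flair_index)
  expect_equal(m$t1_index, o$t1_index)
  expect_equal(m$n_dropped, o$n_dropped)
})

test_that("sampling map equals exhaustive nearest-center search on random rigid cases", {
  for (seed in 1:6) {
    set.seed(seed + 100)
    t1 <- grid(sample(6:12, 3, replace = TRUE), runif(3, 0.8, 2))
    fl <- grid(sample(4:8, 3, replace = TRUE), runif(3, 0.8, 3))
    rig <- rand_rigid(seed, max_deg = 20, max_mm = 3)
    m <- build_sampling_map(fl, t1, rig)
    o <- oracle_sampling_map(fl, t1, rig)
    expect_equal(nrow(m$flair_index) + m$n_dropped, prod(fl$shape))
    expect_equal(m$n_dropped, o$n_dropped)
    expect_equal(m$flair_index, o$flair_index)
    expect_equal(m$t1_index, o$t1_index)
  }
})

test_that("sampling map: translation pushing all centers out drops everything", {
  g <- grid(c(4L, 4L, 4L), c(1, 1, 1))
  tr <- diag(4); tr[1, 4] <- 100
  m <- build_sampling_map(g, g, rigid_transform(tr))
  expect_equal(nrow(m$flair_index), 0L)
  expect_equal(m$n_dropped, prod(g$shape))
})

test_that("rounding ties go toward the lower index, deterministically", {
  # centers exactly halfway between two T1 voxels along x
  t1 <- grid(c(4L, 4L, 4L), c(1, 1, 1))
  fl <- grid(c(4L, 4L, 4L), c(1, 1, 1), {
    a <- diag(4); a[1, 4] <- 0.5; a
  })
  m <- build_sampling_map(fl, t1, rigid_transform())
  # flair voxel i=0 sits at x=0.5 -> tie between T1 index 0 and 1 -> 0
  first <- m$t1_index[m$flair_lin == 1L, ]
  expect_equal(first, c(0L, 0L, 0L))
})

test_that("resample: identity, constants, and the trilinear closed form", {
  g <- grid(c(8L, 8L, 8L), c(1, 1, 1))
  set.seed(5)
  v <- volume(array(runif(512), g$shape), g)
  for (mode in c("nearest", "trilinear")) {
    expect_equal(resample(v, g, mode = mode)$data, v$data, tolerance = 1e-12)
  }
  cst <- volume(array(3.5, g$shape), g)
  rig <- rand_rigid(2, max_deg = 10, max_mm = 1)
  out <- resample(cst, g, rig, mode = "trilinear")
  inside <- out$data[3:6, 3:6, 3:6]
  expect_true(all(abs(inside - 3.5) < 1e-9))

  # trilinear at a known fractional offset vs the closed form
  off <- c(0.3, 0.6, 0.25)
  dst <- grid(c(6L, 6L, 6L), c(1, 1, 1), {
    a <- diag(4); a[1:3, 4] <- off; a
  })
  out2 <- resample(v, dst, mode = "trilinear")
  manual <- function(i, j, k) {
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) off[1] else 1 - off[1]) *
           (if (dy) off[2] else 1 - off[2]) *
           (if (dz) off[3] else 1 - off[3])
      acc <- acc + w * v$data[i + dx, j + dy, k + dz]
    }
    acc
  }
  for (p in list(c(1, 1, 1), c(3, 4, 2), c(5, 5, 5))) {
    expect_equal(out2$data[p[1], p[2], p[3]], manual(p[1], p[2], p[3]),
                 tolerance = 1e-12)
  }
  expect_error(resample(v, g, mode = "bicubic"))
})

test_that("nearest resample is idempotent on its own grid", {
  g <- grid(c(7L, 6L, 5L), c(1, 1.2, 2))
  set.seed(9)
  v <- volume(array(runif(prod(g$shape)), g$shape), g)
  rig <- rand_rigid(11, max_deg = 8, max_mm = 2)
  r1 <- resample(v, g, rig, mode = "nearest")
  r2 <- resample(r1, g, mode = "nearest")
  expect_identical(r1$data, r2$data)
})

test_that("transform composition, inversion, and text round trip", {
  a <- rand_rigid(1); b <- rand_rigid(2)
  ab <- compose_transforms(a, b)
  expect_equal(as_mat4(ab), as_mat4(a) %*% as_mat4(b), tolerance = 1e-12)
  inv <- invert_transform(a)
  expect_equal(as_mat4(compose_transforms(a, inv)), diag(4), tolerance = 1e-9)
  p <- tempfile(fileext = ".txt")
  write_transform(a, p)
  expect_equal(as_mat4(read_transform(p)), as_mat4(a), tolerance = 1e-12)
})
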
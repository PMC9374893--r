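# brute-force oracle: double loop over the sampling-map pairs
oracle_sparse_loss <- function(out1, flair_wmh, map) {
  tot <- 0
  for (i in seq_len(nrow(map$flair_index))) {
    fi <- map$flair_index[i, ] + 1L
    ti <- map$t1_index[i, ] + 1L
    tot <- tot + (out1$data[ti[1], ti[2], ti[3]] -
                    flair_wmh$data[fi[1], fi[2], fi[3]])^2
  }
  tot
}

rand_setup <- function(seed, max_t1 = 12L) {
  set.seed(seed)
  t1g <- grid(sample(6:max_t1, 3, replace = TRUE), runif(3, 0.8, 1.6))
  flg <- grid(sample(4:8, 3, replace = TRUE), runif(3, 0.9, 4))
  rig <- rand_rigid(seed + 50, max_deg = 15, max_mm = 3)
  list(t1g = t1g, flg = flg, rig = rig,
       out1 = volume(array(runif(prod(t1g$shape)), t1g$shape), t1g),
       tgt = volume(array(rbinom(prod(flg$shape), 1, 0.4), flg$shape), flg))
}

test_that("sparse loss: perfect fit and counting cases", {
  g <- grid(c(6L, 6L, 6L), c(1, 1, 1))
  map <- build_sampling_map(g, g, rigid_transform())
  set.seed(3)
  tgt <- volume(array(rbinom(216, 1, 0.3), g$shape), g)
  expect_equal(sparse_lesion_loss(tgt, tgt, map), 0)
  zero <- volume(array(0, g$shape), g)
  expect_equal(sparse_lesion_loss(zero, tgt, map), sum(tgt$data))
})

test_that("sparse loss equals the exhaustive double-loop oracle", {
  for (seed in 1:8) {
    s <- rand_setup(seed)
    map <- build_sampling_map(s$flg, s$t1g, s$rig)
    expect_equal(sparse_lesion_loss(s$out1, s$tgt, map),
                 oracle_sparse_loss(s$out1, s$tgt, map), tolerance = 1e-12)
  }
})

test_that("sparse-loss gradient is exactly zero at unsampled voxels and exact elsewhere", {
  for (seed in 1:4) {
    s <- rand_setup(seed + 20)
    map <- build_sampling_map(s$flg, s$t1g, s$rig)
    r <- sparse_lesion_loss(s$out1, s$tgt, map, grad = TRUE)
    unsampled <- setdiff(seq_len(prod(s$t1g$shape)), map$t1_lin)
    expect_true(all(r$grad[unsampled] == 0))
    # central finite differences on a few sampled voxels
    for (v in utils::head(unique(map$t1_lin), 4)) {
      eps <- 1e-6
      up <- s$out1; up$data[v] <- up$data[v] + eps
      dn <- s$out1; dn$data[v] <- dn$data[v] - eps
      num <- (sparse_lesion_loss(up, s$tgt, map) -
                sparse_lesion_loss(dn, s$tgt, map)) / (2 * eps)
      expect_equal(r$grad[v], num, tolerance = 1e-6)
    }
  }
})

test_that("duplicate T1 hits are counted once per FLAIR voxel (sum semantics)", {
  # two flair voxels collapse onto one T1 voxel under 2x in-plane downscaling
  t1 <- grid(c(2L, 2L, 2L), c(2, 2, 2))
  fl <- grid(c(4L, 2L, 2L), c(0.9, 2, 2), {
    a <- diag(c(0.9, 2, 2, 1)); a
  })
  map <- build_sampling_map(fl, t1, rigid_transform())
  expect_gt(nrow(map$t1_index), length(unique(map$t1_lin)))
  out1 <- volume(array(0.5, t1$shape), t1)
  tgt <- volume(array(1, fl$shape), fl)
  expect_equal(sparse_lesion_loss(out1, tgt, map),
               nrow(map$t1_index) * 0.25, tolerance = 1e-12)
  r <- sparse_lesion_loss(out1, tgt, map, grad = TRUE)
  dup <- as.integer(names(which(table(map$t1_lin) > 1)))[1]
  expect_equal(r$grad[dup], 2 * (0.5 - 1) * sum(map$t1_lin == dup))
})

test_that("ribbon loss matches direct summation", {
  g <- grid(c(5L, 5L, 5L), c(1, 1, 1))
  a <- volume(array(runif(125), g$shape), g)
  b <- volume(array(runif(125), g$shape), g)
  expect_equal(ribbon_loss(a, a), 0)
  expect_equal(ribbon_loss(volume(array(0, g$shape), g),
                           volume(array(1, g$shape), g)), 125)
  expect_equal(ribbon_loss(a, b), sum((a$data - b$data)^2), tolerance = 1e-12)
  r <- ribbon_loss(a, b, grad = TRUE)
  expect_equal(r$grad, 2 * (a$data - b$data))
})

test_that("joint loss is the 0.001-weighted sum and reports n_sampled", {
  s <- rand_setup(31)
  map <- build_sampling_map(s$flg, s$t1g, s$rig)
  out2 <- volume(array(runif(prod(s$t1g$shape)), s$t1g$shape), s$t1g)
  rib <- volume(array(rbinom(prod(s$t1g$shape), 1, 0.2), s$t1g$shape), s$t1g)
  jl <- joint_loss(s$out1, out2, s$tgt, rib, map)
  expect_equal(jl$total,
               sparse_lesion_loss(s$out1, s$tgt, map) +
                 0.001 * ribbon_loss(out2, rib), tolerance = 1e-12)
  expect_equal(jl$n_sampled, nrow(map$t1_index))
  # both perfect -> zero
  tgt_perfect <- s$out1
  tgt_perfect$data[] <- 0
  z <- volume(array(0, s$flg$shape), s$flg)
  rib0 <- volume(array(0, s$t1g$shape), s$t1g)
  jl0 <- joint_loss(tgt_perfect, rib0, z, rib0, map)
  expect_equal(jl0$total, 0)
  # the ribbon term dominates only past the 1000x ratio
  expect_lt(0.001 * jl$ribbon / max(jl$sparse_lesion, 1e-12), 1000)
})

test_that("dense interpolating loss: reduction, perfection, and resample oracle", {
  g <- grid(c(6L, 6L, 6L), c(1, 1, 1))
  set.seed(12)
  pred <- volume(array(runif(216), g$shape), g)
  tgt <- volume(array(rbinom(216, 1, 0.5), g$shape), g)
  # identical grids + identity -> plain dense squared error
  expect_equal(dense_interpolating_loss(pred, tgt),
               ribbon_loss(pred, tgt), tolerance = 1e-12)
  # perfect prediction of the interpolated target -> 0
  s <- rand_setup(41)
  res <- resample(s$tgt, s$t1g, s$rig, mode = "trilinear")
  expect_lt(dense_interpolating_loss(res, s$tgt, s$rig), 1e-18)
  # random case matches resample-then-sum over the field of view
  fov <- resample(volume(array(1, s$flg$shape), s$flg), s$t1g, s$rig,
                  mode = "nearest")$data > 0
  expect_equal(dense_interpolating_loss(s$out1, s$tgt, s$rig),
               sum(((s$out1$data - res$data)[fov])^2), tolerance = 1e-12)
})

test_that("degenerate limit: sparse equals dense when grids coincide", {
  g <- grid(c(8L, 7L, 6L), c(1, 1.1, 1.5))
  set.seed(77)
  pred <- volume(array(runif(prod(g$shape)), g$shape), g)
  tgt <- volume(array(rbinom(prod(g$shape), 1, 0.35), g$shape), g)
  map <- build_sampling_map(g, g, rigid_transform())
  expect_equal(sparse_lesion_loss(pred, tgt, map),
               dense_interpolating_loss(pred, tgt), tolerance = 1e-10)
})

test_that("losses reject mismatched shapes", {
  g <- grid(c(4L, 4L, 4L), c(1, 1, 1))
  h <- grid(c(5L, 4L, 4L), c(1, 1, 1))
  map <- build_sampling_map(g, g, rigid_transform())
  bad <- volume(array(0, h$shape), h)
  good <- volume(array(0, g$shape), g)
  expect_error(sparse_lesion_loss(bad, good, map), "does not match")
  expect_error(ribbon_loss(bad, good), "differ")
})
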
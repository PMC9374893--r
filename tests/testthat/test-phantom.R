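test_that("phantom generation is deterministic and respects empty counts", {
  a <- make_phantom(11, shape = c(32, 32, 24), n_lesions_by_class = c(2, 0, 0))
  b <- make_phantom(11, shape = c(32, 32, 24), n_lesions_by_class = c(2, 0, 0))
  expect_identical(a$tissue_labels$data, b$tissue_labels$data)
  expect_identical(a$lesion_field$data, b$lesion_field$data)
  expect_identical(a$lesion_components, b$lesion_components)

  e <- make_phantom(2, shape = c(32, 32, 24), n_lesions_by_class = c(0, 0, 0))
  expect_true(all(e$lesion_field$data == 0))
  expect_equal(nrow(e$lesion_components), 0L)
  expect_error(make_phantom(1, shape = c(16, 16, 8)), "at least")
})

test_that("phantom anatomy: disjoint tissues, lesions confined to WM", {
  t <- tiny_phantom(21, n = c(2, 0, 0))
  lab <- t$tissue_labels$data
  expect_setequal(unique(as.integer(lab)), 0:3)
  # ribbon and ventricle disjoint by coding; lesions only in WM
  expect_true(all(t$lesion_field$data[lab != 1L] == 0))
  expect_true(all(t$lesion_field$data >= 0 & t$lesion_field$data <= 1))
})

test_that("lesion components carry the classes the ROI oracle recomputes", {
  t <- make_phantom(31, shape = c(64, 64, 48), n_lesions_by_class = c(2, 3, 1),
                    lesion_radius_range = c(3, 5))
  expect_equal(nrow(t$lesion_components), 6L)
  expect_equal(sum(t$lesion_components$class == "periventricular"), 2L)
  expect_equal(sum(t$lesion_components$class == "deep"), 3L)
  expect_equal(sum(t$lesion_components$class == "juxtacortical"), 1L)
  # each component's center voxel must lie in its nominal region
  part <- partition_wm(mask_vol(t, "wm"), mask_vol(t, "ventricle"),
                       mask_vol(t, "ribbon"),
                       pv_radius_mm = t$pv_radius_mm,
                       jc_radius_mm = t$jc_radius_mm)
  code <- c(periventricular = 1L, deep = 2L, juxtacortical = 3L)
  for (i in seq_len(nrow(t$lesion_components))) {
    v <- round(unlist(t$lesion_components[i, c("x", "y", "z")]) /
                 t$grid$voxel_size) + 1L
    expect_equal(part$labels$data[v[1], v[2], v[3]],
                 code[[t$lesion_components$class[i]]])
  }
})

test_that("T1 rendering puts lesions at gray-matter intensity", {
  t <- tiny_phantom(41, n = c(2, 0, 0), radius = c(4, 6))
  img <- render(t, acquisition_spec("t1", noise_sd = 0))
  lab <- t$tissue_labels$data
  les_core <- t$lesion_field$data > 0.99
  skip_if(sum(les_core) < 10) # degenerate placement; other seeds cover this
  m_les <- mean(img$data[les_core])
  m_rib <- mean(img$data[lab == 2L])
  expect_lt(abs(m_les - m_rib) / m_rib, 0.01)
  # intensity ordering WM > GM > CSF
  expect_gt(mean(img$data[lab == 1L & t$lesion_field$data == 0]), m_rib)
  expect_gt(m_rib, mean(img$data[lab == 3L]))
})

test_that("FLAIR rendering is slab-averaged and lesions are hyperintense", {
  t <- tiny_phantom(51, n = c(2, 0, 0), radius = c(4, 6))
  spec <- acquisition_spec("flair", slice_thickness_mm = 6, noise_sd = 0)
  r <- render(t, spec)
  expect_equal(r$grid$shape[1:2], t$grid$shape[1:2])
  expect_equal(r$grid$voxel_size[3], 6)
  expect_equal(as_mat4(r$rigid), diag(4))

  # brute-force slab averaging of the high-res signal (in-plane grids match)
  lab <- t$tissue_labels$data
  fi <- sparsewmh:::FLAIR_INTENSITY
  base <- array(fi[["bg"]], dim(lab))
  base[lab == 1L] <- fi[["wm"]]; base[lab == 2L] <- fi[["gm"]]
  base[lab == 3L] <- fi[["csf"]]
  sig <- base * (1 - t$lesion_field$data) + fi[["lesion"]] * t$lesion_field$data
  m <- 6L
  k0 <- (t$grid$shape[3] - r$grid$shape[3] * m) %/% 2L
  for (s in seq_len(r$grid$shape[3])) {
    zr <- (k0 + (s - 1L) * m + 1L):(k0 + s * m)
    expect_equal(r$volume$data[, , s],
                 apply(sig[, , zr], 1:2, mean), tolerance = 1e-9)
  }
  # lesion-containing slices exceed the WM level
  msk <- lesion_mask_flair(t, spec)
  for (s in which(apply(msk$data, 3, sum) > 0)) {
    expect_gt(max(r$volume$data[, , s]), fi[["wm"]])
  }
})

test_that("FLAIR mask volume approximates the true lesion volume for thick lesions", {
  t <- make_phantom(61, shape = c(64, 64, 48), n_lesions_by_class = c(0, 1, 0),
                    lesion_radius_range = c(8, 8))
  spec <- acquisition_spec("flair", slice_thickness_mm = 6)
  msk <- lesion_mask_flair(t, spec)
  vol_mask <- sum(msk$data) * prod(msk$grid$voxel_size)
  vol_true <- sum(t$lesion_field$data >= 0.5) * prod(t$grid$voxel_size)
  expect_gt(vol_true, 0)
  expect_lt(abs(vol_mask - vol_true) / vol_true, 0.3)
  # empty field -> empty mask
  e <- make_phantom(62, shape = c(48, 48, 36), n_lesions_by_class = c(0, 0, 0))
  expect_equal(sum(lesion_mask_flair(e, spec)$data), 0)
})

test_that("corrupt_target implements the failure taxonomy", {
  t <- make_phantom(71, shape = c(64, 64, 48), n_lesions_by_class = c(1, 1, 1),
                    lesion_radius_range = c(4, 6))
  spec <- acquisition_spec("flair", slice_thickness_mm = 6)
  msk <- lesion_mask_flair(t, spec)
  skip_if(sum(msk$data) == 0)

  # miss_small with a tiny threshold: nothing below it -> unchanged
  same <- corrupt_target(msk, "miss_small", seed = 1, min_voxels = 1L)
  expect_identical(same$data, msk$data)
  # miss_small drops exactly the components the oracle counts as small
  thr <- 25L
  cut <- corrupt_target(msk, "miss_small", seed = 1, min_voxels = thr)
  lab <- sparsewmh:::label_components(msk$data > 0.5, dim(msk$data))
  sizes <- tabulate(lab[lab > 0])
  lab2 <- sparsewmh:::label_components(cut$data > 0.5, dim(cut$data))
  expect_equal(max(lab2), sum(sizes >= thr))

  # bright_artifact strictly adds voxels
  art <- corrupt_target(msk, "bright_artifact", seed = 2)
  expect_true(all(art$data >= msk$data))
  expect_gt(sum(art$data), sum(msk$data))

  # determinism + unknown mode
  expect_identical(corrupt_target(msk, "motion", seed = 3)$data,
                   corrupt_target(msk, "motion", seed = 3)$data)
  expect_error(corrupt_target(msk, "blur"))
})

test_that("no global intensity threshold separates lesion from ribbon on T1", {
  t <- make_phantom(81) # the default phantom geometry
  img <- render(t, acquisition_spec("t1", noise_sd = 0.02, seed = 81))
  truth <- t$lesion_field$data >= 0.5
  skip_if(sum(truth) == 0)
  best <- 0
  qs <- quantile(img$data, seq(0.02, 0.98, by = 0.04))
  for (lo in qs) for (hi in qs) {
    if (hi <= lo) next
    cand <- img$data >= lo & img$data <= hi
    best <- max(best, dice(cand, truth))
  }
  expect_lt(best, 0.5)
})
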
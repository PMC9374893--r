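# shared tiny FLAIR-space dataset: phantom-derived image + clean target mask
make_flair_dataset <- function(n, seed0 = 500, corrupt = integer(0),
                               shape = c(32, 32, 24)) {
  spec_noise <- function(s) acquisition_spec("flair", slice_thickness_mm = 6,
                                             noise_sd = 0.02, seed = s)
  lapply(seq_len(n), function(i) {
    t <- make_phantom(seed0 + i, shape = shape,
                      n_lesions_by_class = c(2, 0, 0),
                      lesion_radius_range = c(4, 7))
    img <- render(t, spec_noise(seed0 + i))$volume
    tgt <- lesion_mask_flair(t, spec_noise(seed0 + i))
    if (i %in% corrupt)
      tgt <- corrupt_target(tgt, "bright_artifact", seed = seed0 + i,
                            n_artifacts = 4L, artifact_radius = 4L)
    list(id = sprintf("s%02d", i), image = img, target = tgt, truth = t)
  })
}

quick_cfg <- function(...) {
  defaults <- list(learning_rate = 2e-3, max_epochs = 2L, width_scale = 0.25,
                   levels = 2L, seed = 9L, shuffle = TRUE,
                   flair_augment = augment_params(max_rotation_deg = 5,
                                                  max_translation_mm = 2,
                                                  axial_only = TRUE))
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, args)
}

test_that("learning rate 0 leaves parameters unchanged", {
  ds <- make_flair_dataset(2)
  cfg <- quick_cfg(learning_rate = 0, max_epochs = 1L)
  m0 <- build_flair_net(0.25, 2, seed = 4)
  res <- train(m0, ds, sparsewmh:::flair_mimic_loss_fn, cfg)
  expect_equal(res$model$params, m0$params, tolerance = 0)
})

test_that("training is deterministic under a fixed seed and reduces the loss", {
  ds <- make_flair_dataset(2)
  cfg <- quick_cfg(max_epochs = 3L)
  m0 <- build_flair_net(0.25, 2, seed = 4)
  r1 <- train(m0, ds, sparsewmh:::flair_mimic_loss_fn, cfg)
  r2 <- train(m0, ds, sparsewmh:::flair_mimic_loss_fn, cfg)
  expect_identical(r1$loss_history, r2$loss_history)
  expect_identical(r1$model$params, r2$model$params)
})

test_that("single-sample loss history strictly decreases without augmentation", {
  ds <- make_flair_dataset(1)
  cfg <- quick_cfg(max_epochs = 4L,
                   flair_augment = augment_params(max_rotation_deg = 0,
                                                  max_translation_mm = 0,
                                                  axial_only = TRUE))
  m0 <- build_flair_net(0.25, 2, seed = 4)
  res <- train(m0, ds, sparsewmh:::flair_mimic_loss_fn, cfg)
  expect_true(all(diff(res$loss_history) < 0))
})

test_that("the slower-convergence stop rule can end training early", {
  ds <- make_flair_dataset(1)
  cfg <- quick_cfg(max_epochs = 20L, stop_patience = 2L, stop_slope = 0.9,
                   learning_rate = 1e-5)
  m0 <- build_flair_net(0.25, 2, seed = 4)
  res <- train(m0, ds, sparsewmh:::flair_mimic_loss_fn, cfg)
  expect_lt(length(res$loss_history), 20L)
})

test_that("non-finite losses abort naming the sample", {
  ds <- make_flair_dataset(1)
  bad_loss <- function(model, sample, aug_seed, cfg)
    list(loss = NaN, grads = sparsewmh:::adam_init(model)$m)
  m0 <- build_flair_net(0.25, 2, seed = 4)
  expect_error(train(m0, ds, bad_loss, quick_cfg()), "s01")
})

test_that("rank_by_loss: equal samples tie in stable order, empty dataset fails", {
  ds <- make_flair_dataset(1)
  same <- list(ds[[1]], ds[[1]], ds[[1]])
  same[[2]]$id <- "s02"; same[[3]]$id <- "s03"
  m0 <- build_flair_net(0.25, 2, seed = 4)
  rep <- rank_by_loss(m0, same, sparsewmh:::flair_mimic_loss_fn, quick_cfg())
  expect_equal(length(unique(rep$loss)), 1L)
  expect_equal(rep$rank, 1:3)
  expect_error(rank_by_loss(m0, list(), sparsewmh:::flair_mimic_loss_fn,
                            quick_cfg()), "empty")
})

test_that("build_curated_dataset: drops, corrections, oversampling arithmetic", {
  ds <- make_flair_dataset(20)
  expect_length(build_curated_dataset(ds), 20L)
  fixed <- ds[[1]]$target
  cur <- build_curated_dataset(ds,
                               corrections = list(s01 = fixed, s02 = fixed),
                               drops = c("s03", "s04"),
                               oversample_factor = 10L)
  # 20 - 2 corrected - 2 dropped = 16 plain, plus 2 x 10 corrected visits
  expect_length(cur, 16L + 20L)
  expect_equal(sum(vapply(cur, function(s) isTRUE(s$corrected), logical(1))),
               20L)
  expect_error(build_curated_dataset(ds, corrections = list(zz = fixed)),
               "unknown ids")
})

test_that("t1 joint loss fn: sparse and dense modes train a step without drama", {
  t <- make_phantom(601, shape = c(32, 32, 24), n_lesions_by_class = c(2, 0, 0),
                    lesion_radius_range = c(4, 7))
  fspec <- acquisition_spec("flair", slice_thickness_mm = 6)
  sample <- list(id = "p", t1 = render(t, acquisition_spec("t1", noise_sd = 0.02,
                                                           seed = 601)),
                 target = lesion_mask_flair(t, fspec),
                 ribbon = mask_vol(t, "ribbon"),
                 rigid = rigid_transform())
  for (mode in c("sparse", "dense")) {
    cfg <- quick_cfg(loss_mode = mode, max_epochs = 1L,
                     augment = augment_params(max_rotation_deg = 5,
                                              max_translation_mm = 2,
                                              histogram_strength = 0.2))
    res <- train_t1_from_flair(list(sample), cfg)
    expect_true(all(is.finite(res$loss_history)))
  }
  # ribbon weight 0 still trains (ablation smoke test)
  cfg0 <- quick_cfg(max_epochs = 1L, ribbon_weight = 0)
  res0 <- train_t1_from_flair(list(sample), cfg0)
  expect_true(all(is.finite(res0$loss_history)))
})

test_that("degenerate equivalence: matched grids make sparse match dense training signal", {
  # when FLAIR grid == T1 grid and transforms are identity, the per-sample
  # losses of the two modes coincide exactly at evaluation
  t <- make_phantom(611, shape = c(32, 32, 24), n_lesions_by_class = c(2, 0, 0))
  g <- t$grid
  tgt <- volume(array(as.numeric(t$lesion_field$data >= 0.5), g$shape), g)
  sample <- list(id = "p", t1 = render(t, acquisition_spec("t1", noise_sd = 0)),
                 target = tgt, ribbon = mask_vol(t, "ribbon"),
                 rigid = rigid_transform())
  m <- build_t1_wmh_net(0.125, 2, seed = 2)
  l_sparse <- sparsewmh:::t1_joint_loss_fn(m, sample, NULL,
                                           quick_cfg(loss_mode = "sparse"))$loss
  l_dense <- sparsewmh:::t1_joint_loss_fn(m, sample, NULL,
                                          quick_cfg(loss_mode = "dense"))$loss
  expect_equal(l_sparse, l_dense, tolerance = 1e-10)
})
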
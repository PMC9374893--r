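# Optimization loop (single-sample minibatches, ADAM), the two-step curation
# workflow (mimic -> rank-by-loss -> correct -> retrain with oversampling),
# and the cross-modality T1 training driver.
#
# The loss-function contract: loss_fn(model, sample, aug_seed, cfg) returns
# list(loss, grads) when aug_seed is an integer (training mode, fresh
# augmentation drawn from the seed) and list(loss) when aug_seed is NULL
# (evaluation mode, no augmentation).

#' Training configuration
#'
#' @param learning_rate ADAM step size.
#' @param max_epochs epoch cap.
#' @param stop_patience window (epochs) of the slower-convergence detector:
#'   training stops when the moving-average loss over the last
#'   `stop_patience` epochs has decreased, relative to the previous window,
#'   by less than `stop_slope`. Set `stop_slope = 0` to disable.
#' @param stop_slope relative-decrease threshold of the stop rule.
#' @param seed master seed: epoch shuffling and all per-visit augmentation
#'   seeds derive from it.
#' @param width_scale,levels network size (passed to the builders).
#' @param ribbon_weight weight of the auxiliary cortical term (default 0.001).
#' @param oversample_factor how many times a manually corrected sample is
#'   visited per epoch in the retraining step (default 10, each visit drawing
#'   fresh augmentation).
#' @param loss_mode `"sparse"` (the cross-resolution sampling loss) or
#'   `"dense"` (interpolating baseline).
#' @param restart_patience ignition detector: if after this many epochs the
#'   epoch-mean loss has decreased by less than `restart_min_decrease`
#'   relative to the first epoch, the model is re-initialized with a shifted
#'   seed (at most `max_restarts` times) and optimization starts over within
#'   the same epoch budget. Squared-error training of rare-positive
#'   segmentations occasionally fails to leave the constant-output regime
#'   for an unlucky initialization; a restart is the classical cure. 0
#'   disables.
#' @param restart_min_decrease,max_restarts see `restart_patience`.
#' @param normalize_loss divide by the number of sampled voxels (default off:
#'   the loss is the plain sum).
#' @param augment an `augment_params` for the T1 space (full 3D affines);
#'   `flair_augment` for the FLAIR space (axial-only rotations).
#' @param flair_augment see `augment`.
#' @param shuffle shuffle sample order each epoch.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, max_epochs = 10L,
                         stop_patience = 3L, stop_slope = 0,
                         seed = 1L, width_scale = 1, levels = 5L,
                         ribbon_weight = default_ribbon_weight,
                         oversample_factor = 10L,
                         loss_mode = c("sparse", "dense"),
                         restart_patience = 0L, restart_min_decrease = 0.1,
                         max_restarts = 2L,
                         normalize_loss = FALSE,
                         augment = augment_params(max_rotation_deg = 10,
                                                  max_translation_mm = 5),
                         flair_augment = augment_params(max_rotation_deg = 10,
                                                        max_translation_mm = 5,
                                                        axial_only = TRUE),
                         shuffle = TRUE) {
  stopifnot(oversample_factor >= 1L)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 stop_patience = as.integer(stop_patience),
                 stop_slope = stop_slope, seed = as.integer(seed),
                 width_scale = width_scale, levels = as.integer(levels),
                 ribbon_weight = ribbon_weight,
                 oversample_factor = as.integer(oversample_factor),
                 loss_mode = match.arg(loss_mode),
                 restart_patience = as.integer(restart_patience),
                 restart_min_decrease = restart_min_decrease,
                 max_restarts = as.integer(max_restarts),
                 normalize_loss = normalize_loss,
                 augment = augment, flair_augment = flair_augment,
                 shuffle = shuffle),
            class = "train_config")
}

draw_seed <- function() sample.int(.Machine$integer.max - 1L, 1L)

#' Train a model
#'
#' Iterates samples singly (mini-batch size 1), drawing fresh augmentation at
#' every visit, and stops at `max_epochs` or when the smoothed loss slope
#' falls below the configured threshold. Fully seeded: identical config and
#' seed give identical histories.
#' @param model a `unet_model`.
#' @param dataset nonempty list of samples (each with an `$id`).
#' @param loss_fn see the contract above.
#' @param cfg a `train_config`.
#' @param reinit optional `function(attempt)` returning a freshly
#'   initialized model, used by the ignition-restart rule (see
#'   [train_config()]); without it restarts are disabled.
#' @return `list(model, loss_history, restarts)` -- `loss_history` is the
#'   per-epoch mean loss of the final attempt.
#' @export
train <- function(model, dataset, loss_fn, cfg, reinit = NULL) {
  stopifnot(inherits(cfg, "train_config"), length(dataset) > 0L)
  set.seed(cfg$seed)
  state <- adam_init(model)
  history <- numeric(0)
  n <- length(dataset)
  restarts <- 0L
  epoch <- 0L
  while (epoch < cfg$max_epochs) {
    epoch <- epoch + 1L
    ord <- if (cfg$shuffle) sample.int(n) else seq_len(n)
    ep_loss <- 0
    for (si in ord) {
      s <- dataset[[si]]
      fb <- loss_fn(model, s, draw_seed(), cfg)
      if (!is.finite(fb$loss))
        stop("non-finite loss on sample '", s$id %||% si, "'")
      upd <- adam_step(model, fb$grads, state, cfg$learning_rate)
      model <- upd$model
      state <- upd$state
      ep_loss <- ep_loss + fb$loss
    }
    history <- c(history, ep_loss / n)
    # ignition restart: optimization stuck near its starting loss
    if (!is.null(reinit) && cfg$restart_patience > 0L &&
        restarts < cfg$max_restarts &&
        length(history) == cfg$restart_patience &&
        (history[1] - history[length(history)]) / max(abs(history[1]), 1e-12) <
          cfg$restart_min_decrease) {
      restarts <- restarts + 1L
      model <- reinit(restarts)
      state <- adam_init(model)
      history <- numeric(0)
    }
    p <- cfg$stop_patience
    if (cfg$stop_slope > 0 && length(history) >= 2L * p) {
      recent <- mean(utils::tail(history, p))
      prev <- mean(history[(length(history) - 2L * p + 1L):(length(history) - p)])
      if ((prev - recent) / max(abs(prev), 1e-12) < cfg$stop_slope) break
    }
  }
  list(model = model, loss_history = history, restarts = restarts)
}

#' Rank a dataset by evaluation-mode per-sample loss
#'
#' No augmentation; descending loss order (rank 1 = largest loss), ties kept
#' in stable dataset order. After a short "mimic" training on a large mixed
#' dataset, mis-segmented targets surface at the top of this ranking.
#' @param model,dataset,loss_fn,cfg as in [train()].
#' @return A `curation_report` data.frame: id, loss, rank, flag.
#' @export
rank_by_loss <- function(model, dataset, loss_fn, cfg) {
  if (length(dataset) == 0L) stop("rank_by_loss: empty dataset")
  losses <- vapply(dataset, function(s) loss_fn(model, s, NULL, cfg)$loss,
                   numeric(1))
  ids <- vapply(seq_along(dataset),
                function(i) as.character(dataset[[i]]$id %||% i), character(1))
  ord <- order(-losses) # stable for ties
  rank <- integer(length(losses))
  rank[ord] <- seq_along(losses)
  structure(data.frame(id = ids, loss = losses, rank = rank, flag = "kept",
                       stringsAsFactors = FALSE),
            class = c("curation_report", "data.frame"))
}

#' Apply corrections and drops; oversample corrected samples
#'
#' Dropped samples are removed; corrected samples get their target replaced
#' and are listed `oversample_factor` times (each visit draws its own fresh
#' augmentation at training time, so this weights them rather than freezing
#' ten copies).
#' @param dataset list of samples with `$id` and `$target`.
#' @param corrections named list id -> replacement target `volume`.
#' @param drops character vector of ids to remove.
#' @param oversample_factor visits per epoch for corrected samples.
#' @return The curated dataset (a list of samples).
#' @export
build_curated_dataset <- function(dataset, corrections = NULL, drops = NULL,
                                  oversample_factor = 10L) {
  ids <- vapply(dataset, function(s) as.character(s$id), character(1))
  unknown <- setdiff(c(names(corrections), drops), ids)
  if (length(unknown))
    stop("corrections/drops reference unknown ids: ",
         paste(unknown, collapse = ", "))
  out <- list()
  for (s in dataset) {
    id <- as.character(s$id)
    if (id %in% drops) next
    if (!is.null(corrections[[id]])) {
      s$target <- corrections[[id]]
      s$corrected <- TRUE
      for (k in seq_len(oversample_factor)) out[[length(out) + 1L]] <- s
    } else {
      s$corrected <- FALSE
      out[[length(out) + 1L]] <- s
    }
  }
  out
}

# ---- FLAIR mimic loss ------------------------------------------------------

# sample: list(id, image = volume on the FLAIR grid, target = binary volume
# on the same grid). Channel 1 of the FLAIR net carries the lesion mask.
flair_mimic_loss_fn <- function(model, sample, aug_seed, cfg) {
  img <- sample$image
  tgt <- sample$target
  if (!is.null(aug_seed)) {
    ctr <- (img$grid$shape - 1) / 2 * img$grid$voxel_size
    aug <- random_affine(cfg$flair_augment, aug_seed, center_mm = ctr)
    if (max(abs(as_transform_matrix(aug) - diag(4))) >= 1e-12) {
      img <- resample(img, img$grid, aug, mode = "trilinear")
      tgt <- resample(tgt, tgt$grid, aug, mode = "nearest")
    }
  }
  if (is.null(aug_seed)) {
    y <- nn_forward(model, img$data, train = FALSE)
    d <- y[1, , , ] - tgt$data
    loss <- sum(d * d)
    if (cfg$normalize_loss) loss <- loss / length(d)
    return(list(loss = loss))
  }
  fwd <- nn_forward(model, img$data, train = TRUE)
  d <- fwd$y[1, , , ] - tgt$data
  loss <- sum(d * d)
  g <- array(0, dim(fwd$y))
  g[1, , , ] <- 2 * d
  if (cfg$normalize_loss) {
    loss <- loss / length(d)
    g <- g / length(d)
  }
  list(loss = loss, grads = nn_backward(model, fwd, g))
}

#' Two-step curated FLAIR training workflow
#'
#' Step 1 trains a FLAIR net to mimic the provided (possibly imperfect)
#' target masks and ranks the samples by evaluation loss. After external
#' corrections/drops are decided, step 2 retrains on the curated dataset
#' (corrected samples oversampled `cfg$oversample_factor` times) and emits
#' model-generated reference masks for the whole dataset -- the targets of
#' the subsequent T1 step.
#' @param dataset list of samples (`id`, `image`, `target`).
#' @param cfg a `train_config`.
#' @param corrections named list id -> corrected mask `volume` (may be empty).
#' @param drops ids to exclude from retraining.
#' @param model optional pre-built FLAIR `unet_model` (default built from cfg).
#' @return list(model, report, reference_masks, history_step1, history_step2).
#' @export
two_step_flair_workflow <- function(dataset, cfg, corrections = NULL,
                                    drops = NULL, model = NULL) {
  if (is.null(model))
    model <- build_flair_net(cfg$width_scale, cfg$levels, seed = cfg$seed)
  step1 <- train(model, dataset, flair_mimic_loss_fn, cfg)
  report <- rank_by_loss(step1$model, dataset, flair_mimic_loss_fn, cfg)
  report$flag[report$id %in% names(corrections)] <- "corrected"
  report$flag[report$id %in% drops] <- "dropped"
  curated <- build_curated_dataset(dataset, corrections, drops,
                                   cfg$oversample_factor)
  cfg2 <- cfg
  cfg2$seed <- cfg$seed + 1L
  step2 <- train(step1$model, curated, flair_mimic_loss_fn, cfg2)
  reference_masks <- lapply(dataset, function(s) {
    y <- nn_forward(step2$model, s$image$data, train = FALSE)
    volume(array(as.numeric(y[1, , , ] >= 0.5), s$image$grid$shape),
           s$image$grid)
  })
  names(reference_masks) <- vapply(dataset, function(s) as.character(s$id),
                                   character(1))
  list(model = step2$model, report = report,
       reference_masks = reference_masks,
       history_step1 = step1$loss_history, history_step2 = step2$loss_history)
}

# ---- T1 cross-modality loss ------------------------------------------------

# sample: list(id, t1 = volume on the T1 grid, target = binary volume on the
# FLAIR grid, ribbon = binary volume on the T1 grid, rigid = FLAIR->T1
# transform). Channel 1: lesion; channel 2: cortical ribbon.
t1_joint_loss_fn <- function(model, sample, aug_seed, cfg) {
  t1 <- sample$t1
  ribbon <- sample$ribbon
  rigid <- sample$rigid %||% rigid_transform()
  aug <- NULL
  if (!is.null(aug_seed)) {
    ctr <- (t1$grid$shape - 1) / 2 * t1$grid$voxel_size
    aug <- random_affine(cfg$augment, aug_seed, center_mm = ctr)
    if (max(abs(as_transform_matrix(aug) - diag(4))) < 1e-12) {
      aug <- NULL # strength-0 augmentation: skip the resampling entirely
    } else {
      t1 <- resample(t1, t1$grid, aug, mode = "trilinear")
      ribbon <- resample(ribbon, ribbon$grid, aug, mode = "nearest")
    }
    t1 <- histogram_warp(t1, cfg$augment, aug_seed + 1L)
  }
  train_mode <- !is.null(aug_seed)
  fwd <- nn_forward(model, t1$data, train = train_mode)
  y <- if (train_mode) fwd$y else fwd
  out1 <- volume(array(y[1, , , ], t1$grid$shape), t1$grid)
  out2 <- array(y[2, , , ], t1$grid$shape)
  if (cfg$loss_mode == "sparse") {
    # the augmentation enters only through the sampling map; the FLAIR
    # target is never interpolated
    map <- build_sampling_map(sample$target$grid, t1$grid, rigid, aug = aug)
    jl <- joint_loss(out1, out2, sample$target, ribbon, map,
                     weight = cfg$ribbon_weight, grad = train_mode)
    loss <- jl$total
    nrm <- max(1L, jl$n_sampled)
    if (train_mode) { g1 <- jl$grad1; g2 <- jl$grad2 }
  } else {
    tr <- if (is.null(aug)) rigid else compose_transforms(aug, rigid)
    dl <- dense_interpolating_loss(out1, sample$target, tr, grad = train_mode)
    rl <- ribbon_loss(out2, ribbon, grad = train_mode)
    if (train_mode) {
      loss <- dl$loss + cfg$ribbon_weight * rl$loss
      g1 <- dl$grad; g2 <- cfg$ribbon_weight * rl$grad
    } else loss <- dl + cfg$ribbon_weight * rl
    nrm <- length(out2)
  }
  if (cfg$normalize_loss) loss <- loss / nrm
  if (!train_mode) return(list(loss = loss))
  g <- array(0, dim(y))
  g[1, , , ] <- g1
  g[2, , , ] <- g2
  if (cfg$normalize_loss) g <- g / nrm
  list(loss = loss, grads = nn_backward(model, fwd, g))
}

#' Train the T1 lesion net from FLAIR-space masks
#'
#' For every visit: draw an augmentation, transform the T1 input (and the
#' dense ribbon target) into the augmented frame, rebuild the sampling map
#' with the augmentation composed in -- the FLAIR targets are untouched --
#' and apply the joint loss. `cfg$loss_mode = "dense"` swaps in the
#' interpolating baseline for comparisons.
#' @param t1_dataset list of samples (`id`, `t1`, `target`, `ribbon`,
#'   `rigid`).
#' @param cfg a `train_config`.
#' @param model optional pre-built `unet_model`.
#' @return list(model, loss_history).
#' @export
train_t1_from_flair <- function(t1_dataset, cfg, model = NULL) {
  if (is.null(model))
    model <- build_t1_wmh_net(cfg$width_scale, cfg$levels, seed = cfg$seed)
  train(model, t1_dataset, t1_joint_loss_fn, cfg,
        reinit = function(attempt)
          build_t1_wmh_net(cfg$width_scale, cfg$levels,
                           seed = cfg$seed + 7919L * attempt))
}

# ---- ROI net training ------------------------------------------------------

# sample: list(id, t1 = volume, roi = roi_labels, wm = binary volume).
roi_loss_fn <- function(model, sample, aug_seed, cfg) {
  img <- sample$t1
  lab <- sample$roi$labels$data # 0..3
  if (!is.null(aug_seed) && isTRUE(cfg$roi_lacunes)) {
    sl <- scatter_lacunes(img, sample$wm, cfg$augment, aug_seed)
    img <- sl$volume
  }
  train_mode <- !is.null(aug_seed)
  fwd <- nn_forward(model, img$data, train = train_mode)
  y <- if (train_mode) fwd$y else fwd
  d <- dim(y)
  tgt <- array(0, d)
  for (k in 0:3) tgt[k + 1L, , , ] <- as.numeric(lab == k)
  df <- y - tgt
  loss <- sum(df * df)
  if (cfg$normalize_loss) loss <- loss / prod(d[2:4])
  if (!train_mode) return(list(loss = loss))
  g <- 2 * df
  if (cfg$normalize_loss) g <- g / prod(d[2:4])
  list(loss = loss, grads = nn_backward(model, fwd, g))
}

#' Train the T1 ROI net, optionally with simulated lacunes
#'
#' Targets are the geometric white-matter partitions; when `lacunes = TRUE`
#' (the default) every training visit scatters fresh simulated lacunes over
#' the white matter of the input image only, teaching the net to keep its
#' region labels over dark cavities instead of carving holes.
#' @param dataset list of samples (`id`, `t1`, `roi` = `roi_labels`, `wm`).
#' @param cfg a `train_config`.
#' @param lacunes enable lacune augmentation.
#' @param model optional pre-built `unet_model`.
#' @return list(model, loss_history).
#' @export
train_roi_net_with_lacunes <- function(dataset, cfg, lacunes = TRUE,
                                       model = NULL) {
  if (is.null(model))
    model <- build_t1_roi_net(cfg$width_scale, cfg$levels, seed = cfg$seed)
  cfg$roi_lacunes <- lacunes
  train(model, dataset, roi_loss_fn, cfg)
}
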
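# The three U-shaped topologies. All use skip *sums* (not concatenation),
# max-pooling that records argmax indices, index-preserving unpooling, and
# instance normalization (batch size is fixed at 1 throughout training, so
# batch norm is not meaningful). The FLAIR net pools the slice axis only once:
# from the second pooling level on, pooling halves the axial (in-plane)
# dimensions only, so thin 18-24-slice stacks survive all five levels.
#
# Channel widths follow the published table at width_scale = 1; smaller scales
# shrink every internal width (minimum 1 channel) for desk-scale runs, and
# `levels` may truncate the depth while preserving the block structure.

#' Specification of a U-shaped network
#'
#' @param kind one of `"t1_wmh"`, `"t1_roi"`, `"flair"`.
#' @param width_scale multiplier on all internal channel counts (1 reproduces
#'   the published widths; must leave every layer with >= 1 channel).
#' @param levels number of pooling levels (default 5, the published depth).
#' @param out_channels number of output channels (defaults per kind: 2, 4, 3).
#' @return A `unet_spec` list describing the topology.
#' @export
unet_spec <- function(kind = c("t1_wmh", "t1_roi", "flair"), width_scale = 1,
                      levels = 5L, out_channels = NULL) {
  kind <- match.arg(kind)
  stopifnot(width_scale > 0, levels >= 1L, levels <= 5L)
  if (is.null(out_channels))
    out_channels <- switch(kind, t1_wmh = 2L, t1_roi = 4L, flair = 3L)
  structure(list(kind = kind, width_scale = width_scale,
                 levels = as.integer(levels),
                 out_channels = as.integer(out_channels),
                 final_activation = if (kind == "t1_roi") "softmax" else "sigmoid",
                 skip = "sum"),
            class = "unet_spec")
}

scale_ch <- function(c, ws) {
  out <- as.integer(round(c * ws))
  if (out < 1L) stop("width_scale ", ws, " leaves a layer with < 1 channel")
  out
}

# tape-building helpers; `env` carries the accumulating tape and params
tape_builder <- function() {
  e <- new.env()
  e$tape <- list()
  e$params <- list()
  e$conv <- function(cin, cout, k = 3L) {
    e$params[[length(e$params) + 1L]] <- new_param_conv(cin, cout, k)
    e$tape[[length(e$tape) + 1L]] <-
      list(op = if (k == 3L) "conv3" else "conv1", par = length(e$params),
           cin = cin, cout = cout, k = k)
    invisible(cout)
  }
  e$inorm <- function(c) {
    e$params[[length(e$params) + 1L]] <- list(g = rep(1, c), b = numeric(c))
    e$tape[[length(e$tape) + 1L]] <- list(op = "inorm", par = length(e$params))
  }
  e$push <- function(opname, ...) {
    e$tape[[length(e$tape) + 1L]] <- list(op = opname, ...)
  }
  e
}

#' Build a model from a `unet_spec`
#'
#' @param spec a `unet_spec`.
#' @param seed integer seed for the weight initialization.
#' @return A `unet_model`: the tape of operations, the parameter list, the
#'   per-axis pooling divisor (inputs are symmetrically zero-padded to a
#'   multiple of it and the output cropped back), and the spec.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  set.seed(seed)
  ws <- spec$width_scale
  L <- spec$levels
  b <- tape_builder()
  wmh <- spec$kind == "t1_wmh"
  roi <- spec$kind == "t1_roi"
  fl <- spec$kind == "flair"
  pool_factor <- function(i) {
    # FLAIR: only the first pool halves the slice axis
    if (fl && i >= 2L) c(2L, 2L, 1L) else c(2L, 2L, 2L)
  }
  if (wmh) {
    c24 <- scale_ch(24, ws); c64 <- scale_ch(64, ws); c128 <- scale_ch(128, ws)
    b$conv(1L, c24); b$inorm(c24); b$push("relu")
    b$conv(c24, c64); b$push("relu"); b$push("save", name = "b0")
    for (i in seq_len(L - 1L)) {
      b$push("pool", factor = pool_factor(i))
      b$conv(c64, c64); b$inorm(c64); b$push("relu")
      b$conv(c64, c64); b$push("relu"); b$push("save", name = paste0("b", i))
    }
    b$push("pool", factor = pool_factor(L))
    b$conv(c64, c128); b$inorm(c128); b$push("relu")
    b$conv(c128, c64); b$push("relu")
    for (i in seq(L - 1L, 0L)) {
      b$push("unpool")
      b$conv(c64, c64); b$inorm(c64); b$push("relu")
      if (i < L - 1L) b$push("add", name = paste0("b", i)) # deepest save unused
      b$conv(c64, c64); b$push("relu")
    }
    b$conv(c64, c24); b$push("relu")
    b$conv(c24, spec$out_channels, k = 1L)
    b$push("sigmoid")
  } else {
    c12 <- scale_ch(12, ws); c16 <- scale_ch(16, ws); c8 <- scale_ch(8, ws)
    if (roi) {
      b$conv(1L, c12); b$push("relu"); b$push("save", name = "b0")
    } else {
      b$conv(1L, c12); b$inorm(c12); b$push("relu")
      b$conv(c12, c12, k = 1L); b$push("relu"); b$push("save", name = "b0")
    }
    for (i in seq_len(L - 1L)) {
      cin <- if (i == 1L) c12 else c16
      b$push("pool", factor = pool_factor(i))
      b$conv(cin, c16); b$push("relu")
      b$conv(c16, c16, k = if (roi) 1L else 3L); b$push("relu")
      b$push("save", name = paste0("b", i))
    }
    b$push("pool", factor = pool_factor(L))
    cbn <- if (L == 1L) c12 else c16 # L=1: decoder re-enters at c12
    b$conv(if (L == 1L) c12 else c16, c16); b$push("relu")
    b$conv(c16, cbn, k = 1L); b$inorm(cbn); b$push("relu")
    for (i in seq(L - 1L, 0L)) {
      if (i >= 1L) {
        b$push("unpool")
        b$conv(c16, c16); b$inorm(c16); b$push("relu")
        b$push("add", name = paste0("b", i))
        b$conv(c16, if (i == 1L) c12 else c16); b$push("relu")
      } else {
        b$push("unpool")
        if (roi) {
          b$conv(c12, c12); b$push("relu")
        } else {
          b$conv(c12, c12); b$inorm(c12); b$push("relu")
        }
        b$push("add", name = "b0")
        b$conv(c12, c12, k = 1L); b$push("relu")
        b$conv(c12, c8); b$push("relu")
        b$conv(c8, spec$out_channels, k = 1L)
      }
    }
    b$push(spec$final_activation)
  }
  if (spec$final_activation == "sigmoid") {
    # rare-positive prior on the output layer: starting the sigmoid near
    # sigmoid(-3) ~ 0.05 prevents the early collapse into saturated all-zero
    # predictions that a plain squared-error loss otherwise provokes on
    # sparse segmentation targets
    b$params[[length(b$params)]]$b[] <- -3
  }
  divisor <- c(1L, 1L, 1L)
  for (op in b$tape) if (op$op == "pool") divisor <- divisor * op$factor
  structure(list(tape = b$tape, params = b$params, divisor = divisor,
                 min_input = pmax(divisor %/% 2L, 2L),
                 spec = spec), class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model %s, width_scale %.3g, %d levels, %d parameters>\n",
              x$spec$kind, x$spec$width_scale, x$spec$levels,
              nn_param_count(x)))
  invisible(x)
}

#' Build the T1 lesion network (lesion + cortical-ribbon sigmoid outputs)
#'
#' Five pooling levels, skip-sums from encoder blocks 0-3, first layer 24
#' channels and a 128-channel bottleneck at `width_scale = 1`.
#' @param width_scale channel multiplier; `levels` network depth; `seed` init seed.
#' @param levels,seed see [build_model()].
#' @return A `unet_model` with 2 output channels (1: lesion, 2: cortex ribbon).
#' @export
build_t1_wmh_net <- function(width_scale = 1, levels = 5L, seed = 1L)
  build_model(unet_spec("t1_wmh", width_scale, levels), seed = seed)

#' Build the T1 region-of-interest network (4 softmax label maps)
#'
#' Output channels are per-voxel softmax-normalized: 1 outside-WM,
#' 2 periventricular, 3 deep, 4 juxtacortical.
#' @param width_scale,levels,seed see [build_model()].
#' @return A `unet_model` with 4 output channels summing to 1 per voxel.
#' @export
build_t1_roi_net <- function(width_scale = 1, levels = 5L, seed = 1L)
  build_model(unet_spec("t1_roi", width_scale, levels), seed = seed)

#' Build the FLAIR-space network (3 sigmoid outputs, variable slice count)
#'
#' Operates in native FLAIR space: from the second pooling level on, pooling
#' halves the axial in-plane dimensions only, so stacks of 18-24 (or any >= 8)
#' slices pass through all levels; the output slice count always equals the
#' input's. Channel 1 carries the lesion mask; the remaining channels are
#' auxiliary and depend on the loaded parameters.
#' @param width_scale,levels,seed see [build_model()].
#' @return A `unet_model` with 3 output channels.
#' @export
build_flair_net <- function(width_scale = 1, levels = 5L, seed = 1L)
  build_model(unet_spec("flair", width_scale, levels), seed = seed)

#' Run a model forward
#'
#' The input is symmetrically zero-padded to the pooling divisor and the
#' output cropped back, so the spatial output shape always equals the input
#' shape.
#' @param model a `unet_model`.
#' @param x 3D array, or `volume`.
#' @return Array of dim `(out_channels, X, Y, Z)`, values in `[0, 1]`.
#' @export
predict_volume <- function(model, x) {
  if (is_volume(x)) x <- x$data
  nn_forward(model, x, train = FALSE)
}

#' Save / load a model (weights plus serialized spec, one RDS container)
#' @param model a `unet_model`; `path` file path.
#' @param path file path.
#' @rdname model_io
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "sparsewmh-unet-1", spec = unclass(model$spec),
               tape = model$tape, divisor = model$divisor,
               min_input = model$min_input, params = model$params), path)
  invisible(path)
}

#' @rdname model_io
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "sparsewmh-unet-1"))
    stop("not a sparsewmh model container: ", path)
  structure(list(tape = x$tape, params = x$params, divisor = x$divisor,
                 min_input = x$min_input,
                 spec = structure(x$spec, class = "unet_spec")),
            class = "unet_model")
}
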
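# Minimal NIfTI-1 reader/writer (no R NIfTI package is assumed). Supports
# 3D volumes, data types uint8/int16/int32/float32/float64, gzip-compressed
# or plain files, and the sform affine (NIfTI world-coordinate convention).
# Masks are written as uint8, probabilities as float32.

nifti_dtypes <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4` = list(what = "integer", size = 2L, signed = TRUE, bitpix = 16L),
  `8` = list(what = "integer", size = 4L, signed = TRUE, bitpix = 32L),
  `16` = list(what = "double", size = 4L, bitpix = 32L),
  `64` = list(what = "double", size = 8L, bitpix = 64L)
)

#' Read a NIfTI-1 volume
#'
#' Accepts `.nii` and `.nii.gz`. The affine is taken from the sform when set,
#' otherwise built diagonally from the pixdims. 3D images only; non-finite
#' voxels are rejected.
#' @param path file path.
#' @return A `volume`.
#' @export
read_volume <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("corrupted NIfTI header (short read): ", path)
  sizeof <- readBin(hdr[1:4], "integer", 1L, 4L, endian = "little")
  endian <- "little"
  if (sizeof != 348L) {
    sizeof <- readBin(hdr[1:4], "integer", 1L, 4L, endian = "big")
    if (sizeof != 348L) stop("corrupted NIfTI header (sizeof_hdr): ", path)
    endian <- "big"
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file: ", path)
  rd <- function(off, what, n, size)
    readBin(hdr[(off + 1L):(off + n * size)], what, n, size, endian = endian)
  dims <- rd(40L, "integer", 8L, 2L)
  ndim <- dims[1]
  if (ndim > 3L && any(dims[(4L + 1L):(ndim + 1L)] > 1L))
    stop("4D (or higher) NIfTI input is not supported: ", path)
  if (ndim < 3L) stop("expected a 3D NIfTI volume: ", path)
  shape <- dims[2:4]
  datatype <- rd(70L, "integer", 1L, 2L)
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rd(76L, "double", 8L, 4L)
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  sform_code <- rd(254L, "integer", 1L, 2L)
  srow <- matrix(rd(280L, "double", 12L, 4L), nrow = 3L, byrow = TRUE)
  n <- prod(shape)
  skip <- as.integer(vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  data <- readBin(con, dt$what, n, dt$size,
                  signed = if (dt$size < 4L) isTRUE(dt$signed) else TRUE,
                  endian = endian)
  if (length(data) < n) stop("corrupted NIfTI data (short read): ", path)
  data <- as.numeric(data)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  if (!all(is.finite(data))) stop("non-finite voxels in ", path)
  vs <- abs(pixdim[2:4])
  vs[vs == 0] <- 1
  aff <- if (sform_code > 0L) rbind(srow, c(0, 0, 0, 1)) else diag(c(vs, 1))
  volume(array(data, shape), grid(shape, sqrt(colSums(aff[1:3, 1:3]^2)), aff))
}

#' Write a volume as NIfTI-1
#'
#' `.gz` suffix selects gzip. `datatype` `"float32"` (default) or `"uint8"`
#' (for masks; values must be 0..255 integers).
#' @param vol a `volume`.
#' @param path output path.
#' @param datatype storage type.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = c("float32", "uint8")) {
  stopifnot(is_volume(vol))
  datatype <- match.arg(datatype)
  if (!all(is.finite(vol$data))) stop("refusing to write non-finite voxels")
  code <- if (datatype == "float32") 16L else 2L
  bitpix <- if (datatype == "float32") 32L else 8L
  hdr <- raw(348L)
  put <- function(off, x, size, what = "integer") {
    b <- writeBin(x, raw(), size, endian = "little")
    hdr[(off + 1L):(off + length(b))] <<- b
  }
  put(0L, 348L, 4L)
  put(40L, c(3L, vol$grid$shape, 1L, 1L, 1L, 1L), 2L)
  put(70L, code, 2L)
  put(72L, bitpix, 2L)
  put(76L, c(1, vol$grid$voxel_size, 0, 0, 0, 0), 4L, "double")
  put(108L, 352, 4L, "double")           # vox_offset
  put(112L, 1, 4L, "double")             # scl_slope
  put(116L, 0, 4L, "double")             # scl_inter
  put(252L, 1L, 2L)                      # qform_code (unused but set)
  put(254L, 1L, 2L)                      # sform_code
  put(280L, as.numeric(t(vol$grid$affine[1:3, ])), 4L, "double")
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con) # no extensions
  if (datatype == "float32") {
    writeBin(as.numeric(vol$data), con, 4L, endian = "little")
  } else {
    v <- as.integer(round(vol$data))
    if (any(v < 0L | v > 255L)) stop("uint8 output requires values in 0..255")
    writeBin(as.raw(v), con)
  }
  invisible(path)
}

#' Resample a T1 volume into the canonical working grid
#'
#' Registration itself is external: the affine mapping the input's world
#' coordinates to template space is supplied (identity with
#' `assume_aligned`-style pipelines).
#' @param t1 input `volume`.
#' @param to_template world transform input -> template (default identity).
#' @param target the working `grid` (default the canonical 184x202x72 at
#'   1x1x1.5 mm).
#' @return A `volume` on `target`.
#' @export
to_workspace <- function(t1, to_template = rigid_transform(),
                         target = canonical_grid()) {
  stopifnot(is_volume(t1))
  if (identical(t1$grid, target) &&
      max(abs(as_transform_matrix(to_template) - diag(4))) == 0)
    return(t1)
  resample(t1, target, to_template, mode = "trilinear")
}

#' Read / write a subject manifest
#'
#' CSV with columns id, t1_path, flair_path, flair_mask_path, rigid_path,
#' split (train|test), corrected. Ids must be unique and splits disjoint by
#' construction.
#' @param path CSV path; `manifest` a data.frame to write.
#' @param manifest data.frame to write.
#' @rdname manifest_io
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(m)) stop("manifest lacks an 'id' column")
  if (anyDuplicated(m$id)) stop("manifest ids are not unique")
  if ("split" %in% names(m) && !all(m$split %in% c("train", "test")))
    stop("manifest split must be 'train' or 'test'")
  m
}

#' @rdname manifest_io
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

write_run_record <- function(out_dir, config = list(), seed = NA) {
  rec <- list(package = "sparsewmh",
              version = as.character(utils::packageVersion("sparsewmh")),
              r_version = R.version.string,
              date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              seed = seed, config = config)
  jsonlite::write_json(rec, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Segment a T1 image end-to-end
#'
#' Loads a trained lesion model (and optionally an ROI model), runs the
#' forward pass on the workspace grid, and writes: the lesion probability
#' map, the cortex probability map, the thresholded lesion mask (50%), ROI
#' labels when available, a regional-volume CSV, and a reproducibility
#' record.
#' @param t1_path input NIfTI path.
#' @param model_path lesion model container (see [save_model()]).
#' @param out_dir output directory (created).
#' @param roi_model_path optional ROI model container.
#' @param to_template world transform to template space (identity for
#'   pre-aligned/phantom inputs).
#' @param target working grid; defaults to the input's own grid when
#'   `assume_aligned`, otherwise the canonical grid.
#' @param assume_aligned treat the input as already on the working grid.
#' @param threshold mask threshold (default 0.5).
#' @return Invisibly, the list of written paths.
#' @export
segment <- function(t1_path, model_path, out_dir, roi_model_path = NULL,
                    to_template = rigid_transform(), target = NULL,
                    assume_aligned = FALSE, threshold = 0.5) {
  t1 <- read_volume(t1_path)
  model <- load_model(model_path)
  if (!identical(model$spec$kind, "t1_wmh"))
    stop("model at ", model_path, " is a '", model$spec$kind,
         "' net, not a T1 lesion net")
  if (is.null(target))
    target <- if (assume_aligned) t1$grid else canonical_grid()
  work <- if (assume_aligned && identical(t1$grid$shape, target$shape)) t1
          else to_workspace(t1, to_template, target)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  y <- predict_volume(model, work)
  wmh <- volume(array(y[1, , , ], target$shape), target)
  cortex <- volume(array(y[2, , , ], target$shape), target)
  mask <- volume(array(as.numeric(wmh$data >= threshold), target$shape),
                 target)
  paths <- list(
    wmh_prob = file.path(out_dir, "wmh_prob.nii.gz"),
    cortex_prob = file.path(out_dir, "cortex_prob.nii.gz"),
    wmh_mask = file.path(out_dir, "wmh_mask.nii.gz"))
  write_volume(wmh, paths$wmh_prob)
  write_volume(cortex, paths$cortex_prob)
  write_volume(mask, paths$wmh_mask, datatype = "uint8")
  if (!is.null(roi_model_path)) {
    roi_model <- load_model(roi_model_path)
    ry <- predict_volume(roi_model, work)
    lab <- array(max.col(t(matrix(ry, nrow = dim(ry)[1]))) - 1L, target$shape)
    roi <- structure(list(labels = volume(lab, target),
                          pv_radius_mm = NA, jc_radius_mm = NA),
                     class = "roi_labels")
    paths$roi_labels <- file.path(out_dir, "roi_labels.nii.gz")
    write_volume(roi$labels, paths$roi_labels, datatype = "uint8")
    vols <- regional_volumes(wmh, roi, threshold = threshold)
    paths$regional_csv <- file.path(out_dir, "regional_volumes.csv")
    utils::write.csv(data.frame(id = basename(t1_path),
                                pv_mm3 = vols[["pv_mm3"]],
                                deep_mm3 = vols[["deep_mm3"]],
                                jc_mm3 = vols[["jc_mm3"]]),
                     paths$regional_csv, row.names = FALSE)
  }
  write_run_record(out_dir,
                   config = list(model = model_path, threshold = threshold,
                                 assume_aligned = assume_aligned))
  invisible(paths)
}
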
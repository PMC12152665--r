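#' Image acquisition metadata
#'
#' Carries the physical calibration every downstream measurement needs:
#' the lateral pixel size in micrometers per pixel and, for time-lapse
#' data, the frame interval in seconds. Pixels are assumed square;
#' anisotropic calibrations are rejected.
#'
#' @param pixel_size_um Pixel size in micrometers per pixel (positive
#'   scalar, or a length-2 vector that must be isotropic).
#' @param frame_interval_s Optional frame interval in seconds (positive
#'   scalar).
#' @param channel_names Optional character vector of channel labels.
#' @return An object of class `ImageMeta`.
#' @export
image_meta <- function(pixel_size_um, frame_interval_s = NULL,
                       channel_names = NULL) {
  if (missing(pixel_size_um) || is.null(pixel_size_um))
    stop("pixel_size_um is required; refusing to assume 1 um/px", call. = FALSE)
  pixel_size_um <- as.numeric(pixel_size_um)
  if (length(pixel_size_um) == 2L) {
    if (!isTRUE(all.equal(pixel_size_um[1], pixel_size_um[2])))
      stop("anisotropic pixel sizes are not supported: ",
           paste(pixel_size_um, collapse = " x "), call. = FALSE)
    pixel_size_um <- pixel_size_um[1]
  }
  if (length(pixel_size_um) != 1L || !is.finite(pixel_size_um) ||
      pixel_size_um <= 0)
    stop("pixel_size_um must be a positive finite scalar", call. = FALSE)
  if (!is.null(frame_interval_s)) {
    frame_interval_s <- as.numeric(frame_interval_s)
    if (length(frame_interval_s) != 1L || !is.finite(frame_interval_s) ||
        frame_interval_s <= 0)
      stop("frame_interval_s must be a positive finite scalar", call. = FALSE)
  }
  structure(list(pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 channel_names = channel_names),
            class = "ImageMeta")
}

#' Fluorescence intensity image
#'
#' A 2D raster of nonnegative fluorescence intensities plus its
#' [image_meta()] calibration. Matrices are stored row-major in the R
#' sense: `values[r, c]` is row `r` (y), column `c` (x), with pixel
#' centers at integer coordinates starting at 1.
#'
#' @param values Numeric matrix of finite, nonnegative intensities.
#' @param meta An `ImageMeta` object.
#' @return An object of class `IntensityImage`.
#' @export
intensity_image <- function(values, meta) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("image must be at least 1x1", call. = FALSE)
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("image values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("image values must be nonnegative", call. = FALSE)
  stopifnot(inherits(meta, "ImageMeta"))
  structure(list(values = values, meta = meta), class = "IntensityImage")
}

#' Integer label mask
#'
#' A 2D raster of nonnegative integer labels: 0 is background, every
#' positive value `k` identifies object `k` (a cell, nucleus, ROI or
#' adhesion). Labels need not be contiguous.
#'
#' @param labels Integer matrix (nonnegative).
#' @param meta An `ImageMeta` object.
#' @return An object of class `LabelMask`.
#' @export
label_mask <- function(labels, meta) {
  labels <- as.matrix(labels)
  if (nrow(labels) < 1L || ncol(labels) < 1L)
    stop("mask must be at least 1x1", call. = FALSE)
  if (any(!is.finite(labels)) || any(labels < 0) ||
      any(labels != round(labels)))
    stop("labels must be nonnegative integers", call. = FALSE)
  storage.mode(labels) <- "integer"
  stopifnot(inherits(meta, "ImageMeta"))
  structure(list(labels = labels, meta = meta), class = "LabelMask")
}

#' @export
print.ImageMeta <- function(x, ...) {
  cat("ImageMeta:", x$pixel_size_um, "um/px",
      if (!is.null(x$frame_interval_s))
        paste0(", dt = ", x$frame_interval_s, " s"), "\n")
  invisible(x)
}

#' @export
print.IntensityImage <- function(x, ...) {
  cat(sprintf("IntensityImage %d x %d px (%.4g um/px), range [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$meta$pixel_size_um,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.LabelMask <- function(x, ...) {
  cat(sprintf("LabelMask %d x %d px (%.4g um/px), %d object(s)\n",
              nrow(x$labels), ncol(x$labels), x$meta$pixel_size_um,
              length(mask_labels(x))))
  invisible(x)
}

#' Labels present in a mask
#'
#' @param mask A `LabelMask` or integer matrix.
#' @return Sorted integer vector of the distinct nonzero labels.
#' @export
mask_labels <- function(mask) {
  m <- if (inherits(mask, "LabelMask")) mask$labels else mask
  sort(unique(m[m > 0L]))
}

# Convert a physical distance (um) to pixels under a mask/image meta.
um_to_px <- function(um, meta) um / meta$pixel_size_um

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards (generators stay pure).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# matrix <-> EBImage::Image with consistent axis order (EBImage stores x,y)
as_eb <- function(m) EBImage::Image(t(m))
from_eb <- function(im) t(EBImage::imageData(im))
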
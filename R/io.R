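#' Read a fluorescence image (TIFF or PNG)
#'
#' Reads a single-plane image or a multi-page TIFF z-stack. Pixel values
#' are returned exactly as stored (integer counts for integer TIFFs);
#' nothing is rescaled. The physical pixel size is never guessed: it
#' must be supplied explicitly or through a config, otherwise reading
#' fails.
#'
#' @param path Path to a TIFF (`.tif`/`.tiff`) or PNG file.
#' @param pixel_size_um Pixel size in um/px (required).
#' @param frame_interval_s Optional frame interval (s) for time-lapse data.
#' @param channel_names Optional channel labels.
#' @return An [intensity_image()] for a single plane, or a list of them
#'   for a multi-page TIFF stack.
#' @export
read_image <- function(path, pixel_size_um = NULL, frame_interval_s = NULL,
                       channel_names = NULL) {
  if (is.null(pixel_size_um))
    stop("pixel size missing for '", path,
         "': supply pixel_size_um explicitly (never assumed to be 1 um/px)",
         call. = FALSE)
  meta <- image_meta(pixel_size_um, frame_interval_s, channel_names)
  planes <- read_raster(path)
  imgs <- lapply(planes, intensity_image, meta = meta)
  if (length(imgs) == 1L) imgs[[1L]] else imgs
}

#' Read a label mask (TIFF or PNG)
#'
#' Label images written by external segmenters (e.g. Cellpose exports)
#' are read as integer rasters: 0 is background, k > 0 is object k.
#'
#' @inheritParams read_image
#' @return A [label_mask()].
#' @export
read_mask <- function(path, pixel_size_um = NULL) {
  if (is.null(pixel_size_um))
    stop("pixel size missing for '", path,
         "': supply pixel_size_um explicitly", call. = FALSE)
  planes <- read_raster(path)
  if (length(planes) != 1L)
    stop("label masks must be single-plane images", call. = FALSE)
  label_mask(round(planes[[1L]]), image_meta(pixel_size_um))
}

# Read TIFF/PNG into a list of numeric matrices with raw stored values.
read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    lapply(planes, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1L]  # greyscale stored with alpha
      matrix(as.numeric(p), nrow = nrow(p))
    })
  } else if (ext == "png") {
    p <- png::readPNG(path)
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    # readPNG normalizes to [0,1]; undo the 8- or 16-bit scaling exactly
    v255 <- p * 255
    v <- if (max(abs(v255 - round(v255))) < 1e-9) round(v255) else
      round(p * 65535)
    list(matrix(as.numeric(v), nrow = nrow(v)))
  } else {
    stop("unsupported raster format: .", ext, call. = FALSE)
  }
}

#' Write an image or mask to TIFF/PNG
#'
#' Integer-valued rasters (intensity counts or labels) are written as
#' 8- or 16-bit greyscale so that a subsequent [read_image()] /
#' [read_mask()] returns the identical pixel array. PNG output is 8-bit
#' only; rasters with values above 255 must go to TIFF (16-bit PNGs can
#' still be read).
#'
#' @param x An `IntensityImage`, `LabelMask`, or numeric matrix of
#'   nonnegative integers < 65536.
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  v <- if (inherits(x, "IntensityImage")) x$values
       else if (inherits(x, "LabelMask")) x$labels
       else as.matrix(x)
  v <- matrix(as.numeric(v), nrow = nrow(v))
  if (any(v < 0) || any(v != round(v)) || max(v) > 65535)
    stop("only nonnegative integer rasters up to 16-bit can be written",
         call. = FALSE)
  bits <- if (max(v) > 255) 16L else 8L
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(v / (2^bits - 1), path, bits.per.sample = bits)
  } else if (ext == "png") {
    if (bits > 8L)
      stop("PNG output is 8-bit; use TIFF for values above 255",
           call. = FALSE)
    png::writePNG(v / 255, path)
  } else {
    stop("unsupported raster format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_image
#' @export
write_mask <- write_image

#' Sum projection of a z-stack
#'
#' All MFI measurements on z-stacks are taken on the per-pixel sum over
#' slices (sum-slices projection); a single plane passes through
#' unchanged.
#'
#' @param stack A single `IntensityImage` or a list of them with
#'   identical shapes and metadata.
#' @return An `IntensityImage` whose values are the per-pixel sum.
#' @export
sum_projection <- function(stack) {
  if (inherits(stack, "IntensityImage")) return(stack)
  stopifnot(is.list(stack), length(stack) >= 1L)
  dims <- vapply(stack, function(s) dim(s$values), integer(2))
  if (any(dims != dims[, 1L]))
    stop("all slices must have identical shape", call. = FALSE)
  acc <- Reduce(`+`, lapply(stack, `[[`, "values"))
  intensity_image(acc, stack[[1L]]$meta)
}

#' Read a run configuration (JSON or YAML)
#'
#' Configurations name the acquisition constants (pixel size, frame
#' interval), channel labels, thresholds and seeds used by the CLI
#' subcommands.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else stop("unsupported config format: .", ext, call. = FALSE)
}
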
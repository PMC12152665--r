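#' Focal-adhesion detection parameters
#'
#' Preprocessing and detection settings for punctate adhesion staining
#' (Paxillin / pY118 Paxillin). Preprocessing is background subtraction,
#' contrast-limited adaptive histogram equalization (CLAHE) and Gaussian
#' blur, in that order; each step can be disabled by setting its
#' parameter to 0 (useful on clean synthetic scenes).
#'
#' @param bg_radius_px Radius (px) of the disc used for morphological
#'   background estimation (grey opening); 0 disables. Default 50.
#' @param clahe_tile_px CLAHE tile size in pixels (default 64). Must not
#'   exceed the image.
#' @param clahe_clip CLAHE clip limit as a fraction of the histogram
#'   (default 0.01); 0 disables CLAHE.
#' @param gaussian_sigma_px Gaussian blur sigma (px); 0 disables.
#'   Default 1.
#' @param fixed_threshold Threshold on the preprocessed, `[0, 1]`-scaled
#'   intensity (default 0.5); must lie in (0, 1].
#' @param min_size_px Minimum adhesion size in pixels (default 4).
#' @return An object of class `FaParams`.
#' @export
fa_params <- function(bg_radius_px = 50, clahe_tile_px = 64,
                      clahe_clip = 0.01, gaussian_sigma_px = 1,
                      fixed_threshold = 0.5, min_size_px = 4L) {
  stopifnot(bg_radius_px >= 0, clahe_tile_px >= 1, clahe_clip >= 0,
            gaussian_sigma_px >= 0, min_size_px >= 0,
            fixed_threshold > 0, fixed_threshold <= 1)
  structure(list(bg_radius_px = bg_radius_px,
                 clahe_tile_px = as.integer(clahe_tile_px),
                 clahe_clip = clahe_clip,
                 gaussian_sigma_px = gaussian_sigma_px,
                 fixed_threshold = fixed_threshold,
                 min_size_px = as.integer(min_size_px)),
            class = "FaParams")
}

#' Preprocess an adhesion-staining image
#'
#' Background subtraction (grey opening with a disc of
#' `bg_radius_px`), CLAHE, Gaussian blur, then rescaling to `[0, 1]`.
#' A constant image stays constant (no structure is invented).
#'
#' @param image An `IntensityImage`.
#' @param params An [fa_params()] object.
#' @return An `IntensityImage` with values in `[0, 1]`.
#' @export
preprocess_fa <- function(image, params = fa_params()) {
  stopifnot(inherits(image, "IntensityImage"), inherits(params, "FaParams"))
  v <- image$values
  if (params$bg_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(params$bg_radius_px) + 1L,
                                shape = "disc")
    bg <- from_eb(EBImage::opening(as_eb(v), brush))
    v <- pmax(v - bg, 0)
  }
  if (params$clahe_clip > 0 && diff(range(v)) > 0) {
    if (params$clahe_tile_px > min(dim(v)))
      stop("clahe_tile_px (", params$clahe_tile_px,
           ") exceeds the image size", call. = FALSE)
    v <- (v - min(v)) / diff(range(v))
    nx <- max(1L, ceiling(ncol(v) / params$clahe_tile_px))
    ny <- max(1L, ceiling(nrow(v) / params$clahe_tile_px))
    # clahe needs dimensions divisible by the tile grid: pad by edge
    # replication, equalize, crop back
    nr0 <- nrow(v); nc0 <- ncol(v)
    nr <- ceiling(nr0 / ny) * ny; nc <- ceiling(nc0 / nx) * nx
    vp <- v[c(seq_len(nr0), rep(nr0, nr - nr0)),
            c(seq_len(nc0), rep(nc0, nc - nc0)), drop = FALSE]
    # EBImage's clip limit is in multiples of the mean bin count
    vp <- from_eb(EBImage::clahe(as_eb(vp), nx = nx, ny = ny,
                                 limit = params$clahe_clip * 256))
    v <- vp[seq_len(nr0), seq_len(nc0), drop = FALSE]
  }
  if (params$gaussian_sigma_px > 0 && length(v) > 1L)
    v <- from_eb(EBImage::gblur(as_eb(v), sigma = params$gaussian_sigma_px))
  rng <- range(v)
  v <- if (rng[1] == rng[2]) matrix(0, nrow(v), ncol(v))
       else (v - rng[1]) / (rng[2] - rng[1])
  intensity_image(v, image$meta)
}

#' Detect focal adhesions in a preprocessed image
#'
#' Applies the fixed threshold, labels 8-connected components inside
#' each cell mask (adhesions never mix across cells), drops components
#' below `min_size_px`, and reports per-adhesion pixel and physical
#' areas. An empty result is valid.
#'
#' @param preprocessed `IntensityImage` in `[0, 1]` from
#'   [preprocess_fa()].
#' @param params An [fa_params()] object.
#' @param cell_mask Optional cell `LabelMask`; when `NULL` the whole
#'   image is treated as one cell (id 1).
#' @return A data.frame with columns `cell_id`, `adhesion_id`,
#'   `area_px`, `area_um2`, `centroid_row`, `centroid_col`.
#' @export
detect_fa <- function(preprocessed, params = fa_params(), cell_mask = NULL) {
  stopifnot(inherits(preprocessed, "IntensityImage"))
  v <- preprocessed$values
  if (min(v) < 0 || max(v) > 1)
    stop("detect_fa expects a preprocessed image in [0, 1]", call. = FALSE)
  px_area_um2 <- preprocessed$meta$pixel_size_um^2
  cl <- if (is.null(cell_mask)) matrix(1L, nrow(v), ncol(v))
        else cell_mask$labels
  stopifnot(all(dim(cl) == dim(v)))
  bw <- v > params$fixed_threshold
  out <- list()
  for (cell in sort(unique(cl[cl > 0L]))) {
    lab <- label_components(bw & cl == cell)
    if (max(lab) == 0L) next
    sizes <- tabulate(lab[lab > 0L])
    for (k in which(sizes >= params$min_size_px)) {
      idx <- which(lab == k, arr.ind = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        cell_id = cell, adhesion_id = k,
        area_px = sizes[k], area_um2 = sizes[k] * px_area_um2,
        centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]))
    }
  }
  if (!length(out))
    return(data.frame(cell_id = integer(), adhesion_id = integer(),
                      area_px = integer(), area_um2 = numeric(),
                      centroid_row = numeric(), centroid_col = numeric()))
  do.call(rbind, out)
}

#' Per-cell focal-adhesion size statistics
#'
#' Mean adhesion area (um^2) and adhesion count per cell. Cells listed
#' in `cells` but carrying no detected adhesion get count 0, an `NA`
#' mean and a flag.
#'
#' @param records Data.frame from [detect_fa()].
#' @param cells Optional integer vector of all cell ids to report.
#' @return A data.frame with `cell_id`, `n_adhesions`, `mean_area_um2`,
#'   `no_adhesions` flag.
#' @export
fa_stats_per_cell <- function(records, cells = NULL) {
  if (is.null(cells)) cells <- sort(unique(records$cell_id))
  res <- lapply(cells, function(cid) {
    r <- records[records$cell_id == cid, , drop = FALSE]
    data.frame(cell_id = cid, n_adhesions = nrow(r),
               mean_area_um2 = if (nrow(r)) mean(r$area_um2) else NA_real_,
               no_adhesions = nrow(r) == 0L)
  })
  do.call(rbind, res)
}
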
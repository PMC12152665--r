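#' Threshold segmentation parameters
#'
#' Fixture-grade segmentation settings. Masks from dedicated segmenters
#' (e.g. Cellpose) are first-class input via [read_mask()]; this
#' thresholding path exists for simple DAPI / pre-conversion-channel
#' ROIs and for synthetic scenes.
#'
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Intensity threshold; required iff
#'   `method = "fixed"`. Pixels strictly above the threshold are
#'   foreground.
#' @param min_object_px Objects smaller than this many pixels are
#'   dropped (default 50).
#' @param fill_holes Fill enclosed background holes (default `TRUE`).
#' @param gaussian_sigma_px Gaussian pre-smoothing sigma in pixels
#'   (0 disables; default 1).
#' @return An object of class `SegmentationParams`.
#' @export
segmentation_params <- function(method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_object_px = 50L,
                                fill_holes = TRUE,
                                gaussian_sigma_px = 1) {
  method <- match.arg(method)
  if (method == "fixed" && is.null(fixed_threshold))
    stop("fixed_threshold is required when method = 'fixed'", call. = FALSE)
  if (method == "otsu" && !is.null(fixed_threshold))
    stop("fixed_threshold is only meaningful with method = 'fixed'",
         call. = FALSE)
  stopifnot(min_object_px >= 0, gaussian_sigma_px >= 0)
  structure(list(method = method, fixed_threshold = fixed_threshold,
                 min_object_px = as.integer(min_object_px),
                 fill_holes = isTRUE(fill_holes),
                 gaussian_sigma_px = gaussian_sigma_px),
            class = "SegmentationParams")
}

#' Connected-component labeling (8-connectivity)
#'
#' Labels the foreground of a binary raster into connected objects,
#' counting diagonal neighbours as connected. Labels are assigned 1..k
#' in order of first occurrence.
#'
#' @param bw Logical or 0/1 matrix.
#' @return Integer matrix of labels (0 background).
#' @export
label_components <- function(bw) {
  bw <- as.matrix(bw) != 0
  L <- from_eb(EBImage::bwlabel(as_eb(bw)))  # 4-connected passes
  k <- as.integer(max(L))
  if (k == 0L) return(matrix(0L, nrow(bw), ncol(bw)))
  # merge 4-connected labels that touch diagonally
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(L); nc <- ncol(L)
  if (nr > 1L && nc > 1L) {
    pairs <- rbind(
      cbind(as.vector(L[-nr, -nc]), as.vector(L[-1, -1])),   # down-right
      cbind(as.vector(L[-nr, -1]),  as.vector(L[-1, -nc])))  # down-left
    pairs <- unique(pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                          pairs[, 1] != pairs[, 2], , drop = FALSE])
    for (i in seq_len(nrow(pairs))) {
      a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(k), find, integer(1))
  out <- matrix(0L, nr, nc)
  out[L > 0] <- root[L[L > 0]]
  relabel_sequential(out)
}

# Renumber nonzero labels to 1..k by order of first occurrence.
relabel_sequential <- function(m) {
  labs <- unique(m[m > 0L])
  if (length(labs) == 0L) return(matrix(0L, nrow(m), ncol(m)))
  out <- matrix(0L, nrow(m), ncol(m))
  out[m > 0L] <- match(m[m > 0L], labs)
  out
}

#' Threshold-based segmentation
#'
#' Gaussian smoothing, thresholding (Otsu or fixed), hole filling,
#' small-object removal and 8-connected labeling, in that order. An
#' all-background result is a valid empty mask, not an error.
#'
#' @param image An `IntensityImage`.
#' @param params A [segmentation_params()] object.
#' @return A [label_mask()].
#' @export
segment_threshold <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "IntensityImage"),
            inherits(params, "SegmentationParams"))
  v <- image$values
  if (params$gaussian_sigma_px > 0 && length(v) > 1L)
    v <- from_eb(EBImage::gblur(as_eb(v), sigma = params$gaussian_sigma_px))
  thr <- if (params$method == "fixed") params$fixed_threshold
         else otsu_threshold(v)
  bw <- v > thr
  if (params$fill_holes)
    bw <- from_eb(EBImage::fillHull(as_eb(bw))) > 0
  lab <- label_components(bw)
  if (params$min_object_px > 0L && max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < params$min_object_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- relabel_sequential(lab)
  }
  label_mask(lab, image$meta)
}

#' @describeIn segment_threshold Segment nuclei from a DAPI channel
#'   (identical procedure; named for pipeline readability).
#' @param dapi_image An `IntensityImage` of the DAPI channel.
#' @export
segment_nuclei <- function(dapi_image, params = segmentation_params())
  segment_threshold(dapi_image, params)

# Otsu threshold on the raw intensity scale.
otsu_threshold <- function(v) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[2])  # constant image -> empty foreground
  vn <- (v - rng[1]) / (rng[2] - rng[1])
  t <- EBImage::otsu(as_eb(vn), range = c(0, 1))
  rng[1] + t * (rng[2] - rng[1])
}

#' Assign nuclei to cells by majority overlap
#'
#' Each nucleus is assigned to the cell label covering the majority of
#' its pixels; a nucleus lying mostly on background stays unassigned.
#' An exact tie between two cells is broken toward the lower cell label,
#' with a warning.
#'
#' @param nucleus_mask,cell_mask `LabelMask` objects of identical shape.
#' @return A data.frame with columns `nucleus` and `cell` (`NA` if
#'   unassigned).
#' @export
match_nuclei_to_cells <- function(nucleus_mask, cell_mask) {
  nl <- nucleus_mask$labels; cl <- cell_mask$labels
  stopifnot(all(dim(nl) == dim(cl)))
  nuclei <- mask_labels(nucleus_mask)
  cell <- rep(NA_integer_, length(nuclei))
  for (i in seq_along(nuclei)) {
    under <- cl[nl == nuclei[i]]
    counts <- table(under)
    labs <- as.integer(names(counts))
    best <- max(counts)
    winners <- labs[counts == best]
    # a tie between background and a cell goes to the cell
    if (length(winners) > 1L && any(winners > 0L))
      winners <- winners[winners > 0L]
    if (length(winners) > 1L)
      warning("nucleus ", nuclei[i], " ties between cells ",
              paste(sort(winners), collapse = ", "),
              "; assigning lower label", call. = FALSE)
    win <- min(winners)
    if (win > 0L) cell[i] <- win
  }
  data.frame(nucleus = nuclei, cell = cell)
}
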
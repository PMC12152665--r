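#' Mean fluorescence intensity over a labeled region
#'
#' Arithmetic mean of the image values over the pixels carrying `label`
#' in the mask. When a z-stack is supplied it is collapsed with
#' [sum_projection()] first.
#'
#' @param image An `IntensityImage` (or list of slices).
#' @param mask A `LabelMask` of identical shape.
#' @param label Positive integer label present in `mask`.
#' @return Numeric scalar MFI.
#' @export
mfi <- function(image, mask, label) {
  image <- sum_projection(image)
  stopifnot(inherits(mask, "LabelMask"),
            all(dim(image$values) == dim(mask$labels)))
  sel <- mask$labels == label
  if (!any(sel)) stop("label ", label, " absent from mask", call. = FALSE)
  mean(image$values[sel])
}

# Shared engine for the per-cell region/total MFI ratio metrics.
region_ratio <- function(image, cell_mask, region_mask, region_kind) {
  image <- sum_projection(image)
  stopifnot(inherits(cell_mask, "LabelMask"),
            inherits(region_mask, "LabelMask"),
            all(dim(image$values) == dim(cell_mask$labels)),
            all(dim(image$values) == dim(region_mask$labels)))
  px_area_um2 <- cell_mask$meta$pixel_size_um^2
  v <- image$values; cl <- cell_mask$labels; rl <- region_mask$labels
  nr <- nrow(cl); nc <- ncol(cl)
  cells <- mask_labels(cell_mask)
  res <- lapply(cells, function(lab) {
    cell_sel <- cl == lab
    reg_sel <- rl == lab
    reg_n <- sum(reg_sel)
    total_mfi <- mean(v[cell_sel])
    region_mfi <- if (reg_n > 0L) mean(v[reg_sel]) else NA_real_
    idx <- which(cell_sel, arr.ind = TRUE)
    on_border <- any(idx[, 1] %in% c(1L, nr)) || any(idx[, 2] %in% c(1L, nc))
    data.frame(cell_id = lab,
               region_kind = region_kind,
               cell_area_px = sum(cell_sel),
               cell_area_um2 = sum(cell_sel) * px_area_um2,
               region_area_px = reg_n,
               region_area_um2 = reg_n * px_area_um2,
               region_mfi = region_mfi,
               total_mfi = total_mfi,
               ratio = if (reg_n > 0L && total_mfi > 0) region_mfi / total_mfi
                       else NA_real_,
               empty_region = reg_n == 0L,
               touches_border = on_border,
               saturated_frac = mean(v[cell_sel] >= 65535))
  })
  do.call(rbind, res)
}

#' Front-to-total intensity ratio per cell
#'
#' MFI of the signal inside the scratch-front band divided by the MFI
#' over the whole cell mask, one record per cell. Cells with an empty
#' front band get an `NA` ratio and are flagged, not dropped.
#'
#' @param image `IntensityImage` (or z-stack list).
#' @param cell_mask Cell `LabelMask`.
#' @param front_band_mask Band mask from [front_band()].
#' @return A data.frame of per-cell ratio records with QC flags.
#' @export
front_ratio <- function(image, cell_mask, front_band_mask)
  region_ratio(image, cell_mask, front_band_mask, "front")

#' Perinuclear-to-total intensity ratio per cell
#'
#' MFI of the signal inside the perinuclear region divided by the MFI
#' over the whole cell mask, one record per cell.
#'
#' @param image `IntensityImage` (or z-stack list).
#' @param cell_mask Cell `LabelMask`.
#' @param perinuclear_mask Region mask from [perinuclear_region()].
#' @return A data.frame of per-cell ratio records with QC flags.
#' @export
perinuclear_ratio <- function(image, cell_mask, perinuclear_mask)
  region_ratio(image, cell_mask, perinuclear_mask, "perinuclear")

#' Membrane-to-total intensity ratio per cell
#'
#' @param image `IntensityImage` (or z-stack list).
#' @param cell_mask Cell `LabelMask`.
#' @param membrane_mask Band mask from [membrane_band()].
#' @return A data.frame of per-cell ratio records with QC flags.
#' @export
membrane_ratio <- function(image, cell_mask, membrane_mask)
  region_ratio(image, cell_mask, membrane_mask, "membrane")

#' Normalize measurements to a control group
#'
#' Divides every test value by the mean of the control values, so the
#' control group maps to mean 1. Used for phalloidin MFI and transwell
#' counts relative to their controls.
#'
#' @param values_test Numeric vector of test-group values.
#' @param values_control Numeric vector of control-group values.
#' @return Numeric vector of normalized test values.
#' @export
normalize_to_control <- function(values_test, values_control) {
  m <- mean(values_control)
  if (!is.finite(m) || m <= 0)
    stop("control mean must be positive; got ", m, call. = FALSE)
  values_test / m
}
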
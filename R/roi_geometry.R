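#' Scratch-front specification
#'
#' The scratch boundary (leading edge) and the depth of the cell-front
#' band. The edge is given in pixel coordinates: either a single x
#' coordinate describing a vertical boundary line, or an n x 2 matrix of
#' `(x, y)` polyline vertices for curved wound fronts. Pixel centers sit
#' at integer coordinates, so the boundary between pixel columns `k` and
#' `k + 1` is at `x = k + 0.5`.
#'
#' @param edge Numeric scalar (vertical line at that x) or n x 2 matrix
#'   of polyline vertices in pixel coordinates.
#' @param depth_um Band depth in micrometers (default 5).
#' @return An object of class `FrontSpec`.
#' @export
front_spec <- function(edge, depth_um = 5) {
  stopifnot(is.numeric(depth_um), length(depth_um) == 1L, depth_um > 0)
  if (is.matrix(edge)) {
    stopifnot(ncol(edge) == 2L, nrow(edge) >= 2L)
  } else {
    stopifnot(is.numeric(edge), length(edge) == 1L, is.finite(edge))
  }
  structure(list(edge = edge, depth_um = depth_um), class = "FrontSpec")
}

# Per-pixel Euclidean distance (px units) from every pixel center to the
# edge (vertical line or polyline). Rows/cols are 1-based pixel centers.
edge_distance_px <- function(nr, nc, edge) {
  if (!is.matrix(edge)) {
    d <- abs(seq_len(nc) - edge)
    return(matrix(d, nr, nc, byrow = TRUE))
  }
  px <- matrix(rep(seq_len(nc), each = nr), nr, nc)   # x = column
  py <- matrix(rep(seq_len(nr), times = nc), nr, nc)  # y = row
  d2 <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(edge) - 1L)) {
    ax <- edge[i, 1]; ay <- edge[i, 2]
    bx <- edge[i + 1L, 1]; by <- edge[i + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx * vx + vy * vy
    t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
    d2 <- pmin(d2, (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
  }
  sqrt(d2)
}

#' Cell-front band along a scratch edge
#'
#' For every cell, the subset of its pixels whose Euclidean distance to
#' the scratch boundary is at most `depth_um` — the region between the
#' leading edge and the edge shifted `depth_um` inward. Cell labels are
#' preserved.
#'
#' @param cell_mask A `LabelMask` of cells.
#' @param spec A [front_spec()].
#' @return A `LabelMask` of the per-cell front bands.
#' @export
front_band <- function(cell_mask, spec) {
  stopifnot(inherits(cell_mask, "LabelMask"), inherits(spec, "FrontSpec"))
  depth_px <- um_to_px(spec$depth_um, cell_mask$meta)
  if (depth_px < 1)
    stop("front-band depth of ", spec$depth_um,
         " um is below one pixel at this pixel size", call. = FALSE)
  cl <- cell_mask$labels
  d <- edge_distance_px(nrow(cl), ncol(cl), spec$edge)
  out <- cl
  out[d > depth_px] <- 0L
  label_mask(out, cell_mask$meta)
}

#' Perinuclear region per cell
#'
#' Each nucleus is enlarged by `enlarge_um` (all pixels within that
#' Euclidean distance of the nucleus) and intersected with its host
#' cell's mask; the result is labeled by cell. Nuclear pixels are
#' included unless `exclude_nucleus = TRUE`. Nuclei without a host cell
#' are skipped with a warning.
#'
#' @param nucleus_mask,cell_mask `LabelMask` objects of identical shape.
#' @param enlarge_um Dilation radius in micrometers (default 5).
#' @param mapping Optional data.frame from [match_nuclei_to_cells()];
#'   computed if missing.
#' @param exclude_nucleus Drop the nuclear pixels themselves (default
#'   `FALSE`).
#' @return A `LabelMask` of perinuclear regions labeled by cell.
#' @export
perinuclear_region <- function(nucleus_mask, cell_mask, enlarge_um = 5,
                               mapping = NULL, exclude_nucleus = FALSE) {
  stopifnot(inherits(nucleus_mask, "LabelMask"),
            inherits(cell_mask, "LabelMask"))
  nl <- nucleus_mask$labels; cl <- cell_mask$labels
  stopifnot(all(dim(nl) == dim(cl)))
  r_px <- um_to_px(enlarge_um, nucleus_mask$meta)
  if (is.null(mapping))
    mapping <- match_nuclei_to_cells(nucleus_mask, cell_mask)
  out <- matrix(0L, nrow(nl), ncol(nl))
  for (i in seq_len(nrow(mapping))) {
    n_lab <- mapping$nucleus[i]; c_lab <- mapping$cell[i]
    if (is.na(c_lab)) {
      warning("nucleus ", n_lab, " has no host cell; skipped", call. = FALSE)
      next
    }
    d <- mask_distance_px(nl == n_lab)
    region <- d <= r_px & cl == c_lab
    if (exclude_nucleus) region <- region & nl != n_lab
    out[region] <- c_lab
  }
  label_mask(out, cell_mask$meta)
}

# Euclidean distance (px) from every pixel center to the nearest pixel
# of `bin` (TRUE set); 0 inside the set.
mask_distance_px <- function(bin) {
  if (!any(bin)) return(matrix(Inf, nrow(bin), ncol(bin)))
  from_eb(EBImage::distmap(as_eb(!bin), metric = "euclidean"))
}

#' Membrane band of a cell
#'
#' The rim of a cell: pixels within `shrink_um` of the cell boundary
#' (the zone between the outline and the outline shrunk inward),
#' optionally restricted to the sector of the cell facing a leading-edge
#' arc. The arc is an angular interval `[from, to]` in degrees around
#' the cell centroid, measured counterclockwise from the +x (rightward)
#' image axis with y pointing up.
#'
#' @param cell_mask A `LabelMask`.
#' @param shrink_um Band width in micrometers; 0 gives an empty band.
#' @param arc_deg Optional length-2 numeric `[from, to]` in degrees;
#'   `NULL` keeps the full perimeter.
#' @return A `LabelMask` of membrane bands labeled by cell.
#' @export
membrane_band <- function(cell_mask, shrink_um, arc_deg = NULL) {
  stopifnot(inherits(cell_mask, "LabelMask"), shrink_um >= 0)
  cl <- cell_mask$labels
  s_px <- um_to_px(shrink_um, cell_mask$meta)
  out <- matrix(0L, nrow(cl), ncol(cl))
  for (lab in mask_labels(cell_mask)) {
    cellpx <- cl == lab
    # distance of each cell pixel to the nearest non-cell pixel
    d <- from_eb(EBImage::distmap(as_eb(cellpx), metric = "euclidean"))
    if (s_px >= max(d) && s_px > 0)
      warning("shrink of ", shrink_um, " um reaches the inradius of cell ",
              lab, "; band covers the whole sector", call. = FALSE)
    band <- cellpx & d <= s_px & d > 0
    if (!is.null(arc_deg)) {
      idx <- which(cellpx, arr.ind = TRUE)
      cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
      ang <- matrix(NA_real_, nrow(cl), ncol(cl))
      bi <- which(band, arr.ind = TRUE)
      if (nrow(bi)) {
        a <- atan2(-(bi[, 1] - cy), bi[, 2] - cx) * 180 / pi  # y up
        keep <- angle_in_arc(a, arc_deg[1], arc_deg[2])
        band[band] <- keep
      }
    }
    out[band] <- lab
  }
  label_mask(out, cell_mask$meta)
}

# Is angle a (deg) inside the CCW arc from `from` to `to`?
angle_in_arc <- function(a, from, to) {
  norm <- function(x) (x %% 360 + 360) %% 360
  a <- norm(a); from <- norm(from); to <- norm(to)
  span <- norm(to - from)
  if (span == 0) span <- 360
  norm(a - from) <= span + 1e-9
}
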
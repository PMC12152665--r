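#' Average speed of one cell track
#'
#' Mean instantaneous step speed (path length over time, not net
#' displacement) over the samples falling inside the tracking window.
#' Tracks are tables of `(t_min, x_um, y_um)` at a nominal 10-min
#' spacing, as exported by common trackers.
#'
#' @param track Data.frame with columns `t_min`, `x_um`, `y_um` (rows in
#'   any order; sorted internally).
#' @param window_h Length-2 numeric: tracking window in hours after
#'   attachment (default `c(3, 9)`).
#' @param max_gap_min Steps longer than this (min) are treated as gaps
#'   and skipped (default `Inf`).
#' @return Mean speed in um/h, or `NA` (with a warning) when fewer than
#'   two samples fall inside the window.
#' @export
track_speed <- function(track, window_h = c(3, 9), max_gap_min = Inf) {
  stopifnot(all(c("t_min", "x_um", "y_um") %in% names(track)))
  tr <- track[order(track$t_min), , drop = FALSE]
  sel <- tr$t_min >= window_h[1] * 60 & tr$t_min <= window_h[2] * 60
  tr <- tr[sel, , drop = FALSE]
  if (nrow(tr) < 2L) {
    warning("fewer than 2 samples in the tracking window; track excluded",
            call. = FALSE)
    return(NA_real_)
  }
  dt <- diff(tr$t_min)
  d <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
  keep <- dt <= max_gap_min
  if (!any(keep)) return(NA_real_)
  mean(d[keep] / dt[keep]) * 60
}

#' Per-cell speeds for a whole track table
#'
#' @param tracks Data.frame with columns `track_id`, `t_min`, `x_um`,
#'   `y_um`.
#' @inheritParams track_speed
#' @return Data.frame with `track_id` and `speed_um_h`.
#' @export
track_speeds <- function(tracks, window_h = c(3, 9), max_gap_min = Inf) {
  ids <- sort(unique(tracks$track_id))
  sp <- vapply(ids, function(id)
    track_speed(tracks[tracks$track_id == id, , drop = FALSE],
                window_h, max_gap_min), numeric(1))
  data.frame(track_id = ids, speed_um_h = sp)
}

#' Median speed of a condition
#'
#' @param speeds Numeric vector of per-cell speeds (um/h); `NA`s from
#'   excluded tracks are dropped.
#' @return Median speed in um/h.
#' @export
condition_median_speed <- function(speeds)
  stats::median(speeds, na.rm = TRUE)

#' Normalize transwell counts to a control
#'
#' Per-field migrated-cell counts of a perturbation condition divided by
#' the mean count of the control fields (the control is set to 1). The
#' standard design images 7 fields per transwell with 2 technical
#' repeats.
#'
#' @param counts_test Integer vector of per-field counts.
#' @param counts_control Integer vector of control per-field counts.
#' @return Numeric vector of normalized migration values.
#' @export
transwell_normalize <- function(counts_test, counts_control) {
  stopifnot(all(counts_test >= 0), all(counts_control >= 0))
  m <- mean(counts_control)
  if (m <= 0) stop("control mean count must be positive", call. = FALSE)
  counts_test / m
}
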
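#' Photoconversion pulse-chase series for one cell
#'
#' Per-frame membrane and whole-cell MFIs of the photoconverted (red)
#' channel, with the acquisition timestamps and the index of the last
#' pre-conversion frame. The standard acquisition is 30 timepoints at
#' 25 s with conversion after frame 5.
#'
#' @param timestamps_s Strictly increasing numeric vector (s).
#' @param membrane_mfi,cell_mfi Numeric vectors, one value per frame.
#' @param conversion_index Index of the last frame before conversion
#'   (default 5); must satisfy `1 <= conversion_index < n`.
#' @return An object of class `PhotoSeries`.
#' @export
photo_series <- function(timestamps_s, membrane_mfi, cell_mfi,
                         conversion_index = 5L) {
  n <- length(timestamps_s)
  stopifnot(n >= 2L, length(membrane_mfi) == n, length(cell_mfi) == n,
            all(diff(timestamps_s) > 0))
  conversion_index <- as.integer(conversion_index)
  if (conversion_index < 1L || conversion_index >= n)
    stop("conversion_index must be in [1, n_frames)", call. = FALSE)
  structure(list(timestamps_s = as.numeric(timestamps_s),
                 membrane_mfi = as.numeric(membrane_mfi),
                 cell_mfi = as.numeric(cell_mfi),
                 conversion_index = conversion_index),
            class = "PhotoSeries")
}

#' Pre-conversion baseline of a photoconversion series
#'
#' Mean MFI over the pre-conversion frames (frames 1..conversion_index)
#' of the chosen region; used as the background signal for correction.
#'
#' @param series A [photo_series()].
#' @param which `"membrane"` or `"cell"`.
#' @return Numeric scalar baseline.
#' @export
baseline <- function(series, which = c("membrane", "cell")) {
  which <- match.arg(which)
  stopifnot(inherits(series, "PhotoSeries"))
  pre <- seq_len(series$conversion_index)
  ch <- if (which == "membrane") series$membrane_mfi else series$cell_mfi
  mean(ch[pre])
}

#' Background-corrected membrane/cell ratio series
#'
#' For every post-conversion frame: (membrane MFI - membrane baseline) /
#' (cell MFI - cell baseline), with time measured from the conversion
#' frame (t = 0 at conversion; the first post frame sits at one frame
#' interval). Frames whose corrected cell MFI is not positive are
#' flagged `excluded` with a warning.
#'
#' @param series A [photo_series()].
#' @return A data.frame of class `RatioSeries` with columns `t_s`,
#'   `ratio`, `excluded`.
#' @export
corrected_ratio <- function(series) {
  stopifnot(inherits(series, "PhotoSeries"))
  ci <- series$conversion_index
  post <- (ci + 1L):length(series$timestamps_s)
  bl_m <- baseline(series, "membrane")
  bl_c <- baseline(series, "cell")
  t_s <- series$timestamps_s[post] - series$timestamps_s[ci]
  mem <- series$membrane_mfi[post] - bl_m
  cell <- series$cell_mfi[post] - bl_c
  excluded <- cell <= 0
  if (any(excluded))
    warning(sum(excluded),
            " frame(s) with non-positive corrected cell MFI excluded",
            call. = FALSE)
  ratio <- ifelse(excluded, NA_real_, mem / cell)
  structure(data.frame(t_s = t_s, ratio = ratio, excluded = excluded),
            class = c("RatioSeries", "data.frame"))
}

#' Fit a saturating exponential to a ratio series
#'
#' Nonlinear least squares for `y = a * (1 - exp(-b * t))` with bounds
#' `a > 0`, `b > 0` (Levenberg-Marquardt, single start: `a0 = max(y)`,
#' `b0 = 3 / t_last`). The half-time is `t1/2 = ln(2) / b`. Fits that
#' fail to converge or land on the rate guard are marked not converged
#' and are excluded from condition medians.
#'
#' @param ratio_series A `RatioSeries` from [corrected_ratio()], or any
#'   data.frame with `t_s` and `ratio` columns.
#' @param b_max Upper guard for the rate (default 1e3 1/s, far beyond
#'   any physical trafficking rate).
#' @param offset Optional additive-offset variant
#'   `y = c + a * (1 - exp(-b t))` for sensitivity analyses (default
#'   `FALSE`; the standard model is forced through 0 at t = 0).
#' @return An object of class `KineticFit` with fields `a`, `b`,
#'   `t_half_s`, `rss`, `converged`, `n_points`.
#' @export
fit_saturating_exponential <- function(ratio_series, b_max = 1e3,
                                       offset = FALSE) {
  use <- is.finite(ratio_series$ratio) & is.finite(ratio_series$t_s)
  t <- ratio_series$t_s[use]
  y <- ratio_series$ratio[use]
  if (length(y) < 5L)
    stop("need at least 5 usable post-conversion frames; got ",
         length(y), call. = FALSE)
  a0 <- max(y)
  if (!is.finite(a0) || a0 <= 0) a0 <- 1e-3
  b0 <- 3 / max(t)
  fit <- NULL
  failed <- FALSE
  dat <- data.frame(t = t, y = y)
  fit <- tryCatch({
    if (offset)
      minpack.lm::nlsLM(y ~ c0 + a * (1 - exp(-b * t)), data = dat,
                        start = list(c0 = 0, a = a0, b = b0),
                        lower = c(-Inf, 1e-12, 1e-12),
                        upper = c(Inf, Inf, b_max),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ a * (1 - exp(-b * t)), data = dat,
                        start = list(a = a0, b = b0),
                        lower = c(1e-12, 1e-12), upper = c(Inf, b_max),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) { failed <<- TRUE; NULL })
  if (is.null(fit)) {
    out <- list(a = NA_real_, b = NA_real_, t_half_s = NA_real_,
                rss = NA_real_, converged = FALSE, n_points = length(y))
    class(out) <- "KineticFit"
    return(out)
  }
  cf <- stats::coef(fit)
  b_hat <- unname(cf["b"]); a_hat <- unname(cf["a"])
  at_guard <- b_hat >= b_max * (1 - 1e-6) || b_hat <= 2e-12 || a_hat <= 2e-12
  out <- list(a = a_hat, b = b_hat,
              t_half_s = log(2) / b_hat,
              rss = sum(stats::resid(fit)^2),
              converged = fit$convInfo$isConv && !at_guard,
              n_points = length(y))
  if (offset) out$offset <- unname(cf["c0"])
  class(out) <- "KineticFit"
  out
}

#' @export
print.KineticFit <- function(x, ...) {
  cat(sprintf(
    "KineticFit: a = %.4g, b = %.4g /s, t1/2 = %.4g s (%s, %d points)\n",
    x$a, x$b, x$t_half_s, if (x$converged) "converged" else "FAILED",
    x$n_points))
  invisible(x)
}

#' Fit every cell of a condition and summarize half-times
#'
#' @param fits A list of `KineticFit` objects for one condition.
#' @return A list with `median_t_half_s` (over converged fits),
#'   `n_converged`, `n_failed`, and the per-cell data.frame `cells`.
#' @export
condition_median_halftime <- function(fits) {
  stopifnot(length(fits) >= 1L)
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(cell = i, a = f$a, b = f$b, t_half_s = f$t_half_s,
               rss = f$rss, converged = f$converged)
  }))
  ok <- tab$converged
  if (!all(ok))
    message(sum(!ok), " non-converged fit(s) excluded from the median")
  list(median_t_half_s = if (any(ok)) stats::median(tab$t_half_s[ok])
                         else NA_real_,
       n_converged = sum(ok), n_failed = sum(!ok), cells = tab)
}
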
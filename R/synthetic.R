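# Ground-truthed synthetic scenes for every assay the pipeline
# quantifies. Every generator is a pure function of (parameters, seed):
# the caller's RNG state is untouched and the same seed reproduces the
# identical output. Truth records store the exact generative quantities
# so noiseless scenes can be re-measured to numerical precision.

# Resolve a distribution argument: scalar/vector (recycled to n) or
# function(n) returning n draws.
draw_param <- function(dist, n, name, positive = TRUE) {
  x <- if (is.function(dist)) dist(n) else rep_len(as.numeric(dist), n)
  if (length(x) != n) stop(name, " distribution must yield ", n, " values",
                           call. = FALSE)
  if (positive && any(x <= 0))
    stop(name, " must be strictly positive", call. = FALSE)
  x
}

#' Synthetic scratch-assay scene
#'
#' Rectangular cells packed along a straight vertical scratch edge. The
#' signal equals `base * (1 + enrichment_front)` inside the true front
#' band (pixels within `depth_um` of the edge) and `base` elsewhere in
#' the cell, plus optional per-pixel Gaussian noise. The truth table
#' stores each cell's exact front/total MFI ratio computed by direct
#' pixel summation over the noiseless field.
#'
#' @param n_cells Number of cells (>= 1).
#' @param enrichment_front Front enrichment factor(s) >= 0 (scalar or
#'   per-cell vector).
#' @param pixel_size_um Pixel size (default 0.2 um/px).
#' @param noise_sd Per-pixel Gaussian noise SD (intensity units).
#' @param seed Integer seed or `NULL`.
#' @param cell_h_px,cell_w_px Cell height/width in pixels (default
#'   40 x 100, i.e. a 20-um-deep cell at 0.2 um/px).
#' @param gap_px Background gap between cells (default 2).
#' @param depth_um True front-band depth (default 5).
#' @param base_intensity Intensity inside the cell away from the front
#'   (default 100).
#' @return List with `image` (`IntensityImage`), `cell_mask`
#'   (`LabelMask`), `front` ([front_spec()]), and `truth` (data.frame
#'   with `cell_id`, `front_ratio_true`, areas).
#' @export
gen_scratch_scene <- function(n_cells, enrichment_front = 1,
                              pixel_size_um = 0.2, noise_sd = 0,
                              seed = NULL, cell_h_px = 40, cell_w_px = 100,
                              gap_px = 2, depth_um = 5,
                              base_intensity = 100) {
  stopifnot(n_cells >= 1, all(enrichment_front >= 0),
            cell_h_px >= 1, cell_w_px >= 1, noise_sd >= 0)
  enr <- rep_len(enrichment_front, n_cells)
  with_seed(seed, {
    margin <- 10L
    nr <- n_cells * (cell_h_px + gap_px) + gap_px
    nc <- margin + cell_w_px + margin
    edge_x <- margin + 0.5  # boundary between scratch and first cell column
    meta <- image_meta(pixel_size_um)
    labels <- matrix(0L, nr, nc)
    field <- matrix(0, nr, nc)
    depth_px <- depth_um / pixel_size_um
    truth <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      r0 <- gap_px + (i - 1L) * (cell_h_px + gap_px) + 1L
      rows <- r0:(r0 + cell_h_px - 1L)
      cols <- (margin + 1L):(margin + cell_w_px)
      labels[rows, cols] <- i
      cellv <- matrix(base_intensity, cell_h_px, cell_w_px)
      in_front <- abs(cols - edge_x) <= depth_px
      cellv[, in_front] <- base_intensity * (1 + enr[i])
      field[rows, cols] <- cellv
      truth[[i]] <- data.frame(
        cell_id = i,
        enrichment_front = enr[i],
        front_area_px = sum(in_front) * cell_h_px,
        cell_area_px = cell_h_px * cell_w_px,
        front_ratio_true = mean(cellv[, in_front]) / mean(cellv))
    }
    noisy <- if (noise_sd > 0)
      pmax(field + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc), 0)
    else field
    list(image = intensity_image(noisy, meta),
         cell_mask = label_mask(labels, meta),
         front = front_spec(edge_x, depth_um),
         truth = do.call(rbind, truth))
  })
}

#' Synthetic perinuclear-enrichment scene
#'
#' Square cells with centered square nuclei; the signal is elevated by
#' `(1 + enrichment_peri)` inside the true perinuclear region (nucleus
#' dilated by `enlarge_um`, intersected with the cell). The true region
#' is computed by a brute-force per-pixel Euclidean-distance scan, so it
#' doubles as an independent oracle for the distance-transform based
#' pipeline.
#'
#' @param n_cells Number of cells.
#' @param enrichment_peri Perinuclear enrichment factor(s) >= 0.
#' @param pixel_size_um Pixel size (default 0.2 um/px).
#' @param noise_sd Per-pixel Gaussian noise SD.
#' @param seed Integer seed or `NULL`.
#' @param cell_px Cell side length in pixels (default 60).
#' @param nucleus_px Nucleus side length in pixels (default 16).
#' @param gap_px Gap between cells (default 6).
#' @param enlarge_um Dilation radius defining the region (default 5).
#' @param base_intensity Baseline cell intensity (default 100).
#' @return List with `image`, `cell_mask`, `nucleus_mask`, and `truth`
#'   (`cell_id`, `perinuclear_ratio_true`, region area).
#' @export
gen_perinuclear_scene <- function(n_cells, enrichment_peri = 1,
                                  pixel_size_um = 0.2, noise_sd = 0,
                                  seed = NULL, cell_px = 60,
                                  nucleus_px = 16, gap_px = 6,
                                  enlarge_um = 5, base_intensity = 100) {
  stopifnot(n_cells >= 1, all(enrichment_peri >= 0),
            nucleus_px <= cell_px, noise_sd >= 0)
  enr <- rep_len(enrichment_peri, n_cells)
  with_seed(seed, {
    nr <- cell_px + 2L * gap_px
    nc <- n_cells * (cell_px + gap_px) + gap_px
    meta <- image_meta(pixel_size_um)
    labels <- matrix(0L, nr, nc)
    nuclei <- matrix(0L, nr, nc)
    field <- matrix(0, nr, nc)
    r_px <- enlarge_um / pixel_size_um
    truth <- vector("list", n_cells)
    rows <- (gap_px + 1L):(gap_px + cell_px)
    off <- (cell_px - nucleus_px) %/% 2L
    for (i in seq_len(n_cells)) {
      c0 <- gap_px + (i - 1L) * (cell_px + gap_px) + 1L
      cols <- c0:(c0 + cell_px - 1L)
      labels[rows, cols] <- i
      n_rows <- rows[(off + 1L):(off + nucleus_px)]
      n_cols <- cols[(off + 1L):(off + nucleus_px)]
      nuclei[n_rows, n_cols] <- i
      # brute-force distance from every cell pixel to the nucleus block
      pr <- matrix(rep(seq_len(cell_px), times = cell_px), cell_px)
      pc <- matrix(rep(seq_len(cell_px), each = cell_px), cell_px)
      nrng <- (off + 1L):(off + nucleus_px)
      dr <- pmax(pmax(nrng[1] - pr, pr - nrng[nucleus_px]), 0)
      dc <- pmax(pmax(nrng[1] - pc, pc - nrng[nucleus_px]), 0)
      in_region <- sqrt(dr^2 + dc^2) <= r_px  # rectangle => closed form
      cellv <- matrix(base_intensity, cell_px, cell_px)
      cellv[in_region] <- base_intensity * (1 + enr[i])
      field[rows, cols] <- cellv
      truth[[i]] <- data.frame(
        cell_id = i, enrichment_peri = enr[i],
        region_area_px = sum(in_region),
        cell_area_px = cell_px^2,
        perinuclear_ratio_true = mean(cellv[in_region]) / mean(cellv))
    }
    noisy <- if (noise_sd > 0)
      pmax(field + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc), 0)
    else field
    list(image = intensity_image(noisy, meta),
         cell_mask = label_mask(labels, meta),
         nucleus_mask = label_mask(nuclei, meta),
         truth = do.call(rbind, truth))
  })
}

#' Synthetic focal-adhesion scene
#'
#' Non-overlapping elliptical objects of exact integer pixel areas on a
#' flat background. Each object is a "digital ellipse": the `N` pixels
#' closest to a random center under a random anisotropic metric, so the
#' stored pixel area is exact by construction. Contrast is set by
#' `snr = amplitude / noise_sd`.
#'
#' @param n_objects Number of adhesions (0 gives a blank image).
#' @param areas Integer pixel areas: scalar, per-object vector, or
#'   function(n).
#' @param pixel_size_um Pixel size (default 0.1 um/px).
#' @param snr Signal-to-noise ratio (amplitude over noise SD); `Inf`
#'   disables noise.
#' @param seed Integer seed or `NULL`.
#' @param background,amplitude Background level and object amplitude
#'   (defaults 0.2 and 1).
#' @return List with `image` (`IntensityImage`) and `truth` (data.frame
#'   `object_id`, `area_px`, `area_um2`).
#' @export
gen_fa_scene <- function(n_objects, areas = 19L, pixel_size_um = 0.1,
                         snr = Inf, seed = NULL, background = 0.2,
                         amplitude = 1) {
  stopifnot(n_objects >= 0, snr > 0, amplitude > 0, background >= 0)
  with_seed(seed, {
    meta <- image_meta(pixel_size_um)
    if (n_objects == 0)
      return(list(image = intensity_image(matrix(background, 32, 32), meta),
                  truth = data.frame(object_id = integer(),
                                     area_px = integer(),
                                     area_um2 = numeric())))
    area_px <- draw_param(areas, n_objects, "areas")
    if (any(area_px != round(area_px)) || any(area_px < 1))
      stop("areas must be positive integers", call. = FALSE)
    area_px <- as.integer(round(area_px))
    tile <- 2L * ceiling(sqrt(max(area_px) * 3 / pi)) + 9L
    g <- ceiling(sqrt(n_objects))
    nr <- g * tile; nc <- g * tile
    field <- matrix(background, nr, nc)
    truth <- data.frame(object_id = seq_len(n_objects), area_px = area_px,
                        area_um2 = area_px * pixel_size_um^2)
    for (i in seq_len(n_objects)) {
      gi <- (i - 1L) %/% g; gj <- (i - 1L) %% g
      cy <- gi * tile + tile / 2 + stats::runif(1, -1, 1)
      cx <- gj * tile + tile / 2 + stats::runif(1, -1, 1)
      theta <- stats::runif(1, 0, pi)
      q <- stats::runif(1, 1, 2.5)  # aspect ratio
      rows <- (gi * tile + 1L):((gi + 1L) * tile)
      cols <- (gj * tile + 1L):((gj + 1L) * tile)
      dy <- matrix(rep(rows - cy, times = length(cols)), length(rows))
      dx <- matrix(rep(cols - cx, each = length(rows)), length(rows))
      u <- dx * cos(theta) + dy * sin(theta)
      w <- -dx * sin(theta) + dy * cos(theta)
      m <- (u / q)^2 + w^2  # elliptical metric
      ord <- order(m, row(m), col(m))[seq_len(area_px[i])]
      block <- field[rows, cols]
      block[ord] <- background + amplitude
      field[rows, cols] <- block
    }
    if (is.finite(snr))
      field <- pmax(field + matrix(stats::rnorm(nr * nc, 0, amplitude / snr),
                                   nr, nc), 0)
    list(image = intensity_image(field, meta), truth = truth)
  })
}

#' Synthetic photoconversion series
#'
#' Per-cell two-channel MFI series on the standard acquisition grid
#' (`n_total` frames at `dt_s`, conversion after frame `n_pre`). After
#' conversion a constant converted pool `C` appears in the cell channel
#' and the membrane channel rises as
#' `baseline + a * C * (1 - exp(-b * t))` with `t = 0` at the
#' conversion frame, so the background-corrected membrane/cell ratio
#' follows `a * (1 - exp(-b t))` exactly. Pre-conversion frames carry
#' only the baselines. Gaussian noise (SD `noise_sd`, MFI units) is
#' added to both channels.
#'
#' @param n_cells Number of cells.
#' @param a_dist,b_dist Plateau and rate (1/s) distributions: scalar,
#'   per-cell vector, or function(n). Rates must be positive.
#' @param baseline_membrane,baseline_cell Pre-conversion backgrounds
#'   (default 100 each).
#' @param converted_pool Constant converted-pool signal `C` (default
#'   1000).
#' @param n_pre Last pre-conversion frame (default 5).
#' @param n_total Total frames (default 30).
#' @param dt_s Frame interval in seconds (default 25).
#' @param noise_sd Additive Gaussian noise SD on the MFIs (default 0).
#' @param seed Integer seed or `NULL`.
#' @return List with `series` (list of [photo_series()]) and `truth`
#'   (data.frame `cell_id`, `a`, `b`, `t_half_s`).
#' @export
gen_photoseries <- function(n_cells, a_dist = 0.5, b_dist = 0.01,
                            baseline_membrane = 100, baseline_cell = 100,
                            converted_pool = 1000, n_pre = 5L,
                            n_total = 30L, dt_s = 25, noise_sd = 0,
                            seed = NULL) {
  stopifnot(n_cells >= 1, n_pre >= 1, n_pre < n_total, dt_s > 0,
            noise_sd >= 0, converted_pool > 0)
  with_seed(seed, {
    a <- draw_param(a_dist, n_cells, "a")
    b <- draw_param(b_dist, n_cells, "b")
    ts <- (seq_len(n_total) - 1) * dt_s
    t_rel <- pmax(ts - ts[n_pre], 0)
    post <- seq_len(n_total) > n_pre
    series <- lapply(seq_len(n_cells), function(i) {
      mem <- rep(baseline_membrane, n_total)
      cell <- rep(baseline_cell, n_total)
      mem[post] <- baseline_membrane +
        a[i] * converted_pool * (1 - exp(-b[i] * t_rel[post]))
      cell[post] <- baseline_cell + converted_pool
      if (noise_sd > 0) {
        mem <- mem + stats::rnorm(n_total, 0, noise_sd)
        cell <- cell + stats::rnorm(n_total, 0, noise_sd)
      }
      photo_series(ts, mem, cell, conversion_index = n_pre)
    })
    list(series = series,
         truth = data.frame(cell_id = seq_len(n_cells), a = a, b = b,
                            t_half_s = log(2) / b))
  })
}

#' Synthetic random-walk cell tracks
#'
#' Isotropic random walks sampled every `dt_min` minutes: step lengths
#' come from `step_um_dist`, directions are uniform. The true mean
#' speed of each cell is `mean(steps) / dt` in um/h, recorded exactly.
#'
#' @param n_cells Number of tracks.
#' @param step_um_dist Step length (um) per `dt_min`: scalar, vector, or
#'   function(n_steps) (redrawn per cell).
#' @param dt_min Sampling interval in minutes (default 10).
#' @param duration_h Track duration in hours (default 9).
#' @param seed Integer seed or `NULL`.
#' @return List with `tracks` (data.frame `track_id`, `frame`, `t_min`,
#'   `x_um`, `y_um`) and `truth` (data.frame `track_id`,
#'   `speed_um_h_true`).
#' @export
gen_tracks <- function(n_cells, step_um_dist = 6, dt_min = 10,
                       duration_h = 9, seed = NULL) {
  stopifnot(n_cells >= 1, dt_min > 0, duration_h > 0)
  with_seed(seed, {
    t_min <- seq(0, duration_h * 60, by = dt_min)
    n_steps <- length(t_min) - 1L
    tracks <- vector("list", n_cells)
    speed <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      steps <- draw_param(step_um_dist, n_steps, "step_um", positive = FALSE)
      if (any(steps < 0)) stop("step lengths must be >= 0", call. = FALSE)
      theta <- stats::runif(n_steps, 0, 2 * pi)
      x <- cumsum(c(0, steps * cos(theta)))
      y <- cumsum(c(0, steps * sin(theta)))
      tracks[[i]] <- data.frame(track_id = i, frame = seq_along(t_min),
                                t_min = t_min, x_um = x, y_um = y)
      speed[i] <- mean(steps) / dt_min * 60
    }
    list(tracks = do.call(rbind, tracks),
         truth = data.frame(track_id = seq_len(n_cells),
                            speed_um_h_true = speed))
  })
}

#' Synthetic FPKM expression table with correlated marker structure
#'
#' A latent per-sample EMT score drives four correlated marker genes
#' (log-normal FPKM); the target gene's log2 expression is shifted by
#' `effect_size` in samples with a high latent score (score above the
#' population median). The truth table stores each sample's latent
#' score and group.
#'
#' @param n_samples Number of samples (>= 8).
#' @param markers Marker gene names (default SLUG, ZEB1, ZEB2, TWIST2).
#' @param target Target gene name (default ARHGEF40).
#' @param effect_size Log2 shift of the target in latent-high samples.
#' @param marker_noise_sd Per-marker noise on the log2 scale (0 gives
#'   perfectly correlated markers; default 0.5).
#' @param target_noise_sd Target-gene log2 noise (default 0.8).
#' @param seed Integer seed or `NULL`.
#' @return List with `fpkm` (genes x samples matrix) and `truth`
#'   (data.frame `sample`, `latent_score`, `latent_high`).
#' @export
gen_expression <- function(n_samples, markers = c("SLUG", "ZEB1", "ZEB2",
                                                  "TWIST2"),
                           target = "ARHGEF40", effect_size = 1,
                           marker_noise_sd = 0.5, target_noise_sd = 0.8,
                           seed = NULL) {
  stopifnot(n_samples >= 8, length(markers) >= 1, marker_noise_sd >= 0,
            target_noise_sd >= 0)
  with_seed(seed, {
    z <- stats::rnorm(n_samples)
    high <- z > stats::median(z)
    logex <- rbind(
      do.call(rbind, lapply(seq_along(markers), function(m)
        3 + 1.5 * z + stats::rnorm(n_samples, 0, marker_noise_sd))),
      2 + effect_size * high + stats::rnorm(n_samples, 0, target_noise_sd))
    fpkm <- 2^logex
    rownames(fpkm) <- c(markers, target)
    colnames(fpkm) <- sprintf("S%03d", seq_len(n_samples))
    list(fpkm = fpkm,
         truth = data.frame(sample = colnames(fpkm), latent_score = z,
                            latent_high = high))
  })
}
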
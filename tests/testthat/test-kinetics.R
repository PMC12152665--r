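ts30 <- (0:29) * 25  # standard grid: 30 frames, 25 s

test_that("baseline is the mean of the pre-conversion frames", {
  s <- photo_series(ts30, c(10, 10, 10, 12, 8, rep(50, 25)),
                    c(rep(0, 5), rep(100, 25)), conversion_index = 5)
  expect_equal(baseline(s, "membrane"), 10)
  expect_equal(baseline(s, "cell"), 0)
  expect_error(photo_series(ts30, rep(1, 30), rep(1, 30),
                            conversion_index = 0), "conversion_index")
  expect_error(photo_series(ts30, rep(1, 30), rep(1, 30),
                            conversion_index = 30), "conversion_index")
})

test_that("corrected ratio subtracts baselines frame by frame", {
  mem <- c(rep(10, 5), rep(30, 25))
  cell <- c(rep(20, 5), rep(60, 25))
  rs <- corrected_ratio(photo_series(ts30, mem, cell))
  expect_equal(nrow(rs), 25L)
  expect_equal(rs$ratio, rep((30 - 10) / (60 - 20), 25))  # 0.5
  expect_equal(rs$t_s, (1:25) * 25)  # t = 0 at conversion, first point at dt
  # membrane at baseline -> ratio 0
  mem0 <- c(rep(10, 5), 10, rep(30, 24))
  rs0 <- corrected_ratio(photo_series(ts30, mem0, cell))
  expect_equal(rs0$ratio[1], 0)
  # non-positive corrected cell MFI flags the frame
  cellbad <- cell; cellbad[8] <- 15
  expect_warning(rsb <- corrected_ratio(photo_series(ts30, mem, cellbad)),
                 "excluded")
  expect_true(rsb$excluded[3])
})

test_that("noiseless generator series follow the closed-form ratio and
           fits recover (a, b) to 1e-6 relative", {
  for (par in list(c(0.5, 0.01), c(0.3, 0.004), c(0.9, 0.05))) {
    g <- gen_photoseries(1, a_dist = par[1], b_dist = par[2], noise_sd = 0)
    rs <- corrected_ratio(g$series[[1]])
    expect_equal(rs$ratio, par[1] * (1 - exp(-par[2] * rs$t_s)),
                 tolerance = 1e-12)
    fit <- fit_saturating_exponential(rs)
    expect_true(fit$converged)
    expect_lt(abs(fit$a - par[1]) / par[1], 1e-6)
    expect_lt(abs(fit$b - par[2]) / par[2], 1e-6)
    expect_identical(fit$t_half_s, log(2) / fit$b)  # exact identity
  }
  # the standard-grid example: a=0.5, b=0.01 -> t1/2 = 69.31 s
  g <- gen_photoseries(1, 0.5, 0.01, noise_sd = 0)
  fit <- fit_saturating_exponential(corrected_ratio(g$series[[1]]))
  expect_equal(fit$t_half_s, log(2) / 0.01, tolerance = 1e-6)
})

test_that("pre-conversion frames carry exactly the configured baselines", {
  g <- gen_photoseries(2, baseline_membrane = 37, baseline_cell = 91,
                       noise_sd = 0)
  s <- g$series[[1]]
  expect_equal(s$membrane_mfi[1:5], rep(37, 5))
  expect_equal(s$cell_mfi[1:5], rep(91, 5))
  expect_equal(baseline(s, "membrane"), 37)
  expect_equal(baseline(s, "cell"), 91)
})

test_that("degenerate fits are flagged, not reported as estimates", {
  # constant positive ratio: the b -> infinity regime
  rs <- data.frame(t_s = (1:25) * 25, ratio = rep(0.4, 25))
  fit <- fit_saturating_exponential(rs)
  expect_false(fit$converged)
  # too few usable frames
  expect_error(fit_saturating_exponential(
    data.frame(t_s = (1:4) * 25, ratio = runif(4))), "at least 5")
})

test_that("fits are invariant to time units and common gain", {
  g <- gen_photoseries(1, 0.6, 0.012, noise_sd = 0)
  rs <- corrected_ratio(g$series[[1]])
  fit_s <- fit_saturating_exponential(rs)
  rs_min <- data.frame(t_s = rs$t_s / 60, ratio = rs$ratio)
  fit_min <- fit_saturating_exponential(rs_min)
  expect_equal(fit_min$b, fit_s$b * 60, tolerance = 1e-6)
  expect_equal(fit_min$t_half_s * 60, fit_s$t_half_s, tolerance = 1e-6)
  # multiplying both corrected MFIs by a gain leaves the ratio, hence
  # the fit, unchanged
  s <- g$series[[1]]
  gained <- photo_series(s$timestamps_s,
                         5 * (s$membrane_mfi - 100) + 100,
                         5 * (s$cell_mfi - 100) + 100)
  fit_g <- fit_saturating_exponential(corrected_ratio(gained))
  expect_equal(fit_g$b, fit_s$b, tolerance = 1e-9)
})

test_that("median rate is recovered within 3% from 200 noisy cells", {
  g <- gen_photoseries(200, a_dist = 0.5, b_dist = 0.01,
                       noise_sd = 0.05 * 0.5 * 1000, seed = 101)
  fits <- lapply(g$series,
                 function(s) fit_saturating_exponential(corrected_ratio(s)))
  summ <- condition_median_halftime(fits)
  b_hat <- stats::median(summ$cells$b[summ$cells$converged])
  expect_lt(abs(b_hat - 0.01) / 0.01, 0.03)
})

test_that("condition medians use converged fits only", {
  mk <- function(t_half, conv) structure(
    list(a = 0.5, b = log(2) / t_half, t_half_s = t_half, rss = 0,
         converged = conv, n_points = 25), class = "KineticFit")
  fits <- list(mk(50, TRUE), mk(55, TRUE), mk(60, TRUE), mk(1000, FALSE))
  expect_message(summ <- condition_median_halftime(fits), "non-converged")
  expect_equal(summ$median_t_half_s, 55)
  expect_equal(summ$n_failed, 1L)
  single <- condition_median_halftime(list(mk(42, TRUE)))
  expect_equal(single$median_t_half_s, 42)
})

test_that("sampled half-time medians follow the analytic transform of the
           rate median", {
  # t1/2 = ln2/b is monotone decreasing, so for an odd sample the
  # median half-time is exactly ln2 / median(b)
  g <- gen_photoseries(31, b_dist = function(n)
    stats::rlnorm(n, log(0.012602), 0.25), seed = 77)
  expect_equal(stats::median(g$truth$t_half_s),
               log(2) / stats::median(g$truth$b))
})
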
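test_that("front band of a rectangular cell has the expected pixel area", {
  # 100 px tall x 50 px wide cell abutting a vertical edge; 0.2 um/px,
  # 5 um depth = 25 px -> band is 25 columns x 100 rows
  cells <- matrix(0L, 110, 70)
  cells[6:105, 11:60] <- 1L
  mask <- label_mask(cells, image_meta(0.2))
  band <- front_band(mask, front_spec(10.5, depth_um = 5))
  expect_equal(sum(band$labels == 1L), 2500L)
  # band is 25 columns wide starting at the edge
  expect_equal(sort(unique(which(band$labels == 1L, arr.ind = TRUE)[, 2])),
               11:35)
})

test_that("front band saturates and empties at the extremes", {
  cells <- matrix(0L, 20, 40); cells[5:15, 30:39] <- 1L
  mask <- label_mask(cells, image_meta(1))
  # cell entirely farther than the depth from the edge -> empty band
  empty <- front_band(mask, front_spec(2.5, depth_um = 5))
  expect_length(mask_labels(empty), 0L)
  # depth covering the whole cell -> band == cell
  full <- front_band(mask, front_spec(29.5, depth_um = 15))
  expect_identical(full$labels, cells)
  # sub-pixel depth is degenerate
  expect_error(front_band(mask, front_spec(2.5, depth_um = 0.4)),
               "below one pixel")
})

test_that("front band equals the per-pixel distance oracle, any edge shape", {
  set.seed(21)
  meta <- image_meta(0.5)
  for (edge in list(7.5,
                    cbind(c(8, 12, 6), c(1, 16, 32)),
                    cbind(c(5, 5), c(1, 32)))) {
    cells <- matrix(0L, 32, 32)
    cells[4:29, 10:30] <- 1L
    cells[15:20, 10:18] <- 2L
    mask <- label_mask(cells, meta)
    band <- front_band(mask, front_spec(edge, depth_um = 4))
    d <- brute_edge_dist(32, 32, edge)
    expected <- cells
    expected[d > 4 / 0.5] <- 0L
    expect_identical(band$labels, expected)
  }
})

test_that("perinuclear region equals the brute-force distance oracle", {
  # 10x10 nucleus, 1 um/px, 5 um dilation, ample cell
  cells <- matrix(1L, 40, 40)
  nuc <- matrix(0L, 40, 40); nuc[16:25, 16:25] <- 1L
  cmask <- label_mask(cells, meta1()); nmask <- label_mask(nuc, meta1())
  reg <- perinuclear_region(nmask, cmask, enlarge_um = 5)
  oracle <- brute_dist_to_set(nuc == 1L) <= 5
  expect_identical(reg$labels == 1L, oracle)
  # the nucleus itself is included by default, excluded on request
  expect_true(all(reg$labels[nuc == 1L] == 1L))
  reg2 <- perinuclear_region(nmask, cmask, enlarge_um = 5,
                             exclude_nucleus = TRUE)
  expect_true(all(reg2$labels[nuc == 1L] == 0L))
})

test_that("perinuclear region is clipped to the host cell", {
  cells <- matrix(0L, 30, 30); cells[1:30, 1:15] <- 1L
  nuc <- matrix(0L, 30, 30); nuc[12:18, 11:14] <- 1L  # near cell border
  reg <- perinuclear_region(label_mask(nuc, meta1()),
                            label_mask(cells, meta1()), enlarge_um = 5)
  expect_true(all(reg$labels[cells == 0L] == 0L))
  expect_gt(sum(reg$labels == 1L), 0L)
  # empty nucleus mask -> empty region
  reg0 <- perinuclear_region(label_mask(matrix(0L, 30, 30), meta1()),
                             label_mask(cells, meta1()))
  expect_length(mask_labels(reg0), 0L)
  # nucleus without host cell is skipped with a warning
  nucbg <- matrix(0L, 30, 30); nucbg[5:8, 25:28] <- 1L
  expect_warning(
    regbg <- perinuclear_region(label_mask(nucbg, meta1()),
                                label_mask(cells, meta1())),
    "no host cell")
  expect_length(mask_labels(regbg), 0L)
})

test_that("membrane band matches the distance-to-background oracle", {
  # disk cell: band = annulus
  cc <- matrix(0L, 41, 41)
  for (r in 1:41) for (c in 1:41)
    if ((r - 21)^2 + (c - 21)^2 <= 15^2) cc[r, c] <- 1L
  mask <- label_mask(cc, meta1())
  band <- membrane_band(mask, shrink_um = 4)
  oracle_d <- brute_dist_to_bg(cc == 1L)
  expect_identical(band$labels == 1L, cc == 1L & oracle_d <= 4 & oracle_d > 0)
  # shrink 0 -> empty band
  expect_length(mask_labels(membrane_band(mask, 0)), 0L)
  # shrink beyond the inradius warns and fills the cell
  expect_warning(full <- membrane_band(mask, 40), "inradius")
  expect_identical(full$labels, cc)
})

test_that("membrane band sector keeps only the leading-edge rim", {
  cc <- matrix(0L, 30, 30); cc[6:25, 6:25] <- 1L  # square cell
  mask <- label_mask(cc, meta1())
  band <- membrane_band(mask, shrink_um = 5, arc_deg = c(-45, 45))
  idx <- which(band$labels == 1L, arr.ind = TRUE)
  # strip along the right edge only: columns 21..25, not the left half
  expect_true(all(idx[, 2] >= 21))
  expect_gt(nrow(idx), 0)
  full <- membrane_band(mask, shrink_um = 5)
  left_rim <- which(full$labels == 1L, arr.ind = TRUE)
  expect_gt(nrow(left_rim), nrow(idx))  # sector is a strict subset
})

test_that("bands are subsets of cells, monotone in depth, and invariant
           to padding and label renumbering", {
  set.seed(9)
  cells <- matrix(0L, 40, 40)
  cells[5:20, 8:30] <- 1L; cells[25:38, 12:35] <- 2L
  meta <- image_meta(0.5)
  mask <- label_mask(cells, meta)
  areas <- sapply(c(2, 4, 6, 10), function(dep)
    sum(front_band(mask, front_spec(7.5, dep))$labels > 0L))
  expect_true(all(diff(areas) >= 0))
  band <- front_band(mask, front_spec(7.5, 4))
  expect_true(all(cells[band$labels > 0L] > 0L))
  # pad by 6 rows/cols of background; same band inside
  pad <- matrix(0L, 52, 52); pad[7:46, 7:46] <- cells
  bandp <- front_band(label_mask(pad, meta), front_spec(13.5, 4))
  expect_identical(bandp$labels[7:46, 7:46], band$labels)
  # renumber labels 1,2 -> 9,4
  ren <- cells; ren[cells == 1L] <- 9L; ren[cells == 2L] <- 4L
  bandr <- front_band(label_mask(ren, meta), front_spec(7.5, 4))
  expect_identical(bandr$labels == 9L, band$labels == 1L)
  expect_identical(bandr$labels == 4L, band$labels == 2L)
})
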
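test_that("a flat phantom yields a uniform total-thickness map", {
  g <- generate_phantom(flat_spec())
  bs <- boundary_set_from_truth(g$truth)
  tm <- thickness_map(bs, 1, 9)
  expect_equal(as.numeric(tm$values_um), rep(275, length(tm$values_um)))
  expect_true(all(tm$valid))
  expect_error(thickness_map(bs, 5, 5), "top < bottom")
  expect_error(thickness_map(bs, 7, 2), "top < bottom")
})

test_that("the eight sublayer maps sum exactly to the total map", {
  g <- small_clean()
  total <- thickness_map(g$bs, 1, 9)$values_um
  subsum <- Reduce(`+`, lapply(1:8, function(k) thickness_map(g$bs, k, k + 1)$values_um))
  expect_lt(max(abs(subsum - total)), 1e-6)
})

test_that("total thickness dominates every sublayer (nesting)", {
  g <- small_clean()
  total <- mean(thickness_map(g$bs, 1, 9)$values_um)
  for (k in 1:8)
    expect_gte(total, mean(thickness_map(g$bs, k, k + 1)$values_um))
})

test_that("fovea is recovered at the scan centre and off-centre", {
  # centred pit, default lateral sampling, truth surfaces
  g <- generate_phantom(phantom_spec(speckle_shape = Inf))
  tm <- thickness_map(boundary_set_from_truth(g$truth), 1, 9)
  f <- locate_fovea(tm)
  expect_lt(abs(f[1] - 3), 6 / 512)
  expect_lt(abs(f[2] - 3), 6 / 128)
  expect_false(attr(f, "low_confidence"))

  sp <- phantom_spec(fovea = list(center_xy_mm = c(2.5, 3.4), pit_depth_um = 120,
                                  pit_radius_mm = 0.6), speckle_shape = Inf)
  g2 <- generate_phantom(sp)
  f2 <- locate_fovea(thickness_map(boundary_set_from_truth(g2$truth), 1, 9))
  expect_lt(abs(f2[1] - 2.5), 2 * 6 / 512)
  expect_lt(abs(f2[2] - 3.4), 2 * 6 / 128)
})

test_that("a pitless map yields a low-confidence central fix", {
  g <- generate_phantom(flat_spec(protocol = small_protocol(n_ascans = 128L,
                                                            n_bscans = 32L)))
  tm <- thickness_map(boundary_set_from_truth(g$truth), 1, 9)
  f <- locate_fovea(tm)
  expect_true(attr(f, "low_confidence"))
  expect_lt(abs(f[1] - 3), 1.5)  # some central minimum
  tm$valid[] <- FALSE
  expect_error(locate_fovea(tm), "fovea not found")
})

test_that("sector summaries are exact on a uniform map", {
  g <- generate_phantom(flat_spec())
  tm <- thickness_map(boundary_set_from_truth(g$truth), 1, 9)
  ss <- sector_summary(tm, sector_grid(c(3, 3)))
  expect_identical(nrow(ss), 9L)
  expect_equal(ss$mean_um, rep(275, 9))
  expect_equal(ss$valid_fraction, rep(1, 9))
  expect_error(sector_summary(tm, sector_grid(c(9, 3))), "outside")
})

test_that("central sector mean of a linear ramp equals the ramp at the centre", {
  p <- scan_protocol(n_bscans = 64L, n_ascans = 256L, n_depth = 100L)
  lc <- retilayers:::.lateral_coords(p)
  slope <- 20  # um per mm
  vals <- outer(rep(1, 64), 100 + slope * lc$x_mm)
  tm <- structure(list(values_um = vals, valid = vals > 0, layer = c(1L, 9L),
                       protocol = p, laterality = "right"),
                  class = "thickness_map")
  ss <- sector_summary(tm, sector_grid(c(3.1, 3)))
  centre_val <- 100 + slope * 3.1
  expect_equal(ss$mean_um[ss$sector == "central"], centre_val,
               tolerance = slope * lc$pitch_x / centre_val)
})

test_that("translating map content and grid centre together preserves sector means", {
  p <- scan_protocol(n_bscans = 64L, n_ascans = 256L, n_depth = 100L)
  lc <- retilayers:::.lateral_coords(p)
  f <- function(x, y) 250 + 15 * sin(x) + 10 * cos(2 * y)
  mk <- function(dx) {
    vals <- outer(lc$y_mm, lc$x_mm, function(y, x) f(x - dx, y))
    structure(list(values_um = vals, valid = vals > 0, layer = c(1L, 9L),
                   protocol = p, laterality = "right"), class = "thickness_map")
  }
  shift <- 8 * lc$pitch_x  # whole-pixel shift: membership pattern identical
  s1 <- sector_summary(mk(0), sector_grid(c(2.8, 3)))
  s2 <- sector_summary(mk(shift), sector_grid(c(2.8 + shift, 3)))
  expect_equal(s2$mean_um, s1$mean_um, tolerance = 0.01)
})

test_that("zero-valid sectors report missing means and fraction 0", {
  g <- generate_phantom(flat_spec())
  tm <- thickness_map(boundary_set_from_truth(g$truth), 1, 9)
  lc <- retilayers:::.lateral_coords(tm$protocol)
  tm$valid[, abs(lc$x_mm - 3) < 0.6] <- FALSE   # kill the central disc
  ss <- sector_summary(tm, sector_grid(c(3, 3)))
  expect_true(is.na(ss$mean_um[ss$sector == "central"]))
  expect_equal(ss$valid_fraction[ss$sector == "central"], 0)
})

test_that("quadrant labels honour laterality", {
  p <- small_protocol(n_ascans = 128L, n_bscans = 64L)
  idR <- retilayers:::.sector_membership(p, sector_grid(c(3, 3)), "right")
  idL <- retilayers:::.sector_membership(p, sector_grid(c(3, 3)), "left")
  # a pixel on the +x side of the inner ring: temporal for OD, nasal for OS
  lc <- retilayers:::.lateral_coords(p)
  ix <- which.min(abs(lc$x_mm - 4)); iy <- which.min(abs(lc$y_mm - 3))
  nm <- retilayers:::.sector_names
  expect_identical(nm[idR[iy, ix]], "inner_temporal")
  expect_identical(nm[idL[iy, ix]], "inner_nasal")
})

test_that("sector_table covers the total retina and all eight sublayers", {
  g <- small_clean()
  st <- sector_table(g$bs, sector_grid(c(3, 3)))
  expect_identical(nrow(st), 81L)
  expect_identical(unique(st$layer_bottom - st$layer_top)[1], 8L)
})
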
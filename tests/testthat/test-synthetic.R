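test_that("noise-free flat phantom is a blurred staircase with exact truth", {
  sp <- flat_spec()
  g <- generate_phantom(sp)
  pitch <- sp$protocol$axial_um_per_px
  # truth exactly at offsets / pitch everywhere
  for (k in 1:9)
    expect_equal(as.numeric(g$truth$boundaries_px[k, , ]),
                 rep(sp$boundary_offsets_um[k] / pitch,
                     sp$protocol$n_ascans * sp$protocol$n_bscans))
  # compartment interiors carry the configured reflectivities
  col <- g$volume$intensity[, 1, 1]
  z <- sp$boundary_offsets_um / pitch
  interior <- function(k) {  # rows well inside compartment k (between b k-1, k)
    lo <- if (k == 1) 1 else ceiling(z[k - 1]) + 4
    hi <- if (k == 10) sp$protocol$n_depth else floor(z[k]) - 3
    lo:hi
  }
  for (k in c(1, 2, 3, 4, 5, 6))
    expect_equal(mean(col[interior(k)]), sp$layer_intensities[k], tolerance = 1e-3)
})

test_that("speckle changes the intensities but never the ground truth", {
  sp1 <- small_spec(seed = 1)
  sp2 <- small_spec(seed = 2)
  g1 <- generate_phantom(sp1); g2 <- generate_phantom(sp2)
  expect_identical(g1$truth$boundaries_px, g2$truth$boundaries_px)
  expect_gt(max(abs(g1$volume$intensity - g2$volume$intensity)), 0)
  # bit-reproducible for a fixed seed
  g1b <- generate_phantom(sp1)
  expect_identical(g1$volume$intensity, g1b$volume$intensity)
})

test_that("compartment mean intensity matches the configured reflectivity under speckle", {
  sp <- small_spec(seed = 4, speckle_shape = 50)
  g <- generate_phantom(sp)
  z <- g$truth$boundaries_px
  # pixels well inside the band between boundaries 1 and 2, all B-scans
  vals <- unlist(lapply(seq_len(sp$protocol$n_bscans), function(b)
    lapply(seq_len(sp$protocol$n_ascans), function(x) {
      rows <- (ceiling(z[1, x, b]) + 4):(floor(z[2, x, b]) - 3)
      g$volume$intensity[rows, x, b]
    })))
  expect_equal(mean(vals), sp$layer_intensities[2], tolerance = 0.02)
})

test_that("ground-truth ordering holds over randomized valid specs", {
  set.seed(99)
  for (i in 1:12) {
    o <- c(100, 140, 190, 220, 250, 320, 335, 355, 375) * runif(1, 0.85, 1.15)
    sp <- phantom_spec(
      protocol = small_protocol(),
      boundary_offsets_um = o,
      waviness = list(amplitude_um = runif(1, 0, 30), wavelength_mm = runif(1, 2, 5),
                      direction_deg = runif(1, 0, 90), phase = runif(1, 0, 2 * pi),
                      thickness_amplitude_um = runif(1, 0, 5), phase2 = runif(1, 0, 2 * pi),
                      rnfl_amplitude_um = runif(1, 0, 12), rnfl_wavelength_mm = 4,
                      rnfl_direction_deg = 70, rnfl_phase = runif(1, 0, 2 * pi)),
      fovea = list(center_xy_mm = runif(2, 2, 4), pit_depth_um = runif(1, 0, 100),
                   pit_radius_mm = runif(1, 0.4, 0.9)),
      speckle_shape = runif(1, 20, 80), seed = i)
    g <- generate_phantom(sp)
    diffs <- g$truth$boundaries_px[2:9, , ] - g$truth$boundaries_px[1:8, , ]
    expect_gte(min(diffs), 0)
  }
})

test_that("specs that would cross boundaries are rejected", {
  expect_error(phantom_spec(boundary_offsets_um = c(100, 90, 190, 220, 250, 320, 335, 355, 375)),
               "strictly increasing")
  expect_error(phantom_spec(fovea = list(center_xy_mm = c(3, 3), pit_depth_um = 160,
                                         pit_radius_mm = 0.6)),
               "pit depth")
  expect_error(phantom_spec(layer_intensities = rep(2, 10)), "layer intensities")
})

test_that("blink injection attenuates the targeted B-scans", {
  g <- generate_phantom(small_spec(seed = 6))
  v0 <- inject_blink(g$volume, 2:3, attenuation = 0)
  expect_true(all(v0$intensity[, , 2:3] == 0))
  expect_identical(v0$intensity[, , 1], g$volume$intensity[, , 1])

  v1 <- inject_blink(g$volume, 2:3, attenuation = 1)
  expect_identical(v1$intensity, g$volume$intensity)

  va <- inject_blink(g$volume, 2L, attenuation = 0.02)
  ratio <- mean(va$intensity[, , 2]) / mean(g$volume$intensity[, , 2])
  expect_equal(ratio, 0.02, tolerance = 0.05 * 0.02)

  expect_warning(inject_blink(g$volume, integer(0)), "no-op")
  expect_error(inject_blink(g$volume, 99L), "outside")
})

test_that("motion injection shifts volume and truth together", {
  g <- generate_phantom(small_spec(seed = 7))
  m0 <- inject_motion(g$truth, g$volume, 3L, 0L)
  expect_identical(m0$volume$intensity, g$volume$intensity)
  expect_identical(m0$truth$boundaries_px, g$truth$boundaries_px)

  m1 <- inject_motion(g$truth, g$volume, 3L, 10L)
  # truth discontinuity across the injection point equals the shift exactly
  jump <- m1$truth$boundaries_px[, , 3] - m1$truth$boundaries_px[, , 2] -
    (g$truth$boundaries_px[, , 3] - g$truth$boundaries_px[, , 2])
  expect_equal(as.numeric(jump), rep(10, length(jump)))
  # shifting back restores the volume except in the fill region
  m2 <- inject_motion(m1$truth, m1$volume, 3L, -10L)
  nz <- g$volume$protocol$n_depth
  expect_equal(m2$volume$intensity[11:(nz - 10), , ],
               g$volume$intensity[11:(nz - 10), , ])
  expect_equal(m2$truth$boundaries_px, g$truth$boundaries_px)
  expect_length(m2$truth$artifact_log, 2L)
})

test_that("clipping injection marks the requested fraction of the field", {
  sp <- small_spec(seed = 8)
  expect_identical(inject_clipping(sp, 0), sp)

  g1 <- generate_phantom(inject_clipping(sp, 1))
  expect_true(all(g1$truth$clipped))

  f <- 0.3
  gf <- generate_phantom(inject_clipping(sp, f))
  n <- sp$protocol$n_ascans * sp$protocol$n_bscans
  expect_lte(abs(mean(gf$truth$clipped) - f), 1 / n)
})

test_that("phantom specs round-trip through YAML", {
  sp <- small_spec(seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_spec(sp, path)
  back <- read_phantom_spec(path)
  g1 <- generate_phantom(sp); g2 <- generate_phantom(back)
  expect_identical(g1$volume$intensity, g2$volume$intensity)
  expect_identical(g1$truth$boundaries_px, g2$truth$boundaries_px)
})
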
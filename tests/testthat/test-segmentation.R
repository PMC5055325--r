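test_that("edge map of a constant image is zero", {
  m <- matrix(0.4, 50, 7)
  E <- dual_scale_edge_map(m, edge_score_params(), "dark-to-bright")
  expect_equal(max(abs(E)), 0)
})

test_that("edge map peaks at an ideal step, for the matching polarity only", {
  z0 <- 20L
  m <- matrix(0, 50, 7); m[(z0 + 1):50, ] <- 1  # dark-to-bright step at depth z0
  E <- dual_scale_edge_map(m, edge_score_params(), "dark-to-bright")
  peaks <- apply(E, 2, which.max) - 1L          # 0-based rows
  expect_true(all(abs(peaks + 0.5 - z0) <= 0.5))
  Eopp <- dual_scale_edge_map(m, edge_score_params(), "bright-to-dark")
  expect_equal(max(Eopp), 0)
  # normalization: a unit step scores ~1 at the peak
  expect_equal(max(E), 1, tolerance = 0.05)
})

test_that("weight endpoints reduce to single-scale responses", {
  set.seed(2)
  m <- matrix(runif(50 * 6), 50, 6)
  pf <- edge_score_params(weight_fine = 1)
  pc <- edge_score_params(weight_fine = 0)
  fine <- pmax(retilayers:::.axial_gradient(m, pf$sigma_fine_px), 0)
  coarse <- pmax(retilayers:::.axial_gradient(m, pf$sigma_coarse_px), 0)
  expect_equal(dual_scale_edge_map(m, pf, "dark-to-bright"), fine)
  expect_equal(dual_scale_edge_map(m, pc, "dark-to-bright"), coarse)
  expect_error(dual_scale_edge_map(matrix(c(NA, 1), 2, 1)), "non-finite")
})

test_that("lambda = 0 tracing is the per-column argmax within the band", {
  set.seed(3)
  E <- matrix(runif(12 * 9), 12, 9)
  path <- trace_boundary(E, c(2, 9), lambda = 0, refine = FALSE)
  expect_equal(path, apply(E[3:10, ], 2, which.max) + 1)  # 0-based rows in [2, 9]
})

test_that("dynamic programming matches exhaustive enumeration", {
  set.seed(4)
  for (i in 1:60) {
    nz <- sample(4:8, 1); nx <- sample(2:5, 1)
    E <- matrix(runif(nz * nx), nz, nx)
    zmin <- sample(0:1, nx, replace = TRUE)
    zmax <- pmin(zmin + sample(2:(nz - 1), nx, replace = TRUE), nz - 1L)
    lambda <- runif(1, 0, 1)
    dp <- trace_boundary(E, list(zmin = zmin, zmax = zmax), lambda, refine = FALSE)
    bf <- brute_force_trace(E, zmin, zmax, lambda)
    expect_equal(dp, as.numeric(bf))
  }
})

test_that("infinite stiffness collapses onto the best flat row", {
  E <- matrix(0.1, 10, 6)
  E[4, ] <- 0.9                      # flat high-score row at depth 3
  E[7, c(2, 5)] <- 2                 # tempting isolated spikes
  path <- trace_boundary(E, c(0, 9), lambda = 1e6, refine = FALSE)
  expect_equal(path, rep(3, 6))
})

test_that("an empty band names the offending column", {
  E <- matrix(1, 10, 4)
  expect_error(trace_boundary(E, list(zmin = c(1, 1, 8, 1), zmax = c(5, 5, 4, 5)), 0.1),
               "column 3")
})

test_that("sub-pixel refinement recovers a blurred step to a fraction of a pixel", {
  z0 <- 17.3
  zz <- seq_len(60) - 0.5
  col <- pnorm(zz, mean = z0, sd = 1.2)
  m <- matrix(rep(col, 5), 60, 5)
  E <- dual_scale_edge_map(m, edge_score_params(), "dark-to-bright")
  d <- trace_boundary(E, c(0, 59), lambda = 0.1) + 0.5
  expect_true(all(abs(d - z0) < 0.2))
})

test_that("segment_volume returns nine ordered surfaces on a clean phantom", {
  g <- small_clean()
  expect_s3_class(g$bs, "boundary_set")
  expect_identical(dim(g$bs$depths_px), c(9L, 64L, 8L))
  diffs <- g$bs$depths_px[2:9, , ] - g$bs$depths_px[1:8, , ]
  expect_gte(min(diffs), 0)
  expect_true(all(g$bs$valid))
})

test_that("boundary recovery on small phantoms is sub-pixel without noise", {
  g <- generate_phantom(small_spec(seed = 55, speckle_shape = Inf))
  bs <- segment_volume(g$volume)
  for (k in 1:9)
    expect_lt(mean(abs(bs$depths_px[k, , ] - g$truth$boundaries_px[k, , ])), 0.5)
})

test_that("ordering is preserved even on pure-noise volumes", {
  set.seed(12)
  p <- small_protocol()
  v <- oct_volume(array(runif(prod(c(160, 64, 8))), c(160, 64, 8)), p)
  bs <- segment_volume(v)
  diffs <- bs$depths_px[2:9, , ] - bs$depths_px[1:8, , ]
  expect_gte(min(diffs), 0)
  expect_true(all(bs$depths_px >= 0 & bs$depths_px < p$n_depth))
})

test_that("boundary error grows monotonically with speckle strength", {
  proto <- scan_protocol(n_bscans = 8L, n_ascans = 192L, n_depth = 200L)
  mean_mae <- function(shape) {
    mean(vapply(1:5, function(s) {
      g <- generate_phantom(small_spec(protocol = proto, speckle_shape = shape,
                                       seed = 600 + s))
      bs <- segment_volume(g$volume)
      mean(abs(bs$depths_px - g$truth$boundaries_px))
    }, numeric(1)))
  }
  errs <- vapply(c(60, 30, 15), mean_mae, numeric(1))  # heavier noise rightward
  expect_lte(errs[1], errs[2])
  expect_lte(errs[2], errs[3])
})

test_that("boundary_set rejects disordered valid surfaces", {
  p <- small_protocol(n_bscans = 1L, n_ascans = 2L, n_depth = 100L)
  z <- array(rep(seq(10, 90, 10), 2), c(9, 2, 1))
  expect_s3_class(boundary_set(z, p), "boundary_set")
  z[3, 1, 1] <- 5
  expect_error(boundary_set(z, p), "not ordered")
})
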
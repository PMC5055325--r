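#' Dual-scale edge scoring parameters
#'
#' The edge score of a B-scan combines axial derivative-of-Gaussian responses
#' at a fine and a coarse scale: the fine scale localizes boundaries sharply,
#' the coarse scale bridges speckle and low-contrast gaps.
#'
#' @param sigma_fine_px Fine axial Gaussian-derivative scale (px).
#' @param sigma_coarse_px Coarse scale (px); must exceed the fine scale.
#' @param weight_fine Combination weight `w` in `[0, 1]`:
#'   `E = w * g_fine + (1 - w) * g_coarse`.
#' @return An `edge_score_params` object.
#' @export
edge_score_params <- function(sigma_fine_px = 1.5, sigma_coarse_px = 6.0,
                              weight_fine = 0.6) {
  stopifnot(sigma_fine_px > 0, sigma_coarse_px > sigma_fine_px,
            weight_fine >= 0, weight_fine <= 1)
  structure(list(sigma_fine_px = sigma_fine_px, sigma_coarse_px = sigma_coarse_px,
                 weight_fine = weight_fine), class = "edge_score_params")
}

# Derivative-of-Gaussian correlation kernel, normalized so that an ideal unit
# intensity step yields a peak response of 1.
.dog_kernel <- function(sigma) {
  h <- ceiling(4 * sigma)
  j <- (-h):h
  k <- j * exp(-j^2 / (2 * sigma^2))
  step_resp <- max(rev(cumsum(rev(k))))  # response maxima over step positions
  k / step_resp
}

.axial_gradient <- function(bscan, sigma) .conv_cols_cpp(bscan, .dog_kernel(sigma))

#' Dual-scale gradient edge map of a B-scan
#'
#' Computes `E(z, x) = w * g_fine + (1 - w) * g_coarse`, where `g_s` is the
#' axial derivative-of-Gaussian response at scale `s`, sign-flipped so the
#' expected transition polarity scores positive; negative scores are clamped
#' to zero at each scale. Kernels are normalized so an ideal unit step scores
#' 1, and borders are handled by reflection.
#'
#' Row `z` of the map corresponds to an intensity transition at sub-pixel
#' depth `z + 0.5` (pixel-centre convention).
#'
#' @param bscan Numeric matrix (`n_depth` x `n_ascans`), intensities in `[0, 1]`.
#' @param params An [edge_score_params()].
#' @param polarity `"dark-to-bright"` (intensity increases with depth) or
#'   `"bright-to-dark"`.
#' @return Edge-score matrix of the same dimensions, non-negative.
#' @export
dual_scale_edge_map <- function(bscan, params = edge_score_params(),
                                polarity = c("dark-to-bright", "bright-to-dark")) {
  polarity <- match.arg(polarity)
  if (!all(is.finite(bscan))) stop("non-finite intensities in B-scan")
  sgn <- if (polarity == "dark-to-bright") 1 else -1
  gf <- pmax(sgn * .axial_gradient(bscan, params$sigma_fine_px), 0)
  gc <- pmax(sgn * .axial_gradient(bscan, params$sigma_coarse_px), 0)
  params$weight_fine * gf + (1 - params$weight_fine) * gc
}

.normalize_band <- function(band, nx, nz) {
  if (is.list(band)) { zmin <- band$zmin; zmax <- band$zmax }
  else if (is.matrix(band)) { zmin <- band[1, ]; zmax <- band[2, ] }
  else { zmin <- band[1]; zmax <- band[2] }
  zmin <- rep_len(as.integer(ceiling(zmin)), nx)
  zmax <- rep_len(as.integer(floor(zmax)), nx)
  bad <- which(zmin > zmax | zmax < 0 | zmin > nz - 1L)
  if (length(bad)) stop(sprintf("empty search band in column %d", bad[1]))
  list(zmin = pmax(zmin, 0L), zmax = pmin(zmax, nz - 1L))
}

#' Trace one boundary across a B-scan
#'
#' Finds the path `{z_x}` maximizing
#' `sum_x E(z_x, x) - lambda * sum_x |z_x - z_{x+1}|` within a per-column band,
#' exactly, by dynamic programming over the banded graph (the L1 transition is
#' applied with a two-pass max-transform, so cost is linear in the map size).
#' Ties break toward the shallower (smaller z) node. With `refine = TRUE` the
#' chosen node is refined to sub-pixel precision by a parabolic fit of the
#' edge score around it.
#'
#' @param edge_map Non-negative edge-score matrix (`n_depth` x `n_ascans`).
#' @param band Search band: a length-2 vector `c(zmin, zmax)` (0-based,
#'   inclusive, recycled across columns), a `2 x n_ascans` matrix, or a
#'   `list(zmin =, zmax =)` of per-column vectors.
#' @param lambda Smoothness penalty per pixel of axial step between adjacent
#'   columns (same units as the edge score).
#' @param refine Apply parabolic sub-pixel refinement (default `TRUE`).
#' @return Numeric vector of per-column depths (0-based row coordinates).
#' @export
trace_boundary <- function(edge_map, band, lambda, refine = TRUE) {
  nz <- nrow(edge_map); nx <- ncol(edge_map)
  b <- .normalize_band(band, nx, nz)
  path <- .dp_trace_cpp(edge_map, b$zmin, b$zmax, lambda)
  if (!refine) return(as.numeric(path))
  .refine_subpixel(edge_map, path)
}

# Parabolic sub-pixel refinement around integer nodes (0-based), on `map`.
# Optionally re-centres on the local argmax of `map` within +/- `window` px
# first (used to localize on the finer scale after tracing on the combined).
# Vectorized across columns; ties in the argmax go to the shallower row.
.refine_subpixel <- function(map, nodes, window = 0L) {
  nz <- nrow(map); nx <- ncol(map)
  cols <- seq_len(nx)
  p <- as.integer(nodes) + 1L  # 1-based rows
  at <- function(r) {
    v <- map[cbind(pmin(pmax(r, 1L), nz), cols)]
    v[r < 1L | r > nz] <- -Inf
    v
  }
  if (window > 0L) {
    offs <- (-window):window
    vals <- vapply(offs, function(o) at(p + o), numeric(nx))
    p <- p + offs[max.col(matrix(vals, nx), ties.method = "first")]
  }
  y0 <- at(p - 1L); y1 <- at(p); y2 <- at(p + 1L)
  denom <- y0 - 2 * y1 + y2
  interior <- p > 1L & p < nz & is.finite(denom) & denom < 0
  off <- ifelse(interior, pmax(-0.5, pmin(0.5, 0.5 * (y0 - y2) / denom)), 0)
  p - 1L + off
}

#' Boundary models for the nine-surface segmentation
#'
#' Returns the default configuration: one model per boundary with its name,
#' expected transition polarity, smoothness penalty, and search band. Only the
#' identity of boundary 7 (the photoreceptor ellipsoid zone, EZ) is fixed by
#' convention; names follow the standard macular sequence and are
#' configuration, not hard-coded.
#'
#' Search bands are hierarchical: the ILM is traced over the full depth, then
#' Bruch's membrane (BM) below `ILM + min_retina_um`; the outer boundaries
#' (OS/RPE, EZ) within absolute-depth bands above the traced BM (the
#' photoreceptor/RPE band geometry varies little); the remaining inner
#' boundaries within fractional bands of the ILM-EZ span, each clipped by
#' already-traced neighbours with a minimum separation of `min_sep_px`.
#' Fractional bands are invariant to overall tissue scaling and wide enough to
#' cover the foveal collapse of the inner layers.
#'
#' @param lambda Default smoothness penalty (edge-score units per px), applied
#'   to every boundary unless overridden in the returned list.
#' @return A list of nine boundary models, ordered by boundary index.
#' @export
default_boundary_models <- function(lambda = 0.3) {
  frac <- function(frame, lo, hi) list(frame = frame, lo = lo, hi = hi)
  list(
    list(index = 1L, name = "ILM",      polarity = "dark-to-bright",
         lambda = lambda, band = frac("full", 0, 1)),
    list(index = 2L, name = "RNFL/GCL", polarity = "bright-to-dark",
         lambda = lambda, band = frac("ilm_ez", 0.01, 0.30)),
    list(index = 3L, name = "IPL/INL",  polarity = "bright-to-dark",
         lambda = lambda, band = frac("ilm_ez", 0.08, 0.50)),
    list(index = 4L, name = "INL/OPL",  polarity = "dark-to-bright",
         lambda = lambda, band = frac("ilm_ez", 0.12, 0.62)),
    list(index = 5L, name = "OPL/ONL",  polarity = "bright-to-dark",
         lambda = lambda, band = frac("ilm_ez", 0.18, 0.75)),
    list(index = 6L, name = "ELM",      polarity = "dark-to-bright",
         lambda = lambda, band = frac("ilm_ez", 0.80, 0.98)),
    list(index = 7L, name = "EZ",       polarity = "dark-to-bright",
         lambda = lambda, band = list(frame = "above_bm", lo_um = 34, hi_um = 48)),
    list(index = 8L, name = "OS/RPE",   polarity = "dark-to-bright",
         lambda = lambda, band = list(frame = "above_bm", lo_um = 10, hi_um = 32)),
    list(index = 9L, name = "BM",       polarity = "bright-to-dark",
         lambda = lambda, band = frac("below_ilm", NA, NA))
  )
}

#' Segmentation configuration
#'
#' @param models Nine boundary models, see [default_boundary_models()].
#' @param edge An [edge_score_params()].
#' @param min_retina_um Minimum ILM-to-BM separation (um) used to band the BM
#'   search below the traced ILM.
#' @param min_sep_px Minimum separation (px) enforced between consecutive
#'   traced boundaries.
#' @param suppress_px After a boundary is traced, its edge response is zeroed
#'   within this radius (px) on its polarity's map so later boundaries cannot
#'   lock onto it.
#' @param min_edge Columns whose ILM edge response falls below this floor are
#'   marked invalid for all surfaces (no detectable retina: blinks, clipped or
#'   empty A-scans).
#' @param sigma_loc_px Scale (px) of the derivative-of-Gaussian response used
#'   only for sub-pixel localization around the traced node; finer than the
#'   fine tracing scale so closely spaced outer boundaries do not bias each
#'   other's peak.
#' @return A `seg_config` object.
#' @export
seg_config <- function(models = default_boundary_models(),
                       edge = edge_score_params(),
                       min_retina_um = 100, min_sep_px = 1L,
                       suppress_px = 2L, min_edge = 0.05,
                       sigma_loc_px = 1.0) {
  stopifnot(length(models) == 9L,
            identical(vapply(models, `[[`, 1L, "index"), 1:9))
  structure(list(models = models, edge = edge, min_retina_um = min_retina_um,
                 min_sep_px = as.integer(min_sep_px),
                 suppress_px = as.integer(suppress_px), min_edge = min_edge,
                 sigma_loc_px = sigma_loc_px),
            class = "seg_config")
}

# Tracing order: highest-contrast boundaries first, then banded descendants.
.trace_order <- c(1L, 9L, 8L, 7L, 2L, 3L, 4L, 5L, 6L)

.suppress_rows <- function(map, depths, radius) {
  nz <- nrow(map)
  lo <- pmax(1L, as.integer(floor(depths - radius)) + 1L)
  hi <- pmin(nz, as.integer(ceiling(depths + radius)) + 1L)
  n <- pmax(hi - lo + 1L, 0L)
  rows <- sequence(n) + rep(lo - 1L, n)
  map[cbind(rows, rep(seq_along(depths), n))] <- 0
  map
}

# Segment one B-scan. Returns list(depths = 9 x nx, valid = 9 x nx,
# ilm_edge = nx vector of combined edge score at the traced ILM node).
.segment_bscan <- function(bscan, config) {
  nz <- nrow(bscan); nx <- ncol(bscan)
  g_fine <- .axial_gradient(bscan, config$edge$sigma_fine_px)
  g_coarse <- .axial_gradient(bscan, config$edge$sigma_coarse_px)
  w <- config$edge$weight_fine
  g_loc <- .axial_gradient(bscan, config$sigma_loc_px)
  maps <- list(
    "dark-to-bright" = w * pmax(g_fine, 0) + (1 - w) * pmax(g_coarse, 0),
    "bright-to-dark" = w * pmax(-g_fine, 0) + (1 - w) * pmax(-g_coarse, 0)
  )
  loc <- list("dark-to-bright" = pmax(g_loc, 0),
              "bright-to-dark" = pmax(-g_loc, 0))
  depths <- matrix(NA_real_, 9L, nx)
  valid <- matrix(TRUE, 9L, nx)
  ilm_edge <- rep(0, nx)
  sep <- config$min_sep_px
  min_retina_px <- config$min_retina_px  # set by segment_volume
  for (k in .trace_order) {
    m <- config$models[[k]]
    bandspec <- m$band
    if (identical(bandspec$frame, "full")) {
      zlo <- rep(0, nx); zhi <- rep(nz - 1, nx)
    } else if (identical(bandspec$frame, "below_ilm")) {
      zlo <- depths[1L, ] + min_retina_px; zhi <- rep(nz - 2, nx)
    } else if (identical(bandspec$frame, "above_bm")) {
      zlo <- depths[9L, ] - bandspec$hi_um / config$pitch_um
      zhi <- depths[9L, ] - bandspec$lo_um / config$pitch_um
    } else {
      ref <- if (identical(bandspec$frame, "ilm_bm")) depths[9L, ] else depths[7L, ]
      span <- ref - depths[1L, ]
      zlo <- depths[1L, ] + bandspec$lo * span
      zhi <- depths[1L, ] + bandspec$hi * span
    }
    # clip by nearest already-traced neighbours, min_sep_px per skipped slot
    traced <- which(!is.na(depths[, 1L]))
    above <- traced[traced < k]; below <- traced[traced > k]
    if (length(above)) {
      a <- max(above)
      zlo <- pmax(zlo, depths[a, ] + (k - a) * sep)
    }
    if (length(below)) {
      b <- min(below)
      zhi <- pmin(zhi, depths[b, ] - (b - k) * sep)
    }
    zmin <- pmax(as.integer(ceiling(zlo)), 0L)
    zmax <- pmin(as.integer(floor(zhi)), nz - 1L)
    collapsed <- zmin > zmax
    if (any(collapsed)) {
      valid[k, collapsed] <- FALSE
      mid <- pmin(pmax((zmin + zmax) %/% 2L, 0L), nz - 1L)
      zmin[collapsed] <- mid[collapsed]; zmax[collapsed] <- mid[collapsed]
    }
    emap <- maps[[m$polarity]]
    path <- .dp_trace_cpp(emap, zmin, zmax, m$lambda * config$lambda_scale)
    if (k == 1L) ilm_edge <- emap[cbind(path + 1L, seq_len(nx))]
    # sub-pixel localization on the finer response near the chosen node;
    # +0.5 converts edge-map rows to boundary depths (pixel-centre convention)
    d <- .refine_subpixel(loc[[m$polarity]], path, window = 2L) + 0.5
    d <- pmin(pmax(d, zlo), zhi + 1)
    d <- pmin(pmax(d, 0), nz - 1e-6)
    depths[k, ] <- d
    maps[[m$polarity]] <- .suppress_rows(maps[[m$polarity]], d, config$suppress_px)
    loc[[m$polarity]] <- .suppress_rows(loc[[m$polarity]], d, config$suppress_px)
  }
  # enforce ordering exactly (refinement may nudge neighbours by < 1 px)
  for (k in 2:9) depths[k, ] <- pmax(depths[k, ], depths[k - 1L, ])
  low_signal <- ilm_edge < config$min_edge
  valid[, low_signal] <- FALSE
  list(depths = depths, valid = valid, ilm_edge = ilm_edge)
}

#' Segment the nine intraretinal boundaries of a volume
#'
#' Traces nine ordered boundary surfaces in every B-scan using dual-scale
#' gradient edge maps and exact dynamic programming, hierarchically: the ILM
#' first over the full depth, then BM below a minimum retinal thickness, the
#' outer photoreceptor boundaries (OS/RPE, EZ) between them, and finally the
#' inner boundaries banded by their traced neighbours. Surface order is
#' enforced by construction. Columns without detectable retinal signal (the
#' ILM edge response below `config$min_edge`) are marked invalid for all
#' surfaces.
#'
#' @param vol An [oct_volume()].
#' @param config A [seg_config()].
#' @return A `boundary_set`: `depths_px` (array `9 x n_ascans x n_bscans`,
#'   sub-pixel, ordered), `valid` (logical, same shape), `protocol`, plus the
#'   per-position ILM edge strength in `$ilm_edge` (`n_bscans x n_ascans`).
#' @export
segment_volume <- function(vol, config = seg_config()) {
  stopifnot(inherits(vol, "oct_volume"))
  p <- vol$protocol
  config$min_retina_px <- config$min_retina_um / p$axial_um_per_px
  config$pitch_um <- p$axial_um_per_px
  # model lambdas are stated for the reference 512-column / 6-mm sampling; a
  # path's total |dz| across a physical feature is sampling-invariant while
  # its edge reward scales with column count, so lambda scales with lateral
  # sampling density to keep the physical smoothness trade-off constant
  config$lambda_scale <- (p$n_ascans / p$fov_mm[1]) / (512 / 6)
  depths <- array(NA_real_, dim = c(9L, p$n_ascans, p$n_bscans))
  valid <- array(TRUE, dim = c(9L, p$n_ascans, p$n_bscans))
  ilm_edge <- matrix(0, p$n_bscans, p$n_ascans)
  for (b in seq_len(p$n_bscans)) {
    res <- .segment_bscan(vol$intensity[, , b, drop = TRUE], config)
    depths[, , b] <- res$depths
    valid[, , b] <- res$valid
    ilm_edge[b, ] <- res$ilm_edge
  }
  boundary_set(depths, p, valid = valid, ilm_edge = ilm_edge,
               subject_id = vol$subject_id, laterality = vol$laterality)
}

#' Construct a boundary set
#'
#' @param depths_px Array `9 x n_ascans x n_bscans` of sub-pixel axial
#'   positions in `[0, n_depth)`; must satisfy `depth(k) <= depth(k+1)`
#'   wherever valid.
#' @param protocol A [scan_protocol()].
#' @param valid Logical array of the same shape (default: positions inside
#'   the axial window).
#' @param ilm_edge Optional `n_bscans x n_ascans` matrix of edge strength at
#'   the traced ILM.
#' @param subject_id,laterality Carried through from the volume.
#' @return A `boundary_set` object.
#' @export
boundary_set <- function(depths_px, protocol, valid = NULL, ilm_edge = NULL,
                         subject_id = "unknown", laterality = "right") {
  stopifnot(length(dim(depths_px)) == 3L, dim(depths_px)[1] == 9L)
  if (is.null(valid))
    valid <- array(depths_px >= 0 & depths_px < protocol$n_depth,
                   dim = dim(depths_px))
  d <- dim(depths_px)
  step_ok <- depths_px[2:9, , , drop = FALSE] - depths_px[1:8, , , drop = FALSE] >= -1e-9
  both_valid <- valid[2:9, , , drop = FALSE] & valid[1:8, , , drop = FALSE]
  if (any(!step_ok & both_valid))
    stop("boundary depths are not ordered: depth(k) > depth(k+1) at a valid position")
  structure(list(depths_px = depths_px, valid = valid, protocol = protocol,
                 ilm_edge = ilm_edge, subject_id = subject_id,
                 laterality = laterality),
            class = "boundary_set")
}

#' Boundary set implied by a phantom's ground truth
#'
#' Useful as an oracle: feeds the true surfaces through the same downstream
#' thickness and QC machinery as segmented ones. Positions outside the axial
#' window are clamped into it and marked invalid.
#'
#' @param truth A `ground_truth` from [generate_phantom()].
#' @return A `boundary_set`.
#' @export
boundary_set_from_truth <- function(truth) {
  p <- truth$protocol
  z <- truth$boundaries_px
  valid <- array(z >= 0 & z < p$n_depth, dim = dim(z))
  z <- pmin(pmax(z, 0), p$n_depth - 1e-6)
  boundary_set(z, p, valid = valid)
}
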
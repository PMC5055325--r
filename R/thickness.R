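#' Thickness map between two boundary surfaces
#'
#' @param bs A `boundary_set` (see [segment_volume()]).
#' @param top,bottom Boundary indices, `1 <= top < bottom <= 9`. The total
#'   retinal map is `top = 1, bottom = 9`.
#' @return A `thickness_map`: `values_um` (`n_bscans x n_ascans` matrix, um),
#'   `valid` (same shape; false where either surface is invalid), `layer`
#'   (the index pair), `protocol`, `laterality`.
#' @export
thickness_map <- function(bs, top = 1L, bottom = 9L) {
  stopifnot(inherits(bs, "boundary_set"))
  top <- as.integer(top); bottom <- as.integer(bottom)
  if (!(top >= 1L && top < bottom && bottom <= 9L))
    stop("need 1 <= top < bottom <= 9")
  p <- bs$protocol
  v <- t(bs$depths_px[bottom, , ] - bs$depths_px[top, , ]) * p$axial_um_per_px
  valid <- t(bs$valid[bottom, , ] & bs$valid[top, , ])
  dim(v) <- c(p$n_bscans, p$n_ascans); dim(valid) <- dim(v)
  structure(list(values_um = v, valid = valid, layer = c(top, bottom),
                 protocol = p, laterality = bs$laterality),
            class = "thickness_map")
}

# lateral pixel-centre coordinates in mm (anisotropic pitch)
.lateral_coords <- function(protocol) {
  list(x_mm = (seq_len(protocol$n_ascans) - 0.5) * protocol$fov_mm[1] / protocol$n_ascans,
       y_mm = (seq_len(protocol$n_bscans) - 0.5) * protocol$fov_mm[2] / protocol$n_bscans,
       pitch_x = protocol$fov_mm[1] / protocol$n_ascans,
       pitch_y = protocol$fov_mm[2] / protocol$n_bscans)
}

#' Locate the fovea in a total-retina thickness map
#'
#' Smooths the map with a 2-D Gaussian (sigma 0.25 mm in lateral units, pitch
#' handled anisotropically), finds the minimum within the central 3 mm square,
#' and refines it to sub-pixel precision with a quadratic fit along each axis.
#' Ties break toward the scan centre. The result carries a `low_confidence`
#' attribute, set when the pit contrast (mean minus minimum of the smoothed
#' central map) is below `min_contrast_um`.
#'
#' @param total_map A [thickness_map()] of the whole retina (boundaries 1-9).
#' @param sigma_mm Smoothing sigma in mm.
#' @param search_mm Side of the central search square in mm.
#' @param min_contrast_um Pit contrast below which the fix is flagged.
#' @return Length-2 numeric `(x_mm, y_mm)` with attribute `low_confidence`.
#' @export
locate_fovea <- function(total_map, sigma_mm = 0.25, search_mm = 3,
                         min_contrast_um = 5) {
  stopifnot(inherits(total_map, "thickness_map"))
  p <- total_map$protocol
  lc <- .lateral_coords(p)
  m <- total_map$values_um
  m[!total_map$valid] <- NA
  centre <- p$fov_mm / 2
  in_x <- abs(lc$x_mm - centre[1]) <= search_mm / 2
  in_y <- abs(lc$y_mm - centre[2]) <= search_mm / 2
  if (all(is.na(m[in_y, in_x]))) stop("fovea not found: central region has no valid thickness")
  # fill invalid pixels with the map median so smoothing stays finite
  m[is.na(m)] <- stats::median(m, na.rm = TRUE)
  kx <- .gauss_kernel(sigma_mm / lc$pitch_x)
  ky <- .gauss_kernel(sigma_mm / lc$pitch_y)
  sm <- t(.conv_cols_cpp(t(.conv_cols_cpp(m, ky)), kx))  # rows = B-scans
  region <- sm
  region[!in_y, ] <- Inf; region[, !in_x] <- Inf
  # ties toward scan centre: add an infinitesimal centre-distance key
  d2 <- outer((lc$y_mm - centre[2])^2, (lc$x_mm - centre[1])^2, "+")
  idx <- which(region + 1e-12 * d2 == min(region + 1e-12 * d2), arr.ind = TRUE)[1, ]
  iy <- idx[1]; ix <- idx[2]
  qfit <- function(vals, i) {
    if (i <= 1 || i >= length(vals)) return(0)
    y0 <- vals[i - 1]; y1 <- vals[i]; y2 <- vals[i + 1]
    den <- y0 - 2 * y1 + y2
    if (den <= 0) return(0)
    max(-0.5, min(0.5, 0.5 * (y0 - y2) / den))
  }
  fx <- lc$x_mm[ix] + qfit(sm[iy, ], ix) * lc$pitch_x
  fy <- lc$y_mm[iy] + qfit(sm[, ix], iy) * lc$pitch_y
  contrast <- mean(sm[in_y, in_x]) - sm[iy, ix]
  structure(c(x_mm = fx, y_mm = fy),
            low_confidence = contrast < min_contrast_um)
}

#' ETDRS-style macular sector grid
#'
#' Nine sectors: a central disc plus inner and outer rings split into
#' superior/inferior/nasal/temporal quadrants by the 45-degree diagonals.
#' Ring diameters default to the ETDRS 1/3/6 mm.
#'
#' @param center_mm Grid centre `(x, y)` in mm, typically from [locate_fovea()].
#' @param diameters_mm Strictly increasing ring diameters (central, inner,
#'   outer) in mm.
#' @return A `sector_grid` object.
#' @export
sector_grid <- function(center_mm, diameters_mm = c(1, 3, 6)) {
  stopifnot(length(center_mm) == 2L, length(diameters_mm) == 3L,
            all(diff(diameters_mm) > 0))
  structure(list(center_mm = as.numeric(center_mm),
                 diameters_mm = as.numeric(diameters_mm)),
            class = "sector_grid")
}

.sector_names <- c("central",
                   "inner_superior", "inner_inferior", "inner_nasal", "inner_temporal",
                   "outer_superior", "outer_inferior", "outer_nasal", "outer_temporal")

# Sector id (1..9, NA outside the grid) of each map pixel by its centre point.
# B-scan index increases inferior -> superior; the A-scan axis is
# nasal -> temporal for right eyes, mirrored for left.
.sector_membership <- function(protocol, grid, laterality) {
  lc <- .lateral_coords(protocol)
  dx <- outer(rep(1, protocol$n_bscans), lc$x_mm - grid$center_mm[1])
  dy <- outer(lc$y_mm - grid$center_mm[2], rep(1, protocol$n_ascans))
  r <- sqrt(dx^2 + dy^2)
  radii <- grid$diameters_mm / 2
  ring <- ifelse(r <= radii[1], 0L, ifelse(r <= radii[2], 1L,
                 ifelse(r <= radii[3], 2L, NA_integer_)))
  horizontal <- abs(dx) >= abs(dy)   # ties on the diagonal go horizontal
  temporal_sign <- if (identical(laterality, "right")) 1 else -1
  quad <- ifelse(horizontal,
                 ifelse(temporal_sign * dx >= 0, 4L, 3L),  # temporal / nasal
                 ifelse(dy >= 0, 1L, 2L))                  # superior / inferior
  id <- ifelse(ring == 0L, 1L, (ring - 1L) * 4L + 1L + quad)
  id
}

#' Sector summary of a thickness map
#'
#' Per-sector mean, SD and valid-pixel fraction of the map over an ETDRS-style
#' grid. Pixel membership is by the pixel's lateral centre point, with the
#' anisotropic x/y pitch handled explicitly. A sector with no valid pixels
#' reports `NA` mean/SD and fraction 0.
#'
#' @param map A [thickness_map()].
#' @param grid A [sector_grid()].
#' @return A `data.frame` with columns `sector`, `mean_um`, `sd_um`,
#'   `valid_fraction`, `n_pixels`.
#' @export
sector_summary <- function(map, grid) {
  stopifnot(inherits(map, "thickness_map"), inherits(grid, "sector_grid"))
  p <- map$protocol
  if (grid$center_mm[1] < 0 || grid$center_mm[1] > p$fov_mm[1] ||
      grid$center_mm[2] < 0 || grid$center_mm[2] > p$fov_mm[2])
    stop("grid centre outside the scan field")
  id <- .sector_membership(p, grid, map$laterality)
  out <- data.frame(sector = .sector_names, mean_um = NA_real_, sd_um = NA_real_,
                    valid_fraction = 0, n_pixels = 0L, stringsAsFactors = FALSE)
  for (s in 1:9) {
    in_s <- !is.na(id) & id == s
    out$n_pixels[s] <- sum(in_s)
    if (!any(in_s)) next
    ok <- in_s & map$valid
    out$valid_fraction[s] <- sum(ok) / sum(in_s)
    if (any(ok)) {
      v <- map$values_um[ok]
      out$mean_um[s] <- mean(v)
      out$sd_um[s] <- if (length(v) > 1) stats::sd(v) else 0
    }
  }
  out
}

#' Sector table across all layer pairs
#'
#' Convenience wrapper producing the per-volume derived data: the 9 sectors
#' for the total retina (1-9) and the eight sublayers (1-2, ..., 8-9).
#'
#' @param bs A `boundary_set`.
#' @param grid A [sector_grid()].
#' @return A `data.frame` of 81 rows with `layer_top`, `layer_bottom` columns
#'   prepended to the [sector_summary()] columns.
#' @export
sector_table <- function(bs, grid) {
  pairs <- rbind(c(1L, 9L), cbind(1:8, 2:9))
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    s <- sector_summary(thickness_map(bs, pairs[i, 1], pairs[i, 2]), grid)
    cbind(data.frame(layer_top = pairs[i, 1], layer_bottom = pairs[i, 2]), s)
  }))
}

#' @export
plot.thickness_map <- function(x, ...) {
  lc <- .lateral_coords(x$protocol)
  v <- x$values_um
  v[!x$valid] <- NA
  graphics::image(lc$x_mm, lc$y_mm, t(v), xlab = "x (mm)", ylab = "y (mm)",
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = sprintf("thickness %d-%d (um)", x$layer[1], x$layer[2]),
                  useRaster = TRUE, ...)
  invisible(x)
}
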
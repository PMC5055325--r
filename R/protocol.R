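#' Scan protocol for a macular OCT raster volume
#'
#' Describes the acquisition geometry and timing of a spectral-domain OCT
#' raster scan. Defaults correspond to a 6 x 6 mm macular raster of 128
#' B-scans x 512 A-scans acquired at 18,000 A-scans per second with 6 um
#' optical axial resolution. The axial pixel count and pitch are device
#' configuration, not optics, and default to 480 samples at 3.5 um/px.
#'
#' @param n_bscans Number of B-scans (slow lateral axis, y).
#' @param n_ascans Number of A-scans per B-scan (fast lateral axis, x).
#' @param n_depth Axial samples per A-scan (z).
#' @param fov_mm Lateral field of view, length-2 numeric `(x, y)` in mm.
#' @param ascan_rate_hz A-scan acquisition rate in Hz.
#' @param axial_um_per_px Axial sampling pitch in um per pixel.
#' @param axial_resolution_um Optical axial resolution in um (informational).
#' @return A `scan_protocol` object (a named list).
#' @examples
#' p <- scan_protocol()
#' acquisition_time_s(p)  # 3.64 s for the default raster
#' @export
scan_protocol <- function(n_bscans = 128L, n_ascans = 512L, n_depth = 480L,
                          fov_mm = c(6, 6), ascan_rate_hz = 18000,
                          axial_um_per_px = 3.5, axial_resolution_um = 6) {
  p <- list(
    n_bscans = as.integer(n_bscans), n_ascans = as.integer(n_ascans),
    n_depth = as.integer(n_depth), fov_mm = as.numeric(fov_mm),
    ascan_rate_hz = as.numeric(ascan_rate_hz),
    axial_um_per_px = as.numeric(axial_um_per_px),
    axial_resolution_um = as.numeric(axial_resolution_um)
  )
  stopifnot(
    p$n_bscans >= 1L, p$n_ascans >= 1L, p$n_depth >= 1L,
    length(p$fov_mm) == 2L, all(p$fov_mm > 0),
    p$ascan_rate_hz > 0, p$axial_um_per_px > 0, p$axial_resolution_um > 0
  )
  structure(p, class = "scan_protocol")
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat(sprintf("OCT scan protocol: %d B-scans x %d A-scans x %d depth px\n",
              x$n_bscans, x$n_ascans, x$n_depth))
  cat(sprintf("  field %.1f x %.1f mm, %.0f A-scans/s, %.2f um/px axial\n",
              x$fov_mm[1], x$fov_mm[2], x$ascan_rate_hz, x$axial_um_per_px))
  invisible(x)
}

#' An OCT raster volume
#'
#' Wraps a 3-D intensity block with its scan protocol and identifiers. The
#' block is stored as an array of dimension `(n_depth, n_ascans, n_bscans)`
#' so that `vol$intensity[, , b]` is B-scan `b` as a depth-by-width image.
#' Intensities live on a fixed dynamic range of `[0, 1]`.
#'
#' Axis conventions (0-based in all depth coordinates): z increases from the
#' vitreous (top) toward the choroid (bottom); the B-scan index increases
#' inferior to superior; the A-scan index increases nasal to temporal for
#' right eyes and is mirrored for left eyes.
#'
#' @param intensity Numeric array `(n_depth, n_ascans, n_bscans)` in `[0, 1]`.
#' @param protocol A [scan_protocol()].
#' @param subject_id Opaque subject identifier string.
#' @param laterality `"left"` or `"right"`.
#' @return An `oct_volume` object.
#' @export
oct_volume <- function(intensity, protocol, subject_id = "unknown",
                       laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  stopifnot(is.array(intensity), length(dim(intensity)) == 3L)
  d <- dim(intensity)
  if (!identical(as.integer(d),
                 c(protocol$n_depth, protocol$n_ascans, protocol$n_bscans)))
    stop("intensity block shape does not match protocol (n_depth, n_ascans, n_bscans)")
  rng <- range(intensity)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
    stop("intensities must be finite and within [0, 1]")
  structure(list(intensity = intensity, protocol = protocol,
                 subject_id = as.character(subject_id), laterality = laterality),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  cat(sprintf("OCT volume [%s, %s eye]: ", x$subject_id, x$laterality))
  print(x$protocol)
  invisible(x)
}

#' Raster acquisition time
#'
#' Time to acquire the raster: `n_ascans * n_bscans / ascan_rate_hz`, plus an
#' optional additive galvanometer overhead. The default 512 x 128 raster at
#' 18,000 A-scans/s takes 3.6 s, or 3.7 s including the 0.1 s overhead.
#'
#' @param protocol A [scan_protocol()].
#' @param overhead_s Additive galvanometer/flyback overhead in seconds
#'   (default 0: pure A-scan time).
#' @return Acquisition time in seconds.
#' @export
acquisition_time_s <- function(protocol, overhead_s = 0) {
  stopifnot(overhead_s >= 0)
  protocol$n_ascans * protocol$n_bscans / protocol$ascan_rate_hz + overhead_s
}
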
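#' Specification of a synthetic OCT phantom
#'
#' Describes a phantom macular volume with known geometry: nine boundary
#' surfaces (baseline depths in um from the volume top), a smooth low-order
#' surface undulation, a Gaussian foveal pit that thins the inner layers,
#' piecewise-constant layer reflectivities, an axial point-spread blur, and
#' multiplicative gamma speckle. [generate_phantom()] turns it into an
#' [oct_volume()] plus its ground truth.
#'
#' The default boundary offsets place a 275 um retina whose bands follow the
#' standard macular sequence (ILM, RNFL/GCL, IPL/INL, INL/OPL, OPL/ONL, ELM,
#' EZ, OS/RPE, BM). The smooth undulation has three components, each a plane
#' sinusoid with its own direction and fixed phase: an additive axial
#' displacement of all boundaries together (globe curvature and tilt;
#' thickness-neutral), a small multiplicative thickness modulation (diffuse
#' lateral thickness gradient), and an "RNFL texture" term that shifts
#' boundaries 2-5 together (nerve-fibre-bundle thickness variation: it moves
#' RNFL thickness without changing total thickness). The pit displaces the
#' ILM downward by `pit_depth_um * G(r)` (Gaussian `G`, sigma `pit_radius_mm`)
#' and compresses boundaries 2-5 between the displaced ILM and boundary 5,
#' which stays fixed: inner layers vanish at the pit centre and total retinal
#' thickness dips by the pit depth, as in a real fovea.
#'
#' @param protocol A [scan_protocol()].
#' @param boundary_offsets_um Nine strictly increasing baseline depths (um).
#' @param waviness List with the three undulation components:
#'   `amplitude_um`, `wavelength_mm`, `direction_deg`, `phase` (additive
#'   displacement); `thickness_amplitude_um` (peak displacement of boundary 9
#'   under the multiplicative modulation, same wavelength/direction, phase
#'   shifted by `phase2`); `rnfl_amplitude_um`, `rnfl_wavelength_mm`,
#'   `rnfl_direction_deg`, `rnfl_phase` (RNFL texture).
#' @param fovea List `center_xy_mm`, `pit_depth_um`, `pit_radius_mm` (Gaussian
#'   sigma). `pit_depth_um` must stay below the ILM-to-OPL/ONL span or the
#'   boundaries would cross.
#' @param layer_intensities Ten mean reflectivities in `[0, 1]`: vitreous, the
#'   eight bands between consecutive boundaries, and the choroid/sclera.
#' @param speckle_shape Gamma shape for multiplicative speckle of mean 1
#'   (variance `1/shape`); `Inf` disables noise.
#' @param psf_axial_px Sigma (px) of the axial Gaussian blur.
#' @param choroid_decay_um Signal attenuation length (um) below boundary 9:
#'   intensity decays exponentially with depth beyond BM, as OCT signal does
#'   beneath the RPE. `Inf` disables the decay.
#' @param artifacts List of artifact descriptors applied after rendering, each
#'   `list(kind = "blink", b_range =, attenuation =)` or
#'   `list(kind = "motion", b_index =, shift_px =)`.
#' @param clip Optional `list(fraction =)`: displace the field so that the
#'   deepest boundary falls beyond the axial window over that fraction of
#'   (B-scan, A-scan) positions (see [inject_clipping()]).
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(protocol = scan_protocol(),
                         boundary_offsets_um = c(100, 140, 190, 220, 250,
                                                 320, 335, 355, 375),
                         waviness = list(amplitude_um = 20, wavelength_mm = 3,
                                         direction_deg = 30, phase = 0.5,
                                         thickness_amplitude_um = 3, phase2 = 1.7,
                                         rnfl_amplitude_um = 10,
                                         rnfl_wavelength_mm = 4,
                                         rnfl_direction_deg = 70, rnfl_phase = 2.3),
                         fovea = list(center_xy_mm = c(3, 3),
                                      pit_depth_um = 120, pit_radius_mm = 0.6),
                         layer_intensities = c(0.05, 0.60, 0.35, 0.20, 0.32,
                                               0.15, 0.28, 0.45, 0.70, 0.25),
                         speckle_shape = 50,
                         psf_axial_px = 0.75,
                         choroid_decay_um = 60,
                         artifacts = list(),
                         clip = NULL,
                         seed = 1L) {
  spec <- structure(list(protocol = protocol,
                         boundary_offsets_um = as.numeric(boundary_offsets_um),
                         waviness = waviness, fovea = fovea,
                         layer_intensities = as.numeric(layer_intensities),
                         speckle_shape = speckle_shape,
                         psf_axial_px = psf_axial_px,
                         choroid_decay_um = choroid_decay_um,
                         artifacts = artifacts, clip = clip,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  o <- spec$boundary_offsets_um
  if (length(o) != 9L || any(diff(o) <= 0))
    stop("invalid phantom spec: boundary offsets must be nine strictly increasing depths")
  if (any(spec$layer_intensities < 0) || any(spec$layer_intensities > 1) ||
      length(spec$layer_intensities) != 10L)
    stop("invalid phantom spec: need ten layer intensities in [0, 1]")
  wv <- spec$waviness
  ta <- wv$thickness_amplitude_um
  ra <- wv$rnfl_amplitude_um
  if (wv$amplitude_um < 0 || ta < 0 || ra < 0)
    stop("invalid phantom spec: waviness amplitudes must be non-negative")
  if (ta >= o[9])
    stop("invalid phantom spec: thickness modulation would collapse the layers")
  min_scale <- 1 - ta / o[9]
  if (ra >= (o[2] - o[1]) * min_scale || ra >= (o[6] - o[5]) * min_scale)
    stop("invalid phantom spec: RNFL texture amplitude would cross boundaries 1/2 or 5/6")
  pd <- spec$fovea$pit_depth_um
  if (pd < 0 || (pd > 0 && pd >= (o[5] - o[1]) * min_scale - ra))
    stop("invalid phantom spec: pit depth would cross boundaries (must be < ILM-to-OPL/ONL span)")
  if (!is.null(spec$clip)) {
    f <- spec$clip$fraction
    if (f < 0 || f > 1) stop("invalid phantom spec: clip fraction must be in [0, 1]")
  }
  invisible(spec)
}

# Ground-truth boundary surfaces implied by a phantom spec, before artifact
# post-ops. Returns array (9, n_ascans, n_bscans) of sub-pixel depths in px.
.phantom_truth_px <- function(spec) {
  p <- spec$protocol
  nx <- p$n_ascans; nb <- p$n_bscans
  x_mm <- (seq_len(nx) - 0.5) * p$fov_mm[1] / nx
  y_mm <- (seq_len(nb) - 0.5) * p$fov_mm[2] / nb
  o <- spec$boundary_offsets_um
  wv <- spec$waviness
  plane_wave <- function(wavelength_mm, direction_deg, phase) {
    th <- direction_deg * pi / 180
    u <- outer(x_mm * cos(th), y_mm * sin(th), "+")      # nx x nb
    sin(2 * pi * u / wavelength_mm + phase)
  }
  disp <- wv$amplitude_um * plane_wave(wv$wavelength_mm, wv$direction_deg, wv$phase)
  scale <- 1 + (wv$thickness_amplitude_um / o[9]) *
    plane_wave(wv$wavelength_mm, wv$direction_deg, wv$phase2)
  rnfl <- wv$rnfl_amplitude_um *
    plane_wave(wv$rnfl_wavelength_mm, wv$rnfl_direction_deg, wv$rnfl_phase)
  fv <- spec$fovea
  r2 <- outer((x_mm - fv$center_xy_mm[1])^2, (y_mm - fv$center_xy_mm[2])^2, "+")
  G <- if (fv$pit_depth_um > 0) exp(-r2 / (2 * fv$pit_radius_mm^2)) else
    matrix(0, nx, nb)
  z <- array(0, dim = c(9L, nx, nb))
  for (k in 1:9) z[k, , ] <- o[k] * scale + disp
  for (k in 2:5) z[k, , ] <- z[k, , ] + rnfl
  z1 <- z[1, , ]; gap5 <- z[5, , ] - z1
  pdG <- fv$pit_depth_um * G
  shrink <- 1 - pdG / gap5
  z1new <- z1 + pdG
  for (k in 2:5) z[k, , ] <- z1new + (z[k, , ] - z1) * shrink
  z[1, , ] <- z1new
  if (!is.null(spec$clip) && spec$clip$fraction > 0) {
    n_clip <- round(spec$clip$fraction * nx * nb)
    if (n_clip > 0) {
      # clip the first n_clip positions in raster order (x fastest)
      idx <- seq_len(n_clip)
      window_um <- p$n_depth * p$axial_um_per_px
      mask <- array(FALSE, dim = c(nx, nb)); mask[idx] <- TRUE
      # displace until even the ILM leaves the window: clipped columns carry
      # no retinal signal at all, as in a scan whose tissue sits below range
      z1 <- z[1, , ]
      shift_um <- max(0, window_um - min(z1[mask])) + 5 * p$axial_um_per_px
      for (k in 1:9) z[k, , ][mask] <- z[k, , ][mask] + shift_um
    }
  }
  z / p$axial_um_per_px
}

#' Ground truth of a phantom without rendering the volume
#'
#' @param spec A [phantom_spec()].
#' @return A `ground_truth` object: `boundaries_px` (array
#'   `9 x n_ascans x n_bscans` of sub-pixel depths), `fovea_xy` (mm),
#'   `clipped` (`n_bscans x n_ascans` logical, positions where any surface
#'   falls outside the axial window), `artifact_log`.
#' @export
phantom_ground_truth <- function(spec) {
  validate_phantom_spec(spec)
  z <- .phantom_truth_px(spec)
  .ground_truth(z, spec)
}

.clipped_mask <- function(boundaries_px, n_depth) {
  t(colSums(boundaries_px < 0 | boundaries_px >= n_depth) > 0)  # n_bscans x n_ascans
}

.ground_truth <- function(boundaries_px, spec, artifact_log = list()) {
  p <- spec$protocol
  clipped <- .clipped_mask(boundaries_px, p$n_depth)
  structure(list(boundaries_px = boundaries_px,
                 fovea_xy = spec$fovea$center_xy_mm,
                 clipped = clipped,               # n_bscans x n_ascans
                 artifact_log = artifact_log,
                 protocol = p),
            class = "ground_truth")
}

#' Generate a phantom OCT volume with known ground truth
#'
#' Renders piecewise-constant layer reflectivities between the true boundary
#' surfaces (box-averaged within each pixel), blurs axially with a Gaussian
#' PSF, multiplies by gamma speckle of mean 1, clips to `[0, 1]`, and applies
#' any artifacts listed in the spec. Deterministic given `spec$seed`; the
#' ground truth does not depend on the seed.
#'
#' @param spec A [phantom_spec()].
#' @param subject_id,laterality Passed to [oct_volume()].
#' @return `list(volume =, truth =)`.
#' @export
generate_phantom <- function(spec, subject_id = "phantom", laterality = "right") {
  validate_phantom_spec(spec)
  p <- spec$protocol
  z <- .phantom_truth_px(spec)
  block <- array(0, dim = c(p$n_depth, p$n_ascans, p$n_bscans))
  psf_kernel <- if (spec$psf_axial_px > 0) .gauss_kernel(spec$psf_axial_px) else NULL
  zpix <- seq_len(p$n_depth) - 0.5
  decay_px <- spec$choroid_decay_um / p$axial_um_per_px
  for (b in seq_len(p$n_bscans)) {
    m <- .render_bscan_cpp(z[, , b, drop = TRUE], spec$layer_intensities, p$n_depth)
    if (is.finite(decay_px)) {
      below <- outer(zpix, z[9, , b], "-")  # px beyond BM, negative above
      m <- m * exp(-pmax(below, 0) / decay_px)
    }
    if (!is.null(psf_kernel)) m <- .conv_cols_cpp(m, psf_kernel)
    block[, , b] <- m
  }
  if (is.finite(spec$speckle_shape)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(spec$seed)
    noise <- rgamma(length(block), shape = spec$speckle_shape,
                    rate = spec$speckle_shape)
    block <- block * noise
  }
  block[block < 0] <- 0
  block[block > 1] <- 1
  vol <- oct_volume(block, p, subject_id = subject_id, laterality = laterality)
  truth <- .ground_truth(z, spec)
  for (a in spec$artifacts) {
    if (identical(a$kind, "blink")) {
      vol <- inject_blink(vol, a$b_range,
                          attenuation = if (is.null(a$attenuation)) 0.02 else a$attenuation)
      truth$artifact_log <- c(truth$artifact_log, list(a))
    } else if (identical(a$kind, "motion")) {
      res <- inject_motion(truth, vol, a$b_index, a$shift_px,
                           fill = spec$layer_intensities[1])
      vol <- res$volume; truth <- res$truth
    } else stop("unknown artifact kind: ", a$kind)
  }
  list(volume = vol, truth = truth)
}

.gauss_kernel <- function(sigma, halfwidth = ceiling(4 * sigma)) {
  k <- exp(-((-halfwidth):halfwidth)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Inject a blink artifact
#'
#' Blinks black out a run of B-scans: the affected scans are multiplied by a
#' small attenuation factor, emulating loss of signal while the lid covers
#' the pupil.
#'
#' @param vol An [oct_volume()].
#' @param b_range Integer vector of 1-based B-scan indices to attenuate.
#' @param attenuation Multiplicative factor (default 0.02).
#' @return The modified volume, with the artifact appended to its
#'   `"artifact_log"` attribute. An empty `b_range` warns and returns the
#'   volume unchanged.
#' @export
inject_blink <- function(vol, b_range, attenuation = 0.02) {
  stopifnot(inherits(vol, "oct_volume"))
  b_range <- as.integer(b_range)
  if (length(b_range) == 0L) {
    warning("empty b_range: blink injection is a no-op")
    return(vol)
  }
  if (any(b_range < 1L | b_range > vol$protocol$n_bscans))
    stop("b_range outside volume")
  vol$intensity[, , b_range] <- vol$intensity[, , b_range] * attenuation
  log <- c(attr(vol, "artifact_log"),
           list(list(kind = "blink", b_range = b_range, attenuation = attenuation)))
  attr(vol, "artifact_log") <- log
  vol
}

#' Inject an axial eye-motion artifact
#'
#' Shifts all B-scans from `b_index` onward axially by an integer number of
#' pixels, filling the vacated rows with the vitreous intensity, and shifts
#' the ground-truth surfaces identically. Models a sudden axial eye movement
#' between consecutive B-scans.
#'
#' @param truth A `ground_truth` (from [generate_phantom()]).
#' @param vol The matching [oct_volume()].
#' @param b_index First affected 1-based B-scan index.
#' @param shift_px Integer axial shift (positive = deeper).
#' @param fill Intensity for vacated rows (default 0.05, vitreous-like).
#' @return `list(volume =, truth =)`.
#' @export
inject_motion <- function(truth, vol, b_index, shift_px, fill = 0.05) {
  stopifnot(inherits(vol, "oct_volume"), inherits(truth, "ground_truth"))
  p <- vol$protocol
  if (b_index < 1L || b_index > p$n_bscans) stop("b_index outside volume")
  shift_px <- as.integer(round(shift_px))
  if (shift_px != 0L) {
    nz <- p$n_depth
    bs <- b_index:p$n_bscans
    for (b in bs) {
      m <- vol$intensity[, , b]
      out <- matrix(fill, nz, p$n_ascans)
      if (shift_px > 0 && shift_px < nz)
        out[(shift_px + 1L):nz, ] <- m[1:(nz - shift_px), ]
      else if (shift_px < 0 && -shift_px < nz)
        out[1:(nz + shift_px), ] <- m[(1L - shift_px):nz, ]
      vol$intensity[, , b] <- out
    }
    truth$boundaries_px[, , bs] <- truth$boundaries_px[, , bs] + shift_px
    truth$clipped <- .clipped_mask(truth$boundaries_px, p$n_depth)
  }
  entry <- list(kind = "motion", b_index = b_index, shift_px = shift_px)
  truth$artifact_log <- c(truth$artifact_log, list(entry))
  attr(vol, "artifact_log") <- c(attr(vol, "artifact_log"), list(entry))
  list(volume = vol, truth = truth)
}

#' Inject axial clipping into a phantom spec
#'
#' Returns a spec whose boundaries are displaced beyond the axial acquisition
#' window over a requested fraction of (B-scan, A-scan) positions, emulating
#' retinal tissue clipped in the B-scan's z direction. The generated ground
#' truth marks the clipped positions.
#'
#' @param spec A [phantom_spec()].
#' @param fraction Fraction of field positions to clip, in `[0, 1]`.
#' @return The modified spec (`fraction = 0` returns it unchanged).
#' @export
inject_clipping <- function(spec, fraction) {
  stopifnot(inherits(spec, "phantom_spec"), fraction >= 0, fraction <= 1)
  if (fraction == 0) return(spec)
  spec$clip <- list(fraction = fraction)
  validate_phantom_spec(spec)
  spec
}

#' Read/write a phantom spec as YAML
#'
#' @param spec A [phantom_spec()].
#' @param path YAML file path.
#' @return `write_phantom_spec` returns `path` invisibly;
#'   `read_phantom_spec` returns a [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  x <- unclass(spec)
  x$protocol <- unclass(x$protocol)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  pr <- x$protocol
  phantom_spec(protocol = scan_protocol(pr$n_bscans, pr$n_ascans, pr$n_depth,
                                        pr$fov_mm, pr$ascan_rate_hz,
                                        pr$axial_um_per_px, pr$axial_resolution_um),
               boundary_offsets_um = x$boundary_offsets_um,
               waviness = x$waviness, fovea = x$fovea,
               layer_intensities = x$layer_intensities,
               speckle_shape = if (is.null(x$speckle_shape)) Inf else x$speckle_shape,
               psf_axial_px = x$psf_axial_px,
               choroid_decay_um = if (is.null(x$choroid_decay_um)) Inf else x$choroid_decay_um,
               artifacts = if (is.null(x$artifacts)) list() else x$artifacts,
               clip = x$clip, seed = x$seed)
}
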
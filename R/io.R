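.sidecar_path <- function(path) paste0(sub("\\.[^./]*$", "", path), ".json")

#' Write an OCT volume to disk
#'
#' Stores the intensity block as a multi-page TIFF (16-bit grayscale, one page
#' per B-scan, page dimensions `n_depth` x `n_ascans`) with a JSON sidecar of
#' the same stem carrying the scan protocol, `subject_id` and `laterality`.
#' [read_volume()] inverts it up to 16-bit quantization.
#'
#' @param vol An [oct_volume()].
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "oct_volume"))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  p <- vol$protocol
  pages <- lapply(seq_len(p$n_bscans), function(b) {
    m <- vol$intensity[, , b, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = p$n_depth, ncol = p$n_ascans)
    matrix(as.integer(round(m * 65535)), nrow = p$n_depth)
  })
  write_tiff16(pages, path)
  header <- list(
    n_bscans = p$n_bscans, n_ascans = p$n_ascans, n_depth = p$n_depth,
    fov_mm = p$fov_mm, ascan_rate_hz = p$ascan_rate_hz,
    axial_um_per_px = p$axial_um_per_px,
    axial_resolution_um = p$axial_resolution_um,
    subject_id = vol$subject_id, laterality = vol$laterality
  )
  jsonlite::write_json(header, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an OCT volume from disk
#'
#' Reads a multi-page TIFF written by [write_volume()] together with its JSON
#' sidecar header. Stored 16-bit integers are rescaled to `[0, 1]`.
#'
#' @param path Path to the TIFF file.
#' @return An [oct_volume()].
#' @section Errors: a missing sidecar raises `"header missing"`; a page count
#'   that disagrees with the header's `n_bscans`, or a page of the wrong
#'   dimensions, raises `"corrupt volume"` (the failure class that corrupted
#'   files fall into during batch processing).
#' @export
read_volume <- function(path) {
  side <- .sidecar_path(path)
  if (!file.exists(side)) stop("header missing: ", side)
  if (!file.exists(path)) stop("corrupt volume: file not found: ", path)
  h <- jsonlite::read_json(side, simplifyVector = TRUE)
  protocol <- scan_protocol(h$n_bscans, h$n_ascans, h$n_depth, h$fov_mm,
                            h$ascan_rate_hz, h$axial_um_per_px,
                            h$axial_resolution_um)
  pages <- tryCatch(read_tiff16(path),
                    error = function(e) stop("corrupt volume: ", conditionMessage(e)))
  if (length(pages) != protocol$n_bscans)
    stop(sprintf("corrupt volume: %d pages but header n_bscans=%d",
                 length(pages), protocol$n_bscans))
  ok <- vapply(pages, function(m) nrow(m) == protocol$n_depth &&
                 ncol(m) == protocol$n_ascans, logical(1))
  if (!all(ok)) stop("corrupt volume: page dimensions disagree with header")
  block <- array(0, dim = c(protocol$n_depth, protocol$n_ascans, protocol$n_bscans))
  for (b in seq_along(pages)) block[, , b] <- pages[[b]] / 65535
  oct_volume(block, protocol, subject_id = h$subject_id, laterality = h$laterality)
}
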
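# Small, fast phantom geometry shared across tests. Fixtures are memoised per
# test run so expensive segmentations happen once.

small_protocol <- function(n_bscans = 8L, n_ascans = 64L, n_depth = 160L)
  scan_protocol(n_bscans = n_bscans, n_ascans = n_ascans, n_depth = n_depth)

flat_spec <- function(protocol = small_protocol(), ...)
  phantom_spec(protocol = protocol,
               waviness = list(amplitude_um = 0, wavelength_mm = 3,
                               direction_deg = 30, phase = 0.5,
                               thickness_amplitude_um = 0, phase2 = 1.7,
                               rnfl_amplitude_um = 0, rnfl_wavelength_mm = 4,
                               rnfl_direction_deg = 70, rnfl_phase = 2.3),
               fovea = list(center_xy_mm = c(3, 3), pit_depth_um = 0,
                            pit_radius_mm = 0.6),
               speckle_shape = Inf, ...)

small_spec <- function(protocol = small_protocol(), ...)
  phantom_spec(protocol = protocol, ...)

.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, make) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- make()
  .fixture_env[[name]]
}

small_clean <- function() fixture("small_clean", function() {
  g <- generate_phantom(small_spec(seed = 101))
  g$bs <- segment_volume(g$volume)
  g
})

# exhaustive path enumeration oracle for the dynamic-programming tracer
brute_force_trace <- function(E, zmin, zmax, lambda) {
  nx <- ncol(E)
  paths <- as.matrix(expand.grid(lapply(seq_len(nx), function(x) zmin[x]:zmax[x])))
  vals <- vapply(seq_len(nx), function(x) E[cbind(paths[, x] + 1L, x)],
                 numeric(nrow(paths)))
  score <- rowSums(matrix(vals, nrow = nrow(paths)))
  if (nx > 1L)
    for (x in seq_len(nx - 1L))
      score <- score - lambda * abs(paths[, x + 1L] - paths[, x])
  paths[which.max(score), ]
}

# build a small on-disk cohort: n valid phantoms (+ optionally one corrupt
# file and one consent-withdrawn row), returning the manifest data.frame
local_cohort <- function(n_valid = 3, corrupt = FALSE, withdrawn = FALSE,
                         dir = withr::local_tempdir(.local_envir = parent.frame())) {
  rows <- lapply(seq_len(n_valid), function(i) {
    path <- file.path(dir, sprintf("vol%02d.tiff", i))
    g <- generate_phantom(small_spec(seed = 200 + i),
                          subject_id = sprintf("subj%02d", i),
                          laterality = if (i %% 2) "right" else "left")
    write_volume(g$volume, path)
    data.frame(volume_path = path, subject_id = sprintf("subj%02d", i),
               laterality = if (i %% 2) "right" else "left", consent = TRUE)
  })
  if (corrupt) {
    path <- file.path(dir, "corrupt.tiff")
    g <- generate_phantom(small_spec(seed = 299), subject_id = "bad")
    write_volume(g$volume, path)
    raw <- readBin(path, "raw", 400)
    writeBin(raw, path)  # truncated payload
    rows <- c(rows, list(data.frame(volume_path = path, subject_id = "bad",
                                    laterality = "right", consent = TRUE)))
  }
  if (withdrawn)
    rows <- c(rows, list(data.frame(volume_path = file.path(dir, "gone.tiff"),
                                    subject_id = "withdrawn", laterality = "left",
                                    consent = FALSE)))
  do.call(rbind, rows)
}
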
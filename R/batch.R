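#' Read or write a batch manifest
#'
#' A manifest is a CSV with columns `volume_path`, `subject_id`, `laterality`,
#' `consent` (logical; rows with withdrawn consent are skipped without
#' fetching). Paths must be unique.
#'
#' @param path CSV path.
#' @return A `data.frame` manifest.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("volume_path", "subject_id", "laterality", "consent")
  if (!all(need %in% names(m))) stop("manifest must have columns: ",
                                     paste(need, collapse = ", "))
  m$consent <- as.logical(m$consent)
  if (anyDuplicated(m$volume_path)) stop("manifest volume paths must be unique")
  m
}

#' @rdname read_manifest
#' @param manifest The manifest `data.frame`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Process one manifest row: fetch, segment, extract, delete
#'
#' Copies the volume (and its sidecar) into a private scratch directory,
#' runs segmentation, fovea localization, sector thickness extraction and QC,
#' and deletes the scratch copy afterwards -- even on failure. Rows with
#' withdrawn consent are skipped without fetching. A corrupt volume is
#' recorded as a failure, not raised, so a batch run can count it and
#' continue.
#'
#' @param row One manifest row (list or single-row `data.frame`).
#' @param workspace Writable scratch directory.
#' @param config A [seg_config()].
#' @param thresholds A [qc_thresholds()].
#' @return `list(status, fetch_s, segment_s, sectors, qc, fovea, error)`;
#'   `status` is one of `"processed"`, `"failed_corrupt"`, `"skipped_consent"`.
#' @export
process_one <- function(row, workspace, config = seg_config(),
                        thresholds = qc_thresholds()) {
  if (!dir.exists(workspace)) stop("workspace directory does not exist: ", workspace)
  base <- list(subject_id = row$subject_id, laterality = row$laterality,
               volume_path = row$volume_path, fetch_s = NA_real_,
               segment_s = NA_real_, sectors = NULL, qc = NULL, fovea = NULL,
               error = NA_character_)
  if (!isTRUE(as.logical(row$consent)))
    return(c(list(status = "skipped_consent"), base))
  scratch <- file.path(workspace,
                       paste0("scratch_", gsub("[^A-Za-z0-9]", "_", basename(row$volume_path)),
                              "_", Sys.getpid()))
  dir.create(scratch)
  on.exit(unlink(scratch, recursive = TRUE), add = TRUE)
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch({
    local_tiff <- file.path(scratch, basename(row$volume_path))
    ok <- file.copy(row$volume_path, local_tiff)
    side <- .sidecar_path(row$volume_path)
    if (file.exists(side)) file.copy(side, .sidecar_path(local_tiff))
    if (!ok) stop("corrupt volume: fetch failed for ", row$volume_path)
    vol <- read_volume(local_tiff)
    t1 <- proc.time()[["elapsed"]]
    bs <- segment_volume(vol, config)
    fov <- locate_fovea(thickness_map(bs, 1L, 9L))
    sect <- sector_table(bs, sector_grid(fov))
    qc <- qc_report(vol, bs, thresholds)
    t2 <- proc.time()[["elapsed"]]
    base$fetch_s <- t1 - t0
    base$segment_s <- t2 - t1
    base$sectors <- sect
    base$qc <- qc
    base$fovea <- as.numeric(fov)
    c(list(status = "processed"), base)
  }, error = function(e) {
    base$error <- conditionMessage(e)
    c(list(status = "failed_corrupt"), base)
  })
  res
}

#' Run a batch of volumes through the pipeline
#'
#' Processes every manifest row with [process_one()], optionally across
#' parallel workers (forked; the unit of parallelism is the row, and rows
#' never share scratch state, so derived outputs are identical whatever the
#' worker count). Writes `results.csv` (statuses and timings), `sectors.csv`,
#' `qc.csv` and a line-delimited JSON log into `out_dir`, and prints the
#' success percentage to two decimals.
#'
#' @param manifest Manifest `data.frame` (see [read_manifest()]) or CSV path.
#' @param workspace Scratch directory for fetched copies.
#' @param out_dir Output directory for derived CSVs (created if needed).
#' @param n_workers Parallel workers (forked; 1 = serial).
#' @param config,thresholds Passed to [process_one()].
#' @param quiet Suppress the console summary.
#' @return A `batch_result`: `rows` (statuses/timings `data.frame`),
#'   `sectors`, `qc`, and `counts`.
#' @export
run_batch <- function(manifest, workspace, out_dir = NULL, n_workers = 1L,
                      config = seg_config(), thresholds = qc_thresholds(),
                      quiet = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(n_workers >= 1L)
  rows <- split(manifest, seq_len(nrow(manifest)))
  worker <- function(row) process_one(row, workspace, config, thresholds)
  results <- if (n_workers > 1L)
    parallel::mclapply(rows, worker, mc.cores = n_workers, mc.preschedule = FALSE)
  else lapply(rows, worker)
  # a forked worker can die without returning (e.g. out of memory); record the
  # row as failed rather than aborting the campaign
  results <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (is.list(r) && !is.null(r$status)) return(r)
    list(status = "failed_corrupt", subject_id = manifest$subject_id[i],
         laterality = manifest$laterality[i],
         volume_path = manifest$volume_path[i], fetch_s = NA_real_,
         segment_s = NA_real_, sectors = NULL, qc = NULL, fovea = NULL,
         error = "worker did not return a result")
  })
  status <- vapply(results, `[[`, "", "status")
  rows_df <- data.frame(
    volume_path = manifest$volume_path, subject_id = manifest$subject_id,
    laterality = manifest$laterality, status = status,
    fetch_s = vapply(results, `[[`, 0, "fetch_s"),
    segment_s = vapply(results, `[[`, 0, "segment_s"),
    error = vapply(results, `[[`, "", "error"),
    stringsAsFactors = FALSE
  )
  proc <- which(status == "processed")
  sectors <- if (length(proc)) do.call(rbind, lapply(proc, function(i) {
    cbind(data.frame(subject_id = manifest$subject_id[i],
                     laterality = manifest$laterality[i],
                     stringsAsFactors = FALSE), results[[i]]$sectors)
  })) else NULL
  qc <- if (length(proc)) do.call(rbind, lapply(proc, function(i) {
    r <- results[[i]]$qc
    data.frame(subject_id = r$subject_id, laterality = r$laterality,
               q_score = r$q_score, ilm_indicator = r$ilm_indicator,
               validity_fraction = r$validity_fraction,
               motion_corr_rnfl = r$motion_corr_rnfl,
               motion_corr_total = r$motion_corr_total,
               excluded = r$excluded, stringsAsFactors = FALSE)
  })) else NULL
  counts <- c(processed = sum(status == "processed"),
              failed_corrupt = sum(status == "failed_corrupt"),
              skipped_consent = sum(status == "skipped_consent"))
  stopifnot(sum(counts) == nrow(manifest))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(rows_df, file.path(out_dir, "results.csv"), row.names = FALSE)
    if (!is.null(sectors))
      utils::write.csv(sectors, file.path(out_dir, "sectors.csv"), row.names = FALSE)
    if (!is.null(qc))
      utils::write.csv(qc, file.path(out_dir, "qc.csv"), row.names = FALSE)
    log <- vapply(seq_along(results), function(i)
      jsonlite::toJSON(list(volume_path = manifest$volume_path[i],
                            status = status[i],
                            fetch_s = results[[i]]$fetch_s,
                            segment_s = results[[i]]$segment_s),
                       auto_unbox = TRUE, na = "null"), character(1))
    writeLines(log, file.path(out_dir, "log.jsonl"))
  }
  if (!quiet)
    cat(sprintf("processed %d/%d volumes (%.2f%% success), %d failed, %d skipped\n",
                counts["processed"], nrow(manifest),
                success_percentage(counts["processed"], nrow(manifest)),
                counts["failed_corrupt"], counts["skipped_consent"]))
  structure(list(rows = rows_df, sectors = sectors, qc = qc, counts = counts),
            class = "batch_result")
}

#' Success percentage, rounded half-up to two decimals
#'
#' @param n_ok Successfully processed count.
#' @param n_total Total attempted.
#' @return Percentage (0-100) rounded half-up to 2 decimals; e.g. 134,611 of
#'   134,642 gives 99.98.
#' @export
success_percentage <- function(n_ok, n_total) {
  if (n_total == 0) return(0)
  # half-up, with a guard against binary representation of exact halves
  floor(n_ok / n_total * 10000 + 0.5 + 1e-9) / 100
}

#' Throughput model for a parallel batch campaign
#'
#' @param per_set_s Wall seconds per image set per login (fetch + segment).
#' @param n_sets Number of image sets.
#' @param n_logins Parallel login slots.
#' @param n_reserved Slots reserved for data transfers (must be < `n_logins`).
#' @param efficiency Fraction of wall time the workers are busy, in `(0, 1]`.
#' @return A `throughput_model` object.
#' @export
throughput_model <- function(per_set_s, n_sets, n_logins, n_reserved = 0L,
                             efficiency = 1) {
  stopifnot(per_set_s > 0, n_sets >= 0, n_logins >= 1, n_reserved >= 0,
            n_reserved < n_logins, efficiency > 0, efficiency <= 1)
  structure(list(per_set_s = per_set_s, n_sets = n_sets, n_logins = n_logins,
                 n_reserved = n_reserved, efficiency = efficiency),
            class = "throughput_model")
}

#' Estimated campaign duration in days
#'
#' `days = per_set_s * n_sets / ((n_logins - n_reserved) * efficiency * 86400)`.
#' At 128 s per set, 134,611 sets and 11 effective logins (12 minus 1 reserved
#' for transfers) the estimate is 18.1 days at 100% efficiency and about 27.9
#' days at 65%.
#'
#' @param tm A [throughput_model()].
#' @return Days (numeric).
#' @export
estimate_days <- function(tm) {
  tm$per_set_s * tm$n_sets / ((tm$n_logins - tm$n_reserved) * tm$efficiency * 86400)
}

#' Total data size in decimal terabytes
#'
#' @param per_file_mb Megabytes per file (e.g. 97.8 for one macular volume in
#'   the vendor container).
#' @param n_files File count.
#' @return Terabytes (`per_file_mb * n_files / 1e6`).
#' @export
data_size_tb <- function(per_file_mb, n_files) {
  stopifnot(per_file_mb >= 0, n_files >= 0)
  per_file_mb * n_files / 1e6
}
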
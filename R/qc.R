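#' Quality-control thresholds
#'
#' @param min_q Minimum signal-strength score (0-100 scale).
#' @param min_ilm Minimum ILM indicator (edge-score units).
#' @param max_clipped_fraction Maximum fraction of invalid/clipped A-scan
#'   positions.
#' @param min_motion_corr Minimum inter-B-scan thickness correlation.
#' @return A `qc_thresholds` object.
#' @export
qc_thresholds <- function(min_q = 45, min_ilm = 0.1,
                          max_clipped_fraction = 0.05, min_motion_corr = 0.8) {
  stopifnot(max_clipped_fraction >= 0, max_clipped_fraction <= 1,
            min_motion_corr >= -1, min_motion_corr <= 1)
  structure(list(min_q = min_q, min_ilm = min_ilm,
                 max_clipped_fraction = max_clipped_fraction,
                 min_motion_corr = min_motion_corr), class = "qc_thresholds")
}

# Otsu threshold of intensities in [0, 1] on a fixed 256-bin histogram.
.otsu <- function(x, nbins = 256L) {
  h <- as.numeric(tabulate(pmin(floor(x * nbins) + 1L, nbins), nbins))
  w <- cumsum(h); total <- w[nbins]
  mids <- (seq_len(nbins) - 0.5) / nbins
  s <- cumsum(h * mids); stot <- s[nbins]
  w1 <- w[-nbins]; w2 <- total - w1
  keep <- w1 > 0 & w2 > 0
  if (!any(keep)) return(NA_real_)
  m1 <- s[-nbins] / w1; m2 <- (stot - s[-nbins]) / w2
  between <- w1 * w2 * (m1 - m2)^2
  between[!keep] <- -Inf
  mids[which.max(between)] + 0.5 / nbins
}

#' Image quality (signal strength) score
#'
#' A 0-100 score of signal-to-background contrast: the volume's intensities
#' are split by an Otsu threshold into signal (mean `S`) and background
#' (mean `B`), and the score is `100 / (1 + exp(-(S / max(B, floor) - k) / s))`.
#' The background floor keeps globally attenuated scans (blinks, occlusions)
#' from scoring as well as clean ones. A zero-variance volume scores 0.
#'
#' @param vol An [oct_volume()].
#' @param k,s Logistic midpoint and scale on the contrast-ratio axis.
#' @param floor Background noise floor on the `[0, 1]` intensity scale.
#' @return Scalar in `[0, 100]`.
#' @export
q_score <- function(vol, k = 3, s = 0.5, floor = 0.01) {
  stopifnot(inherits(vol, "oct_volume"))
  x <- as.numeric(vol$intensity)
  if (stats::var(x) == 0) return(0)
  thr <- .otsu(x)
  hi <- x[x > thr]; lo <- x[x <= thr]
  if (!length(hi) || !length(lo)) return(0)
  ratio <- mean(hi) / max(mean(lo), floor)
  100 / (1 + exp(-(ratio - k) / s))
}

#' ILM indicator: minimum localized edge strength along the ILM
#'
#' Each B-scan's traced ILM curve is split into `n_windows` lateral windows;
#' the indicator is the minimum over all windows of all B-scans of the mean
#' edge score at the traced ILM. Blinks and segmentation failures zero the
#' local ILM edge and pull the minimum down.
#'
#' @param bs A `boundary_set` from [segment_volume()] (which records the ILM
#'   edge strength), or any boundary set plus an explicit `ilm_edge` matrix.
#' @param n_windows Number of lateral windows per B-scan.
#' @param ilm_edge Optional `n_bscans x n_ascans` matrix overriding
#'   `bs$ilm_edge`.
#' @return Scalar (edge-score units).
#' @export
ilm_indicator <- function(bs, n_windows = 16L, ilm_edge = NULL) {
  e <- if (!is.null(ilm_edge)) ilm_edge else bs$ilm_edge
  if (is.null(e)) stop("boundary set carries no ILM edge strengths")
  nx <- ncol(e)
  win <- pmin(floor((seq_len(nx) - 1L) / (nx / n_windows)) + 1L, n_windows)
  worst <- Inf
  for (b in seq_len(nrow(e))) {
    means <- tapply(e[b, ], win, mean)
    worst <- min(worst, means)
  }
  as.numeric(worst)
}

#' Validity count: clipped or unplaceable surface positions
#'
#' Counts (B-scan, A-scan) positions where any of the nine surfaces is
#' invalid or lies within `margin_px` of the axial window limits, i.e. where
#' retinal tissue is clipped in the B-scan's z direction.
#'
#' @param bs A `boundary_set`.
#' @param margin_px Proximity to the axial limits counted as clipped.
#' @return `list(count =, fraction =)`.
#' @export
validity_count <- function(bs, margin_px = 2) {
  p <- bs$protocol
  z <- bs$depths_px
  bad <- !bs$valid | z < margin_px | z > p$n_depth - 1 - margin_px
  pos_bad <- colSums(bad) > 0            # n_ascans x n_bscans
  count <- sum(pos_bad)
  list(count = count, fraction = count / (p$n_bscans * p$n_ascans))
}

#' Motion indicators: worst inter-B-scan thickness correlation
#'
#' For every consecutive B-scan pair, computes the Pearson correlation of the
#' per-A-scan RNFL thickness profiles (boundaries 1-2) and of the total
#' retinal thickness profiles (boundaries 1-9), and returns the minimum of
#' each across the volume. Blinks, axial eye motion that clips content, and
#' segmentation failures decorrelate adjacent profiles. Zero-variance pairs
#' are skipped; if every pair is skipped the indicator is `NA`.
#'
#' Profiles are smoothed laterally with a moving average of `smooth_window`
#' A-scans before correlating, so the indicator measures scan-to-scan
#' consistency of the thickness structure rather than per-column tracing
#' jitter.
#'
#' @param bs A `boundary_set` (at least 3 B-scans).
#' @param smooth_window Lateral moving-average width in A-scans (odd; 1
#'   disables smoothing).
#' @return `list(corr_rnfl =, corr_total =)`.
#' @export
motion_indicators <- function(bs, smooth_window = 31L) {
  p <- bs$protocol
  if (p$n_bscans < 3L) stop("need at least 3 B-scans")
  rnfl <- t(bs$depths_px[2, , ] - bs$depths_px[1, , ])   # n_bscans x n_ascans
  total <- t(bs$depths_px[9, , ] - bs$depths_px[1, , ])
  if (smooth_window > 1L) {
    k <- rep(1 / smooth_window, smooth_window)
    smooth_rows <- function(m) t(.conv_cols_cpp(t(m), k))
    rnfl <- smooth_rows(rnfl); total <- smooth_rows(total)
  }
  worst <- function(m) {
    vals <- rep(NA_real_, nrow(m) - 1L)
    for (b in seq_len(nrow(m) - 1L)) {
      a <- m[b, ]; z <- m[b + 1L, ]
      if (stats::sd(a) == 0 || stats::sd(z) == 0) next
      vals[b] <- stats::cor(a, z)
    }
    if (all(is.na(vals))) NA_real_ else min(vals, na.rm = TRUE)
  }
  list(corr_rnfl = worst(rnfl), corr_total = worst(total))
}

#' Full QC report for one segmented volume
#'
#' @param vol The [oct_volume()].
#' @param bs Its `boundary_set` from [segment_volume()].
#' @param thresholds A [qc_thresholds()].
#' @return A `qc_report`: the four indices, per-index pass flags, and the
#'   overall `excluded` flag (the OR of the individual failures).
#' @export
qc_report <- function(vol, bs, thresholds = qc_thresholds()) {
  q <- q_score(vol)
  ilm <- ilm_indicator(bs)
  vc <- validity_count(bs)
  mo <- motion_indicators(bs)
  flags <- c(
    q_score = q >= thresholds$min_q,
    ilm_indicator = ilm >= thresholds$min_ilm,
    validity = vc$fraction <= thresholds$max_clipped_fraction,
    motion = !is.na(mo$corr_rnfl) && !is.na(mo$corr_total) &&
      min(mo$corr_rnfl, mo$corr_total) >= thresholds$min_motion_corr
  )
  structure(list(subject_id = bs$subject_id, laterality = bs$laterality,
                 q_score = q, ilm_indicator = ilm,
                 validity_count = vc$count, validity_fraction = vc$fraction,
                 motion_corr_rnfl = mo$corr_rnfl, motion_corr_total = mo$corr_total,
                 flags = flags, excluded = !all(flags)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report [%s, %s eye]\n", x$subject_id, x$laterality))
  cat(sprintf("  q_score          %6.1f  [%s]\n", x$q_score,
              if (x$flags["q_score"]) "pass" else "FAIL"))
  cat(sprintf("  ilm_indicator    %6.3f  [%s]\n", x$ilm_indicator,
              if (x$flags["ilm_indicator"]) "pass" else "FAIL"))
  cat(sprintf("  validity         %6.4f  [%s]\n", x$validity_fraction,
              if (x$flags["validity"]) "pass" else "FAIL"))
  cat(sprintf("  motion (rnfl/total) %.3f / %.3f  [%s]\n",
              x$motion_corr_rnfl, x$motion_corr_total,
              if (x$flags["motion"]) "pass" else "FAIL"))
  cat(sprintf("  excluded: %s\n", x$excluded))
  invisible(x)
}

#' Apply exclusion thresholds to a cohort of QC reports
#'
#' Re-evaluates each report against the given thresholds and partitions the
#' cohort into kept and excluded volumes, with per-index exclusion counts.
#' Exclusion is reported both per volume (eye) and per subject (a subject is
#' excluded if any of their volumes is).
#'
#' @param reports List of [qc_report()]s.
#' @param thresholds A [qc_thresholds()].
#' @return `list(kept =, excluded =, summary =)`; `summary` is a `data.frame`
#'   of per-index failure counts and fractions plus the overall row, and the
#'   result also carries `n_subjects_excluded`.
#' @export
apply_exclusions <- function(reports, thresholds = qc_thresholds()) {
  n <- length(reports)
  if (n == 0L)
    return(list(kept = list(), excluded = list(),
                summary = data.frame(index = character(), n_failed = integer(),
                                     fraction = numeric()),
                n_subjects_excluded = 0L))
  flag_mat <- t(vapply(reports, function(r) {
    c(q_score = r$q_score >= thresholds$min_q,
      ilm_indicator = r$ilm_indicator >= thresholds$min_ilm,
      validity = r$validity_fraction <= thresholds$max_clipped_fraction,
      motion = !is.na(r$motion_corr_rnfl) && !is.na(r$motion_corr_total) &&
        min(r$motion_corr_rnfl, r$motion_corr_total) >= thresholds$min_motion_corr)
  }, logical(4)))
  excluded <- !apply(flag_mat, 1, all)
  fails <- colSums(!flag_mat)
  summary <- data.frame(
    index = c(colnames(flag_mat), "overall"),
    n_failed = c(as.integer(fails), sum(excluded)),
    fraction = c(fails, sum(excluded)) / n
  )
  subj <- vapply(reports, function(r) r$subject_id, character(1))
  n_subj_excl <- length(unique(subj[excluded]))
  list(kept = reports[!excluded], excluded = reports[excluded],
       summary = summary, n_subjects_excluded = n_subj_excl)
}
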
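#' Re-center the fall label window on the acceleration peak
#'
#' Button-press labels collected in real time are noisy: the press can come
#' too early, too late, or last too long. This post-processing step enforces
#' the convention that the fall window is exactly `width` contiguous samples
#' centered on the sample of maximum acceleration magnitude; everything else
#' becomes not-fall. At the recording boundaries the window is shifted
#' inward so the full width is preserved. Argmax ties break to the earliest
#' index.
#'
#' @param rec a [recording()].
#' @param width fall window width in samples (default 100).
#' @return A relabeled [recording()] with exactly `width` fall labels.
#' @export
relabel_fall_peak <- function(rec, width = 100L) {
  stopifnot(inherits(rec, "recording"), width >= 1)
  n <- nrow(rec)
  if (width > n) {
    stop("fall window width (", width, ") exceeds recording length (", n,
         ")", call. = FALSE)
  }
  center <- which.max(magnitude(rec)) # earliest tie
  start <- center - width %/% 2L
  start <- max(1L, min(start, n - width + 1L))
  lab <- rep(0L, n)
  lab[start:(start + width - 1L)] <- 1L
  df <- rec
  df$label <- lab
  with_samples(rec, df)
}

#' Locate multiple fall peaks in a multi-trial recording
#'
#' Greedy non-maximum suppression: repeatedly take the highest-magnitude
#' sample still available, then exclude all indices closer than `width` to
#' it. Returns the `n_trials` selected centers sorted ascending; they are
#' pairwise at least `width` samples apart.
#'
#' @param rec a [recording()].
#' @param n_trials number of fall trials expected in the file.
#' @param width exclusion width in samples (default 35, the programmatic
#'   labeler's convention).
#' @return Integer vector of `n_trials` sample indices (1-based).
#' @export
locate_fall_peaks <- function(rec, n_trials, width = 35L) {
  stopifnot(inherits(rec, "recording"), n_trials >= 1, width >= 1)
  n <- nrow(rec)
  if (n < n_trials * width) {
    stop("recording too short (", n, " samples) to host ", n_trials,
         " non-overlapping windows of width ", width, call. = FALSE)
  }
  mag <- magnitude(rec)
  available <- rep(TRUE, n)
  centers <- integer(0)
  for (k in seq_len(n_trials)) {
    if (!any(available)) {
      stop("no candidate sample left for trial ", k,
           " after exclusion; fewer than ", n_trials,
           " separable peaks present", call. = FALSE)
    }
    cand <- which(available)
    c_k <- cand[which.max(mag[cand])]
    centers <- c(centers, c_k)
    excl <- max(1L, c_k - width + 1L):min(n, c_k + width - 1L)
    available[excl] <- FALSE
  }
  sort(centers)
}

#' Trim an ADL recording to the smallest multiple of the unit length
#'
#' Activities of daily living are recorded with slack before and after the
#' movement. The activity span is taken as the first through last sample
#' whose magnitude deviates from the recording's median magnitude by more
#' than `threshold` g; the recording is then cut to the smallest multiple of
#' `unit` samples that covers that span, centered on it (shifted inward at
#' the boundaries). All labels in the result are not-fall.
#'
#' @param rec a [recording()].
#' @param unit length quantum in samples (default 100).
#' @param threshold activity-detection deviation from the median magnitude,
#'   in g (default 0.05).
#' @return A trimmed [recording()] whose length is
#'   `unit * ceiling(span / unit)` (capped at the recording length).
#' @export
trim_adl <- function(rec, unit = 100L, threshold = 0.05) {
  stopifnot(inherits(rec, "recording"), unit >= 1)
  mag <- magnitude(rec)
  dev <- abs(mag - stats::median(mag))
  active <- which(dev > threshold)
  if (length(active) == 0) {
    stop("no activity detected: all samples within ", threshold,
         " g of the median magnitude", call. = FALSE)
  }
  n <- nrow(rec)
  span <- c(active[1], active[length(active)])
  span_len <- span[2] - span[1] + 1L
  out_len <- min(n, unit * as.integer(ceiling(span_len / unit)))
  center <- (span[1] + span[2]) %/% 2L
  start <- center - out_len %/% 2L
  start <- max(1L, min(start, n - out_len + 1L))
  df <- rec[start:(start + out_len - 1L), , drop = FALSE]
  df$label <- 0L
  with_samples(rec, df)
}

#' Split a multi-trial file into individual trial recordings
#'
#' Fall files are split at the midpoints between consecutive peak centers
#' found by [locate_fall_peaks()]; ADL files are split at equal-length
#' boundaries. The pieces cover the input exactly once, in order.
#'
#' @param rec a [recording()].
#' @param n_trials number of trials in the file.
#' @param kind `"fall"` or `"adl"`; the default `"auto"` chooses `"fall"`
#'   when any sample is fall-labeled.
#' @param width peak exclusion width passed to [locate_fall_peaks()].
#' @return List of `n_trials` [recording()] objects.
#' @export
segment_trials <- function(rec, n_trials, kind = c("auto", "fall", "adl"),
                           width = 35L) {
  kind <- match.arg(kind)
  stopifnot(inherits(rec, "recording"), n_trials >= 1)
  n <- nrow(rec)
  if (kind == "auto") kind <- if (any(rec$label == 1)) "fall" else "adl"
  if (n_trials == 1) return(list(rec))
  if (kind == "fall") {
    centers <- locate_fall_peaks(rec, n_trials, width = width)
    cuts <- floor((centers[-1] + centers[-n_trials]) / 2)
  } else {
    cuts <- floor(n * seq_len(n_trials - 1) / n_trials)
  }
  bounds <- c(0L, as.integer(cuts), n)
  lapply(seq_len(n_trials), function(k) {
    df <- rec[(bounds[k] + 1L):bounds[k + 1L], , drop = FALSE]
    with_samples(rec, df)
  })
}
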
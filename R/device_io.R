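#' Device profiles for heterogeneous wrist sensors
#'
#' A device profile describes the hardware a recording came from: its
#' sampling rate, the multiplicative constant converting raw sensor units to
#' g, which wrists the device is worn on, and the per-device default
#' hyperparameters (window, step, smoothing window and fall threshold) that
#' the classifier uses for that hardware.
#'
#' Three profiles ship with the package:
#' \describe{
#'   \item{`"msband"`}{32 Hz, raw units already in g (scale 1).}
#'   \item{`"huawei"`}{32 Hz, raw units in g (scale 1).}
#'   \item{`"metasensor"`}{50 Hz, raw units of 2 g (scale 2), worn on either
#'     wrist.}
#' }
#'
#' @param name profile name, one of `"msband"`, `"huawei"`, `"metasensor"`,
#'   or any identifier when the remaining fields are given explicitly.
#' @param sampling_hz samples per second; defaults to the named device's rate.
#' @param unit_scale multiplier applied at read time so that x, y, z are in g.
#' @param wrists character subset of `c("left", "right")`.
#' @param hparams [hyperparameters()] defaults for this device; when `NULL`
#'   they are derived from the sampling rate (window = 1 s of samples,
#'   step 1, smooth window = 2 s of samples, threshold 0.4).
#' @return An object of class `device_profile`.
#' @examples
#' device_profile("metasensor")
#' @export
device_profile <- function(name, sampling_hz = NULL, unit_scale = NULL,
                           wrists = NULL, hparams = NULL) {
  builtin <- list(
    msband     = list(sampling_hz = 32, unit_scale = 1.0, wrists = "left"),
    huawei     = list(sampling_hz = 32, unit_scale = 1.0, wrists = "left"),
    metasensor = list(sampling_hz = 50, unit_scale = 2.0,
                      wrists = c("left", "right"))
  )
  base <- builtin[[name]]
  if (is.null(base) && (is.null(sampling_hz) || is.null(unit_scale))) {
    stop("unknown device profile '", name,
         "'; supply sampling_hz and unit_scale explicitly", call. = FALSE)
  }
  sampling_hz <- sampling_hz %||% base$sampling_hz
  unit_scale <- unit_scale %||% base$unit_scale
  wrists <- wrists %||% base$wrists %||% "left"
  stopifnot(sampling_hz > 0, unit_scale > 0,
            all(wrists %in% c("left", "right")))
  if (is.null(hparams)) {
    hparams <- hyperparameters(
      window_size = round(sampling_hz),
      step_size = 1,
      smooth_window = 2L * round(sampling_hz),
      fall_threshold = 0.4
    )
  }
  stopifnot(hparams$window_size == round(sampling_hz))
  structure(list(name = name, sampling_hz = sampling_hz,
                 unit_scale = unit_scale, wrists = wrists,
                 default_hparams = hparams),
            class = "device_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.device_profile <- function(x, ...) {
  cat(sprintf("<device_profile '%s': %g Hz, unit scale %g, wrists: %s>\n",
              x$name, x$sampling_hz, x$unit_scale,
              paste(x$wrists, collapse = "/")))
  invisible(x)
}

#' Construct a labeled tri-axial accelerometer recording
#'
#' A recording is one subject/wrist/activity trial: a strictly time-ordered
#' sequence of tri-axial samples in g, each carrying a binary fall label.
#'
#' @param t_ms integer-ish milliseconds since recording start, strictly
#'   increasing.
#' @param x,y,z acceleration per axis, in g.
#' @param label binary vector (1 = fall, 0 = not fall).
#' @param profile a [device_profile()].
#' @param subject_id,wrist,activity recording metadata.
#' @return An object of class `recording` (a data frame of samples with
#'   metadata attributes).
#' @export
recording <- function(t_ms, x, y, z, label = rep(0L, length(t_ms)),
                      profile = device_profile("msband"),
                      subject_id = "s1", wrist = "left",
                      activity = "unknown") {
  n <- length(t_ms)
  stopifnot(length(x) == n, length(y) == n, length(z) == n,
            length(label) == n)
  if (n == 0L) stop("a recording must contain at least one sample",
                    call. = FALSE)
  if (any(!is.finite(c(x, y, z)))) {
    stop("non-finite acceleration values", call. = FALSE)
  }
  if (!all(label %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  d <- diff(t_ms)
  if (any(d <= 0)) {
    stop(sprintf("timestamps not strictly increasing at row %d",
                 which(d <= 0)[1] + 1L), call. = FALSE)
  }
  df <- data.frame(t_ms = as.numeric(t_ms), x = as.numeric(x),
                   y = as.numeric(y), z = as.numeric(z),
                   label = as.integer(label))
  structure(df, class = c("recording", "data.frame"),
            profile = profile, subject_id = subject_id, wrist = wrist,
            activity = activity)
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording %s/%s '%s': %d samples @ %g Hz, %d fall-labeled>\n",
    attr(x, "subject_id"), attr(x, "wrist"), attr(x, "activity"),
    nrow(x), attr(x, "profile")$sampling_hz, sum(x$label)))
  invisible(x)
}

rec_meta <- function(rec) {
  list(profile = attr(rec, "profile"), subject_id = attr(rec, "subject_id"),
       wrist = attr(rec, "wrist"), activity = attr(rec, "activity"))
}

with_samples <- function(rec, df) {
  m <- rec_meta(rec)
  recording(df$t_ms, df$x, df$y, df$z, df$label, profile = m$profile,
            subject_id = m$subject_id, wrist = m$wrist,
            activity = m$activity)
}

#' Euclidean acceleration magnitude
#'
#' @param x a `recording`, or a numeric vector/matrix of axis values.
#' @return numeric vector of `sqrt(x^2 + y^2 + z^2)` per sample, in g.
#' @examples
#' magnitude(cbind(3, 4, 0)) # 5
#' @export
magnitude <- function(x) {
  if (inherits(x, "recording")) {
    sqrt(x$x^2 + x$y^2 + x$z^2)
  } else {
    m <- matrix(x, ncol = 3)
    sqrt(rowSums(m^2))
  }
}

#' Read a labeled accelerometer CSV
#'
#' Expects a header `t_ms,x,y,z,label`. Axis values are multiplied by
#' `profile$unit_scale` so the in-memory recording is in g regardless of the
#' device's raw units. The label column may be numeric 0/1 or activity
#' strings, in which case `"Fall"` (case-insensitive) maps to 1 and anything
#' else to 0.
#'
#' @param path CSV file path.
#' @param profile [device_profile()] the file was recorded with.
#' @param subject_id,wrist,activity metadata; defaults are parsed from the
#'   conventional `<dataset>/<subject>/<wrist>/<activity>_<trial>.csv` layout
#'   when possible.
#' @return A [recording()].
#' @export
read_recording <- function(path, profile, subject_id = NULL, wrist = NULL,
                           activity = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_ms", "x", "y", "z", "label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("malformed recording CSV '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lab <- df$label
  if (!is.numeric(lab)) {
    lab <- ifelse(tolower(trimws(as.character(lab))) == "fall", 1L, 0L)
  }
  parts <- rev(strsplit(normalizePath(path, mustWork = FALSE), "/")[[1]])
  fname <- sub("\\.csv$", "", parts[1])
  recording(df$t_ms,
            df$x * profile$unit_scale,
            df$y * profile$unit_scale,
            df$z * profile$unit_scale,
            lab, profile = profile,
            subject_id = subject_id %||% (if (length(parts) >= 3) parts[3] else "s1"),
            wrist = wrist %||% (if (length(parts) >= 2 &&
                                    parts[2] %in% c("left", "right"))
                                  parts[2] else "left"),
            activity = activity %||% sub("_[0-9]+$", "", fname))
}

#' Write a recording back to the CSV dialect
#'
#' Axis values are divided by the profile's unit scale so that
#' `read_recording(write_recording(rec))` round-trips: timestamps and labels
#' exactly, axis values to about 1e-6 g (values are printed with 6 decimals).
#'
#' @param rec a [recording()].
#' @param path output file path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  scale <- attr(rec, "profile")$unit_scale
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(
    t_ms = format(rec$t_ms, trim = TRUE, scientific = FALSE),
    x = sprintf("%.6f", rec$x / scale),
    y = sprintf("%.6f", rec$y / scale),
    z = sprintf("%.6f", rec$z / scale),
    label = rec$label)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a recording onto a uniform grid
#'
#' Linear interpolation of each axis onto a uniform grid at `target_hz`
#' spanning the original time range; the label of each new sample is copied
#' from the nearest original sample. The output has
#' `floor(duration_s * target_hz) + 1` samples.
#'
#' @param rec a [recording()] with at least 2 samples.
#' @param target_hz target sampling rate (> 0).
#' @return A resampled [recording()]; the attached profile's `sampling_hz`
#'   is updated to `target_hz`.
#' @export
resample <- function(rec, target_hz) {
  stopifnot(inherits(rec, "recording"))
  if (target_hz <= 0) stop("target_hz must be > 0", call. = FALSE)
  if (nrow(rec) < 2) stop("resample needs at least 2 samples", call. = FALSE)
  t0 <- rec$t_ms[1]
  t1 <- rec$t_ms[nrow(rec)]
  dur_s <- (t1 - t0) / 1000
  n_out <- floor(dur_s * target_hz) + 1
  tt <- t0 + (seq_len(n_out) - 1) * 1000 / target_hz
  ax <- function(v) stats::approx(rec$t_ms, v, xout = tt)$y
  # nearest original sample for the label
  nearest <- vapply(tt, function(t) which.min(abs(rec$t_ms - t)), integer(1))
  m <- rec_meta(rec)
  prof <- m$profile
  prof$sampling_hz <- target_hz
  recording(tt, ax(rec$x), ax(rec$y), ax(rec$z), rec$label[nearest],
            profile = prof, subject_id = m$subject_id, wrist = m$wrist,
            activity = m$activity)
}

#' Bundle recordings into a dataset
#'
#' A dataset groups recordings by subject; it is the unit that splits,
#' cross-validation folds and the transfer protocol operate on. All
#' recordings must share one device profile.
#'
#' @param recordings list of [recording()] objects.
#' @return An object of class `fall_dataset`.
#' @export
fall_dataset <- function(recordings) {
  stopifnot(length(recordings) > 0,
            all(vapply(recordings, inherits, logical(1), "recording")))
  devs <- unique(vapply(recordings,
                        function(r) attr(r, "profile")$name, character(1)))
  if (length(devs) != 1) {
    stop("all recordings in a dataset must share one device profile; got: ",
         paste(devs, collapse = ", "), call. = FALSE)
  }
  structure(list(recordings = recordings), class = "fall_dataset")
}

#' @export
print.fall_dataset <- function(x, ...) {
  subj <- dataset_subjects(x)
  nfall <- sum(vapply(x$recordings, function(r) any(r$label == 1), logical(1)))
  cat(sprintf("<fall_dataset: %d recordings (%d with falls), %d subjects [%s]>\n",
              length(x$recordings), nfall, length(subj),
              paste(subj, collapse = ", ")))
  invisible(x)
}

#' @rdname fall_dataset
#' @param ds a `fall_dataset`.
#' @export
dataset_subjects <- function(ds) {
  sort(unique(vapply(ds$recordings, attr, character(1), "subject_id")))
}

#' @rdname fall_dataset
#' @param wrist `"left"` or `"right"`.
#' @export
dataset_wrist <- function(ds, wrist) {
  keep <- vapply(ds$recordings, function(r) attr(r, "wrist") == wrist,
                 logical(1))
  fall_dataset(ds$recordings[keep])
}

subset_dataset <- function(ds, keep) fall_dataset(ds$recordings[keep])

#' Read / write a dataset directory
#'
#' Directory layout: `<root>/<subject_id>/<wrist>/<activity>_<trial>.csv`,
#' one CSV per trial in the dialect of [read_recording()].
#'
#' @param root dataset directory.
#' @param profile [device_profile()] used for every file.
#' @return `read_dataset`: a [fall_dataset()]; `write_dataset`: `root`,
#'   invisibly.
#' @export
read_dataset <- function(root, profile) {
  files <- sort(list.files(root, pattern = "\\.csv$", recursive = TRUE,
                           full.names = TRUE))
  if (length(files) == 0) stop("no CSV files under ", root, call. = FALSE)
  fall_dataset(lapply(files, read_recording, profile = profile))
}

#' @rdname read_dataset
#' @param ds a [fall_dataset()].
#' @export
write_dataset <- function(ds, root) {
  for (rec in ds$recordings) {
    sub <- attr(rec, "subject_id")
    wr <- attr(rec, "wrist")
    act <- attr(rec, "activity")
    dir <- file.path(root, sub, wr)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    k <- length(list.files(dir, pattern = paste0("^", act, "_[0-9]+\\.csv$")))
    write_recording(rec, file.path(dir, sprintf("%s_%d.csv", act, k + 1L)))
  }
  invisible(root)
}
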
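#' Classifier hyperparameters
#'
#' The four knobs that govern how a stream is classified:
#' \describe{
#'   \item{`window_size`}{number of consecutive samples per data block (the
#'     classifier input is a `window_size x 3` tensor). The per-device
#'     optimum is one second of samples: 32 at 32 Hz, 50 at 50 Hz.}
#'   \item{`step_size`}{offset between consecutive blocks; consecutive
#'     blocks overlap by `window_size - step_size` samples. Optimum 1.}
#'   \item{`smooth_window`}{number of trailing block probabilities whose
#'     median is the emitted fall probability; about two seconds of samples
#'     (64 at 32 Hz, 100 at 50 Hz) works best.}
#'   \item{`fall_threshold`}{probability cutoff; a smoothed probability
#'     strictly above it is declared a fall. Optimum 0.4.}
#' }
#'
#' @param window_size samples per block (>= 1).
#' @param step_size block stride, `1 <= step_size <= window_size`.
#' @param smooth_window trailing median length in blocks (>= 1).
#' @param fall_threshold decision cutoff in (0, 1).
#' @return An object of class `hyperparameters`.
#' @export
hyperparameters <- function(window_size, step_size = 1L,
                            smooth_window = 2L * window_size,
                            fall_threshold = 0.4) {
  stopifnot(window_size >= 1, step_size >= 1, step_size <= window_size,
            smooth_window >= 1, fall_threshold > 0, fall_threshold < 1)
  structure(list(window_size = as.integer(window_size),
                 step_size = as.integer(step_size),
                 smooth_window = as.integer(smooth_window),
                 fall_threshold = fall_threshold),
            class = "hyperparameters")
}

#' @export
print.hyperparameters <- function(x, ...) {
  cat(sprintf("<hyperparameters: W=%d S=%d K=%d threshold=%g>\n",
              x$window_size, x$step_size, x$smooth_window,
              x$fall_threshold))
  invisible(x)
}

#' Cut a recording into overlapping fixed-size data blocks
#'
#' Blocks start at sample offsets `0, step, 2*step, ...`; a recording of `N`
#' samples yields `floor((N - W) / S) + 1` blocks for `N >= W` and none
#' otherwise. Each block carries a binary label: fall when at least half of
#' its samples are fall-labeled (see [block_label()]).
#'
#' @param rec a [recording()].
#' @param hp [hyperparameters()].
#' @return A `block_set`: list with `x` (array `W x 3 x n_blocks`), `label`
#'   (integer vector), `start_index` (0-based sample offsets),
#'   `window_size`, `step_size`.
#' @export
make_blocks <- function(rec, hp) {
  stopifnot(inherits(rec, "recording"), inherits(hp, "hyperparameters"))
  W <- hp$window_size
  S <- hp$step_size
  n <- nrow(rec)
  if (n < W) {
    return(block_set(array(0, dim = c(W, 3, 0)), integer(0), integer(0),
                     W, S))
  }
  starts <- seq.int(0L, n - W, by = S)
  nb <- length(starts)
  xmat <- as.matrix(rec[, c("x", "y", "z")])
  xarr <- array(0, dim = c(W, 3, nb))
  labs <- integer(nb)
  for (i in seq_len(nb)) {
    idx <- (starts[i] + 1L):(starts[i] + W)
    xarr[, , i] <- xmat[idx, ]
    labs[i] <- block_label(rec$label[idx])
  }
  block_set(xarr, labs, starts, W, S)
}

#' @rdname make_blocks
#' @param x array `W x 3 x n` of axis values in g.
#' @param label integer block labels.
#' @param start_index 0-based start offsets.
#' @param window_size,step_size the block geometry.
#' @export
block_set <- function(x, label, start_index, window_size, step_size = 1L) {
  stopifnot(length(dim(x)) == 3, dim(x)[1] == window_size, dim(x)[2] == 3,
            dim(x)[3] == length(label), length(start_index) == length(label))
  structure(list(x = x, label = as.integer(label),
                 start_index = as.integer(start_index),
                 window_size = as.integer(window_size),
                 step_size = as.integer(step_size)),
            class = "block_set")
}

#' @export
length.block_set <- function(x) dim(x$x)[3]

#' @export
print.block_set <- function(x, ...) {
  cat(sprintf("<block_set: %d blocks of %d x 3, step %d, %d fall-labeled>\n",
              length(x), x$window_size, x$step_size, sum(x$label)))
  invisible(x)
}

#' Concatenate block sets (identical geometry required)
#' @param sets list of `block_set` objects.
#' @return a single `block_set`.
#' @export
bind_blocks <- function(sets) {
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  if (length(sets) == 0) stop("no non-empty block sets", call. = FALSE)
  W <- unique(vapply(sets, function(b) b$window_size, integer(1)))
  if (length(W) != 1) {
    stop("mixed window sizes: ", paste(W, collapse = ", "), call. = FALSE)
  }
  S <- sets[[1]]$step_size
  xs <- array(unlist(lapply(sets, function(b) b$x)),
              dim = c(W, 3, sum(vapply(sets, length, integer(1)))))
  block_set(xs, unlist(lapply(sets, function(b) b$label)),
            unlist(lapply(sets, function(b) b$start_index)), W, S)
}

#' Resample every block onto a different window length
#'
#' Linear interpolation along the time axis of each block, mapping
#' `window_size` samples onto `width_to`. Used for rate-aligned transfer:
#' a model trained at one sampling rate can consume blocks recorded at
#' another with its per-step time scale preserved. Labels, start indices and
#' step size are unchanged.
#'
#' @param blocks a `block_set`.
#' @param width_to target number of samples per block.
#' @return A `block_set` with `window_size = width_to`.
#' @export
resample_blocks <- function(blocks, width_to) {
  stopifnot(inherits(blocks, "block_set"), width_to >= 1)
  W <- blocks$window_size
  if (W == width_to) return(blocks)
  if (length(blocks) == 0) {
    return(block_set(array(0, dim = c(width_to, 3, 0)), integer(0),
                     integer(0), width_to, blocks$step_size))
  }
  if (W == 1L) {
    xs <- blocks$x[rep(1L, width_to), , , drop = FALSE]
  } else {
    pos <- seq(1, W, length.out = width_to)
    lo <- pmin(floor(pos), W - 1L)
    w <- pos - lo
    xs <- blocks$x[lo, , , drop = FALSE] * (1 - w) +
      blocks$x[lo + 1L, , , drop = FALSE] * w
  }
  block_set(xs, blocks$label, blocks$start_index, width_to,
            blocks$step_size)
}

#' Majority label of a block
#'
#' @param entry_labels nonempty binary vector of per-sample labels.
#' @return 1 when at least 50% of the samples are fall-labeled, else 0.
#' @export
block_label <- function(entry_labels) {
  stopifnot(length(entry_labels) > 0)
  as.integer(mean(entry_labels) >= 0.5)
}

#' Trailing-median smoothing of block probabilities
#'
#' The emitted fall probability at block `i` is the median of the last
#' `smooth_window` block probabilities (`i - K + 1 .. i`). During warm-up
#' (`i < K`) the median is over the available prefix. The median of an even
#' count is the mean of the two central order statistics.
#'
#' @param block_probs numeric vector of per-block probabilities in \[0, 1\].
#' @param hp [hyperparameters()] (only `smooth_window` is used).
#' @return Numeric vector, same length as the input.
#' @export
smooth_predict <- function(block_probs, hp) {
  stopifnot(all(block_probs >= 0 & block_probs <= 1))
  K <- hp$smooth_window
  if (K == 1L || length(block_probs) == 0) return(block_probs)
  vapply(seq_along(block_probs), function(i) {
    stats::median(block_probs[max(1L, i - K + 1L):i])
  }, numeric(1))
}

#' Threshold a smoothed probability into a fall decision
#'
#' @param prob probabilities in \[0, 1\].
#' @param hp [hyperparameters()] (only `fall_threshold` is used).
#' @return Integer 0/1 vector: 1 iff `prob > fall_threshold` (strict).
#' @export
classify <- function(prob, hp) {
  stopifnot(all(prob >= 0 & prob <= 1))
  as.integer(prob > hp$fall_threshold)
}
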
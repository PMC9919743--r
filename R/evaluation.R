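#' F1 score of binary predictions
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`, defined as 0 when the denominator is 0.
#'
#' @param pred,truth equal-length binary vectors.
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(pred, truth) {
  cm <- confusion_counts(pred, truth)
  den <- 2 * cm$tp + cm$fp + cm$fn
  if (den == 0) 0 else 2 * cm$tp / den
}

confusion_counts <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("pred and truth lengths differ (", length(pred), " vs ",
         length(truth), ")", call. = FALSE)
  }
  list(tp = sum(pred == 1 & truth == 1), fp = sum(pred == 1 & truth == 0),
       fn = sum(pred == 0 & truth == 1), tn = sum(pred == 0 & truth == 0))
}

#' Precision-recall curve and its area
#'
#' Sweeps the decision threshold over the unique predicted probabilities
#' (predicting positive at `prob >= threshold`), computes precision and
#' recall at each, sorts by recall and integrates precision over recall with
#' the trapezoidal rule after prepending a `(recall = 0)` point that carries
#' the first point's precision. Thresholds with undefined precision (no
#' positive predictions) are dropped.
#'
#' @param probs probabilities in \[0, 1\].
#' @param truth binary vector.
#' @return List with `points` (data frame `recall`, `precision`,
#'   `threshold`) and `auc`.
#' @export
pr_curve <- function(probs, truth) {
  stopifnot(length(probs) == length(truth),
            all(probs >= 0 & probs <= 1))
  if (length(unique(truth)) < 2) {
    warning("single-class truth: PR curve is degenerate", call. = FALSE)
  }
  npos <- sum(truth == 1)
  pts <- do.call(rbind, lapply(sort(unique(probs), decreasing = TRUE),
    function(th) {
      pred <- as.integer(probs >= th)
      npp <- sum(pred == 1)
      if (npp == 0) return(NULL)
      tp <- sum(pred == 1 & truth == 1)
      data.frame(recall = if (npos == 0) NA_real_ else tp / npos,
                 precision = tp / npp, threshold = th)
    }))
  if (is.null(pts) || all(is.na(pts$recall))) {
    return(list(points = data.frame(recall = numeric(0),
                                    precision = numeric(0),
                                    threshold = numeric(0)),
                auc = NA_real_))
  }
  pts <- pts[order(pts$recall, -pts$precision), ]
  rec <- c(0, pts$recall)
  prec <- c(pts$precision[1], pts$precision)
  auc <- sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Assemble an evaluation report
#'
#' @param probs smoothed per-block probabilities.
#' @param truth per-block truth labels.
#' @param hp [hyperparameters()] providing the fall threshold.
#' @param trace_extra optional data frame columns bound into the trace.
#' @return An `eval_report`: `f1`, `precision`, `recall`, `confusion`,
#'   `pr_points`, `auc`, `n_events_pred`, `n_events_true` and a `trace` data
#'   frame (one row per block: truth, probability, decision).
#' @export
eval_report <- function(probs, truth, hp, trace_extra = NULL) {
  pred <- classify(probs, hp)
  cm <- confusion_counts(pred, truth)
  precision <- if (cm$tp + cm$fp == 0) 0 else cm$tp / (cm$tp + cm$fp)
  recall <- if (cm$tp + cm$fn == 0) 0 else cm$tp / (cm$tp + cm$fn)
  pr <- if (length(probs) > 0 && length(unique(truth)) == 2) {
    pr_curve(probs, truth)
  } else {
    list(points = NULL, auc = NA_real_)
  }
  trace <- data.frame(truth = truth, prob = probs, pred = pred)
  if (!is.null(trace_extra)) trace <- cbind(trace, trace_extra)
  structure(list(f1 = f1_score(pred, truth), precision = precision,
                 recall = recall, confusion = cm, pr_points = pr$points,
                 auc = pr$auc, n_events_pred = detect_events(pred),
                 n_events_true = detect_events(truth), trace = trace),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<eval_report: F1 %.3f, precision %.3f, recall %.3f, PR-AUC %s,\n",
    "  %d blocks, events predicted/true: %d/%d>\n"),
    x$f1, x$precision, x$recall,
    if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc),
    nrow(x$trace), x$n_events_pred, x$n_events_true))
  invisible(x)
}

#' Count discrete fall alerts in a decision sequence
#'
#' Each maximal run of consecutive positive decisions counts as one event.
#'
#' @param pred binary vector.
#' @return Integer event count.
#' @export
detect_events <- function(pred) {
  if (length(pred) == 0) return(0L)
  r <- rle(as.integer(pred))
  sum(r$values == 1)
}

#' Person-aware 70/30 train/test split
#'
#' Every subject contributes to both splits: each subject's recordings are
#' partitioned (at the recording level, never splitting a recording, so
#' overlapping windows cannot leak across the split) so that the training
#' share of that subject's samples is as close as possible to
#' `train_fraction`.
#'
#' @param ds a [fall_dataset()].
#' @param train_fraction fraction of each subject's data for training.
#' @param seed split seed.
#' @return List with `train` and `test` datasets.
#' @export
split_per_person <- function(ds, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(ds, "fall_dataset"),
            train_fraction > 0, train_fraction < 1)
  subj <- vapply(ds$recordings, attr, character(1), "subject_id")
  sizes <- vapply(ds$recordings, nrow, integer(1))
  in_train <- logical(length(ds$recordings))
  withr_seed(seed, {
    for (s in unique(subj)) {
      idx <- which(subj == s)
      if (length(idx) == 1) {
        warning("subject '", s, "' has a single recording; it goes to train",
                call. = FALSE)
        in_train[idx] <- TRUE
        next
      }
      ord <- sample(idx)
      cum <- cumsum(sizes[ord]) / sum(sizes[ord])
      # prefix whose sample share is closest to the target fraction
      k <- which.min(abs(cum - train_fraction))
      k <- min(max(k, 1L), length(ord) - 1L) # both splits nonempty
      in_train[ord[seq_len(k)]] <- TRUE
    }
  })
  list(train = subset_dataset(ds, in_train),
       test = subset_dataset(ds, !in_train))
}

#' Leave-one-person-out cross-validation folds
#'
#' One fold per subject: the held-out subject's recordings form the test
#' set, everyone else's the training set. Folds are exhaustive and their
#' test sets partition the dataset.
#'
#' @param ds a [fall_dataset()] with at least 2 subjects.
#' @return Named list of folds, each `list(train, test, subject)`.
#' @export
lopo_folds <- function(ds) {
  stopifnot(inherits(ds, "fall_dataset"))
  subs <- dataset_subjects(ds)
  if (length(subs) < 2) {
    stop("leave-one-person-out needs at least 2 subjects", call. = FALSE)
  }
  subj <- vapply(ds$recordings, attr, character(1), "subject_id")
  folds <- lapply(subs, function(s) {
    list(train = subset_dataset(ds, subj != s),
         test = subset_dataset(ds, subj == s),
         subject = s)
  })
  names(folds) <- subs
  folds
}

#' Run the full streaming pipeline over recordings and score it
#'
#' For each recording: cut into blocks, predict per-block probabilities,
#' smooth them with the trailing median window (smoothing never crosses
#' recording boundaries), threshold, and score against the majority block
#' labels. Traces of all recordings are concatenated into one report.
#'
#' The trailing median emitted at block `i` summarizes blocks
#' `i - K + 1 .. i`, so in a stream it rises roughly `K/2` blocks after the
#' event it detects. Scoring the emission-time sequence against time-aligned
#' truth would penalize this fixed detection latency (capping F1 well below
#' 1 for any perfect detector whose positive runs are not much longer than
#' `K`). The report therefore scores the smoothed probability against the
#' truth at the center of its smoothing window: each truth label at block
#' `i` is compared with the smoothed value emitted at `i + (K - 1) %/% 2`
#' (clamped at the end of the recording). The trace keeps the aligned
#' probabilities used for scoring.
#'
#' @param model a `fall_model` or a [wrist_ensemble()].
#' @param recordings a [fall_dataset()], a list of recordings, or a single
#'   [recording()]. For an ensemble, a list of two datasets
#'   `list(left = ..., right = ...)` with time-aligned recordings.
#' @param hp [hyperparameters()].
#' @return An [eval_report()].
#' @export
evaluate_stream <- function(model, recordings, hp) {
  if (inherits(model, "wrist_ensemble")) {
    return(evaluate_stream_ensemble(model, recordings, hp))
  }
  recs <- as_recording_list(recordings)
  pieces <- lapply(recs, function(rec) {
    blocks <- make_blocks(rec, hp)
    if (length(blocks) == 0) return(NULL)
    probs <- align_lag(smooth_predict(predict_blocks(model, blocks), hp), hp)
    data.frame(truth = blocks$label, prob = probs,
               start_index = blocks$start_index,
               subject = attr(rec, "subject_id"),
               activity = attr(rec, "activity"))
  })
  tr <- do.call(rbind, pieces)
  if (is.null(tr)) stop("no recording long enough to form a block",
                        call. = FALSE)
  eval_report(tr$prob, tr$truth, hp,
              trace_extra = tr[, c("start_index", "subject", "activity")])
}

# undo the fixed detection latency of the trailing median: pair the truth
# at block i with the smoothed value whose window is centered there
align_lag <- function(smoothed, hp) {
  n <- length(smoothed)
  if (n == 0) return(smoothed)
  lag <- (hp$smooth_window - 1L) %/% 2L
  smoothed[pmin(n, seq_len(n) + lag)]
}

as_recording_list <- function(x) {
  if (inherits(x, "fall_dataset")) return(x$recordings)
  if (inherits(x, "recording")) return(list(x))
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "recording")))
  x
}

#' Write an evaluation report to JSON
#'
#' @param report an [eval_report()].
#' @param path output JSON path.
#' @param trace include the per-block trace.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, trace = TRUE) {
  out <- list(f1 = report$f1, precision = report$precision,
              recall = report$recall, auc = report$auc,
              confusion = report$confusion,
              n_events_pred = report$n_events_pred,
              n_events_true = report$n_events_true)
  if (!is.null(report$pr_points)) out$pr_points <- report$pr_points
  if (trace) out$trace <- report$trace
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
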
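#' Fuse time-aligned left- and right-wrist probabilities
#'
#' Both wrists stream synchronized data; each wrist's model produces a
#' smoothed probability per block. The fused probability at block `i` is by
#' default the arithmetic mean `(left[i] + right[i]) / 2` — the simplest
#' symmetric rule compatible with a single decision threshold. Two
#' alternatives are available: `"max"` (elementwise maximum) and `"or"`
#' (threshold each wrist first, fire when either does; returned as a 0/1
#' sequence).
#'
#' @param left_probs,right_probs equal-length smoothed probability
#'   sequences, aligned by block start index.
#' @param hp [hyperparameters()] (threshold, used by the `"or"` rule and by
#'   downstream [classify()]).
#' @param rule `"mean"`, `"max"` or `"or"`.
#' @return Fused probability sequence, same length as the inputs.
#' @export
ensemble_predict <- function(left_probs, right_probs, hp,
                             rule = c("mean", "max", "or")) {
  rule <- match.arg(rule)
  if (length(left_probs) != length(right_probs)) {
    stop("wrist streams not aligned: ", length(left_probs), " vs ",
         length(right_probs), " blocks", call. = FALSE)
  }
  switch(rule,
         mean = (left_probs + right_probs) / 2,
         max = pmax(left_probs, right_probs),
         or = as.numeric(classify(left_probs, hp) |
                           classify(right_probs, hp)))
}

#' Two-wrist ensemble classifier
#'
#' Bundles a left-wrist and a right-wrist model with a fusion rule. Each
#' member is trained only on its own wrist's data; fusion happens on the
#' smoothed probability streams via [ensemble_predict()].
#'
#' @param left,right trained `fall_model`s for the respective wrists.
#' @param rule fusion rule, see [ensemble_predict()].
#' @return An object of class `wrist_ensemble`.
#' @export
wrist_ensemble <- function(left, right, rule = c("mean", "max", "or")) {
  rule <- match.arg(rule)
  stopifnot(inherits(left, "fall_model"), inherits(right, "fall_model"))
  structure(list(left = left, right = right, rule = rule),
            class = "wrist_ensemble")
}

#' @export
print.wrist_ensemble <- function(x, ...) {
  cat(sprintf("<wrist_ensemble: rule '%s'>\n", x$rule))
  invisible(x)
}

# streaming evaluation of an ensemble over paired wrist datasets
evaluate_stream_ensemble <- function(ens, recordings, hp) {
  stopifnot(is.list(recordings), !is.null(recordings$left),
            !is.null(recordings$right))
  lrecs <- as_recording_list(recordings$left)
  rrecs <- as_recording_list(recordings$right)
  if (length(lrecs) != length(rrecs)) {
    stop("left/right recording counts differ", call. = FALSE)
  }
  pieces <- lapply(seq_along(lrecs), function(i) {
    bl <- make_blocks(lrecs[[i]], hp)
    br <- make_blocks(rrecs[[i]], hp)
    if (length(bl) == 0) return(NULL)
    if (length(bl) != length(br)) {
      stop("wrist streams not aligned in recording ", i, ": ",
           length(bl), " vs ", length(br), " blocks", call. = FALSE)
    }
    pl <- smooth_predict(predict_blocks(ens$left, bl), hp)
    pr <- smooth_predict(predict_blocks(ens$right, br), hp)
    fused <- align_lag(ensemble_predict(pl, pr, hp, rule = ens$rule), hp)
    data.frame(truth = bl$label,
               prob = fused,
               start_index = bl$start_index,
               subject = attr(lrecs[[i]], "subject_id"),
               activity = attr(lrecs[[i]], "activity"))
  })
  tr <- do.call(rbind, pieces)
  if (is.null(tr)) stop("no recording long enough to form a block",
                        call. = FALSE)
  eval_report(tr$prob, tr$truth, hp,
              trace_extra = tr[, c("start_index", "subject", "activity")])
}

#' Leave-one-person-out comparison of single-wrist and ensemble models
#'
#' For every held-out subject, trains one model per wrist on the remaining
#' subjects' wrist-specific data (optionally fine-tuned from a source model
#' via [transfer_train()]), then evaluates each single-wrist model and their
#' fused ensemble on the held-out subject.
#'
#' @param ds_left,ds_right paired [fall_dataset()]s covering the same
#'   subjects with synchronized recordings.
#' @param hp [hyperparameters()].
#' @param epochs,batch_size,seed training controls.
#' @param base_model optional source `fall_model`; when given, wrist models
#'   are fine-tuned from it instead of trained from scratch.
#' @param rule fusion rule.
#' @param subjects optional subset of held-out subjects to evaluate (a
#'   runtime control: folds are expensive; the default runs all of them).
#' @return List with `folds` (per-fold F1 data frame: `subject`, `left`,
#'   `right`, `ensemble`) and `mean` (column means).
#' @export
ensemble_lopo <- function(ds_left, ds_right, hp, epochs = 10L,
                          batch_size = 64L, seed = 1L, base_model = NULL,
                          rule = "mean", subjects = NULL) {
  stopifnot(identical(dataset_subjects(ds_left), dataset_subjects(ds_right)))
  fl <- lopo_folds(ds_left)
  fr <- lopo_folds(ds_right)
  if (!is.null(subjects)) {
    stopifnot(all(subjects %in% names(fl)))
    fl <- fl[subjects]
    fr <- fr[subjects]
  }
  rows <- lapply(seq_along(fl), function(i) {
    fold_seed <- seed + i - 1L
    fit_wrist <- function(train_ds) {
      blocks <- blocks_from_dataset(train_ds, hp)
      if (is.null(base_model)) {
        train_model(build_model(model_spec(hp$window_size), seed = fold_seed),
                    blocks, epochs = epochs, batch_size = batch_size,
                    seed = fold_seed)
      } else {
        transfer_train(base_model, blocks, epochs = epochs,
                       batch_size = batch_size, seed = fold_seed)
      }
    }
    ml <- fit_wrist(fl[[i]]$train)
    mr <- fit_wrist(fr[[i]]$train)
    ens <- wrist_ensemble(ml, mr, rule = rule)
    data.frame(
      subject = fl[[i]]$subject,
      left = evaluate_stream(ml, fl[[i]]$test, hp)$f1,
      right = evaluate_stream(mr, fr[[i]]$test, hp)$f1,
      ensemble = evaluate_stream(ens, list(left = fl[[i]]$test,
                                           right = fr[[i]]$test), hp)$f1)
  })
  folds <- do.call(rbind, rows)
  list(folds = folds,
       mean = colMeans(folds[, c("left", "right", "ensemble")]))
}
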
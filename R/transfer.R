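#' Fine-tune a source-trained model on target data with frozen layers
#'
#' The transfer step of the protocol: the recurrent layer of the source
#' model ("precursory layers") is frozen — its weight arrays come out
#' bitwise identical to the source's — while the dense head (dense layers,
#' batch-norm scale/shift, output layer) is re-trained on the target blocks
#' with the same optimizer contract as [train_model()]. The target block
#' width may differ from the source's training width. By default
#' (`rate_align = TRUE`) such cross-rate blocks are linearly resampled onto
#' the source model's native window length (its unit count, one second of
#' source-rate samples) before entering the frozen recurrent layer, so the
#' per-step time scale the frozen gates were trained at is preserved; the
#' resampling step becomes part of the returned model. With
#' `rate_align = FALSE` the variable-length recurrent layer consumes native
#' target windows directly.
#'
#' @param source_model a trained `fall_model`.
#' @param target_blocks `block_set` of target-domain training data.
#' @param epochs,batch_size,seed,lr,class_weight,bn_momentum,verbose as in
#'   [train_model()].
#' @param freeze freeze boundary: `"recurrent"` (default) freezes only the
#'   LSTM; `"recurrent+dense1"` also freezes the first dense block.
#' @param rate_align align cross-rate target blocks to the source model's
#'   window length (default `TRUE`).
#' @param update_bn_stats whether batch-norm running statistics keep
#'   adapting to the target data (default `TRUE`: they are data statistics,
#'   not source knowledge).
#' @return The fine-tuned `fall_model`.
#' @export
transfer_train <- function(source_model, target_blocks, epochs = 25L,
                           batch_size = 64L, seed = 1L, lr = 1e-3,
                           freeze = c("recurrent", "recurrent+dense1"),
                           rate_align = TRUE, update_bn_stats = TRUE,
                           class_weight = FALSE, bn_momentum = 0.9,
                           verbose = FALSE) {
  freeze <- match.arg(freeze)
  if (rate_align && is.null(source_model$input_window) &&
      target_blocks$window_size != source_model$spec$units) {
    source_model$input_window <- source_model$spec$units
  }
  m <- train_model(source_model, target_blocks, epochs = epochs,
                   batch_size = batch_size, seed = seed, lr = lr,
                   class_weight = class_weight, bn_momentum = bn_momentum,
                   freeze = freeze, update_bn_stats = update_bn_stats,
                   verbose = verbose)
  m$training_meta$transfer <- list(freeze = freeze,
                                   fine_tune_epochs = as.integer(epochs))
  m
}

#' Convert every recording of a dataset into one pooled block set
#'
#' @param ds a [fall_dataset()].
#' @param hp [hyperparameters()].
#' @return A `block_set` pooling all recordings (recordings shorter than one
#'   window contribute nothing).
#' @export
blocks_from_dataset <- function(ds, hp) {
  bind_blocks(lapply(ds$recordings, make_blocks, hp = hp))
}

#' Paired transfer-learning vs train-from-scratch protocol
#'
#' Runs the full comparison: a source model is trained on the entire source
#' dataset; for each evaluation split of the target dataset, one model is
#' fine-tuned from the source with frozen recurrent layer (`tl`) and one is
#' trained from scratch on the target training portion only (`tfs`). Both
#' are evaluated on the identical target test portion through the streaming
#' pipeline.
#'
#' @param source,target [fall_dataset()]s (possibly from different devices).
#' @param hp_source,hp_target [hyperparameters()]; default to each dataset's
#'   device profile defaults.
#' @param split_strategy `"train_test_70_30"` or `"leave_one_person_out"`.
#' @param seed master seed (initialization, splitting, shuffling).
#' @param epochs_source source-model training epochs.
#' @param epochs_target epochs for both target arms (identical budget keeps
#'   the comparison fair).
#' @param batch_size minibatch size for all trainings.
#' @param freeze freeze boundary for the transfer arm.
#' @param verbose log progress.
#' @return List with `tl` and `tfs` (each: `f1`, mean over folds for LOPO,
#'   plus per-fold `reports`), `f1_diff = tl$f1 - tfs$f1`, the trained
#'   `source_model`, and `test_checksum` per fold proving both arms saw the
#'   same test blocks.
#' @export
run_protocol <- function(source, target, hp_source = NULL, hp_target = NULL,
                         split_strategy = c("train_test_70_30",
                                            "leave_one_person_out"),
                         seed = 1L, epochs_source = 15L, epochs_target = 15L,
                         batch_size = 64L,
                         freeze = c("recurrent", "recurrent+dense1"),
                         verbose = FALSE) {
  split_strategy <- match.arg(split_strategy)
  freeze <- match.arg(freeze)
  stopifnot(inherits(source, "fall_dataset"), inherits(target, "fall_dataset"))
  prof_s <- attr(source$recordings[[1]], "profile")
  prof_t <- attr(target$recordings[[1]], "profile")
  hp_source <- hp_source %||% prof_s$default_hparams
  hp_target <- hp_target %||% prof_t$default_hparams

  if (verbose) message("training source model on ",
                       length(source$recordings), " recordings")
  src_spec <- model_spec(units = round(prof_s$sampling_hz))
  source_model <- train_model(build_model(src_spec, seed = seed),
                              blocks_from_dataset(source, hp_source),
                              epochs = epochs_source,
                              batch_size = batch_size, seed = seed)

  run_fold <- function(train_ds, test_ds, fold_seed) {
    train_blocks <- blocks_from_dataset(train_ds, hp_target)
    tfs_spec <- model_spec(units = round(prof_t$sampling_hz))
    tfs <- train_model(build_model(tfs_spec, seed = fold_seed), train_blocks,
                       epochs = epochs_target, batch_size = batch_size,
                       seed = fold_seed)
    tl <- transfer_train(source_model, train_blocks,
                         epochs = epochs_target, batch_size = batch_size,
                         seed = fold_seed, freeze = freeze)
    list(tl = evaluate_stream(tl, test_ds, hp_target),
         tfs = evaluate_stream(tfs, test_ds, hp_target),
         tl_model = tl, tfs_model = tfs,
         checksum = dataset_checksum(test_ds))
  }

  if (split_strategy == "train_test_70_30") {
    sp <- split_per_person(target, 0.7, seed = seed)
    fold <- run_fold(sp$train, sp$test, seed)
    folds <- list(fold)
  } else {
    fl <- lopo_folds(target)
    if (length(fl) < 2) stop("need >= 2 subjects", call. = FALSE)
    folds <- lapply(seq_along(fl), function(i) {
      if (verbose) message("fold ", i, "/", length(fl),
                           " (held out: ", fl[[i]]$subject, ")")
      run_fold(fl[[i]]$train, fl[[i]]$test, seed + i - 1L)
    })
  }

  f1_tl <- mean(vapply(folds, function(f) f$tl$f1, numeric(1)))
  f1_tfs <- mean(vapply(folds, function(f) f$tfs$f1, numeric(1)))
  list(tl = list(f1 = f1_tl, reports = lapply(folds, `[[`, "tl")),
       tfs = list(f1 = f1_tfs, reports = lapply(folds, `[[`, "tfs")),
       f1_diff = f1_tl - f1_tfs,
       source_model = source_model,
       models = lapply(folds, function(f) list(tl = f$tl_model,
                                               tfs = f$tfs_model)),
       test_checksum = vapply(folds, `[[`, numeric(1), "checksum"),
       split_strategy = split_strategy)
}

# deterministic fingerprint of the evaluated samples
dataset_checksum <- function(ds) {
  sum(vapply(ds$recordings, function(r) {
    sum(r$x) + 2 * sum(r$y) + 3 * sum(r$z) + sum(r$label) + nrow(r)
  }, numeric(1)))
}
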
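#' LSTM classifier architecture specification
#'
#' Two architectures are supported, both fully connected, both ending in a
#' single sigmoid unit:
#' \describe{
#'   \item{`baseline`}{LSTM(U) -> Dense(U, relu) -> BatchNorm ->
#'     Dense(1, sigmoid). 13,601 parameters at U = 50.}
#'   \item{`improved`}{adds one more Dense(U, relu) + BatchNorm pair before
#'     the output, i.e. LSTM(U) -> Dense(U, relu) -> BatchNorm ->
#'     Dense(U, relu) -> BatchNorm -> Dense(1, sigmoid). 16,351 parameters
#'     at U = 50.}
#' }
#' `U`, the neuron count of every hidden layer, defaults to the number of
#' samples the device senses in one second (32 or 50), matching the window
#' size.
#'
#' @param units neuron count U per hidden layer.
#' @param variant `"improved"` (default) or `"baseline"`.
#' @param input_channels input channels per time step (3 accelerometer axes).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(units, variant = c("improved", "baseline"),
                       input_channels = 3L) {
  variant <- match.arg(variant)
  stopifnot(units >= 1, input_channels >= 1)
  structure(list(units = as.integer(units), variant = variant,
                 input_channels = as.integer(input_channels)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec: %s, U=%d, %d channels, %s parameters>\n",
              x$variant, x$units, x$input_channels,
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Total parameter count of an architecture
#'
#' Counts every stored array: LSTM kernels and biases
#' (`4 * (U * (C + U) + U)`), each Dense(U -> U) (`U^2 + U`), each batch
#' normalization layer (`4U`: scale, shift, and the two non-learned running
#' statistics), and the output Dense(U -> 1) (`U + 1`).
#'
#' @param spec a [model_spec()].
#' @return Integer parameter total.
#' @examples
#' count_params(model_spec(50, "improved")) # 16351
#' count_params(model_spec(50, "baseline")) # 13601
#' @export
count_params <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  U <- spec$units
  C <- spec$input_channels
  lstm <- 4L * (U * (C + U) + U)
  dense_uu <- U^2 + U
  bn <- 4L * U
  out <- U + 1L
  n_pairs <- if (spec$variant == "improved") 2L else 1L
  as.integer(lstm + n_pairs * (dense_uu + bn) + out)
}

glorot <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

orthogonal <- function(n) {
  a <- matrix(stats::rnorm(n * n), n, n)
  qr.Q(qr(a))
}

#' Build a model with seeded random initialization
#'
#' Kernels use Glorot-uniform initialization, recurrent kernels are
#' orthogonal per gate, the LSTM forget-gate bias starts at 1, batch-norm
#' scale/shift at 1/0 with running statistics 0/1. Identical seeds give
#' bitwise identical weights.
#'
#' @param spec a [model_spec()].
#' @param seed integer RNG seed.
#' @return An object of class `fall_model` (spec + named weight arrays +
#'   training metadata).
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  U <- spec$units
  C <- spec$input_channels
  w <- withr_seed(seed, {
    w <- list(
      lstm_Wx = glorot(4L * U, C, C, 4L * U),
      lstm_Wh = do.call(rbind, lapply(1:4, function(i) orthogonal(U))),
      lstm_b = c(rep(0, U), rep(1, U), rep(0, 2L * U)),
      d1_W = glorot(U, U, U, U),
      d1_b = rep(0, U),
      bn1_gamma = rep(1, U), bn1_beta = rep(0, U),
      bn1_mean = rep(0, U), bn1_var = rep(1, U))
    if (spec$variant == "improved") {
      w <- c(w, list(
        d2_W = glorot(U, U, U, U),
        d2_b = rep(0, U),
        bn2_gamma = rep(1, U), bn2_beta = rep(0, U),
        bn2_mean = rep(0, U), bn2_var = rep(1, U)))
    }
    c(w, list(out_W = glorot(1L, U, U, 1L), out_b = 0))
  })
  structure(list(spec = spec, weights = w,
                 training_meta = list(seed = as.integer(seed), epochs = 0L,
                                      source = NA_character_)),
            class = "fall_model")
}

# evaluate `code` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @export
print.fall_model <- function(x, ...) {
  cat(sprintf("<fall_model: %s U=%d, %d params, trained %d epochs>\n",
              x$spec$variant, x$spec$units, count_params(x$spec),
              x$training_meta$epochs))
  invisible(x)
}

n_stored_params <- function(model) {
  sum(vapply(model$weights, length, integer(1)))
}

#' Train a model on labeled data blocks
#'
#' Minimizes binary cross-entropy with the Adam optimizer at its default
#' settings (learning rate 1e-3, beta1 0.9, beta2 0.999). Training order is
#' reshuffled every epoch from `seed`; given identical data and seed the
#' result is bit-reproducible.
#'
#' @param model a [build_model()] result (or an already trained model).
#' @param blocks a `block_set` from [make_blocks()]/[bind_blocks()]; all
#'   blocks share one window size by construction.
#' @param epochs training epochs; 0 returns the model unchanged.
#' @param batch_size minibatch size.
#' @param seed shuffling seed.
#' @param lr Adam learning rate.
#' @param class_weight when `TRUE`, samples are weighted inversely to class
#'   frequency (off by default; the reference pipeline does not correct the
#'   fall/ADL imbalance).
#' @param bn_momentum running-statistics momentum of the batch-norm layers.
#' @param freeze `"none"` trains everything; `"recurrent"` freezes the LSTM
#'   layer; `"recurrent+dense1"` additionally freezes the first dense block
#'   (used by [transfer_train()]).
#' @param update_bn_stats whether batch-norm running statistics keep
#'   updating (they are data statistics, so they do by default even under
#'   freezing).
#' @param verbose log per-epoch training loss via `message()`.
#' @return The trained `fall_model`; `$training_meta$loss` holds the
#'   per-epoch loss history.
#' @export
train_model <- function(model, blocks, epochs = 25L, batch_size = 64L,
                        seed = 1L, lr = 1e-3, class_weight = FALSE,
                        bn_momentum = 0.9,
                        freeze = c("none", "recurrent", "recurrent+dense1"),
                        update_bn_stats = TRUE, verbose = FALSE) {
  freeze <- match.arg(freeze)
  stopifnot(inherits(model, "fall_model"), inherits(blocks, "block_set"))
  n <- length(blocks)
  if (n == 0) stop("no training blocks", call. = FALSE)
  blocks <- align_blocks(model, blocks)
  if (dim(blocks$x)[2] != model$spec$input_channels) {
    stop("block channel count ", dim(blocks$x)[2], " does not match model (",
         model$spec$input_channels, ")", call. = FALSE)
  }
  if (length(unique(blocks$label)) < 2) {
    warning("training data contains a single class", call. = FALSE)
  }
  if (epochs == 0) return(model)
  sw <- rep(1, n)
  if (class_weight) {
    tab <- table(factor(blocks$label, levels = c(0, 1)))
    sw <- n / (2 * as.numeric(tab[as.character(blocks$label)]))
  }
  fit <- nn_train_cpp(model$weights, blocks$x, as.numeric(blocks$label), sw,
                      as.integer(epochs), as.integer(batch_size), lr,
                      as.integer(seed),
                      improved = model$spec$variant == "improved",
                      train_lstm = freeze == "none",
                      train_dense1 = freeze != "recurrent+dense1",
                      update_bn_stats = update_bn_stats,
                      bn_momentum = bn_momentum)
  if (verbose) {
    for (ep in seq_along(fit$loss)) {
      message(sprintf("epoch %d/%d: loss %.5f", ep, epochs, fit$loss[ep]))
    }
  }
  model$weights <- reshape_like(fit$weights, model$weights)
  model$training_meta$epochs <- model$training_meta$epochs + as.integer(epochs)
  model$training_meta$loss <- as.numeric(fit$loss)
  model
}

# rate-aligned transfer models carry a fixed input-resampling step
align_blocks <- function(model, blocks) {
  iw <- model$input_window
  if (is.null(iw) || blocks$window_size == iw) return(blocks)
  resample_blocks(blocks, iw)
}

# C++ hands back plain vectors for 1-row arrays; restore original shapes
reshape_like <- function(new, old) {
  out <- old
  for (nm in names(old)) {
    v <- new[[nm]]
    if (is.matrix(old[[nm]]) && !is.matrix(v)) {
      v <- matrix(v, nrow(old[[nm]]), ncol(old[[nm]]))
    }
    out[[nm]] <- v
  }
  out
}

#' Per-block fall probabilities
#'
#' The recurrent layer consumes sequences of any length, so the block width
#' may differ from the width the model was trained on (this is what makes
#' cross-rate transfer work without resampling). Batch-norm layers run in
#' inference mode (running statistics).
#'
#' @param model a `fall_model`.
#' @param blocks a `block_set` (any window size, 3 channels).
#' @return Numeric vector of probabilities in (0, 1), one per block.
#' @export
predict_blocks <- function(model, blocks) {
  stopifnot(inherits(model, "fall_model"), inherits(blocks, "block_set"))
  blocks <- align_blocks(model, blocks)
  if (dim(blocks$x)[2] != model$spec$input_channels) {
    stop("block channel count ", dim(blocks$x)[2], " does not match model (",
         model$spec$input_channels, ")", call. = FALSE)
  }
  if (length(blocks) == 0) return(numeric(0))
  as.numeric(nn_predict_cpp(model$weights, blocks$x,
                            model$spec$variant == "improved"))
}

#' Save / load a model bundle
#'
#' A bundle is a directory holding `manifest.json` (spec, training metadata,
#' and the shape of every layer array) plus `weights/<index>_<name>.bin`,
#' each a little-endian 32-bit float dump. Loading verifies that every
#' array's length matches its manifest shape. Weights survive a round trip
#' at float32 precision (about 1e-7 relative); a second round trip is exact.
#'
#' @param model a `fall_model`.
#' @param path bundle directory (created, overwritten if present).
#' @return `save_model`: `path` invisibly; `load_model`: the `fall_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fall_model"))
  dir.create(file.path(path, "weights"), recursive = TRUE,
             showWarnings = FALSE)
  layers <- lapply(seq_along(model$weights), function(i) {
    nm <- names(model$weights)[i]
    w <- model$weights[[i]]
    list(name = nm, file = sprintf("weights/%02d_%s.bin", i, nm),
         shape = if (is.matrix(w)) dim(w) else length(w))
  })
  manifest <- list(format = "wristfall-model-bundle", version = 1L,
                   spec = unclass(model$spec),
                   training_meta = model$training_meta,
                   layers = layers)
  if (!is.null(model$input_window)) {
    manifest$input_window <- model$input_window
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(model$weights)) {
    con <- file(file.path(path, layers[[i]]$file), "wb")
    writeBin(as.numeric(model$weights[[i]]), con, size = 4L,
             endian = "little")
    close(con)
  }
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  mf <- jsonlite::read_json(file.path(path, "manifest.json"),
                            simplifyVector = TRUE)
  if (is.null(mf$format) || mf$format != "wristfall-model-bundle") {
    stop("not a model bundle: ", path, call. = FALSE)
  }
  spec <- model_spec(mf$spec$units, mf$spec$variant, mf$spec$input_channels)
  layers <- mf$layers
  weights <- list()
  for (i in seq_len(nrow(layers))) {
    shape <- unlist(layers$shape[i])
    f <- file.path(path, layers$file[i])
    n_expect <- prod(shape)
    sz <- file.info(f)$size
    if (is.na(sz) || sz != 4L * n_expect) {
      stop("bundle integrity error: '", layers$name[i], "' has ",
           if (is.na(sz)) 0 else sz %/% 4L, " values, manifest says ",
           n_expect, call. = FALSE)
    }
    con <- file(f, "rb")
    v <- readBin(con, "numeric", n = n_expect, size = 4L, endian = "little")
    close(con)
    weights[[layers$name[i]]] <-
      if (length(shape) == 2) matrix(v, shape[1], shape[2]) else v
  }
  tm <- mf$training_meta
  tm$epochs <- as.integer(tm$epochs)
  m <- structure(list(spec = spec, weights = weights, training_meta = tm),
                 class = "fall_model")
  iw <- unlist(mf$input_window)
  if (length(iw) == 1 && !is.na(iw)) m$input_window <- as.integer(iw)
  m
}
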
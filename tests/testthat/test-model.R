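test_that("count_params reproduces the published totals and closed forms", {
  expect_identical(count_params(model_spec(50, "improved")), 16351L)
  expect_identical(count_params(model_spec(50, "baseline")), 13601L)
  # U = 1 improved: 20 + 2 + 4 + 2 + 4 + 2
  expect_identical(count_params(model_spec(1, "improved")), 34L)
  # one extra Dense(U) + Norm pair: difference is U^2 + 5U
  for (U in c(1, 7, 32, 50)) {
    expect_equal(count_params(model_spec(U)) -
                   count_params(model_spec(U, "baseline")),
                 U^2 + 5 * U)
  }
})

test_that("build_model is seed-deterministic and allocates count_params values", {
  for (U in c(1, 32, 50)) {
    m <- build_model(model_spec(U), seed = 3)
    expect_equal(sum(vapply(m$weights, length, integer(1))),
                 count_params(model_spec(U)))
  }
  m1 <- build_model(model_spec(8), seed = 5)
  m2 <- build_model(model_spec(8), seed = 5)
  m3 <- build_model(model_spec(8), seed = 6)
  expect_identical(m1$weights, m2$weights)
  expect_false(identical(m1$weights$lstm_Wx, m3$weights$lstm_Wx))
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  U <- 4; T <- 6; n <- 5
  m <- build_model(model_spec(U, "improved"), seed = 7)
  # move away from symmetric initial points
  m$weights$bn1_beta <- rnorm(U, 0, 0.3)
  m$weights$bn2_beta <- rnorm(U, 0, 0.3)
  m$weights$out_b <- 0.2
  X <- array(rnorm(T * 3 * n), dim = c(T, 3, n))
  y <- c(0, 1, 1, 0, 1)
  sw <- runif(n, 0.5, 2)
  g <- wristfall:::nn_grad_cpp(m$weights, X, y, sw, TRUE)
  num_grad <- function(name, i, h = 1e-6) {
    wp <- m$weights; wm <- m$weights
    wp[[name]][i] <- wp[[name]][i] + h
    wm[[name]][i] <- wm[[name]][i] - h
    (wristfall:::nn_loss_cpp(wp, X, y, sw, TRUE) -
       wristfall:::nn_loss_cpp(wm, X, y, sw, TRUE)) / (2 * h)
  }
  for (nm in setdiff(names(g),
                     c("loss", "bn1_mean", "bn1_var", "bn2_mean",
                       "bn2_var"))) {
    idx <- sample(length(g[[nm]]), min(4, length(g[[nm]])))
    for (i in idx) {
      expect_equal(g[[nm]][i], num_grad(nm, i), tolerance = 1e-4,
                   info = paste(nm, i))
    }
  }
})

test_that("training contract: identity at 0 epochs, determinism, separable toy", {
  blocks <- toy_blocks()
  m0 <- build_model(model_spec(10), seed = 1)
  expect_identical(train_model(m0, blocks, epochs = 0), m0)

  m1 <- train_model(m0, blocks, epochs = 20, batch_size = 4, seed = 2)
  m2 <- train_model(m0, blocks, epochs = 20, batch_size = 4, seed = 2)
  expect_identical(m1$weights, m2$weights)
  expect_equal(m1$training_meta$loss, m2$training_meta$loss)

  # linearly separable toy reaches training accuracy 1
  p <- predict_blocks(m1, blocks)
  expect_equal(as.integer(p > 0.5), blocks$label)
  expect_lt(tail(m1$training_meta$loss, 1), 0.1)

  expect_warning(train_model(m0, toy_blocks(n_fall = 0, n_adl = 6),
                             epochs = 1),
                 "single class")
})

test_that("predict_blocks is pure, bounded and batch-order invariant", {
  blocks <- toy_blocks(seed = 9)
  m <- train_model(build_model(model_spec(10), seed = 1), blocks,
                   epochs = 5, seed = 1)
  p <- predict_blocks(m, blocks)
  expect_true(all(p > 0 & p < 1))
  # duplicated block gives the identical probability
  dup <- block_set(blocks$x[, , c(1, 1, 3)], blocks$label[c(1, 1, 3)],
                   c(0L, 1L, 2L), blocks$window_size)
  pd <- predict_blocks(m, dup)
  expect_identical(pd[1], pd[2])
  # reversing the batch permutes the outputs identically
  rev_idx <- rev(seq_len(length(blocks)))
  prev <- predict_blocks(m, block_set(blocks$x[, , rev_idx],
                                      blocks$label[rev_idx],
                                      blocks$start_index[rev_idx],
                                      blocks$window_size))
  expect_equal(prev, rev(p))
})

test_that("the recurrent layer accepts windows of any length", {
  m <- train_model(build_model(model_spec(10), seed = 1), toy_blocks(),
                   epochs = 3, seed = 1)
  wide <- toy_blocks(W = 17L, seed = 4)
  p <- predict_blocks(m, wide)
  expect_length(p, length(wide))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("model bundles round-trip and detect tampering", {
  dir <- withr::local_tempdir()
  m <- train_model(build_model(model_spec(6), seed = 2), toy_blocks(W = 8),
                   epochs = 2, seed = 2)
  save_model(m, file.path(dir, "bundle"))
  back <- load_model(file.path(dir, "bundle"))
  expect_identical(back$spec, m$spec)
  expect_equal(back$weights, m$weights, tolerance = 1e-6)
  # float32 storage: a second round trip is exact
  save_model(back, file.path(dir, "bundle2"))
  back2 <- load_model(file.path(dir, "bundle2"))
  expect_identical(back2$weights, back$weights)
  # manifest records the architecture
  mf <- jsonlite::read_json(file.path(dir, "bundle", "manifest.json"))
  expect_equal(mf$spec$variant, "improved")
  expect_equal(mf$spec$units, 6)
  # tampered array length -> integrity error
  f <- file.path(dir, "bundle", "weights", "01_lstm_Wx.bin")
  writeBin(raw(4), f)
  expect_error(load_model(file.path(dir, "bundle")), "integrity")
})
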
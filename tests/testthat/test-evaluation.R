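# confusion-matrix brute-force oracle
f1_oracle <- function(pred, truth) {
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

test_that("f1_score matches the confusion-matrix oracle", {
  expect_equal(f1_score(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(f1_score(c(1, 1, 0), c(1, 0, 1)), 0.5) # TP=1 FP=1 FN=1
  expect_equal(f1_score(c(0, 0, 0), c(1, 0, 1)), 0)
  expect_equal(f1_score(c(0, 0), c(0, 0)), 0) # degenerate denominator
  set.seed(21)
  for (i in 1:25) {
    n <- sample(5:80, 1)
    pred <- rbinom(n, 1, 0.4)
    truth <- rbinom(n, 1, 0.3)
    expect_equal(f1_score(pred, truth), f1_oracle(pred, truth))
  }
  expect_error(f1_score(c(1, 0), c(1, 0, 1)), "length")
})

test_that("eval_report is internally consistent", {
  set.seed(4)
  truth <- rbinom(120, 1, 0.3)
  probs <- pmin(1, pmax(0, truth * 0.6 + runif(120, 0, 0.5)))
  hp <- hyperparameters(10)
  rep <- eval_report(probs, truth, hp)
  cm <- rep$confusion
  expect_equal(rep$f1, f1_oracle(classify(probs, hp), truth))
  expect_equal(rep$f1,
               if (2 * cm$tp + cm$fp + cm$fn == 0) 0 else
                 2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn))
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 120)
  expect_equal(nrow(rep$trace), 120)
})

test_that("pr_curve: perfect separation, chance level, and monotone invariance", {
  truth <- c(rep(1, 10), rep(0, 30))
  probs <- c(runif(10, 0.8, 1), runif(30, 0, 0.2))
  pr <- pr_curve(probs, truth)
  expect_equal(pr$auc, 1)

  # probabilities independent of truth: AUC ~ prevalence (Monte Carlo)
  set.seed(99)
  n <- 5000
  truth <- rbinom(n, 1, 0.5)
  probs <- runif(n)
  expect_equal(pr_curve(probs, truth)$auc, 0.5, tolerance = 0.05)

  # AUC is invariant under strictly monotone transforms
  set.seed(7)
  truth <- rbinom(300, 1, 0.3)
  probs <- runif(300)
  a1 <- pr_curve(probs, truth)$auc
  a2 <- pr_curve(probs^3, truth)$auc
  expect_equal(a1, a2, tolerance = 1e-12)

  # reversing the ranking destroys the curve
  good <- pmin(1, pmax(0, truth * 0.8 + runif(300) * 0.2))
  expect_gt(pr_curve(good, truth)$auc, pr_curve(1 - good, truth)$auc)

  expect_warning(pr_curve(runif(10), rep(1, 10)), "single-class")
})

test_that("split_per_person keeps every subject on both sides, reproducibly", {
  ds <- simulate_dataset(synthetic_config(n_subjects = 3, falls_per_type = 1,
                                          adl_menu = c(walking = 2,
                                                       sitting = 2),
                                          seed = 44))
  sp <- split_per_person(ds, 0.7, seed = 2)
  expect_setequal(dataset_subjects(sp$train), dataset_subjects(ds))
  expect_setequal(dataset_subjects(sp$test), dataset_subjects(ds))
  # recording-level partition: counts add up
  expect_equal(length(sp$train$recordings) + length(sp$test$recordings),
               length(ds$recordings))
  # train share of samples within each subject near the target fraction
  n_of <- function(d, s) sum(vapply(d$recordings, function(r)
    if (attr(r, "subject_id") == s) nrow(r) else 0L, numeric(1)))
  for (s in dataset_subjects(ds)) {
    frac <- n_of(sp$train, s) / (n_of(sp$train, s) + n_of(sp$test, s))
    expect_gt(frac, 0.4); expect_lt(frac, 0.95)
  }
  sp2 <- split_per_person(ds, 0.7, seed = 2)
  expect_identical(vapply(sp2$train$recordings, attr, "", "activity"),
                   vapply(sp$train$recordings, attr, "", "activity"))
})

test_that("lopo_folds partition the dataset exactly", {
  ds <- tiny_dataset(seed = 3, n_subjects = 4)
  folds <- lopo_folds(ds)
  expect_length(folds, 4)
  test_subjects <- vapply(folds, `[[`, "", "subject")
  expect_setequal(test_subjects, dataset_subjects(ds))
  # union of test sets is the dataset, disjointly
  n_test <- sum(vapply(folds, function(f) length(f$test$recordings),
                       integer(1)))
  expect_equal(n_test, length(ds$recordings))
  for (f in folds) {
    expect_false(f$subject %in% dataset_subjects(f$train))
    expect_equal(length(f$train$recordings) + length(f$test$recordings),
                 length(ds$recordings))
  }
  one <- subset_one <- fall_dataset(ds$recordings[
    vapply(ds$recordings, attr, "", "subject_id") == "s01"])
  expect_error(lopo_folds(one), "2 subjects")
})

test_that("detect_events counts maximal positive runs", {
  expect_equal(detect_events(c(0, 1, 1, 0, 1)), 2)
  expect_equal(detect_events(rep(0, 5)), 0)
  expect_equal(detect_events(rep(1, 5)), 1)
  expect_equal(detect_events(integer(0)), 0L)
})

test_that("evaluate_stream runs the full pipeline deterministically", {
  ds <- tiny_dataset(seed = 8)
  hp <- metasensor()$default_hparams
  blocks <- blocks_from_dataset(ds, hp)
  m <- train_model(build_model(model_spec(50), seed = 1), blocks,
                   epochs = 3, seed = 1)
  r1 <- evaluate_stream(m, ds, hp)
  r2 <- evaluate_stream(m, ds, hp)
  expect_identical(r1$trace$prob, r2$trace$prob)
  expect_equal(nrow(r1$trace), length(blocks))
  expect_true(r1$f1 >= 0 && r1$f1 <= 1)

  # a sane model stays silent on an all-quiet recording
  quiet <- toy_recording(rep(1, 400) + rnorm(400, 0, 0.02),
                         y = rnorm(400, 0, 0.02), z = rnorm(400, 0, 0.02),
                         profile = metasensor())
  rq <- evaluate_stream(m, quiet, hp)
  expect_equal(sum(rq$trace$pred), 0)
})

test_that("reports serialize to JSON", {
  ds <- tiny_dataset(seed = 8)
  hp <- metasensor()$default_hparams
  m <- train_model(build_model(model_spec(50), seed = 1),
                   blocks_from_dataset(ds, hp), epochs = 2, seed = 1)
  rep <- evaluate_stream(m, ds, hp)
  path <- file.path(withr::local_tempdir(), "report.json")
  write_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$f1, rep$f1)
  expect_equal(length(back$trace$prob), nrow(rep$trace))
})
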
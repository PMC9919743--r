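test_that("relabel_fall_peak centers the window on the magnitude peak", {
  rec <- spike_recording(200, at = 101) # 0-based index 100
  out <- relabel_fall_peak(rec, width = 100)
  expect_equal(which(out$label == 1), 51:150) # 0-based 50..149
  expect_equal(sum(out$label), 100)

  # peak at the first sample: window shifts inward, width preserved
  out2 <- relabel_fall_peak(spike_recording(200, at = 1), width = 100)
  expect_equal(which(out2$label == 1), 1:100)

  # width 1 labels exactly the argmax
  out3 <- relabel_fall_peak(spike_recording(200, at = 60), width = 1)
  expect_equal(which(out3$label == 1), 60)

  expect_error(relabel_fall_peak(spike_recording(50, at = 10), width = 100),
               "width")
})

test_that("relabel_fall_peak properties: exact width, earliest-tie argmax", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(100:300, 1)
    w <- sample(c(1, 35, 100), 1)
    rec <- toy_recording(runif(n, 0.5, 3), runif(n), runif(n))
    out <- relabel_fall_peak(rec, width = w)
    expect_equal(sum(out$label), w)
    run <- rle(out$label)
    expect_equal(sum(run$values == 1), 1) # one contiguous run
    expect_true(which.max(magnitude(rec)) %in% which(out$label == 1))
  }
  # tie broken to the earliest index
  rec <- spike_recording(100, at = c(30, 70), heights = c(2, 2))
  out <- relabel_fall_peak(rec, width = 1)
  expect_equal(which(out$label == 1), 30)
})

# independent greedy non-maximum-suppression oracle
nms_oracle <- function(mag, n_trials, width) {
  centers <- integer(0)
  mag <- as.numeric(mag)
  for (k in seq_len(n_trials)) {
    if (all(is.na(mag))) return(NULL)
    c_k <- which.max(mag)
    centers <- c(centers, c_k)
    lo <- max(1, c_k - width + 1)
    hi <- min(length(mag), c_k + width - 1)
    mag[lo:hi] <- NA
  }
  sort(centers)
}

test_that("locate_fall_peaks matches the greedy oracle and separation bound", {
  rec <- spike_recording(1000, at = c(200, 700), heights = c(3, 2.5))
  expect_equal(locate_fall_peaks(rec, 2, width = 35), c(200, 700))
  expect_equal(locate_fall_peaks(rec, 1), 200)

  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(80:200, 1)
    rec <- toy_recording(runif(n, 0.5, 3), runif(n), runif(n))
    n_trials <- sample(1:3, 1)
    width <- sample(c(10, 20, 35), 1)
    oracle <- nms_oracle(magnitude(rec), n_trials, width)
    if (n < n_trials * width || is.null(oracle)) next
    centers <- locate_fall_peaks(rec, n_trials, width = width)
    expect_equal(centers, oracle)
    if (n_trials > 1) expect_true(min(diff(centers)) >= width)
  }
})

test_that("locate_fall_peaks rejects impossible requests", {
  rec <- spike_recording(60, at = 30)
  expect_error(locate_fall_peaks(rec, 2, width = 35), "too short")
  # two spikes 10 apart with width 35: second pick lands outside the
  # exclusion zone of the first, never inside it
  rec2 <- spike_recording(100, at = c(40, 50), heights = c(3, 2.8))
  centers <- locate_fall_peaks(rec2, 2, width = 35)
  expect_true(40 %in% centers) # the taller spike wins; 50 is suppressed
  other <- setdiff(centers, 40)
  expect_true(abs(other - 40) >= 35)
})

test_that("trim_adl cuts to the smallest multiple of the unit", {
  # activity spanning 250 samples inside a 600-sample recording
  x <- rep(1, 600)
  x[151:400] <- 1 + 0.5 * sin(seq(0, 6 * pi, length.out = 250))
  rec <- toy_recording(x, y = rep(0, 600), z = rep(0, 600))
  out <- trim_adl(rec)
  expect_equal(nrow(out), 300) # ceil(250 / 100) * 100
  expect_true(all(out$label == 0))

  # exact multiple stays as-is
  x2 <- rep(1, 400)
  x2[101:200] <- 2
  expect_equal(nrow(trim_adl(toy_recording(x2, rep(0, 400), rep(0, 400)))),
               100)

  # single active sample still yields one full unit
  x3 <- rep(1, 300)
  x3[150] <- 2
  expect_equal(nrow(trim_adl(toy_recording(x3, rep(0, 300), rep(0, 300)))),
               100)

  expect_error(trim_adl(toy_recording(rep(1, 200), rep(0, 200),
                                      rep(0, 200))),
               "no activity")
})

test_that("segment_trials splits falls at peak midpoints and ADLs equally", {
  at <- c(100, 300, 500, 700, 900)
  rec <- spike_recording(1000, at = at, heights = seq(3, 2.6, by = -0.1))
  rec$label[at] <- 1L
  parts <- segment_trials(rec, 5)
  expect_length(parts, 5)
  # each piece contains exactly one spike and pieces tile the input
  expect_equal(vapply(parts, function(p) sum(magnitude(p) > 2), integer(1)),
               rep(1L, 5))
  expect_equal(sum(vapply(parts, nrow, integer(1))), 1000)
  expect_equal(do.call(c, lapply(parts, function(p) p$x)), rec$x)
  # midpoint boundaries
  expect_equal(vapply(parts, nrow, integer(1)),
               c(200, 200, 200, 200, 200))

  adl <- toy_recording(rep(1, 300), rep(0, 300), rep(0, 300))
  pieces <- segment_trials(adl, 3, kind = "adl")
  expect_equal(vapply(pieces, nrow, integer(1)), rep(100L, 3))

  expect_equal(nrow(segment_trials(rec, 1)[[1]]), 1000)
})
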
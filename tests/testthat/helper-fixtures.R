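# Small fixtures built in code; everything is deterministic given the seed.

msband <- function() device_profile("msband")
metasensor <- function() device_profile("metasensor")

# recording from axis vectors at a nominal rate; labels default to 0
toy_recording <- function(x, y = x, z = x, label = rep(0L, length(x)),
                          profile = msband()) {
  recording(t_ms = seq(0, by = 1000 / profile$sampling_hz,
                       length.out = length(x)),
            x = x, y = y, z = z, label = label, profile = profile)
}

# flat 1 g signal with unit spikes of the given magnitudes at `at` (1-based)
spike_recording <- function(n, at, heights = rep(3, length(at)),
                            profile = msband()) {
  x <- rep(1, n)
  x[at] <- heights
  toy_recording(x, y = rep(0, n), z = rep(0, n), profile = profile)
}

# linearly separable block set: falls at 3 g on every axis, ADLs at 0.1 g
toy_blocks <- function(n_fall = 8, n_adl = 8, W = 10L, seed = 1) {
  set.seed(seed)
  xs <- array(0, dim = c(W, 3, n_fall + n_adl))
  for (i in seq_len(n_fall)) xs[, , i] <- 3 + rnorm(W * 3, 0, 0.05)
  for (i in seq_len(n_adl)) xs[, , n_fall + i] <- 0.1 + rnorm(W * 3, 0, 0.05)
  block_set(xs, c(rep(1L, n_fall), rep(0L, n_adl)),
            seq_len(n_fall + n_adl) - 1L, W)
}

# tiny synthetic dataset for pipeline tests
tiny_dataset <- function(seed = 1, n_subjects = 2, device = "metasensor",
                         wrists = "left") {
  simulate_dataset(synthetic_config(
    n_subjects = n_subjects, falls_per_type = 1,
    adl_menu = c(walking = 1, jacket = 1), device = device,
    wrists = wrists, seed = seed))
}
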
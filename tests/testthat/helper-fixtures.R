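# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# the default repeated segment, centered and endpoint-zeroed
test_repeated <- function() {
  if (is.null(.fixtures$repeated))
    .fixtures$repeated <- center_and_zero(
      render_segment(default_repeated_coefficients(), kind = "repeated"))
  .fixtures$repeated
}

# a cached pool of accepted random segments
test_random_pool <- function(n = 10, seed = 501) {
  key <- sprintf("pool_%d_%d", seed, n)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- sample_random_segments(seed, test_repeated(), n = n)
  .fixtures[[key]]
}

# a segment object wrapping arbitrary samples
make_segment <- function(samples, sample_rate = 50, kind = "random") {
  structure(list(kind = kind, coefficients = NULL, samples = samples,
                 duration_s = length(samples) / sample_rate,
                 sample_rate = sample_rate),
            class = "ct_segment")
}

# a delayed-plus-noise response for lag tests
delayed_response <- function(target, delay_samples, noise_sd = 0) {
  n <- length(target)
  d <- delay_samples
  out <- if (d > 0) c(rep(target[1], d), target[seq_len(n - d)]) else target
  if (noise_sd > 0) out <- out + rnorm(n, 0, noise_sd)
  out
}
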
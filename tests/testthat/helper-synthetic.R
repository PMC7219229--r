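# Shared fixtures, all built in code.

# Ideal radar: balanced channels, no offsets, no noise.
ideal_params <- function(...) {
  radar_params(A_I = 1, A_Q = 1, DC_I = 0, DC_Q = 0, dphi = 0,
               phase_noise_sd = 0, noise_sd = 0, ...)
}

# Jitter-free vitals for deterministic beat placement.
steady_vitals <- function(mean_hr = 60, ...) {
  vital_model(mean_hr = mean_hr, hrv_sd = 0, ...)
}

# A tiny low-noise cohort for fast end-to-end checks.
tiny_cohort <- function(n = 3, duration = 40, seed = 7) {
  generate_cohort(n, duration,
                  base_params = radar_params(noise_sd = 0.01),
                  seed = seed)
}

# Constructed window set: linearly separable targets driven by one input.
separable_windows <- function(n = 100, d = 8, seed = 5) {
  withr::with_seed(seed, {
    X <- matrix(stats::runif(n * d, -1, 1), n, d)
    y <- as.numeric(X[, 1] > 0)
    structure(list(inputs = X, targets = y,
                   timestamps = seq_len(n) / 100, rate = 100, memory = d / 100,
                   groups = NULL),
              class = "window_set")
  })
}

expect_close <- function(object, expected, tol = 1e-9) {
  expect_true(max(abs(object - expected)) <= tol,
              label = sprintf("max|diff| = %g <= %g",
                              max(abs(object - expected)), tol))
}
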
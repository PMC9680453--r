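# Shared fixtures, all generated in code at test time.

# Compact phantom configuration: small images keep rendering fast while
# preserving every morphological contract.
small_config <- function(n_subjects = 4L, seed = 42L, image_size = 64L, ...) {
  phantom_config(n_subjects = n_subjects, image_size = image_size, seed = seed, ...)
}

# A fixed geometry draw usable without a subject (mirrors sample_geometry()).
fixed_geometry <- function() {
  list(cx = 0.5, cy = 0.5,
       cavity = c(ap = 0.065, mid = 0.11, bs = 0.15) * 64,
       wall = 0.05 * 64,
       blob_r = 2.0, n_blobs = 2L,
       blob_angle = c(0.6, 3.4), blob_dist = c(0.3, 0.45),
       systolic_scale = 0.7,
       crescent_arc = pi, crescent_rot = 1.0)
}

random_cm <- function(seed, max_count = 20L) {
  withr::with_seed(seed, matrix(sample(0:max_count, 25, TRUE), 5, 5))
}

random_sequence <- function(n, d = 6L, seed = 1L, time_steps = 25L) {
  withr::with_seed(seed, build_sequences(
    matrix(rnorm(n * d), n, d),
    sample(0:4, n, TRUE),
    time_steps = time_steps))
}
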
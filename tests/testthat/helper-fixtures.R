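# Shared fixtures, built once per test run and cached in-process.
.fixtures <- new.env(parent = emptyenv())

# Full-scale study-condition cohort (50 patients, 3-7 days) used by the
# end-to-end evaluation tests; extraction is the expensive step, so both
# the cohort and its feature store are cached.
study_cohort <- function() {
  if (is.null(.fixtures$study_co)) {
    .fixtures$study_co <- simulate_cohort(cohort_config(n_patients = 50,
                                                        seed = 42))
  }
  .fixtures$study_co
}

study_features <- function() {
  if (is.null(.fixtures$study_fx)) {
    .fixtures$study_fx <- extract_features(study_cohort())
  }
  .fixtures$study_fx
}

study_prep <- function() {
  if (is.null(.fixtures$study_prep)) {
    .fixtures$study_prep <- prepare_loocv(study_features())
  }
  .fixtures$study_prep
}

# Small cohort for structural pipeline tests.
small_features <- function() {
  if (is.null(.fixtures$small_fx)) {
    co <- simulate_cohort(cohort_config(n_patients = 6,
                                        recording_days_range = c(3, 3),
                                        seed = 11))
    .fixtures$small_co <- co
    .fixtures$small_fx <- extract_features(co)
  }
  .fixtures$small_fx
}

small_cohort <- function() {
  invisible(small_features())
  .fixtures$small_co
}

# rr_series tibble from a plain vector of intervals (contiguous beats).
rr_series <- function(rr_ms, t0 = 0) {
  onsets <- t0 + c(0, cumsum(rr_ms))[seq_along(rr_ms)]
  tibble::tibble(onset_ms = onsets, rr_ms = as.numeric(rr_ms))
}

# Beat sequence whose RR is sinusoidally modulated at f_hz, evaluated at
# each beat's onset; used as a known-band spectral fixture.
sine_rr <- function(f_hz, amp_ms, duration_min = 30, mean_rr = 800) {
  t <- 0
  onsets <- c()
  rr <- c()
  while (t < duration_min * 60 * 1000) {
    r <- mean_rr + amp_ms * sin(2 * pi * f_hz * t / 1000)
    onsets <- c(onsets, t)
    rr <- c(rr, r)
    t <- t + r
  }
  tibble::tibble(onset_ms = onsets, rr_ms = rr)
}

# A minimal model configuration for fast structural tests.
tiny_model_config <- function(max_epochs = 3, ...) {
  model_config(lstm_units = c(6, 5, 4), attention_dim = 4, head_hidden = 4,
               max_epochs = max_epochs, batch_size = 4, ...)
}

random_tensor <- function(t_len, f, seed, n_masked = 0) {
  withr::with_seed(seed, {
    mask <- rep(TRUE, t_len)
    if (n_masked > 0) mask[sample.int(t_len, n_masked)] <- FALSE
    x <- matrix(rnorm(t_len * f), t_len, f)
    x[!mask, ] <- 0
    structure(list(patient_id = paste0("T", seed),
                   X = x, mask = mask, context = rnorm(2)),
              class = "af_tensor")
  })
}
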
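# Shared fixtures. Expensive cohorts are built once per test run and
# memoised in this environment.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# An "easy" simulation regime: strong, consistent multichannel reactions
# and low sensor noise, so that the latent pain level is clearly encoded
# in the features. Used for parameter-recovery checks.
easy_sim_config <- function(n_subjects = 6, seed = 11) {
  sim_config(
    n_subjects = n_subjects,
    episode_rate = 2.5,
    pain_decay_s = 120,
    reactivity_ranges = list(EDA = c(1.5, 2.5), EMG = c(1.5, 2.5),
                             RSP = c(1.5, 2.5), BVP = c(1.5, 2.5),
                             GRIP = c(1.5, 2.5)),
    noise_levels = list(EDA = 0.002, EMG = 0.01, RSP = 0.004,
                        BVP = 0.004, GRIP = 0.004),
    seed = seed
  )
}

# Easy-regime cohort with full scattering features (the expensive fixture).
easy_scattering_dataset <- function() {
  memo("easy_scattering_dataset", function() {
    cohort <- simulate_cohort(easy_sim_config())
    build_dataset(lapply(cohort, `[[`, "recording"), "scattering")
  })
}

# Larger easy-regime cohort with cheap STFT features, for checks that only
# exercise the labeling / classification machinery.
easy_stft_dataset <- function() {
  memo("easy_stft_dataset", function() {
    cohort <- simulate_cohort(easy_sim_config(n_subjects = 12, seed = 23))
    build_dataset(lapply(cohort, `[[`, "recording"), "stft")
  })
}

# One default-regime simulated subject, preprocessed.
default_subject <- function() {
  memo("default_subject", function() {
    sub <- simulate_subject(sim_config(n_subjects = 1, seed = 7), 1)
    list(raw = sub$recording, truth = sub$truth,
         pre = preprocess_recording(sub$recording))
  })
}

# Two-class Gaussian blob toy set.
make_blobs <- function(n = 200, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n), ncol = 2),
               matrix(rnorm(n, mean = sep), ncol = 2))
    y <- factor(rep(c("a", "b"), each = n / 2))
    list(x = x, y = y)
  })
}
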
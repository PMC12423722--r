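# Shared fixtures, built in code.

# distance from each true position to the nearest detected index
match_err <- function(detected, truth) {
  vapply(truth, function(t) {
    if (length(detected) == 0) return(Inf)
    min(abs(detected - t))
  }, numeric(1))
}

# random in-bounds five-Gaussian parameter draw for a cycle of length M:
# positions inside ordered fifths with margin, separated widths/amplitudes
rand_components <- function(M) {
  fifth <- M / 5
  repeat {
    beta <- sort(stats::runif(5, (0:4) * fifth + 2, (1:5) * fifth - 2))
    if (all(diff(beta) > M / 25)) break
  }
  component_set(alpha = stats::runif(5, 0.1, 1.0),
                beta = beta,
                gamma = stats::runif(5, M / 30, M / 8), M = M)
}

# minimal pulse_cycle wrapper around a sample vector
as_cycle <- function(samples, fs = 256, n_R = -70L) {
  structure(list(samples = samples, M = length(samples), Ts = 1 / fs,
                 fs = fs, n_R = n_R), class = "pulse_cycle")
}

# clean synthetic record (no drift / mains / noise), jittered morphology
clean_record <- function(n_beats = 40, seed = 1, ...) {
  synth_record(n_beats = n_beats, baseline_amp = 0, powerline_amp = 0,
               noise_sd = 0, seed = seed, ...)
}

# noise SD corresponding to 20 dB SNR for the default clean record
snr20_noise_sd <- function() {
  rec <- clean_record(n_beats = 20, seed = 999, jitter_sd = 0, hrv_sd = 0)
  sqrt(mean(rec$ppg^2)) / 10
}

# band power via the discrete Fourier transform (oracle for filter tests)
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- freqs >= lo & freqs <= hi & freqs <= fs / 2
  sum(sp[sel])
}

model_features <- c("age", "PAT", "SI", "P2O", "age_index",
                    paste0("noise", 1:4))

# participant-split train/test from a feature cohort
split_cohort <- function(cohort, n_test = 15, seed = 1) {
  parts <- unique(cohort$participant_id)
  set.seed(seed)
  test_p <- sample(parts, n_test)
  list(train = cohort[!cohort$participant_id %in% test_p, , drop = FALSE],
       test = cohort[cohort$participant_id %in% test_p, , drop = FALSE])
}

rmse_of <- function(model, data) {
  sqrt(mean((data$pwv - as.numeric(predict(model, data)))^2))
}
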
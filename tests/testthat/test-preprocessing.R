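# Baseline removal, notch filtering, normalization, detection, SQI.

test_that("wavelet transform reconstructs perfectly and conserves energy", {
  set.seed(4)
  x <- rnorm(1024)
  d <- dwt_periodized(x, 9)
  expect_lt(max(abs(idwt_periodized(d) - x)), 1e-10)
  energy <- sum(d$approx^2) + sum(unlist(d$details)^2)
  expect_equal(energy, sum(x^2), tolerance = 1e-12)
})

test_that("baseline removal suppresses sub-0.5 Hz drift, preserves the pulse band", {
  fs <- 256
  rec <- clean_record(n_beats = 40, seed = 2, jitter_sd = 0, hrv_sd = 0)
  n0 <- 17L * 512L                       # circular-projection domain
  x <- rec$ppg[seq_len(n0)] - mean(rec$ppg[seq_len(n0)])
  tt <- (seq_len(n0) - 1) / fs
  drift <- 0.5 * sin(2 * pi * 0.1 * tt)
  cleaned <- remove_baseline(x + drift, fs)
  p_in <- band_power(x + drift, fs, 0.02, 0.45)
  p_out <- band_power(cleaned, fs, 0.02, 0.45)
  expect_lt(p_out / p_in, 0.1)                       # >= 90% drift power gone
  # pulse band amplitude preserved within 5% on a drift-free (mean-free)
  # signal; the comparison excludes the 1.5 s boundary transients of the
  # circular transform
  flat <- remove_baseline(x, fs)
  trim <- round(1.5 * fs)
  expect_lt(max(abs(flat - x)[trim:(n0 - trim)]) / max(abs(x)), 0.05)
  # linearity: zero in, zero out
  expect_equal(remove_baseline(numeric(4 * fs), fs), numeric(4 * fs))
  expect_error(remove_baseline(numeric(100), fs), "two seconds")
})

test_that("baseline removal is idempotent on its projection domain", {
  rec <- clean_record(n_beats = 40, seed = 6)
  x <- rec$ppg[seq_len(16L * 512L)]
  once <- remove_baseline(x, rec$fs)
  twice <- remove_baseline(once, rec$fs)
  expect_lt(max(abs(twice - once)) / max(abs(once)), 1e-6)
})

test_that("notch attenuates 60 Hz by >= 20 dB and spares the pulse band", {
  fs <- 256
  tt <- (0:(6 * fs - 1)) / fs
  tone60 <- sin(2 * pi * 60 * tt)
  out60 <- suppress_powerline(tone60, fs)
  expect_lt(sqrt(mean(out60^2)) / sqrt(mean(tone60^2)), 0.1)   # >= 20 dB
  tone2 <- sin(2 * pi * 2 * tt)
  out2 <- suppress_powerline(tone2, fs)
  expect_gt(sqrt(mean(out2^2)) / sqrt(mean(tone2^2)), 0.89)    # <= 1 dB
  # zero phase: impulse response symmetric about the impulse (up to the
  # filter's end-condition approximation)
  imp <- numeric(512); imp[256] <- 1
  h <- suppress_powerline(imp, fs)
  expect_lt(max(abs(h[256 + 1:200] - h[256 - 1:200])), 1e-3)
  expect_error(suppress_powerline(tone2, fs = 100), "too low")
})

test_that("amplitude normalization maps the segment onto [-1, +1]", {
  expect_equal(normalize_amplitude(c(-2, 0, 2)), c(-1, 0, 1))
  expect_equal(normalize_amplitude(c(0, 2, 4)), c(-1, 0, 1))
  expect_error(normalize_amplitude(c(5, 5, 5)), "constant")
  set.seed(8)
  x <- normalize_amplitude(rnorm(100))
  expect_equal(range(x), c(-1, 1))
})

test_that("R peaks are exact on clean records and robust at SNR 20 dB", {
  rec <- clean_record(n_beats = 60, seed = 3)
  r <- detect_r_peaks(rec$ecg, rec$fs)
  err <- match_err(r, rec$annotations$r_peaks)
  expect_length(r, 60)
  expect_true(all(err <= 2))
  expect_identical(detect_r_peaks(numeric(2000), 256), integer(0))

  nsd <- snr20_noise_sd()
  hits <- 0; total <- 0
  for (s in 1:3) {
    rn <- synth_record(n_beats = 60, baseline_amp = 0, powerline_amp = 0,
                       noise_sd = nsd, seed = 300 + s)
    e <- match_err(detect_r_peaks(rn$ecg, rn$fs), rn$annotations$r_peaks)
    hits <- hits + sum(e <= 2); total <- total + 60
  }
  expect_gte(hits / total, 59 / 60)
})

test_that("valleys are within 2 samples of the construction onsets", {
  for (s in 1:3) {
    rec <- clean_record(n_beats = 60, seed = s)
    v <- detect_valleys(rec$ppg, rec$fs)
    expect_true(all(match_err(v, rec$annotations$valleys) <= 2))
  }
  # a single pulse padded into a flat record yields exactly one valley
  M <- 200
  pulse <- synth_pulse(template_components(M), M)
  padded <- c(rep(pulse[1], 300), pulse, rep(pulse[M], 500))
  expect_length(detect_valleys(padded, 256), 1)
  # monotone ramp: no cycle
  expect_length(detect_valleys(seq(0, 1, length.out = 1000), 256), 0)
})

test_that("cycle-length SQI statistics and screening behave as specified", {
  fs <- 256
  # identical cycle lengths: CV = 0, skewness = 0, all cycles pass
  valleys <- seq(1L, by = 200L, length.out = 6L)
  r_peaks <- valleys - 70L
  r_peaks <- r_peaks[r_peaks > 0]
  n <- max(valleys) + 300L
  seg <- segment_and_screen(rep(sin(seq_len(n) / 10), 1), rnorm(n, 0, 1e-3),
                            valleys, r_peaks, fs)
  expect_equal(seg$sqi$stats$cv, c(0, 0))
  expect_equal(seg$sqi$stats$skewness, c(0, 0))
  expect_true(seg$sqi$record_pass)

  # lengths 200,200,200,400: population-SD CV = 0.3464 > 0.2 -> record fails
  valleys2 <- c(1L, 201L, 401L, 601L, 1001L)
  r2 <- valleys2 - 70L; r2 <- r2[r2 > 0]
  n2 <- 1400L
  seg2 <- segment_and_screen(rnorm(n2), rnorm(n2), valleys2, r2, fs)
  expect_equal(seg2$sqi$stats$cv[1], sqrt(7500) / 250, tolerance = 1e-6)
  expect_false(seg2$sqi$record_pass)
  expect_true(all(seg2$sqi$flags %in% c("sqi_fail", "no_r_pairing")))

  # a valley with no R peak within the pairing window is flagged distinctly
  valleys3 <- seq(1L, by = 200L, length.out = 6L)
  r3 <- (valleys3 - 70L)[-2]          # second cycle loses its R peak
  r3 <- r3[r3 > 0]
  seg3 <- segment_and_screen(rnorm(1400), rnorm(1400), valleys3, r3, fs)
  expect_equal(seg3$sqi$flags[1], "no_r_pairing")

  expect_error(segment_and_screen(rnorm(500), rnorm(500), c(1L, 100L), 1L, fs),
               "3 cycles")
})

test_that("segmentation tiles the record between first and last valley", {
  rec <- clean_record(n_beats = 20, seed = 9)
  fs <- rec$fs
  ppg <- normalize_amplitude(rec$ppg)
  v <- detect_valleys(ppg, fs)
  r <- detect_r_peaks(rec$ecg, fs)
  seg <- segment_and_screen(ppg, rec$ecg, v, r, fs)
  spans <- vapply(seg$cycles, function(cy) cy$M, numeric(1))
  expect_equal(sum(spans), v[length(v)] - v[1])
  onsets <- vapply(seg$cycles, function(cy) cy$onset_index, numeric(1))
  expect_equal(onsets, v[-length(v)])               # no gaps, no overlap
})
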
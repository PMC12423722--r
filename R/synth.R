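# Synthetic-data module: Gaussian pulse model, PPG/ECG record generator and
# cohort generator with known ground truth. The pulse model doubles as the
# oracle for the weighted pulse decomposition.

#' Construct a Gaussian component-wave parameter set
#'
#' A component wave i is parameterized by theta_i = (alpha_i, beta_i,
#' gamma_i): pulse amplitude (normalized units), pulse position and pulse
#' width (both in samples). A canonical set holds exactly five components
#' with non-decreasing positions; the systolic complex is G1-G3 and the
#' diastolic complex G4-G5.
#'
#' @param alpha,beta,gamma numeric vectors of equal length (amplitudes > 0,
#'   positions >= 0, widths > 0).
#' @param M optional cycle length; when given, positions must satisfy
#'   `beta < M`.
#' @param n_components required number of components (default 5; set to
#'   `NA` to allow any count, e.g. for single-wave illustrations).
#' @return object of class `component_set`: a data.frame with columns
#'   `alpha`, `beta`, `gamma`, one row per component.
#' @export
component_set <- function(alpha, beta, gamma, M = NULL, n_components = 5L) {
  k <- length(alpha)
  stopifnot(length(beta) == k, length(gamma) == k)
  if (!is.na(n_components) && k != n_components)
    stop("expected ", n_components, " components, got ", k)
  if (any(alpha <= 0)) stop("component amplitudes must be positive")
  if (any(gamma <= 0)) stop("component widths must be positive")
  if (any(beta < 0)) stop("component positions must be non-negative")
  if (!is.null(M) && any(beta >= M)) stop("component positions must lie before M")
  if (is.unsorted(beta)) stop("component positions must be non-decreasing")
  structure(data.frame(alpha = alpha, beta = beta, gamma = gamma),
            class = c("component_set", "data.frame"))
}

#' Synthesize a PPG pulse from Gaussian component waves
#'
#' Evaluates `G(n) = sum_i alpha_i * exp(-(n - beta_i)^2 / (2 gamma_i^2))`
#' for n = 0..M-1 (positions and widths in samples; the sampling interval
#' cancels when all quantities are expressed in samples).
#'
#' @param theta a `component_set` (or data.frame with columns alpha, beta,
#'   gamma).
#' @param M cycle length in samples (>= 32).
#' @param fs sampling rate in Hz (carried for metadata; the waveform is
#'   sample-indexed).
#' @return numeric vector of length `M`.
#' @export
synth_pulse <- function(theta, M, fs = 256) {
  stopifnot(M >= 32)
  if (any(theta$beta >= M)) stop("component positions must lie before M")
  if (any(theta$alpha <= 0) || any(theta$gamma <= 0))
    stop("invalid component parameters")
  n <- seq_len(M) - 1
  out <- numeric(M)
  for (i in seq_len(nrow(theta))) {
    out <- out + theta$alpha[i] *
      exp(-(n - theta$beta[i])^2 / (2 * theta$gamma[i]^2))
  }
  out
}

# Default wrist-PPG component template, as fractions of the cycle length.
# Chosen to emulate wrist morphology: dominant forward/systolic complex, a
# shallow notch, and a broad, low diastolic wave whose tail meets the next
# foot near-continuously.
.default_template <- function() {
  list(alpha = c(0.85, 0.50, 0.30, 0.08, 0.16),
       beta  = c(0.11, 0.19, 0.30, 0.48, 0.74),
       gamma = c(0.040, 0.055, 0.075, 0.085, 0.140))
}

#' Default component template scaled to a cycle length
#'
#' @param M cycle length in samples.
#' @param template list with `alpha`, `beta`, `gamma` as fractions of `M`
#'   (positions/widths); defaults to the built-in wrist template.
#' @return a `component_set` in sample units.
#' @export
template_components <- function(M, template = .default_template()) {
  component_set(alpha = template$alpha,
                beta = template$beta * M,
                gamma = pmax(1, template$gamma * M), M = M)
}

#' Generate a synthetic wrist PPG + ECG record
#'
#' Builds a quasi-periodic PPG as a concatenation of five-Gaussian pulses
#' (per-beat parameter jitter, heart-rate variability) and a synchronized
#' ECG with a narrow R spike and a broader T bump per beat, the R peak
#' preceding each PPG valley by the pulse arrival time. Baseline wander,
#' 60 Hz interference and white noise are added to both channels.
#'
#' @param n_beats number of beats (>= 3).
#' @param fs sampling rate in Hz (default 256).
#' @param hr_bpm mean heart rate in beats per minute (default 72).
#' @param pat_samples pulse arrival time in samples (> 0; default 70,
#'   i.e. ~0.27 s at 256 Hz).
#' @param template component template (fractions of M), as in
#'   [template_components()].
#' @param jitter_sd relative SD of per-beat multiplicative jitter on
#'   component amplitudes/positions/widths (default 0.01).
#' @param hrv_sd relative SD of per-beat cycle-length variation
#'   (default 0.01).
#' @param baseline_amp,baseline_freq baseline-wander amplitude (normalized
#'   units) and frequency (Hz); defaults 0.3 and 0.2.
#' @param powerline_amp 60 Hz interference amplitude (default 0.05).
#' @param noise_sd additive white-noise SD (default 0.01).
#' @param participant_id,round_id metadata labels.
#' @param seed integer seed; the record is a pure function of the
#'   configuration and seed.
#' @return object of class `ppg_record`: list with `ppg`, `ecg`, `fs`,
#'   `participant_id`, `round_id`, and `annotations` (ground-truth valley
#'   and R indices (1-based), per-beat true PAT in samples, per-beat true
#'   `component_set`, per-beat cycle lengths).
#' @export
synth_record <- function(n_beats, fs = 256, hr_bpm = 72, pat_samples = 70,
                         template = .default_template(),
                         jitter_sd = 0.01, hrv_sd = 0.01,
                         baseline_amp = 0.3, baseline_freq = 0.2,
                         powerline_amp = 0.05, noise_sd = 0.01,
                         participant_id = "P01", round_id = "R01",
                         seed) {
  if (missing(seed)) stop("seed is required: records are reproducible by contract")
  if (n_beats < 3) stop("need at least 3 beats for cycle statistics")
  if (pat_samples <= 0) stop("pulse arrival time must be positive")
  set.seed(as.integer(seed))
  M0 <- round(60 / hr_bpm * fs)
  lead <- pat_samples + round(0.3 * fs)
  tail <- round(0.4 * fs)

  Ms <- pmax(32L, round(M0 * (1 + stats::rnorm(n_beats, 0, hrv_sd))))
  onsets <- lead + 1L + c(0L, cumsum(Ms[-n_beats]))  # 1-based valley indices
  total <- lead + sum(Ms) + tail

  ppg <- numeric(total)
  # lead-in carries the tail of a phantom beat so the record starts
  # mid-cycle (no artificial flat segment below the pulse foot)
  phantom <- synth_pulse(template_components(M0, template), M0, fs)
  fill <- rep(phantom, ceiling(lead / M0) + 1L)
  ppg[seq_len(lead)] <- fill[seq.int(length(fill) - lead + 1L, length(fill))]
  thetas <- vector("list", n_beats)
  for (k in seq_len(n_beats)) {
    M <- Ms[k]
    jit <- 1 + stats::rnorm(9, 0, jitter_sd)
    th <- component_set(
      alpha = template$alpha * c(jit[1], jit[1], jit[1], jit[2], jit[2]),
      beta  = sort(template$beta * M * c(1, jit[3], jit[4], jit[5], jit[6])),
      gamma = pmax(1, template$gamma * M * c(jit[7], jit[7], jit[8], jit[9], jit[9])),
      M = M)
    thetas[[k]] <- th
    ppg[seq.int(onsets[k], onsets[k] + M - 1L)] <- synth_pulse(th, M, fs)
  }

  # ECG: R spike (narrow Gaussian) + T bump per beat
  ecg <- numeric(total)
  r_idx <- onsets - pat_samples
  t_off <- round(0.25 * fs)
  n_all <- seq_len(total)
  for (k in seq_len(n_beats)) {
    ecg <- ecg + exp(-(n_all - r_idx[k])^2 / (2 * 2.5^2)) +
      0.3 * exp(-(n_all - (r_idx[k] + t_off))^2 / (2 * 10^2))
  }

  tt <- (n_all - 1) / fs
  drift <- baseline_amp * sin(2 * pi * baseline_freq * tt)
  mains <- powerline_amp * sin(2 * pi * 60 * tt)
  ppg <- ppg + drift + mains + stats::rnorm(total, 0, noise_sd)
  ecg <- ecg + drift + mains + stats::rnorm(total, 0, noise_sd)

  structure(list(
    ppg = ppg, ecg = ecg, fs = fs,
    participant_id = participant_id, round_id = round_id,
    annotations = list(valleys = onsets, r_peaks = r_idx,
                       pat = rep(pat_samples, n_beats),
                       components = thetas, M = Ms)),
    class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("Synthetic PPG/ECG record: %d samples @ %g Hz, %d beats (%s/%s)\n",
              length(x$ppg), x$fs, length(x$annotations$valleys),
              x$participant_id, x$round_id))
  invisible(x)
}

#' Plot a synthetic record with its ground-truth annotations
#'
#' @param x a `ppg_record`.
#' @param seconds time span to display from the start (default 6).
#' @param ... ignored.
#' @export
plot.ppg_record <- function(x, seconds = 6, ...) {
  n <- min(length(x$ppg), round(seconds * x$fs))
  tt <- (seq_len(n) - 1) / x$fs
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(tt, x$ppg[seq_len(n)], type = "l", xlab = "", ylab = "PPG")
  v <- x$annotations$valleys[x$annotations$valleys <= n]
  graphics::abline(v = (v - 1) / x$fs, col = "grey70", lty = 3)
  graphics::plot(tt, x$ecg[seq_len(n)], type = "l", xlab = "time (s)", ylab = "ECG")
  r <- x$annotations$r_peaks[x$annotations$r_peaks <= n]
  graphics::abline(v = (r - 1) / x$fs, col = "grey70", lty = 3)
  invisible(x)
}

#' Write a record to CSV (with a JSON annotation sidecar)
#'
#' Columns `t`, `ppg`, `ecg`; annotations are written to `<path>.json`.
#'
#' @param record a `ppg_record`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  tt <- (seq_along(record$ppg) - 1) / record$fs
  utils::write.csv(data.frame(t = tt, ppg = record$ppg, ecg = record$ecg),
                   path, row.names = FALSE)
  ann <- record$annotations
  jsonlite::write_json(
    list(fs = record$fs, participant_id = record$participant_id,
         round_id = record$round_id, valleys = ann$valleys,
         r_peaks = ann$r_peaks, pat = ann$pat, M = ann$M,
         components = lapply(ann$components, as.data.frame)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a record written by [write_record_csv()]
#'
#' @param path CSV path; the `<path>.json` sidecar is read when present.
#' @return a `ppg_record` (annotations `NULL` when no sidecar exists).
#' @export
read_record_csv <- function(path) {
  df <- utils::read.csv(path)
  side <- paste0(path, ".json")
  ann <- NULL; fs <- NULL; pid <- "unknown"; rid <- "unknown"
  if (file.exists(side)) {
    j <- jsonlite::read_json(side, simplifyVector = TRUE)
    fs <- j$fs; pid <- j$participant_id; rid <- j$round_id
    comps <- lapply(seq_len(length(j$M)), function(k) {
      cd <- as.data.frame(j$components[[k]])
      component_set(cd$alpha, cd$beta, cd$gamma)
    })
    ann <- list(valleys = j$valleys, r_peaks = j$r_peaks, pat = j$pat,
                components = comps, M = j$M)
  }
  if (is.null(fs)) fs <- round(1 / stats::median(diff(df$t)))
  structure(list(ppg = df$ppg, ecg = df$ecg, fs = fs,
                 participant_id = pid, round_id = rid, annotations = ann),
            class = "ppg_record")
}

#' Generate a synthetic cohort of records with planted PWV ground truth
#'
#' Assigns each participant anthropometrics and a true baPWV per
#' measurement, then maps PWV to signal morphology so that downstream
#' recovery is possible: higher PWV shortens the pulse arrival time and
#' advances the diastolic component (shorter stiffness index), mirroring
#' the physiology of stiffer arteries.
#'
#' @param n_participants number of participants (>= 4, so participant-
#'   disjoint splits exist).
#' @param rounds_per_participant measurement rounds per participant
#'   (default 3); each round yields one record and shares the
#'   participant's PWV measurement for that round.
#' @param n_beats beats per record (default 20).
#' @param pwv_range true PWV range in cm/s (default c(1000, 2100), within
#'   the validated [800, 2400] envelope).
#' @param pwv_function optional function(age, pat_samples) -> PWV used
#'   instead of the default uniform draw; must map into `pwv_range`.
#' @param noise_sd record noise SD (default 0.01).
#' @param seed integer seed.
#' @return object of class `synthetic_cohort`: list with `records`,
#'   `participants` (data.frame: participant_id, age, height_cm,
#'   weight_kg), `measurements` (data.frame: participant_id, round_id,
#'   true_pwv, pat_samples), and `generative_spec`.
#' @export
synth_cohort <- function(n_participants, rounds_per_participant = 3,
                         n_beats = 20, pwv_range = c(1000, 2100),
                         pwv_function = NULL, noise_sd = 0.01, seed) {
  if (missing(seed)) stop("seed is required")
  if (n_participants < 4) stop("need >= 4 participants for participant splits")
  if (pwv_range[1] < 800 || pwv_range[2] > 2400)
    stop("pwv_range must lie within [800, 2400] cm/s")
  set.seed(as.integer(seed))
  participants <- data.frame(
    participant_id = sprintf("P%02d", seq_len(n_participants)),
    age = round(stats::runif(n_participants, 35, 85)),
    height_cm = round(stats::runif(n_participants, 150, 190)),
    weight_kg = round(stats::runif(n_participants, 50, 95)))

  recs <- list()
  meas <- NULL
  for (i in seq_len(n_participants)) {
    base_pwv <- stats::runif(1, pwv_range[1], pwv_range[2])
    for (r in seq_len(rounds_per_participant)) {
      pwv <- min(pwv_range[2], max(pwv_range[1],
               base_pwv + stats::rnorm(1, 0, 20)))
      # morphology mapping: PAT and diastolic timing shrink with PWV
      frac <- (pwv - 800) / (2400 - 800)
      pat <- round(110 - 60 * frac)            # ~ 85..65 samples in range
      if (!is.null(pwv_function)) pwv <- pwv_function(participants$age[i], pat)
      tpl <- .default_template()
      tpl$beta[4] <- 0.48 - 0.06 * frac        # earlier reflection when stiff
      tpl$beta[5] <- 0.74 - 0.10 * frac
      tpl$alpha[5] <- 0.16 + 0.06 * frac
      rec_seed <- (as.integer(seed) * 1009L + i * 131L + r) %% .Machine$integer.max
      rec <- synth_record(
        n_beats = n_beats, pat_samples = pat, template = tpl,
        noise_sd = noise_sd,
        participant_id = participants$participant_id[i],
        round_id = sprintf("R%02d", r), seed = rec_seed)
      recs[[length(recs) + 1L]] <- rec
      meas <- rbind(meas, data.frame(
        participant_id = participants$participant_id[i],
        round_id = sprintf("R%02d", r), true_pwv = pwv, pat_samples = pat))
    }
  }
  structure(list(records = recs, participants = participants,
                 measurements = meas,
                 generative_spec = list(pwv_range = pwv_range,
                                        noise_sd = noise_sd, seed = seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, %d records, PWV %g-%g cm/s\n",
              nrow(x$participants), length(x$records),
              min(x$measurements$true_pwv), max(x$measurements$true_pwv)))
  invisible(x)
}

#' Generate a feature-level synthetic cohort with a piecewise PWV mapping
#'
#' Emulates the measurement-level feature matrix directly (no signal
#' synthesis): each participant receives a base PWV and every measurement
#' inherits features whose relation to PWV changes at the subdivision
#' boundary `tau`. The pulse arrival time shortens with PWV and saturates
#' above the boundary (a noisy regime separator); SI and P2O relate to
#' PWV with opposite slopes on the two sides, flat within a band around
#' the boundary, so resolving the regime first — the structure a
#' classify-then-regress model exploits — is required to use them; the
#' ageing index is informative in the high range only. Informative
#' features carry additive noise; four pure-noise features are appended.
#'
#' @param n_participants number of participants (>= 4).
#' @param rounds_per_participant measurements per participant (default 3).
#' @param pwv_range true PWV range in cm/s (default c(1000, 2300)).
#' @param tau slope-change point of the generative mapping (1600 cm/s).
#' @param noise_scale multiplier on all feature noise SDs (default 1;
#'   0 gives a noise-free cohort).
#' @param seed integer seed.
#' @return data.frame with `participant_id`, `pwv` (true value, cm/s) and
#'   feature columns `age`, `PAT`, `SI`, `P2O`, `age_index`,
#'   `noise1..noise4`.
#' @export
synth_feature_cohort <- function(n_participants = 50,
                                 rounds_per_participant = 3,
                                 pwv_range = c(1000, 2300), tau = 1600,
                                 noise_scale = 1, seed) {
  if (missing(seed)) stop("seed is required")
  if (n_participants < 4) stop("need >= 4 participants")
  set.seed(as.integer(seed))
  n <- n_participants * rounds_per_participant
  pid <- rep(sprintf("P%03d", seq_len(n_participants)),
             each = rounds_per_participant)
  base <- rep(stats::runif(n_participants, pwv_range[1], pwv_range[2]),
              each = rounds_per_participant)
  pwv <- pmin(pwv_range[2], pmax(pwv_range[1],
              base + stats::rnorm(n, 0, 30)))
  ns <- noise_scale
  lowside <- pwv < tau
  # Regime structure. PAT separates the regimes (timing shortens through
  # the boundary and saturates above it) but is noisy, so classification
  # is uncertain near the boundary. SI and P2O are informative in BOTH
  # regimes with opposite slopes that meet in a flat band of +/- dz
  # around the boundary: away from it their value does not identify the
  # regime, which a classify-then-regress model resolves before
  # regressing, while inside the band rows from either side are
  # feature-interchangeable, so widening a submodel's training range
  # across the boundary brings no contradictory labels. The age index
  # carries the high range only; age is a weak global trend.
  dz <- 200
  pat <- ifelse(lowside, 230 - 0.060 * pwv, 134 - 0.018 * (pwv - tau)) +
    stats::rnorm(n, 0, 6 * ns)
  si <- 40 + ifelse(lowside, 0.040 * pmax(0, tau - dz - pwv),
                    0.050 * pmax(0, pwv - tau - dz)) +
    stats::rnorm(n, 0, 1.5 * ns)
  p2o <- 130 + ifelse(lowside, 0.055 * pmax(0, tau - dz - pwv),
                      0.065 * pmax(0, pwv - tau - dz)) +
    stats::rnorm(n, 0, 2 * ns)
  agei <- -0.26 + ifelse(lowside, 0, 6e-4 * (pwv - tau)) +
    stats::rnorm(n, 0, 0.05 * ns)
  age <- 30 + (pwv - pwv_range[1]) / diff(pwv_range) * 45 +
    stats::rnorm(n, 0, 8 * ns)
  out <- data.frame(participant_id = pid, pwv = pwv, age = age, PAT = pat,
                    SI = si, P2O = p2o, age_index = agei)
  for (k in 1:4) out[[paste0("noise", k)]] <- stats::rnorm(n)
  out
}
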
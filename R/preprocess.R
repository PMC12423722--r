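# Preprocessing: baseline correction, powerline suppression, amplitude
# normalization, R-peak / valley detection, cycle segmentation and the
# cycle-length signal quality index (SQI).

#' Remove baseline wander by wavelet decomposition
#'
#' Decomposes the signal with a periodized sym8 DWT to a depth at which the
#' approximation band lies below 0.5 Hz (level 9 at fs = 256 Hz, band
#' [0, 0.25] Hz), zeroes the approximation coefficients and reconstructs.
#' The pulse band (0.5-10 Hz) passes essentially unchanged.
#'
#' The signal is reflection-padded to a multiple of `2^level` and cropped
#' after reconstruction, so arbitrary lengths are accepted as long as the
#' record covers at least two seconds.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz (default 256).
#' @param level decomposition depth; default chosen so the approximation
#'   band edge `fs / 2^(level+1)` falls below 0.25 Hz.
#' @return baseline-corrected signal, same length as `x`.
#' @export
remove_baseline <- function(x, fs = 256, level = NULL) {
  n <- length(x)
  if (n < 2 * fs) stop("signal shorter than two seconds; baseline removal unsupported")
  if (is.null(level)) level <- max(1L, ceiling(log2(fs / 0.25)) - 1L)  # fs=256 -> 9
  block <- 2L^level
  # When the length divides the decomposition block, the circular DWT
  # projection applies directly and the operator is exactly idempotent;
  # otherwise pad by reflection up to the next multiple and crop.
  pad_total <- (block - n %% block) %% block
  lp <- ceiling(pad_total / 2)
  rp <- floor(pad_total / 2)
  xp <- if (pad_total == 0L) x else
    c(rev(x[seq_len(min(lp, n))]), x, rev(x[seq.int(n - min(rp, n) + 1L, n)]))
  dec <- dwt_periodized(xp, level)
  dec$approx[] <- 0
  out <- idwt_periodized(dec)
  out[seq.int(min(lp, n) + 1L, min(lp, n) + n)]
}

#' Suppress 60 Hz powerline interference
#'
#' Second-order IIR notch (RBJ biquad) centered at `f0` with quality factor
#' `Q`, applied forward-backward ([signal::filtfilt]) for zero phase so that
#' fiducial positions are not delayed.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz; must exceed `2 * f0`.
#' @param f0 notch center frequency in Hz (default 60).
#' @param Q notch quality factor (default 30; ~2 Hz rejection bandwidth).
#' @return filtered signal, same length as `x`.
#' @export
suppress_powerline <- function(x, fs = 256, f0 = 60, Q = 30) {
  if (fs <= 2 * f0) stop("sampling rate too low for a ", f0, " Hz notch")
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  signal::filtfilt(signal::Arma(b = b, a = a), x)
}

#' Normalize a signal segment to [-1, +1]
#'
#' Affine map of the whole segment (not per cycle): the minimum maps to -1
#' and the maximum to +1.
#'
#' @param x numeric signal vector with non-zero range.
#' @return normalized signal.
#' @export
normalize_amplitude <- function(x) {
  r <- range(x)
  if (diff(r) <= 0) stop("constant signal: amplitude normalization undefined")
  2 * (x - r[1]) / (r[2] - r[1]) - 1
}

# Zero-phase Butterworth bandpass helper.
.bandpass <- function(x, fs, low, high, order = 2) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Detect ECG R peaks
#'
#' Energy-based QRS detector in the Pan-Tompkins style: bandpass 5-25 Hz,
#' differentiate, square, moving-window integrate (150 ms), threshold at a
#' fraction of the integrated-energy envelope, enforce a 200 ms refractory
#' period, then refine each detection to the local ECG maximum within
#' +/- 40 ms.
#'
#' @param ecg cleaned ECG signal.
#' @param fs sampling rate in Hz.
#' @param threshold_frac detection threshold as a fraction of the upper
#'   envelope of the integrated energy (default 0.35).
#' @return ascending integer vector of R-peak sample indices (1-based);
#'   empty when no QRS energy is found.
#' @export
detect_r_peaks <- function(ecg, fs = 256, threshold_frac = 0.35) {
  n <- length(ecg)
  if (n < fs) return(integer(0))
  if (max(ecg) - min(ecg) < .Machine$double.eps^0.5) return(integer(0))
  bp <- .bandpass(ecg, fs, 5, 25)
  der <- c(0, diff(bp))
  sq <- der^2
  win <- max(3L, round(0.15 * fs))
  integ <- stats::filter(sq, rep(1 / win, win), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)
  thr <- threshold_frac * stats::quantile(integ, 0.99)
  if (thr <= 0) return(integer(0))
  refractory <- round(0.2 * fs)
  above <- integ > thr
  peaks <- integer(0)
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      # refine: local maximum of the raw ECG around the energy burst
      lo <- max(1L, i - round(0.04 * fs))
      hi <- min(n, j + round(0.04 * fs))
      cand <- lo + which.max(ecg[lo:hi]) - 1L
      if (length(peaks) == 0L || cand - peaks[length(peaks)] >= refractory) {
        peaks <- c(peaks, cand)
      } else if (ecg[cand] > ecg[peaks[length(peaks)]]) {
        peaks[length(peaks)] <- cand
      }
      i <- j + refractory
    } else i <- i + 1L
  }
  peaks
}

#' Detect PPG pulse onsets (valleys)
#'
#' Locates the systolic upstrokes on a low-passed copy of the PPG
#' (zero-phase), walks left from each upstroke to the nearest local
#' minimum of a heavily smoothed copy (`coarse_hz`), then refines the
#' position on a lighter smoothing (`refine_hz`) within a small window.
#' The two-stage scheme keeps the foot localization robust to broadband
#' noise while limiting the bias a heavy smoother introduces at the
#' asymmetric pulse foot.
#'
#' @param ppg cleaned, normalized PPG signal.
#' @param fs sampling rate in Hz.
#' @param coarse_hz low-pass cutoff for the walk stage (default 8).
#' @param refine_hz low-pass cutoff for the refinement stage (default 12).
#' @return ascending integer vector of valley indices (1-based); empty when
#'   the signal carries no pulse cycle.
#' @export
detect_valleys <- function(ppg, fs = 256, coarse_hz = 8, refine_hz = 12) {
  n <- length(ppg)
  if (n < fs) return(integer(0))
  if (max(ppg) - min(ppg) < .Machine$double.eps^0.5) return(integer(0))
  sm <- .bandpass_low(ppg, fs, 15)
  der <- c(0, diff(sm))
  # systolic upstrokes: prominent maxima of the derivative
  thr <- 0.25 * max(der)
  if (thr <= 0) return(integer(0))
  min_sep <- round(0.4 * fs)
  ups <- integer(0)
  i <- 1L
  while (i <= n) {
    if (der[i] > thr) {
      j <- i
      while (j < n && der[j + 1L] > thr) j <- j + 1L
      cand <- i + which.max(der[i:j]) - 1L
      if (length(ups) == 0L || cand - ups[length(ups)] >= min_sep) ups <- c(ups, cand)
      i <- j + 1L
    } else i <- i + 1L
  }
  # zero-phase filtering rings at the record boundaries; ignore upstrokes
  # within the edge transients
  ups <- ups[ups > round(0.1 * fs) & ups <= n - round(0.25 * fs)]
  if (length(ups) == 0L) return(integer(0))
  sm_c <- .bandpass_low(ppg, fs, coarse_hz)
  sm_r <- .bandpass_low(ppg, fs, refine_hz)
  valleys <- integer(length(ups))
  max_walk <- round(0.5 * fs)
  w <- 5L
  for (k in seq_along(ups)) {
    i <- ups[k]
    lo <- max(1L, ups[k] - max_walk)
    while (i > lo && sm_c[i - 1L] < sm_c[i]) i <- i - 1L
    lo2 <- max(1L, i - w); hi2 <- min(n, i + w)
    valleys[k] <- lo2 + which.min(sm_r[lo2:hi2]) - 1L
  }
  unique(valleys)
}

.bandpass_low <- function(x, fs, high, order = 4) {
  bf <- signal::butter(order, high / (fs / 2), type = "low")
  signal::filtfilt(bf, x)
}

# Moment-based skewness; population (N) denominator, 0 for zero-spread input.
.skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

# Coefficient of variation with population (N) denominator.
.cv <- function(x) {
  m <- mean(x)
  if (m == 0) return(Inf)
  sqrt(mean((x - mean(x))^2)) / abs(m)
}

#' Segment a record into pulse cycles and screen them with the SQI
#'
#' Cuts the PPG into valley-to-valley cycles, pairs each cycle with the
#' latest R peak preceding its onset (within `pair_window_s`), and computes
#' the cycle-length signal quality index: skewness and coefficient of
#' variation of the PPG cycle lengths and of the ECG RR intervals. When
#' either statistic exceeds its threshold on either channel, the record's
#' cycles are flagged as failing the SQI and excluded from feature
#' extraction. Cycles without an R pairing are flagged separately.
#'
#' @param ppg,ecg preprocessed signals of equal length.
#' @param valleys valley indices from [detect_valleys()].
#' @param r_peaks R-peak indices from [detect_r_peaks()].
#' @param fs sampling rate in Hz.
#' @param skew_max maximum absolute cycle-length skewness (default 1.0).
#' @param cv_max maximum cycle-length coefficient of variation (default 0.2).
#' @param pair_window_s maximum R-to-valley pairing distance in seconds
#'   (default 0.6).
#' @return list with `cycles` (list of `pulse_cycle` objects that passed all
#'   screens) and `sqi` (an `sqi_report`: per-channel statistics, thresholds,
#'   and per-cycle pass/fail flags with reasons).
#' @export
segment_and_screen <- function(ppg, ecg, valleys, r_peaks, fs = 256,
                               skew_max = 1.0, cv_max = 0.2,
                               pair_window_s = 0.6) {
  stopifnot(length(ppg) == length(ecg))
  if (length(valleys) < 4L) stop("need at least 3 cycles (4 valleys) for the SQI")
  ppg_len <- diff(valleys)
  rr_len <- if (length(r_peaks) >= 2L) diff(r_peaks) else ppg_len
  stats_tab <- data.frame(
    channel = c("ppg", "ecg"),
    skewness = c(.skewness(ppg_len), .skewness(rr_len)),
    cv = c(.cv(ppg_len), .cv(rr_len)))
  record_pass <- all(abs(stats_tab$skewness) <= skew_max) &&
    all(stats_tab$cv <= cv_max)

  n_cyc <- length(valleys) - 1L
  Ts <- 1 / fs
  cycles <- vector("list", n_cyc)
  flag <- character(n_cyc)
  for (k in seq_len(n_cyc)) {
    onset <- valleys[k]
    M <- valleys[k + 1L] - onset
    prior <- r_peaks[r_peaks < onset & onset - r_peaks <= pair_window_s * fs]
    if (length(prior) == 0L) {
      flag[k] <- "no_r_pairing"
      next
    }
    if (!record_pass) {
      flag[k] <- "sqi_fail"
      next
    }
    if (M < 32L) {
      flag[k] <- "too_short"
      next
    }
    r_idx <- prior[length(prior)]
    # T peak: ECG maximum 150-350 ms after the paired R peak
    t_lo <- min(length(ecg), r_idx + round(0.15 * fs))
    t_hi <- min(length(ecg), r_idx + round(0.35 * fs))
    t_idx <- if (t_hi > t_lo) t_lo + which.max(ecg[t_lo:t_hi]) - 1L else NA_integer_
    cyc <- structure(list(
      samples = ppg[seq.int(onset, onset + M - 1L)],
      ecg = ecg[seq.int(max(1L, r_idx - round(0.1 * fs)), onset + M - 1L)],
      M = M, Ts = Ts, fs = fs,
      onset_index = onset,
      r_index = r_idx,
      n_R = r_idx - onset,
      n_T = if (is.na(t_idx)) NA_integer_ else t_idx - onset),
      class = "pulse_cycle")
    flag[k] <- "pass"
    cycles[[k]] <- cyc
  }
  keep <- flag == "pass"
  sqi <- structure(list(
    cycle_lengths_ppg = ppg_len, cycle_lengths_ecg = rr_len,
    stats = stats_tab, record_pass = record_pass,
    thresholds = c(skew_max = skew_max, cv_max = cv_max),
    flags = flag), class = "sqi_report")
  list(cycles = cycles[keep], sqi = sqi)
}

#' @export
print.sqi_report <- function(x, ...) {
  cat("Cycle-length SQI report\n")
  print(x$stats, row.names = FALSE)
  cat(sprintf("record %s; %d/%d cycles pass\n",
              if (x$record_pass) "PASS" else "FAIL",
              sum(x$flags == "pass"), length(x$flags)))
  invisible(x)
}

#' @export
print.pulse_cycle <- function(x, ...) {
  cat(sprintf("PPG pulse cycle: M = %d samples (%.3f s), onset @%d, nR = %d\n",
              x$M, x$M * x$Ts, x$onset_index, x$n_R))
  invisible(x)
}
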
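# Fiducial detection: PPG landmarks (systolic peak, dicrotic notch,
# diastolic peak), maximal-slope point on the first derivative, and the
# SDPPG a-f points on the second derivative.
#
# Convention: cycle-relative positions are 0-based offsets from the pulse
# onset (the valley), so the associated R peak has n_R < 0.

#' Derivative of a pulse cycle
#'
#' Central-difference first derivative scaled by 1/Ts, or the central
#' second difference scaled by 1/Ts^2; endpoints use one-sided differences.
#'
#' @param cycle a `pulse_cycle` (or numeric vector via `samples`).
#' @param order 1 (FDPPG) or 2 (SDPPG).
#' @param Ts sampling interval in seconds (taken from the cycle when given).
#' @return numeric vector, same length as the cycle.
#' @export
derivative_signal <- function(cycle, order = 1, Ts = NULL) {
  x <- if (inherits(cycle, "pulse_cycle")) cycle$samples else as.numeric(cycle)
  if (is.null(Ts)) Ts <- if (inherits(cycle, "pulse_cycle")) cycle$Ts else 1
  M <- length(x)
  stopifnot(M >= 32)
  if (!order %in% c(1, 2)) stop("order must be 1 or 2")
  if (order == 1) {
    d <- c(x[2] - x[1], (x[3:M] - x[1:(M - 2)]) / 2, x[M] - x[M - 1]) / Ts
  } else {
    d <- c(x[3] - 2 * x[2] + x[1],
           x[3:M] - 2 * x[2:(M - 1)] + x[1:(M - 2)],
           x[M] - 2 * x[M - 1] + x[M - 2]) / Ts^2
  }
  d
}

# 3-sample moving average (endpoints kept) to suppress quantization
# plateaus before extremum scans.
.smooth3 <- function(x) {
  M <- length(x)
  c(x[1], (x[1:(M - 2)] + x[2:(M - 1)] + x[3:M]) / 3, x[M])
}

# Landmark-scan smoothing: zero-phase 15 Hz low-pass (the pulse contour
# lives well below it), falling back to the 3-sample average on cycles
# too short to filter.
.scan_smooth <- function(x, fs) {
  if (length(x) >= 40)
    tryCatch(.bandpass_low(x, fs, 15), error = function(e) .smooth3(x))
  else .smooth3(x)
}

# Strict local maxima / minima indices of a vector (ties broken earliest
# by the strict comparison itself).
.strict_max <- function(x) {
  M <- length(x)
  idx <- 2:(M - 1)
  idx[x[idx] > x[idx - 1] & x[idx] > x[idx + 1]]
}
.strict_min <- function(x) {
  M <- length(x)
  idx <- 2:(M - 1)
  idx[x[idx] < x[idx - 1] & x[idx] < x[idx + 1]]
}

#' Locate systolic peak, dicrotic notch and diastolic peak
#'
#' The systolic peak is the first prominent maximum of the (lightly
#' smoothed) pulse; the notch is the first local minimum after it and the
#' diastolic peak the first local maximum after the notch. Landmarks that
#' do not exist in the waveform (frequent for the diastolic peak in wrist
#' PPG) are reported in `missing`.
#'
#' @param cycle a `pulse_cycle`.
#' @param prominence_frac minimum height of the systolic peak as a
#'   fraction of the cycle range (default 0.5).
#' @param min_prominence minimum rise of the diastolic peak above the
#'   notch, as a fraction of the cycle range (default 0.005); a shallower
#'   bump counts as a vanished diastolic peak.
#' @return list of class `fiducial_set` with 0-based cycle-relative
#'   positions `n_sys`, `n_notch`, `n_dia`, amplitudes `A_sys`, `A_notch`,
#'   `A_dia`, `n_R` (when the cycle carries one), and `missing` (character
#'   vector of absent landmark names).
#' @export
locate_ppg_landmarks <- function(cycle, prominence_frac = 0.5,
                                 min_prominence = 0.005) {
  fs_cyc <- if (!is.null(cycle$Ts)) 1 / cycle$Ts else 256
  if (max(cycle$samples) - min(cycle$samples) <= 1e-12)
    stop("flat cycle: no landmarks")
  s <- .scan_smooth(cycle$samples, fs_cyc)
  M <- length(s)
  rng <- max(s) - min(s)
  floor_amp <- min(s) + prominence_frac * rng
  cand <- .strict_max(s)
  cand <- cand[s[cand] >= floor_amp]
  if (length(cand) == 0L) cand <- which.max(s)
  n_sys <- cand[1L]
  missing <- character(0)
  n_notch <- NA_integer_; n_dia <- NA_integer_
  # notch: deepest point of the post-systolic basin (global argmin over
  # the 60% of the remaining cycle after the peak - robust to the shallow
  # plateau of wrist pulses); a minimum sitting at the search edge means
  # the decay is monotone and the notch has vanished
  hi_n <- n_sys + max(3L, round(0.6 * (M - n_sys)))
  hi_n <- min(hi_n, M - 1L)
  if (hi_n > n_sys + 2L) {
    seg <- s[(n_sys + 1L):hi_n]
    cand <- n_sys + which.min(seg)
    if (cand < hi_n - 2L) n_notch <- cand
  }
  if (is.na(n_notch)) missing <- c(missing, "notch", "diastolic")
  else {
    maxs_after <- .strict_max(s); maxs_after <- maxs_after[maxs_after > n_notch]
    maxs_after <- maxs_after[s[maxs_after] - s[n_notch] >= min_prominence * rng]
    if (length(maxs_after)) n_dia <- maxs_after[1L] else missing <- c(missing, "diastolic")
  }
  structure(list(
    n_sys = n_sys - 1L, A_sys = cycle$samples[n_sys],
    n_notch = if (is.na(n_notch)) NA_integer_ else n_notch - 1L,
    A_notch = if (is.na(n_notch)) NA_real_ else cycle$samples[n_notch],
    n_dia = if (is.na(n_dia)) NA_integer_ else n_dia - 1L,
    A_dia = if (is.na(n_dia)) NA_real_ else cycle$samples[n_dia],
    n_R = if (!is.null(cycle$n_R)) cycle$n_R else NA_integer_,
    M = M, missing = missing), class = "fiducial_set")
}

#' Locate the maximal-slope point
#'
#' First local maximum of the first-derivative PPG (the maximal rate of
#' blood-volume increase during the systolic upstroke); it must precede
#' the systolic peak.
#'
#' @param cycle a `pulse_cycle`.
#' @param landmarks optional result of [locate_ppg_landmarks()] (computed
#'   when absent).
#' @return list with `n_ms` (0-based position) and `A_ms1` (first-
#'   derivative amplitude at the point).
#' @export
locate_max_slope <- function(cycle, landmarks = NULL) {
  if (is.null(landmarks)) landmarks <- locate_ppg_landmarks(cycle)
  fs_cyc <- if (!is.null(cycle$Ts)) 1 / cycle$Ts else 256
  d1 <- .scan_smooth(derivative_signal(cycle, 1), fs_cyc)
  cand <- .strict_max(d1)
  cand <- cand[d1[cand] > 0]
  if (length(cand) == 0L || (cand[1L] - 1L) >= landmarks$n_sys)
    stop("no maximal-slope point before the systolic peak")
  list(n_ms = cand[1L] - 1L, A_ms1 = derivative_signal(cycle, 1)[cand[1L]])
}

#' Locate the SDPPG a-f points
#'
#' Scans the (lightly smoothed) second-derivative PPG: within the systolic
#' region, `a` is the first local maximum, `b` the first local minimum
#' after `a`, `c` the next local maximum and `d` the next local minimum.
#' `e` is the local maximum around the systole/diastole boundary (searched
#' in a window of +/- `e_window_frac * M` around the notch position, or
#' around `0.4 * M` when the notch is missing) and `f` the first local
#' minimum after `e`. Unresolvable points are reported in `missing`; when
#' `a` or `b` cannot be resolved the cycle is unusable for SDPPG features
#' (`usable = FALSE`).
#'
#' @param cycle a `pulse_cycle`.
#' @param landmarks result of [locate_ppg_landmarks()].
#' @param e_window_frac half-width of the e-search window as a fraction of
#'   M (default 0.1).
#' @return the `fiducial_set` extended with `n_a..n_f` (0-based), the
#'   second-derivative amplitudes `A_a2..A_f2`, `usable`, and an updated
#'   `missing`.
#' @export
locate_sdppg_points <- function(cycle, landmarks = NULL, e_window_frac = 0.1) {
  if (is.null(landmarks)) landmarks <- locate_ppg_landmarks(cycle)
  d2_raw <- derivative_signal(cycle, 2)
  d2 <- .smooth3(d2_raw)
  M <- length(d2)
  sys_end <- if (!is.na(landmarks$n_notch)) landmarks$n_notch + 1L else round(0.4 * M)
  sys_end <- min(max(sys_end, 8L), M)

  seg <- d2[seq_len(sys_end)]
  maxs <- .strict_max(seg); mins <- .strict_min(seg)
  pt <- list(a = NA_integer_, b = NA_integer_, c = NA_integer_,
             d = NA_integer_, e = NA_integer_, f = NA_integer_)
  miss <- landmarks$missing
  if (length(maxs)) {
    pt$a <- maxs[1L]
    bm <- mins[mins > pt$a]
    if (length(bm)) {
      pt$b <- bm[1L]
      cm <- maxs[maxs > pt$b]
      if (length(cm)) {
        pt$c <- cm[1L]
        dm <- mins[mins > pt$c]
        if (length(dm)) pt$d <- dm[1L] else miss <- c(miss, "d")
      } else miss <- c(miss, "c", "d")
    } else miss <- c(miss, "b", "c", "d")
  } else miss <- c(miss, "a", "b", "c", "d")
  usable <- !is.na(pt$a) && !is.na(pt$b)

  # e: local max of SDPPG around the systole/diastole boundary, strictly
  # after the last resolved systolic point (preserves a < b < c < d < e).
  # The boundary region carries little curvature, so e and f are searched
  # on a heavily low-passed SDPPG (8 Hz, zero phase) that suppresses the
  # second difference's noise amplification.
  fs_cyc <- if (!is.null(cycle$Ts)) 1 / cycle$Ts else 256
  d2_bound <- if (M >= 40) tryCatch(.bandpass_low(d2_raw, fs_cyc, 5),
                                    error = function(e) d2) else d2
  center <- if (!is.na(landmarks$n_notch)) landmarks$n_notch + 1L else round(0.4 * M)
  half <- max(3L, round(e_window_frac * M))
  last_sys <- max(c(1L, pt$a, pt$b, pt$c, pt$d), na.rm = TRUE)
  lo <- max(last_sys + 1L, center - half)
  hi <- min(M - 1L, center + half)
  if (lo < hi) {
    wseg <- d2_bound[lo:hi]
    wmax <- .strict_max(c(-Inf, wseg, -Inf)) - 1L  # allow window-edge maxima
    wmax <- wmax[wmax >= 1 & wmax <= length(wseg)]
    if (length(wmax)) pt$e <- lo + wmax[which.max(wseg[wmax])] - 1L
  }
  if (is.na(pt$e)) miss <- c(miss, "e", "f") else {
    fm <- .strict_min(d2_bound); fm <- fm[fm > pt$e]
    if (length(fm)) pt$f <- fm[1L] else miss <- c(miss, "f")
  }

  out <- landmarks
  for (nm in names(pt)) {
    out[[paste0("n_", nm)]] <- if (is.na(pt[[nm]])) NA_integer_ else pt[[nm]] - 1L
    out[[paste0("A_", nm, "2")]] <- if (is.na(pt[[nm]])) NA_real_ else d2_raw[pt[[nm]]]
  }
  out$usable <- usable
  out$missing <- unique(miss)
  out
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat("Fiducials (0-based cycle-relative positions):\n")
  show <- c("n_sys", "n_notch", "n_dia", "n_ms", "n_a", "n_b", "n_c",
            "n_d", "n_e", "n_f", "n_R")
  for (nm in show) if (!is.null(x[[nm]]))
    cat(sprintf("  %-8s %s\n", nm, format(x[[nm]])))
  if (length(x$missing)) cat("  missing:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Extract all fiducials of a cycle in one call
#'
#' Convenience wrapper running [locate_ppg_landmarks()],
#' [locate_max_slope()] and [locate_sdppg_points()].
#'
#' @param cycle a `pulse_cycle`.
#' @return a `fiducial_set` including `n_ms`/`A_ms1`.
#' @export
locate_fiducials <- function(cycle) {
  lm <- locate_ppg_landmarks(cycle)
  fs <- locate_sdppg_points(cycle, lm)
  ms <- tryCatch(locate_max_slope(cycle, lm), error = function(e) NULL)
  if (is.null(ms)) {
    fs$n_ms <- NA_integer_; fs$A_ms1 <- NA_real_
    fs$missing <- unique(c(fs$missing, "max_slope"))
  } else {
    fs$n_ms <- ms$n_ms; fs$A_ms1 <- ms$A_ms1
  }
  fs
}
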
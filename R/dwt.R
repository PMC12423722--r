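# Periodized orthogonal discrete wavelet transform (Mallat algorithm).
# Used by remove_baseline(): the level-9 approximation at fs = 256 Hz spans
# [0, 0.25] Hz, i.e. the baseline-wander band.

# sym8 orthonormal filter pair (least-asymmetric Daubechies, 8 vanishing
# moments); h = reconstruction lowpass, g = quadrature highpass.
.sym8_lo <- c(
   0.0018899503327594609, -0.0003029205147213668, -0.0149522583370482300,
   0.0038087520138906151,  0.0491371796736075060, -0.0272190299170560030,
  -0.0519458381077090400,  0.3644418948353314000,  0.7771857517005235000,
   0.4813596512583722000, -0.0612733590676585240, -0.1432942383508097000,
   0.0076074873249176050,  0.0316950878114929800, -0.0005421323317911481,
  -0.0033824159510061256)
.sym8_hi <- c(
  -0.0033824159510061256,  0.0005421323317911481,  0.0316950878114929800,
  -0.0076074873249176050, -0.1432942383508097000,  0.0612733590676585240,
   0.4813596512583722000, -0.7771857517005235000,  0.3644418948353314000,
   0.0519458381077090400, -0.0272190299170560030, -0.0491371796736075060,
   0.0038087520138906151,  0.0149522583370482300, -0.0003029205147213668,
  -0.0018899503327594609)

# One analysis step: x (even length N) -> list(a, d) of length N/2.
# a[k] = <x, h[. - 2k]> with circular indexing (orthonormal expansion).
.dwt_step <- function(x) {
  n <- length(x)
  stopifnot(n %% 2L == 0L)
  half <- n / 2L
  a <- numeric(half)
  d <- numeric(half)
  base <- 2L * (seq_len(half) - 1L)
  for (m in seq_along(.sym8_lo)) {
    idx <- (base + (m - 1L)) %% n + 1L
    a <- a + .sym8_lo[m] * x[idx]
    d <- d + .sym8_hi[m] * x[idx]
  }
  list(a = a, d = d)
}

# One synthesis step: exact inverse of .dwt_step.
.idwt_step <- function(a, d) {
  half <- length(a)
  n <- 2L * half
  u <- numeric(n); v <- numeric(n)
  u[seq(1L, n, by = 2L)] <- a   # upsampled coefficients at even shifts 0,2,..
  v[seq(1L, n, by = 2L)] <- d
  x <- numeric(n)
  pos <- seq_len(n) - 1L
  for (m in seq_along(.sym8_lo)) {
    idx <- (pos - (m - 1L)) %% n + 1L
    x <- x + .sym8_lo[m] * u[idx] + .sym8_hi[m] * v[idx]
  }
  x
}

#' Multi-level periodized DWT
#'
#' Decomposes a signal into `level` detail bands plus one approximation band
#' using the sym8 orthonormal wavelet with circular (periodized) boundary
#' handling. The input length must be divisible by `2^level`.
#'
#' @param x numeric vector, length divisible by `2^level`.
#' @param level decomposition depth (integer >= 1).
#' @return list with `approx` (coarsest approximation coefficients) and
#'   `details` (list of detail coefficient vectors, finest first).
#' @seealso [idwt_periodized()], [remove_baseline()]
#' @export
dwt_periodized <- function(x, level) {
  level <- as.integer(level)
  stopifnot(level >= 1L, length(x) %% 2L^level == 0L)
  details <- vector("list", level)
  a <- as.numeric(x)
  for (j in seq_len(level)) {
    s <- .dwt_step(a)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details)
}

#' Inverse multi-level periodized DWT
#'
#' Exact inverse of [dwt_periodized()] (perfect reconstruction up to
#' floating-point rounding).
#'
#' @param decomp list as returned by [dwt_periodized()].
#' @return reconstructed numeric vector.
#' @export
idwt_periodized <- function(decomp) {
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details))) {
    a <- .idwt_step(a, decomp$details[[j]])
  }
  a
}
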
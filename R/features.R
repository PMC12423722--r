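# Feature stack: PPG-morphology, WPD, ECG and basic-information features,
# systematic ratio combination, and per-measurement aggregation.
#
# Units: positions and intervals in samples (Ts carried alongside; seconds
# are a view), amplitudes in normalized units, lengths in cm, age in years.
# Missing values are NA; provenance is tracked per feature.

#' The feature catalog
#'
#' Registry of the named features of the four families (PPG, WPD, ECG,
#' BASIC). Ids pinned by the estimation method: 1 = P2O, 18/19/20 = SDPPG
#' amplitudes of points c/d/e, 23 = age, 51 = SI, 63 = age squared.
#'
#' @return data.frame with columns `id`, `name`, `family`.
#' @export
feature_catalog <- function() {
  ppg <- data.frame(
    id = c(1, 2:17, 18, 19, 20, 21, 22),
    name = c("P2O", "n_sys", "A_sys", "n_notch", "A_notch", "n_dia", "A_dia",
             "n_ms", "A_ms1", "n_a", "A_a2", "n_b", "A_b2", "n_c", "n_d",
             "n_e", "n_f", "A_c2", "A_d2", "A_e2", "age_index", "age_index_v"),
    family = "PPG")
  wpd <- data.frame(
    id = c(31:45, 46, 47, 48, 51, 52, 53),
    name = c(paste0("alpha", 1:5), paste0("beta", 1:5), paste0("gamma", 1:5),
             "n_pf", "n_ps", "n_pd", "SI", "beta3_to_pf", "beta4_to_pf"),
    family = "WPD")
  ecg <- data.frame(
    id = 54:60,
    name = c("n_R", "n_T", "PAT", "PAT2", "H2_over_PAT2",
             "R_to_ms", "R_to_ps"),
    family = "ECG")
  ecg <- rbind(ecg, data.frame(id = 61, name = "R_to_beta2", family = "ECG"))
  basic <- data.frame(
    id = c(23, 62, 63, 64, 65, 66, 67, 68),
    name = c("age", "height", "age2", "weight", "bmi", "La", "Lb", "La_minus_Lb"),
    family = "BASIC")
  out <- rbind(ppg, wpd, ecg, basic)
  rownames(out) <- NULL
  out
}

#' PPG-morphology features of one cycle
#'
#' Includes P2O = M - n_sys, landmark positions/amplitudes, the SDPPG
#' amplitudes, and the ageing indices
#' `(A_b - A_c - A_d - A_e) / A_a` and its variant
#' `(A_b - A_c - A_d) / A_a` (second-derivative amplitudes). Missing
#' SDPPG points propagate NA into their dependent features.
#'
#' @param cycle a `pulse_cycle`.
#' @param fiducials a `fiducial_set` from [locate_fiducials()].
#' @param eps denominator guard for the ageing indices (default 1e-9).
#' @return named numeric vector (NA = missing).
#' @export
extract_ppg_features <- function(cycle, fiducials, eps = 1e-9) {
  f <- fiducials
  M <- cycle$M
  idx_den <- !is.na(f$A_a2) && abs(f$A_a2) >= eps
  age_index <- if (idx_den && !any(is.na(c(f$A_b2, f$A_c2, f$A_d2, f$A_e2))))
    (f$A_b2 - f$A_c2 - f$A_d2 - f$A_e2) / f$A_a2 else NA_real_
  age_index_v <- if (idx_den && !any(is.na(c(f$A_b2, f$A_c2, f$A_d2))))
    (f$A_b2 - f$A_c2 - f$A_d2) / f$A_a2 else NA_real_
  c(P2O = M - f$n_sys,
    n_sys = as.numeric(f$n_sys), A_sys = f$A_sys,
    n_notch = as.numeric(f$n_notch), A_notch = f$A_notch,
    n_dia = as.numeric(f$n_dia), A_dia = f$A_dia,
    n_ms = as.numeric(f$n_ms), A_ms1 = f$A_ms1,
    n_a = as.numeric(f$n_a), A_a2 = f$A_a2,
    n_b = as.numeric(f$n_b), A_b2 = f$A_b2,
    n_c = as.numeric(f$n_c), n_d = as.numeric(f$n_d),
    n_e = as.numeric(f$n_e), n_f = as.numeric(f$n_f),
    A_c2 = f$A_c2, A_d2 = f$A_d2, A_e2 = f$A_e2,
    age_index = age_index, age_index_v = age_index_v)
}

#' WPD features of one decomposition
#'
#' Component parameters, synthesized-wave peaks, the stiffness index
#' SI = n_pd - n_ps, and the intervals from the third and fourth component
#' waves to the forward-wave peak.
#'
#' @param decomposition a `wpd` object that passed [wpd_quality()].
#' @return named numeric vector.
#' @export
extract_wpd_features <- function(decomposition) {
  d <- decomposition
  th <- d$theta_hat
  si <- if (is.na(d$n_pd)) NA_real_ else d$n_pd - d$n_ps
  out <- c(stats::setNames(th$alpha, paste0("alpha", 1:5)),
           stats::setNames(th$beta, paste0("beta", 1:5)),
           stats::setNames(th$gamma, paste0("gamma", 1:5)),
           n_pf = as.numeric(d$n_pf), n_ps = as.numeric(d$n_ps),
           n_pd = if (is.na(d$n_pd)) NA_real_ else as.numeric(d$n_pd),
           SI = si,
           beta3_to_pf = th$beta[3] - d$n_pf,
           beta4_to_pf = th$beta[4] - d$n_pf)
  out
}

#' ECG features of one cycle
#'
#' PAT = -n_R (the R peak precedes the valley so n_R < 0), its square,
#' Height^2/PAT^2, and the R-to-X spans (maximal slope, systolic-wave peak
#' ps, component wave 2).
#'
#' @param cycle a `pulse_cycle` with a paired R peak.
#' @param fiducials a `fiducial_set`.
#' @param height_cm participant height in cm.
#' @param wpd_features optional vector from [extract_wpd_features()] for
#'   the ps- and beta2-based spans.
#' @return named numeric vector.
#' @export
extract_ecg_features <- function(cycle, fiducials, height_cm,
                                 wpd_features = NULL) {
  n_R <- fiducials$n_R
  if (is.null(n_R) || is.na(n_R) || n_R >= 0)
    return(c(n_R = NA_real_, n_T = NA_real_, PAT = NA_real_, PAT2 = NA_real_,
             H2_over_PAT2 = NA_real_, R_to_ms = NA_real_, R_to_ps = NA_real_,
             R_to_beta2 = NA_real_))
  pat <- -n_R
  n_T <- if (!is.null(cycle$n_T)) cycle$n_T else NA_real_
  c(n_R = as.numeric(n_R), n_T = as.numeric(n_T),
    PAT = pat, PAT2 = pat^2,
    H2_over_PAT2 = height_cm^2 / pat^2,
    R_to_ms = if (is.na(fiducials$n_ms)) NA_real_ else fiducials$n_ms - n_R,
    R_to_ps = if (is.null(wpd_features) || is.na(wpd_features["n_ps"]))
      NA_real_ else unname(wpd_features["n_ps"]) - n_R,
    R_to_beta2 = if (is.null(wpd_features) || is.na(wpd_features["beta2"]))
      NA_real_ else unname(wpd_features["beta2"]) - n_R)
}

#' Basic-information features
#'
#' Heart-to-ankle and heart-to-brachium path lengths approximated from
#' height: `La = 0.8219 H + 12.328`, `Lb = 0.2195 H - 2.073` (cm), their
#' difference, plus age, age squared, weight and BMI pass-throughs.
#'
#' @param height_cm height in cm, validated range [100, 220].
#' @param age years; `weight_kg` optional.
#' @param weight_kg weight in kg (optional; BMI needs it).
#' @return named numeric vector.
#' @export
compute_body_lengths <- function(height_cm, age = NA_real_, weight_kg = NA_real_) {
  if (is.na(height_cm) || height_cm < 100 || height_cm > 220)
    stop("height outside the validated range [100, 220] cm")
  la <- 0.8219 * height_cm + 12.328
  lb <- 0.2195 * height_cm - 2.073
  bmi <- if (is.na(weight_kg)) NA_real_ else weight_kg / (height_cm / 100)^2
  c(age = age, age2 = age^2, height = height_cm, weight = weight_kg,
    bmi = bmi, La = la, Lb = lb, La_minus_Lb = la - lb)
}

#' Systematic ratio-combined features
#'
#' Adds `u / v` for ordered feature pairs (all ordered pairs by default,
#' diagonal excluded), named `"<u>_over_<v>"`. Combinations with missing
#' operands or `|v| < eps` are NA.
#'
#' @param features named numeric vector.
#' @param pair_spec optional 2-column character matrix (or data.frame) of
#'   (u, v) name pairs; default all ordered pairs.
#' @param eps denominator guard (default 1e-9).
#' @return the input extended with the combined features.
#' @export
combine_ratio_features <- function(features, pair_spec = NULL, eps = 1e-9) {
  nm <- names(features)
  if (is.null(pair_spec)) {
    pair_spec <- expand.grid(u = nm, v = nm, stringsAsFactors = FALSE)
    pair_spec <- pair_spec[pair_spec$u != pair_spec$v, ]
  } else {
    pair_spec <- as.data.frame(pair_spec, stringsAsFactors = FALSE)
    names(pair_spec) <- c("u", "v")
  }
  u <- features[pair_spec$u]
  v <- features[pair_spec$v]
  val <- ifelse(is.na(u) | is.na(v) | abs(v) < eps, NA_real_, u / v)
  names(val) <- paste0(pair_spec$u, "_over_", pair_spec$v)
  c(features, val)
}

#' Aggregate cycle-level features to measurement level
#'
#' Per sequence (record), each feature is the median over its accepted
#' cycles (missing excluded); per measurement, the mean over the medians
#' of its sequences. A feature missing in every sequence of a measurement
#' stays NA.
#'
#' @param cycle_features list (per sequence) of matrices or data.frames,
#'   rows = cycles, columns = features; or a single data.frame with a
#'   `sequence` column.
#' @param groups optional vector assigning each sequence to a measurement
#'   (default: all sequences belong to one measurement).
#' @return named numeric vector (one measurement) or matrix (rows =
#'   measurements) when `groups` has several levels.
#' @export
aggregate_measurement <- function(cycle_features, groups = NULL) {
  if (is.data.frame(cycle_features) || is.matrix(cycle_features))
    cycle_features <- list(cycle_features)
  seq_medians <- lapply(cycle_features, function(m) {
    m <- as.matrix(m)
    apply(m, 2, function(col) {
      col <- col[!is.na(col)]
      if (length(col)) stats::median(col) else NA_real_
    })
  })
  med_mat <- do.call(rbind, seq_medians)
  if (is.null(groups)) groups <- rep(1L, nrow(med_mat))
  stopifnot(length(groups) == nrow(med_mat))
  grp <- split(seq_len(nrow(med_mat)), groups)
  out <- matrix(NA_real_, length(grp), ncol(med_mat),
                dimnames = list(names(grp), colnames(med_mat)))
  for (g in seq_along(grp)) {
    out[g, ] <- colMeans(med_mat[grp[[g]], , drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  if (nrow(out) == 1L)
    stats::setNames(as.numeric(out[1L, ]), colnames(out))
  else out
}

#' Full feature vector of one cycle
#'
#' Convenience wrapper combining the four families for one accepted cycle
#' and its decomposition. PPG-morphology timings missing in the raw pulse
#' are imputed from their WPD-synthesized counterparts (diastolic timing
#' from the diastolic-wave peak), with provenance recorded.
#'
#' @param cycle a `pulse_cycle`.
#' @param fiducials a `fiducial_set`.
#' @param decomposition a `wpd` passing [wpd_quality()] (optional).
#' @param age,height_cm,weight_kg participant basics.
#' @return named numeric vector with attribute `provenance` (named
#'   character: "measured", "wpd_derived" or "missing").
#' @export
cycle_features <- function(cycle, fiducials, decomposition = NULL,
                           age = NA_real_, height_cm = NA_real_,
                           weight_kg = NA_real_) {
  ppg <- extract_ppg_features(cycle, fiducials)
  wpd <- if (!is.null(decomposition)) extract_wpd_features(decomposition) else NULL
  ecg <- extract_ecg_features(cycle, fiducials, height_cm, wpd)
  basic <- if (!is.na(height_cm)) compute_body_lengths(height_cm, age, weight_kg)
           else c(age = age, age2 = age^2)
  prov <- rep("measured", length(ppg)); names(prov) <- names(ppg)
  # imputation policy: WPD-synthesized diastolic timing stands in for a
  # vanished diastolic peak
  if (!is.null(wpd) && is.na(ppg["n_dia"]) && !is.na(wpd["n_pd"])) {
    ppg["n_dia"] <- wpd["n_pd"]
    prov["n_dia"] <- "wpd_derived"
  }
  out <- c(ppg, wpd, ecg, basic)
  prov <- c(prov, stats::setNames(rep("measured", length(out) - length(ppg)),
                                  names(out)[-seq_along(ppg)]))
  prov[is.na(out)] <- "missing"
  attr(out, "provenance") <- prov
  out
}
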
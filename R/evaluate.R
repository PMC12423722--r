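# Evaluation: error metrics, correlation with p-values, per-participant
# averaging, Bland-Altman agreement.
#
# Sign convention throughout: error = measured - estimated, so a positive
# mean error means underestimation.

#' Error metrics between PWV estimates and references
#'
#' With `e_j = v_j - vhat_j` (measured minus estimated): MAE = mean |e|,
#' ME = mean e, SD of e with the N-1 denominator, RMSE = sqrt(mean e^2).
#'
#' @param estimates,references equal-length numeric vectors (N >= 2).
#' @param level label carried in the report ("rounds" or "participants").
#' @return object of class `eval_report` with `MAE`, `ME`, `SD`, `RMSE`,
#'   `pearson_r`, `p_value`, `N`, `level`.
#' @export
error_metrics <- function(estimates, references, level = "rounds") {
  stopifnot(length(estimates) == length(references))
  n <- length(estimates)
  if (n < 2) stop("need at least 2 pairs (SD undefined)")
  e <- references - estimates
  corr <- if (n >= 3 && stats::sd(estimates) > 0 && stats::sd(references) > 0)
    correlation(estimates, references) else list(r = NA_real_, p = NA_real_)
  structure(list(MAE = mean(abs(e)), ME = mean(e), SD = stats::sd(e),
                 RMSE = sqrt(mean(e^2)), pearson_r = corr$r,
                 p_value = corr$p, N = n, level = level),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "PWV agreement (%s, N = %d): MAE %.1f | ME %.1f | SD %.1f | RMSE %.1f cm/s",
    x$level, x$N, x$MAE, x$ME, x$SD, x$RMSE))
  if (!is.na(x$pearson_r))
    cat(sprintf(" | r = %.2f (P %s)", x$pearson_r,
                format.pval(x$p_value, digits = 2)))
  cat("\n")
  invisible(x)
}

#' Pearson correlation with a two-sided p-value
#'
#' @param estimates,references numeric vectors (N >= 3, non-constant).
#' @param method "pearson" (default) or "spearman".
#' @return list with `r` and `p` (t transform, N-2 df).
#' @export
correlation <- function(estimates, references, method = "pearson") {
  if (length(estimates) < 3) stop("need N >= 3 for a correlation")
  if (stats::sd(estimates) == 0 || stats::sd(references) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(estimates, references, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Average estimate/reference pairs per participant
#'
#' One (mean estimate, mean reference) pair per participant, avoiding the
#' unbalanced weighting of participants with several measurements.
#'
#' @param estimates,references aligned numeric vectors.
#' @param participant_ids grouping vector of the same length.
#' @return data.frame with `participant_id`, `estimate`, `reference`.
#' @export
per_participant <- function(estimates, references, participant_ids) {
  stopifnot(length(estimates) == length(references),
            length(estimates) == length(participant_ids))
  est <- tapply(estimates, participant_ids, mean)
  ref <- tapply(references, participant_ids, mean)
  data.frame(participant_id = names(est), estimate = as.numeric(est),
             reference = as.numeric(ref), row.names = NULL)
}

#' Bland-Altman agreement analysis
#'
#' Per-pair mean and difference (reference minus estimate), the bias
#' (mean difference) and the 95% limits of agreement
#' `bias +/- 1.96 * SD`.
#'
#' @param estimates,references equal-length numeric vectors (N >= 2).
#' @return object of class `bland_altman`: list with `table` (columns
#'   `mean`, `difference`), `bias`, `loa_lower`, `loa_upper`, `sd`.
#' @export
bland_altman <- function(estimates, references) {
  stopifnot(length(estimates) == length(references), length(estimates) >= 2)
  d <- references - estimates
  m <- (references + estimates) / 2
  s <- stats::sd(d)
  structure(list(table = data.frame(mean = m, difference = d),
                 bias = mean(d), sd = s,
                 loa_lower = mean(d) - 1.96 * s,
                 loa_upper = mean(d) + 1.96 * s),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.1f, limits of agreement [%.1f, %.1f] (N = %d)\n",
              x$bias, x$loa_lower, x$loa_upper, nrow(x$table)))
  invisible(x)
}

#' Plot a Bland-Altman analysis
#'
#' @param x a `bland_altman` object.
#' @param ... passed to [graphics::plot].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$table$mean, x$table$difference,
                 xlab = "mean of reference and estimate (cm/s)",
                 ylab = "reference - estimate (cm/s)", ...)
  graphics::abline(h = c(x$bias, x$loa_lower, x$loa_upper),
                   lty = c(1, 2, 2), col = "grey40")
  invisible(x)
}

#' Round-level and participant-level evaluation in one call
#'
#' @param estimates,references aligned numeric vectors.
#' @param participant_ids grouping vector.
#' @return list with `rounds` and `participants` (`eval_report`s) and
#'   `bland_altman` (round level).
#' @export
evaluate_estimates <- function(estimates, references, participant_ids) {
  pp <- per_participant(estimates, references, participant_ids)
  list(rounds = error_metrics(estimates, references, "rounds"),
       participants = error_metrics(pp$estimate, pp$reference, "participants"),
       bland_altman = bland_altman(estimates, references))
}
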
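# Model evaluation metrics (RC, RMSEC, RP, RMSEP, RPD and its interpretation
# bands) and the reference-assay helpers (gravimetric moisture, vitamin-C
# standard curve).

#' Residual predictive deviation
#'
#' `RPD = stdp / RMSEP`, where `stdp` is the sample standard deviation of the
#' measured prediction-set values and RMSEP the root mean square error of
#' prediction.
#'
#' @param stdp prediction-set standard deviation (denominator N-1).
#' @param rmsep root mean square error of prediction, > 0.
#' @return the quotient.
#' @export
rpd <- function(stdp, rmsep) {
  if (!is.finite(rmsep) || rmsep <= 0)
    stop("RPD undefined: RMSEP must be positive (got ", rmsep, ")")
  stdp / rmsep
}

#' Interpret an RPD value
#'
#' Standard chemometric reading: below 1.5 the model's predictive ability is
#' poor; between 1.5 and 2.0 it is fair (rough quantitative prediction);
#' at or above 2.0 it is excellent.
#'
#' @param rpd nonnegative RPD value.
#' @return one of `"poor"`, `"fair"`, `"excellent"`.
#' @export
interpret_rpd <- function(rpd) {
  stopifnot(is.numeric(rpd), all(rpd >= 0))
  cut_lab <- function(v) if (v < 1.5) "poor" else if (v < 2.0) "fair" else "excellent"
  vapply(rpd, cut_lab, "")
}

#' Calibration and prediction metrics of a regression model
#'
#' Computes the standard chemometric report: RC and RP are the Pearson
#' correlations between measured and predicted values on the calibration and
#' prediction sets; RMSEC and RMSEP are root mean square errors with the set
#' size as denominator; RPD is the prediction-set sample standard deviation
#' (denominator N-1) divided by RMSEP.
#'
#' A raw residual-ratio diagnostic,
#' `sqrt(sum((pred - meas)^2) / sum((meas - mean(meas))^2))` per set, is also
#' reported (fields `ratio_c`, `ratio_p`); unlike a correlation it is not
#' bounded by 1.
#'
#' @param y_cal_meas,y_cal_pred measured and predicted calibration values.
#' @param y_pred_meas,y_pred_pred measured and predicted prediction-set
#'   values.
#' @return object of class `"evaluation_report"` with fields `rc`, `rmsec`,
#'   `rp`, `rmsep`, `rpd`, `rpd_band`, `stdp`, `n_cal`, `n_pred`, `ratio_c`,
#'   `ratio_p`, `flags`. When RMSEP is zero (perfect prediction) `rpd` is `NA`
#'   and the flag `"rpd_undefined"` is set.
#' @export
regression_metrics <- function(y_cal_meas, y_cal_pred,
                               y_pred_meas, y_pred_pred) {
  y_cal_meas <- as.numeric(y_cal_meas); y_cal_pred <- as.numeric(y_cal_pred)
  y_pred_meas <- as.numeric(y_pred_meas); y_pred_pred <- as.numeric(y_pred_pred)
  if (length(y_cal_meas) != length(y_cal_pred) ||
      length(y_pred_meas) != length(y_pred_pred))
    stop("measured/predicted vectors must be paired")
  if (length(y_cal_meas) < 2 || length(y_pred_meas) < 2)
    stop("each set needs at least 2 samples")
  if (sd(y_cal_meas) == 0 || sd(y_pred_meas) == 0)
    stop("correlation undefined: zero-variance measured values")
  pear <- function(a, b) if (sd(b) == 0) NA_real_ else cor(a, b)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  ratio <- function(meas, pred)
    sqrt(sum((pred - meas)^2) / sum((meas - mean(meas))^2))
  rmsec <- rmse(y_cal_meas, y_cal_pred)
  rmsep <- rmse(y_pred_meas, y_pred_pred)
  stdp <- sd(y_pred_meas)
  flags <- character(0)
  if (rmsep > 0) {
    rpd_val <- rpd(stdp, rmsep)
    band <- interpret_rpd(rpd_val)
  } else {
    rpd_val <- NA_real_
    band <- NA_character_
    flags <- c(flags, "rpd_undefined")
  }
  structure(list(rc = pear(y_cal_meas, y_cal_pred), rmsec = rmsec,
                 rp = pear(y_pred_meas, y_pred_pred), rmsep = rmsep,
                 rpd = rpd_val, rpd_band = band, stdp = stdp,
                 n_cal = length(y_cal_meas), n_pred = length(y_pred_meas),
                 ratio_c = ratio(y_cal_meas, y_cal_pred),
                 ratio_p = ratio(y_pred_meas, y_pred_pred),
                 flags = flags),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  calibration (n=%d): RC = %.4f, RMSEC = %.4f\n",
              x$n_cal, x$rc, x$rmsec))
  cat(sprintf("  prediction  (n=%d): RP = %.4f, RMSEP = %.4f\n",
              x$n_pred, x$rp, x$rmsep))
  if (is.na(x$rpd)) cat("  RPD: undefined (RMSEP = 0)\n")
  else cat(sprintf("  RPD = %.4f (%s)\n", x$rpd, x$rpd_band))
  invisible(x)
}

#' Format an evaluation report as a fixed-column table row
#'
#' Mirrors the usual comparison-table ordering: Lvs (or hyperparameters), RC,
#' RMSEC, RP, RMSEP, RPD.
#'
#' @param report an [regression_metrics()] result.
#' @param label row label.
#' @param lvs optional factor count / hyperparameter string.
#' @return one-row data.frame.
#' @export
report_row <- function(report, label = "", lvs = NA) {
  data.frame(method = label, lvs = as.character(lvs),
             rc = report$rc, rmsec = report$rmsec,
             rp = report$rp, rmsep = report$rmsep,
             rpd = report$rpd, stringsAsFactors = FALSE)
}

#' Gravimetric moisture content
#'
#' Oven-drying moisture fraction from three weighings: `m0` empty box, `m1`
#' box plus fresh sample, `m2` box plus dried sample. Moisture content is
#' `(m1 - m2) / (m1 - m0)`, a fraction in `[0, 1]`.
#'
#' @param m0,m1,m2 masses in grams; `m1 > m0` and `m0 <= m2 <= m1`.
#' @return moisture fraction.
#' @export
moisture_content <- function(m0, m1, m2) {
  if (any(m1 <= m0)) stop("m1 must exceed m0 (fresh sample has mass)")
  if (any(m2 < m0) || any(m2 > m1))
    stop("m2 must lie between m0 and m1")
  (m1 - m2) / (m1 - m0)
}

#' Fit a standard curve (absorbance versus concentration)
#'
#' Least-squares line `absorbance = slope * concentration + intercept`, used
#' for the colorimetric vitamin-C assay. When `absorbances` is a matrix
#' (replicate wells in columns, e.g. 3 wells per gradient), replicates are
#' averaged per concentration before fitting.
#'
#' @param concentrations numeric vector of standard concentrations (ug/mL), at
#'   least two distinct values.
#' @param absorbances numeric vector (one value per concentration) or matrix
#'   (rows = concentrations, columns = replicate wells).
#' @return object of class `"standard_curve"`: `slope`, `intercept`,
#'   `r_squared`.
#' @export
fit_standard_curve <- function(concentrations, absorbances) {
  concentrations <- as.numeric(concentrations)
  if (length(unique(concentrations)) < 2)
    stop("need at least two distinct concentrations")
  if (is.matrix(absorbances)) absorbances <- rowMeans(absorbances)
  absorbances <- as.numeric(absorbances)
  if (length(absorbances) != length(concentrations))
    stop("one absorbance (or replicate row) per concentration required")
  fit <- lm.fit(cbind(1, concentrations), absorbances)
  slope <- unname(fit$coefficients[2])
  if (slope == 0) stop("degenerate standard curve: zero slope")
  ssr <- sum(fit$residuals^2)
  sst <- sum((absorbances - mean(absorbances))^2)
  structure(list(slope = slope, intercept = unname(fit$coefficients[1]),
                 r_squared = if (sst > 0) 1 - ssr / sst else NA_real_),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> A = %.6g * c + %.6g (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Invert a standard curve
#'
#' @param curve a [fit_standard_curve()] result.
#' @param absorbance absorbance value(s).
#' @return concentration(s) `(absorbance - intercept) / slope`, in the units
#'   of the curve's concentrations (ug/mL).
#' @export
concentration_from_absorbance <- function(curve, absorbance) {
  stopifnot(inherits(curve, "standard_curve"))
  (as.numeric(absorbance) - curve$intercept) / curve$slope
}
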
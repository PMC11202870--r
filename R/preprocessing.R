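# The seven spectral preprocessing transforms, plus a fit/apply dispatcher
# that keeps calibration statistics separate from prediction data.
#
# Conventions: rows are spectra, columns are wavelength channels; standard
# deviations use the sample convention (denominator N-1) throughout.

PREPROCESS_METHODS <- c("RAW", "MVN", "Center", "Nor", "MA", "S_G", "SNV", "MSC")

#' Column-wise centering
#'
#' Subtracts the column (per-wavelength) mean, so every output column has mean
#' zero. Idempotent.
#'
#' @param X numeric N x P matrix.
#' @return matrix of the same shape.
#' @export
pp_center <- function(X) {
  X <- as.matrix(X)
  sweep(X, 2, colMeans(X))
}

#' Mean-variance normalisation (column autoscaling)
#'
#' Standardises every wavelength channel to mean 0 and sample variance 1
#' (denominator N-1). This is a per-wavelength operation, distinct from the
#' per-spectrum SNV.
#'
#' @param X numeric N x P matrix; every column must have nonzero variance.
#' @return matrix of the same shape.
#' @export
pp_mvn <- function(X) {
  X <- as.matrix(X)
  s <- apply(X, 2, sd)
  bad <- which(s == 0)
  if (length(bad))
    stop("MVN: zero-variance column(s): ", paste(head(bad, 10), collapse = ", "))
  sweep(sweep(X, 2, colMeans(X)), 2, s, "/")
}

#' Row-wise min-max normalisation
#'
#' Rescales every spectrum to the `[0, 1]` interval. A constant row cannot be
#' scaled; it is mapped to all zeros with a warning.
#'
#' @param X numeric N x P matrix.
#' @return matrix of the same shape.
#' @export
pp_nor <- function(X) {
  X <- as.matrix(X)
  lo <- apply(X, 1, min)
  hi <- apply(X, 1, max)
  rng <- hi - lo
  flat <- which(rng == 0)
  if (length(flat)) {
    warning("Nor: constant row(s) mapped to zeros: ",
            paste(head(flat, 10), collapse = ", "))
    rng[flat] <- 1
  }
  out <- (X - lo) / rng
  if (length(flat)) out[flat, ] <- 0
  out
}

#' Moving-average smoothing
#'
#' Convolves each spectrum with a uniform kernel of odd width `window`. At the
#' edges the window shrinks: channel j averages the channels in
#' `[max(1, j-h), min(P, j+h)]` with `h = (window-1)/2`, so no padding values
#' are invented and constants are reproduced exactly.
#'
#' @param X numeric N x P matrix.
#' @param window odd integer window width, `3 <= window <= P`.
#' @return matrix of the same shape.
#' @export
pp_moving_average <- function(X, window = 5) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (window %% 2 != 1 || window < 3)
    stop("MA: window must be an odd integer >= 3")
  if (window > p) stop("MA: window exceeds number of channels")
  half <- (window - 1L) / 2L
  cs <- cbind(0, t(apply(X, 1, cumsum)))  # N x (P+1)
  lo <- pmax(seq_len(p) - half, 1L)
  hi <- pmin(seq_len(p) + half, p)
  (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1, each = nrow(X))
}

#' Savitzky-Golay smoothing
#'
#' Row-wise least-squares polynomial smoothing (via [signal::sgolayfilt()]).
#' Polynomials of degree `<= polyorder` are reproduced exactly, including at
#' the edges.
#'
#' @param X numeric N x P matrix.
#' @param window odd integer frame length (default 11).
#' @param polyorder polynomial order, `< window` (default 2).
#' @return matrix of the same shape.
#' @export
pp_savitzky_golay <- function(X, window = 11, polyorder = 2) {
  X <- as.matrix(X)
  if (window %% 2 != 1 || window < 3)
    stop("S_G: window must be an odd integer >= 3")
  if (polyorder >= window)
    stop("S_G: polyorder must be smaller than window")
  if (window > ncol(X)) stop("S_G: window exceeds number of channels")
  t(apply(X, 1, signal::sgolayfilt, p = polyorder, n = window))
}

#' Standard normal variate transform
#'
#' Standardises every spectrum (row) to mean 0 and sample standard deviation 1
#' (denominator N-1), removing per-spectrum multiplicative scatter and
#' baseline offset: `a*x + b` (a > 0) maps to the same output as `x`.
#'
#' @param X numeric N x P matrix; every row must have nonzero sd.
#' @return matrix of the same shape.
#' @export
pp_snv <- function(X) {
  X <- as.matrix(X)
  mu <- rowMeans(X)
  s <- apply(X, 1, sd)
  bad <- which(s == 0)
  if (length(bad))
    stop("SNV: constant row(s): ", paste(head(bad, 10), collapse = ", "))
  (X - mu) / s
}

#' Multiplicative scatter correction
#'
#' Regresses every spectrum on a reference spectrum, `x_i = a_i * ref + b_i +
#' e_i`, and returns the scatter-inverted spectrum `(x_i - b_i) / a_i`. The
#' reference defaults to the column-mean spectrum of `X`; supply the
#' calibration-set mean when correcting prediction data.
#'
#' @param X numeric N x P matrix.
#' @param reference optional numeric P-vector; must not be constant.
#' @return matrix of the same shape, with the fitted `(a, b)` per row attached
#'   as attributes `"msc_a"`, `"msc_b"`.
#' @export
pp_msc <- function(X, reference = NULL) {
  X <- as.matrix(X)
  if (is.null(reference)) reference <- colMeans(X)
  reference <- as.numeric(reference)
  if (length(reference) != ncol(X))
    stop("MSC: reference length does not match number of channels")
  if (sd(reference) == 0) stop("MSC: reference spectrum is constant")
  rc <- reference - mean(reference)
  ss <- sum(rc^2)
  a <- as.numeric((X - rowMeans(X)) %*% rc) / ss  # slope of x_i on ref
  bad <- which(a == 0)
  if (length(bad))
    stop("MSC: zero scatter slope for row(s): ",
         paste(head(bad, 10), collapse = ", "))
  b <- rowMeans(X) - a * mean(reference)
  out <- (X - b) / a
  attr(out, "msc_a") <- a
  attr(out, "msc_b") <- b
  out
}

#' Preprocessing specification
#'
#' @param method one of `"RAW"`, `"MVN"`, `"Center"`, `"Nor"`, `"MA"`,
#'   `"S_G"`, `"SNV"`, `"MSC"`.
#' @param window odd window width for `MA` (default 5) and `S_G` (default 11).
#' @param polyorder polynomial order for `S_G` (default 2), `< window`.
#' @param msc_reference optional fixed reference spectrum for `MSC`; if
#'   `NULL`, the calibration-set mean spectrum is used (and stored at fit
#'   time).
#' @return an object of class `"preprocess_spec"`.
#' @export
preprocess_spec <- function(method = "RAW", window = NULL, polyorder = NULL,
                            msc_reference = NULL) {
  method <- match.arg(method, PREPROCESS_METHODS)
  if (is.null(window)) window <- switch(method, MA = 5L, S_G = 11L, NULL)
  if (is.null(polyorder) && method == "S_G") polyorder <- 2L
  if (!is.null(window) && (window %% 2 != 1 || window < 3))
    stop("window must be an odd integer >= 3")
  if (method == "S_G" && polyorder >= window)
    stop("polyorder must be smaller than window")
  structure(list(method = method, window = window, polyorder = polyorder,
                 msc_reference = msc_reference),
            class = "preprocess_spec")
}

#' @export
print.preprocess_spec <- function(x, ...) {
  extra <- switch(x$method,
    MA = sprintf(" (window %d)", x$window),
    S_G = sprintf(" (window %d, polyorder %d)", x$window, x$polyorder),
    "")
  cat("<preprocess_spec> ", x$method, extra, "\n", sep = "")
  invisible(x)
}

#' Fit a preprocessing transform on calibration data
#'
#' Column-statistic methods (`Center`, `MVN`) and `MSC` with a data-derived
#' reference have state that must be learned on the calibration set and
#' re-used on prediction data; this function computes and stores it. Row-wise
#' methods (`Nor`, `SNV`, `MA`, `S_G`, `RAW`) are stateless.
#'
#' @param X calibration N x P matrix.
#' @param spec a [preprocess_spec()].
#' @return an object of class `"preprocess_fit"`; apply it with
#'   [apply_preprocess()] or `predict()`.
#' @export
fit_preprocess <- function(X, spec) {
  stopifnot(inherits(spec, "preprocess_spec"))
  X <- as.matrix(X)
  stats <- switch(spec$method,
    Center = list(center = colMeans(X)),
    MVN = {
      s <- apply(X, 2, sd)
      bad <- which(s == 0)
      if (length(bad))
        stop("MVN: zero-variance column(s): ",
             paste(head(bad, 10), collapse = ", "))
      list(center = colMeans(X), scale = s)
    },
    MSC = list(reference = spec$msc_reference %||% colMeans(X)),
    NULL)
  structure(list(spec = spec, stats = stats, p = ncol(X)),
            class = "preprocess_fit")
}

#' Apply a fitted preprocessing transform
#'
#' @param fit a `"preprocess_fit"` from [fit_preprocess()].
#' @param X matrix to transform (calibration or prediction rows); its
#'   statistics are never used for the column-wise methods — the stored
#'   calibration statistics are.
#' @return transformed matrix.
#' @export
apply_preprocess <- function(fit, X) {
  if (!inherits(fit, "preprocess_fit"))
    stop("state error: preprocessing must be fitted (fit_preprocess) before application")
  X <- as.matrix(X)
  if (ncol(X) != fit$p)
    stop("column count ", ncol(X), " does not match fitted width ", fit$p)
  spec <- fit$spec
  switch(spec$method,
    RAW = X,
    Center = sweep(X, 2, fit$stats$center),
    MVN = sweep(sweep(X, 2, fit$stats$center), 2, fit$stats$scale, "/"),
    Nor = pp_nor(X),
    MA = pp_moving_average(X, spec$window),
    S_G = pp_savitzky_golay(X, spec$window, spec$polyorder),
    SNV = pp_snv(X),
    MSC = pp_msc(X, fit$stats$reference))
}

#' @export
predict.preprocess_fit <- function(object, newdata, ...) {
  apply_preprocess(object, newdata)
}

#' Restore a fitted preprocessing transform from its serialised form
#'
#' Rebuilds the `"preprocess_fit"` object stored inside a saved model's
#' provenance (see [write_model()]), so new spectra can be preprocessed with
#' the original calibration statistics before prediction.
#'
#' @param x list with elements `method`, `window`, `polyorder`, `p` and
#'   optionally `stats` (as read back from the model JSON).
#' @return a `"preprocess_fit"` usable with [apply_preprocess()].
#' @export
restore_preprocess_fit <- function(x) {
  spec <- preprocess_spec(x$method, window = x$window,
                          polyorder = x$polyorder)
  stats <- if (!is.null(x$stats)) lapply(x$stats, as.numeric)
  structure(list(spec = spec, stats = stats, p = as.integer(x$p)),
            class = "preprocess_fit")
}
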
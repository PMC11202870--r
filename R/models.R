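# Calibration models: PLSR (NIPALS), MLR and LS-SVM with RBF kernel, with a
# common S3 surface (predict / coef / print / residuals / fitted) and JSON
# persistence.

new_spec_model <- function(kind, fields, X, y, wavelengths_nm = NULL,
                           provenance = NULL) {
  X <- as.matrix(X)
  structure(c(list(kind = kind,
                   n_train = nrow(X), p = ncol(X),
                   wavelengths_nm = wavelengths_nm,
                   colnames = colnames(X),
                   provenance = provenance,
                   y = as.numeric(y)),
              fields),
            class = c(paste0(tolower(kind), "_model"), "spec_model"))
}

check_newdata <- function(object, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != object$p)
    stop("provenance error: newdata has ", ncol(X_new),
         " columns; model was fitted on ", object$p)
  if (!is.null(object$colnames) && !is.null(colnames(X_new)) &&
      !identical(colnames(X_new), object$colnames))
    stop("provenance error: newdata column names/order do not match the ",
         "fitted variables")
  X_new
}

#' Fit a partial least squares regression (PLSR) model
#'
#' Single-response NIPALS PLS on column-centered data. Score vectors are
#' mutually orthogonal; with `n_factors = rank(X)` the fit coincides with
#' ordinary least squares. Regression coefficients are stored in the original
#' variable space.
#'
#' @param X calibration N x P matrix (typically preprocessed, selected
#'   channels).
#' @param y calibration response vector.
#' @param n_factors number of latent factors (Lvs). `"cv"` selects the factor
#'   count in `1..min(25, rank)` minimising 5-fold RMSECV.
#' @param cv_folds,seed fold count and seed for `n_factors = "cv"`.
#' @param wavelengths_nm optional wavelengths (nm) of the columns of `X`,
#'   stored for provenance.
#' @param provenance optional list (preprocess spec, selection) carried along.
#' @return object of class `c("plsr_model", "spec_model")`.
#' @export
fit_plsr <- function(X, y, n_factors = 10, cv_folds = 5, seed = 1,
                     wavelengths_nm = NULL, provenance = NULL) {
  X <- as.matrix(X)
  if (identical(n_factors, "cv")) {
    fold_id <- make_folds(nrow(X), cv_folds, substream_seed(seed, "plsr-cv"))
    cand <- seq_len(min(25L, nrow(X) - 1L, ncol(X)))
    cv <- vapply(cand, function(a) pls1_rmsecv(X, y, a, fold_id), 0)
    n_factors <- cand[which.min(cv)]
  }
  if (n_factors > min(nrow(X) - 1L, ncol(X)))
    stop("n_factors = ", n_factors, " exceeds min(N-1, P) = ",
         min(nrow(X) - 1L, ncol(X)))
  core <- pls1_fit(X, y, n_factors)
  m <- new_spec_model("PLSR",
                      c(core, list(n_factors = core$ncomp)),
                      X, y, wavelengths_nm, provenance)
  m$fitted_values <- pls1_predict(core, X)
  m
}

#' Fit a multiple linear regression (MLR / inverse least squares) model
#'
#' Ordinary least squares with intercept. MLR requires more samples than
#' variables; when `P >= N` the normal equations are underdetermined and the
#' fit refuses, directing the user to wavelength selection first. Setting
#' `allow_pinv = TRUE` instead computes the minimum-norm solution via the
#' Moore-Penrose pseudo-inverse ([MASS::ginv()]); this is reported in the
#' model and should be understood as a different estimator, not ordinary MLR.
#'
#' @inheritParams fit_plsr
#' @param allow_pinv allow the pseudo-inverse fallback for `P >= N` or
#'   singular designs (default `FALSE`).
#' @return object of class `c("mlr_model", "spec_model")`.
#' @export
fit_mlr <- function(X, y, allow_pinv = FALSE, wavelengths_nm = NULL,
                    provenance = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  Xd <- cbind(`(Intercept)` = 1, X)
  if (p >= n && !allow_pinv)
    stop("MLR needs more samples than variables (N=", n, ", P=", p,
         "); run wavelength selection first, or set allow_pinv = TRUE")
  used_pinv <- FALSE
  if (p >= n) {
    beta <- drop(MASS::ginv(Xd) %*% y)
    used_pinv <- TRUE
  } else {
    fit <- lm.fit(Xd, y)
    if (fit$rank < ncol(Xd)) {
      if (!allow_pinv)
        stop("singular normal equations (rank ", fit$rank, " < ", ncol(Xd),
             "); consider wavelength selection or allow_pinv = TRUE")
      beta <- drop(MASS::ginv(Xd) %*% y)
      used_pinv <- TRUE
    } else beta <- fit$coefficients
  }
  m <- new_spec_model("MLR",
                      list(coefficients = unname(beta[-1]),
                           intercept = unname(beta[1]),
                           used_pinv = used_pinv),
                      X, y, wavelengths_nm, provenance)
  m$fitted_values <- drop(Xd %*% beta)
  m
}

rbf_kernel <- function(U, V, sigma2) {
  U <- as.matrix(U); V <- as.matrix(V)
  d2 <- outer(rowSums(U^2), rowSums(V^2), "+") - 2 * tcrossprod(U, V)
  exp(-pmax(d2, 0) / sigma2)
}

#' Fit a least-squares support vector machine (LS-SVM) regression model
#'
#' RBF kernel `K(u, v) = exp(-||u - v||^2 / sigma2)`. The fit solves the
#' LS-SVM linear system
#' \deqn{\begin{pmatrix} 0 & 1^T \\ 1 & K + I/\gamma \end{pmatrix}
#'       \begin{pmatrix} b \\ \alpha \end{pmatrix} =
#'       \begin{pmatrix} 0 \\ y \end{pmatrix}}
#' so no quadratic programming is involved; predictions are
#' `sum_i alpha_i K(x, x_i) + b`. Large `gamma` approaches interpolation.
#'
#' @inheritParams fit_plsr
#' @param gamma regularisation weight, > 0.
#' @param sigma2 RBF kernel width (direct divisor of the squared distance),
#'   > 0.
#' @return object of class `c("lssvm_model", "spec_model")`; field
#'   `kkt_residual` holds the residual norm of the solved linear system.
#' @export
fit_lssvm <- function(X, y, gamma, sigma2, wavelengths_nm = NULL,
                      provenance = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (gamma <= 0 || sigma2 <= 0) stop("gamma and sigma2 must be positive")
  n <- nrow(X)
  K <- rbf_kernel(X, X, sigma2)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / gamma))
  rhs <- c(0, y)
  sol <- tryCatch(solve(A, rhs), error = function(e)
    stop("singular LS-SVM system (reciprocal condition ",
         format(rcond(A), digits = 3), "): ", conditionMessage(e)))
  m <- new_spec_model("LSSVM",
                      list(alpha = sol[-1], b = sol[1],
                           gamma = gamma, sigma2 = sigma2,
                           X_train = X,
                           kkt_residual = sqrt(sum((A %*% sol - rhs)^2))),
                      X, y, wavelengths_nm, provenance)
  m$fitted_values <- drop(K %*% m$alpha) + m$b
  m
}

#' Grid search for LS-SVM hyperparameters
#'
#' Evaluates every (gamma, sigma2) candidate by k-fold cross-validated RMSE
#' with a fixed, seeded fold assignment and returns the minimising pair
#' (ties broken by grid order).
#'
#' @param X,y calibration data.
#' @param gamma_grid,sigma2_grid candidate values (positive).
#' @param folds number of CV folds (default 5).
#' @param seed fold-assignment seed.
#' @return list with `gamma`, `sigma2` and the full `rmsecv` table
#'   (data.frame `gamma`, `sigma2`, `rmsecv`).
#' @export
tune_lssvm <- function(X, y, gamma_grid, sigma2_grid, folds = 5, seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (!length(gamma_grid) || !length(sigma2_grid)) stop("empty grid")
  n <- nrow(X)
  fold_id <- make_folds(n, folds, substream_seed(seed, "lssvm-folds"))
  if (length(unique(fold_id)) < 2 || any(table(fold_id) < 1))
    stop("degenerate folds")
  grid <- expand.grid(gamma = gamma_grid, sigma2 = sigma2_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rms <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pred <- numeric(n)
    for (f in sort(unique(fold_id))) {
      te <- fold_id == f
      fit <- fit_lssvm(X[!te, , drop = FALSE], y[!te],
                       grid$gamma[g], grid$sigma2[g])
      pred[te] <- predict(fit, X[te, , drop = FALSE])
    }
    rms[g] <- sqrt(mean((pred - y)^2))
  }
  best <- which.min(rms)
  list(gamma = grid$gamma[best], sigma2 = grid$sigma2[best],
       rmsecv = cbind(grid, rmsecv = rms))
}

#' @export
predict.plsr_model <- function(object, newdata, ...) {
  X <- check_newdata(object, newdata)
  drop(X %*% object$coefficients) + object$intercept
}

#' @export
predict.mlr_model <- function(object, newdata, ...) {
  X <- check_newdata(object, newdata)
  drop(X %*% object$coefficients) + object$intercept
}

#' @export
predict.lssvm_model <- function(object, newdata, ...) {
  X <- check_newdata(object, newdata)
  drop(rbf_kernel(X, object$X_train, object$sigma2) %*% object$alpha) +
    object$b
}

#' @export
coef.spec_model <- function(object, ...) {
  if (object$kind == "LSSVM")
    return(c(b = object$b, alpha = object$alpha))
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
fitted.spec_model <- function(object, ...) object$fitted_values

#' @export
residuals.spec_model <- function(object, ...) object$y - object$fitted_values

#' @export
print.spec_model <- function(x, ...) {
  cat(sprintf("<%s model> %d training samples, %d variables\n",
              x$kind, x$n_train, x$p))
  if (x$kind == "PLSR") cat("  latent factors (Lvs):", x$n_factors, "\n")
  if (x$kind == "LSSVM")
    cat(sprintf("  gamma = %g, sigma2 = %g\n", x$gamma, x$sigma2))
  if (x$kind == "MLR" && isTRUE(x$used_pinv))
    cat("  note: pseudo-inverse (minimum-norm) solution\n")
  rmse <- sqrt(mean(residuals(x)^2))
  cat(sprintf("  training RMSE: %.6g\n", rmse))
  invisible(x)
}

#' @export
summary.spec_model <- function(object, ...) {
  r <- residuals(object)
  structure(list(model = object,
                 rmsec = sqrt(mean(r^2)),
                 rc = cor(object$y, object$fitted_values)),
            class = "summary.spec_model")
}

#' @export
print.summary.spec_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  RC = %.4f, RMSEC = %.4f\n", x$rc, x$rmsec))
  invisible(x)
}

# ---- persistence ----------------------------------------------------------

#' Save / load a fitted model as JSON
#'
#' Numeric values are serialised as base-10 decimal strings with 17
#' significant digits (`%.17g`), which round-trip IEEE doubles exactly, so a
#' load -> predict round trip is bit-identical to predictions from the
#' in-memory model.
#'
#' @param model a fitted `spec_model`.
#' @param path file path for the JSON document.
#' @return `write_model` invisibly returns `path`; `read_model` returns the
#'   restored model object.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "spec_model"))
  num <- function(x) if (is.null(x)) NULL else sprintf("%.17g", x)
  doc <- list(kind = model$kind, n_train = model$n_train, p = model$p,
              wavelengths_nm = num(model$wavelengths_nm),
              colnames = model$colnames,
              provenance = serialize_provenance(model$provenance),
              y = num(model$y),
              fitted_values = num(model$fitted_values))
  doc <- c(doc, switch(model$kind,
    PLSR = list(coefficients = num(model$coefficients),
                intercept = num(model$intercept),
                ncomp = model$ncomp, n_factors = model$n_factors,
                xbar = num(model$xbar), ybar = num(model$ybar)),
    MLR = list(coefficients = num(model$coefficients),
               intercept = num(model$intercept),
               used_pinv = model$used_pinv),
    LSSVM = list(alpha = num(model$alpha), b = num(model$b),
                 gamma = num(model$gamma), sigma2 = num(model$sigma2),
                 X_train = num(as.numeric(model$X_train)),
                 kkt_residual = num(model$kkt_residual))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

serialize_provenance <- function(prov) {
  if (is.null(prov)) return(NULL)
  out <- list()
  if (!is.null(prov$preprocess)) {
    ps <- prov$preprocess
    out$preprocess <- list(method = ps$method, window = ps$window,
                           polyorder = ps$polyorder)
  }
  if (!is.null(prov$preprocess_fit)) {
    fit <- prov$preprocess_fit
    num <- function(x) if (is.null(x)) NULL else sprintf("%.17g", x)
    out$preprocess_fit <- list(
      method = fit$spec$method, window = fit$spec$window,
      polyorder = fit$spec$polyorder, p = fit$p,
      stats = if (!is.null(fit$stats)) lapply(fit$stats, num))
  }
  if (!is.null(prov$selection))
    out$selection <- list(method = prov$selection$method,
                          selected_idx = prov$selection$selected_idx)
  out
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  fields <- switch(doc$kind,
    PLSR = list(coefficients = num(doc$coefficients),
                intercept = as.numeric(doc$intercept), ncomp = doc$ncomp,
                n_factors = doc$n_factors,
                xbar = num(doc$xbar), ybar = as.numeric(doc$ybar)),
    MLR = list(coefficients = num(doc$coefficients),
               intercept = as.numeric(doc$intercept),
               used_pinv = isTRUE(doc$used_pinv)),
    LSSVM = list(alpha = num(doc$alpha), b = as.numeric(doc$b),
                 gamma = as.numeric(doc$gamma),
                 sigma2 = as.numeric(doc$sigma2),
                 X_train = matrix(as.numeric(doc$X_train),
                                  nrow = doc$n_train),
                 kkt_residual = as.numeric(doc$kkt_residual)),
    stop("unknown model kind: ", doc$kind))
  m <- structure(c(list(kind = doc$kind, n_train = doc$n_train, p = doc$p,
                        wavelengths_nm = num(doc$wavelengths_nm),
                        colnames = if (length(doc$colnames)) doc$colnames,
                        provenance = doc$provenance,
                        y = num(doc$y)),
                   fields,
                   list(fitted_values = num(doc$fitted_values))),
                 class = c(paste0(tolower(doc$kind), "_model"), "spec_model"))
  m
}
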
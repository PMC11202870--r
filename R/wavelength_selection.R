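# Characteristic wavelength selection: CARS, UVE and SPA.
#
# All three selectors operate on a calibration matrix X (rows = samples,
# columns = wavelength channels) and a response y, and return a
# "wl_selection" object: sorted unique channel indices plus method-specific
# diagnostics. Each is deterministic given (X, y, config incl. seed).

new_wl_selection <- function(selected_idx, method, diagnostics) {
  selected_idx <- sort(unique(as.integer(selected_idx)))
  if (!length(selected_idx)) stop(method, ": empty selection")
  structure(list(selected_idx = selected_idx, method = method,
                 diagnostics = diagnostics),
            class = "wl_selection")
}

#' @export
print.wl_selection <- function(x, ...) {
  cat(sprintf("<wl_selection> %s: %d channels selected\n",
              x$method, length(x$selected_idx)))
  invisible(x)
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Monte-Carlo PLS wavelength selection. At iteration i of `n_iterations`:
#' a random `mc_ratio` fraction of the calibration samples is drawn; a PLS
#' model is fitted on the currently retained channels and its absolute
#' regression coefficients become channel weights; an exponentially decreasing
#' function (EDF) forces the retained-channel count down from P at the first
#' iteration to 2 at the last; adaptive reweighted sampling (weighted draws
#' with replacement) then competitively picks the survivors. Every iteration's
#' subset is scored by k-fold RMSECV (with one fixed fold assignment, so the
#' trace is comparable across iterations); the subset with minimum RMSECV is
#' returned.
#'
#' The EDF constants are `a = (P/2)^(1/(N-1))`, `k = log(P/2)/(N-1)` with
#' `N = n_iterations`, so the forced retention runs from exactly P down to
#' exactly 2.
#'
#' @param X calibration N x P matrix.
#' @param y calibration response vector.
#' @param n_iterations number of Monte-Carlo iterations (default 160).
#' @param mc_ratio fraction of samples drawn per iteration (default 0.8).
#' @param n_pc maximum number of PLS factors (default 11; always capped by the
#'   effective rank of the draw).
#' @param cv_folds folds for the RMSECV trace (default 5).
#' @param seed integer seed controlling the Monte-Carlo draws and fold
#'   assignment.
#' @return a `"wl_selection"` whose `diagnostics` contain the per-iteration
#'   `trace` (data.frame: `iteration`, `n_forced`, `n_subset`, `rmsecv`,
#'   `degenerate`), the `best_iteration`, and the per-iteration subsets.
#' @export
cars_select <- function(X, y, n_iterations = 160, mc_ratio = 0.8, n_pc = 11,
                        cv_folds = 5, seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (p < 2) stop("CARS needs at least 2 channels")
  if (n_iterations < 2) stop("n_iterations must be >= 2")
  if (mc_ratio <= 0 || mc_ratio >= 1) stop("mc_ratio must be in (0, 1)")
  if (n < cv_folds) stop("too few samples for ", cv_folds, "-fold CV")
  N <- as.integer(n_iterations)
  n_draw <- ceiling(mc_ratio * n)
  # EDF: forced retention count round(r_i * p), r_i = a*exp(-k*i)
  k_edf <- log(p / 2) / (N - 1)
  a_edf <- (p / 2)^(1 / (N - 1))
  n_forced_all <- pmax(2L, pmin(p, as.integer(round(
    a_edf * exp(-k_edf * seq_len(N)) * p))))
  fold_id <- make_folds(n, cv_folds, substream_seed(seed, "cars-folds"))
  retained <- seq_len(p)
  subsets <- vector("list", N)
  rmsecv <- rep(NA_real_, N)
  n_subset <- integer(N)
  degen <- logical(N)
  with_seed(substream_seed(seed, "cars-mc"), {
    for (i in seq_len(N)) {
      rows <- sample(n, n_draw)
      nc <- min(n_pc, n_draw - 1L, length(retained))
      w <- tryCatch({
        fit <- pls1_fit(X[rows, retained, drop = FALSE], y[rows], nc)
        abs(fit$coefficients)
      }, error = function(e) rep(0, length(retained)))
      keep_n <- min(n_forced_all[i], length(retained))
      if (all(w == 0)) {
        degen[i] <- TRUE
        survivors <- retained[seq_len(keep_n)]
        newset <- survivors
      } else {
        ord <- order(-w, retained)  # ties -> lowest channel index
        survivors <- sort(retained[ord[seq_len(keep_n)]])
        wsurv <- w[match(survivors, retained)]
        if (sum(wsurv) == 0) {
          degen[i] <- TRUE
          newset <- survivors
        } else {
          picks <- sample(length(survivors), size = keep_n, replace = TRUE,
                          prob = wsurv)
          newset <- sort(survivors[unique(picks)])
        }
      }
      retained <- newset
      subsets[[i]] <- retained
      n_subset[i] <- length(retained)
      nc_cv <- min(n_pc, length(retained))
      rmsecv[i] <- tryCatch(
        pls1_rmsecv(X[, retained, drop = FALSE], y, nc_cv, fold_id),
        error = function(e) {degen[i] <<- TRUE; NA_real_})
    }
  })
  score <- ifelse(degen, Inf, rmsecv)
  score[is.na(score)] <- Inf
  best <- which.min(score)
  trace <- data.frame(iteration = seq_len(N), n_forced = n_forced_all,
                      n_subset = n_subset, rmsecv = rmsecv,
                      degenerate = degen)
  new_wl_selection(subsets[[best]], "CARS",
                   list(trace = trace, best_iteration = best,
                        subsets = subsets,
                        config = list(n_iterations = N, mc_ratio = mc_ratio,
                                      n_pc = n_pc, cv_folds = cv_folds,
                                      seed = seed)))
}

#' Uninformative variable elimination (UVE)
#'
#' Appends P artificial noise channels (uniform on `[0, noise_amplitude]`) to
#' the spectral matrix, builds an ensemble of PLS coefficient vectors by
#' cross-validated refitting (leave-one-out by default), and computes each
#' channel's stability `s_j = mean_j / sd_j` across the ensemble. Channels
#' whose |stability| does not exceed `cutoff_factor` times the largest
#' absolute stability among the noise channels are eliminated as
#' uninformative.
#'
#' The noise amplitude defaults to `1e-10 * max(|X|)` so the artificial
#' channels cannot influence the PLS fit itself; stability is scale-free, so
#' their stabilities remain a valid null reference.
#'
#' @param X calibration N x P matrix.
#' @param y calibration response vector.
#' @param n_pc number of PLS factors (default 13).
#' @param cutoff_factor fraction of the maximum absolute noise stability used
#'   as cutoff (default 0.9).
#' @param noise_amplitude upper bound of the uniform noise channels.
#' @param folds `"loo"` (default) or an integer number of folds for the
#'   coefficient ensemble.
#' @param seed integer seed for the noise draw (and fold assignment when
#'   `folds` is numeric).
#' @return a `"wl_selection"`; `diagnostics` hold the real and noise
#'   `stability` vectors and the `cutoff` actually applied.
#' @export
uve_select <- function(X, y, n_pc = 13, cutoff_factor = 0.9,
                       noise_amplitude = NULL, folds = "loo", seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (cutoff_factor <= 0 || cutoff_factor > 1)
    stop("cutoff_factor must be in (0, 1]")
  if (n < n_pc + 2) stop("need at least n_pc + 2 samples")
  if (is.null(noise_amplitude)) noise_amplitude <- 1e-10 * max(abs(X))
  noise <- with_seed(substream_seed(seed, "uve-noise"),
                     matrix(runif(n * p, 0, noise_amplitude), n, p))
  A <- cbind(X, noise)
  fold_id <- if (identical(folds, "loo")) seq_len(n) else
    make_folds(n, as.integer(folds), substream_seed(seed, "uve-folds"))
  ids <- sort(unique(fold_id))
  B <- matrix(0, length(ids), 2 * p)
  for (fi in seq_along(ids)) {
    keep <- fold_id != ids[fi]
    nc <- min(n_pc, sum(keep) - 1L)
    B[fi, ] <- pls1_fit(A[keep, , drop = FALSE], y[keep], nc)$coefficients
  }
  mu <- colMeans(B)
  sdv <- apply(B, 2, sd)
  zero_sd <- sdv == 0
  s <- mu / sdv
  if (any(zero_sd)) {
    warning("UVE: ", sum(zero_sd),
            " channel(s) with zero coefficient sd; stability set to +Inf")
    s[zero_sd] <- ifelse(mu[zero_sd] >= 0, Inf, -Inf)
  }
  s_real <- s[seq_len(p)]
  s_noise <- s[p + seq_len(p)]
  cutoff <- cutoff_factor * max(abs(s_noise))
  sel <- which(abs(s_real) > cutoff)
  fallback <- FALSE
  if (!length(sel)) {
    warning("UVE: no channel exceeded the noise cutoff; ",
            "returning the single most stable channel")
    sel <- which.max(abs(s_real))
    fallback <- TRUE
  }
  new_wl_selection(sel, "UVE",
                   list(stability_real = s_real, stability_noise = s_noise,
                        cutoff = cutoff, cutoff_factor = cutoff_factor,
                        noise_amplitude = noise_amplitude,
                        fallback = fallback,
                        config = list(n_pc = n_pc, folds = folds, seed = seed)))
}

# one successive-projection chain: indices of length <= m_max starting at
# column `start`; truncated if residual norms vanish (rank deficiency)
spa_chain <- function(X, start, m_max, tol = 1e-10) {
  R <- as.matrix(X)
  norm0 <- max(colSums(R^2))
  chain <- integer(0)
  cur <- as.integer(start)
  for (step in seq_len(m_max)) {
    chain <- c(chain, cur)
    v <- R[, cur]
    vv <- sum(v^2)
    if (vv < tol * norm0) break
    R <- R - v %*% (crossprod(v, R) / vv)  # project all columns off v
    R[, chain] <- 0
    nrm <- colSums(R^2)
    if (max(nrm) < tol * norm0) break
    cur <- which.max(nrm)  # ties -> lowest index (which.max is first max)
    if (length(chain) == m_max) break
  }
  chain
}

#' Successive projections algorithm (SPA)
#'
#' Forward selection of minimally collinear channels. For every candidate
#' starting channel a chain is grown by successive orthogonal projection (the
#' next channel is the one with the largest residual norm after projecting out
#' the span of the chain so far). Each chain prefix of size m is scored by the
#' RMSE of an MLR model fitted on an internal Kennard-Stone 2/3-1/3 split of
#' the calibration data; the per-size best RMSE forms the RMSE-versus-size
#' curve, and the returned size is the curve's turning point: the first m
#' whose relative improvement to m+1 falls below `knee_tolerance` (not
#' necessarily the minimum of the curve).
#'
#' @param X calibration N x P matrix.
#' @param y calibration response vector.
#' @param min_vars,max_vars candidate subset sizes; `max_vars` defaults to
#'   `min(N - 1, P, 30)` and is additionally capped so the internal MLR stays
#'   overdetermined.
#' @param knee_tolerance relative-improvement threshold for the turning point
#'   (default 0.02).
#' @return a `"wl_selection"`; `diagnostics` hold the `rmse_curve`
#'   (data.frame `m`, `rmse`, `start`), the `chosen_m`, and the winning chain.
#' @export
spa_select <- function(X, y, min_vars = 1, max_vars = NULL,
                       knee_tolerance = 0.02) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  split <- kennard_stone(X, n_cal = max(2L, round(n * 2 / 3)))
  tr <- split$calibration_idx; va <- split$prediction_idx
  cap <- min(n - 1L, p, length(tr) - 1L)
  if (is.null(max_vars)) max_vars <- min(cap, 30L)
  max_vars <- min(max_vars, cap)
  if (min_vars < 1 || max_vars < min_vars)
    stop("invalid [min_vars, max_vars] = [", min_vars, ", ", max_vars, "]")
  chains <- lapply(seq_len(p), function(s) spa_chain(X[tr, , drop = FALSE],
                                                     s, max_vars))
  ms <- seq.int(min_vars, max_vars)
  rmse_best <- rep(Inf, length(ms))
  start_best <- integer(length(ms))
  chain_best <- vector("list", length(ms))
  for (s in seq_len(p)) {
    ch <- chains[[s]]
    for (mi in seq_along(ms)) {
      m <- ms[mi]
      if (length(ch) < m) next
      sub <- ch[seq_len(m)]
      Xtr <- cbind(1, X[tr, sub, drop = FALSE])
      fit <- lm.fit(Xtr, y[tr])
      if (fit$rank < ncol(Xtr)) next
      pred <- drop(cbind(1, X[va, sub, drop = FALSE]) %*% fit$coefficients)
      r <- sqrt(mean((pred - y[va])^2))
      if (r < rmse_best[mi]) {
        rmse_best[mi] <- r
        start_best[mi] <- s
        chain_best[[mi]] <- sub
      }
    }
  }
  ok <- is.finite(rmse_best)
  if (!any(ok)) stop("SPA: no evaluable subset (rank deficiency everywhere)")
  ms <- ms[ok]; rmse_best <- rmse_best[ok]
  start_best <- start_best[ok]; chain_best <- chain_best[ok]
  chosen <- length(ms)
  if (length(ms) > 1) {
    for (i in seq_len(length(ms) - 1L)) {
      improv <- (rmse_best[i] - rmse_best[i + 1]) / rmse_best[i]
      if (improv < knee_tolerance) {chosen <- i; break}
    }
  }
  curve <- data.frame(m = ms, rmse = rmse_best, start = start_best)
  new_wl_selection(chain_best[[chosen]], "SPA",
                   list(rmse_curve = curve, chosen_m = ms[chosen],
                        chain = chain_best[[chosen]],
                        config = list(min_vars = min_vars,
                                      max_vars = max_vars,
                                      knee_tolerance = knee_tolerance)))
}

#' Fraction of the wavelength axis retained by a selection
#'
#' @param n_selected number of selected channels, or a `"wl_selection"`.
#' @param n_total total number of channels.
#' @param digits rounding for the percentage (default 2).
#' @return the selected percentage of the full axis.
#' @export
selected_fraction <- function(n_selected, n_total, digits = 2) {
  if (inherits(n_selected, "wl_selection"))
    n_selected <- length(n_selected$selected_idx)
  round(100 * n_selected / n_total, digits)
}

#' Export selected wavelengths as a two-column table
#'
#' @param selection a `"wl_selection"`.
#' @param wavelengths_nm the wavelength axis the indices refer to.
#' @return data.frame with columns `index` (1-based channel index) and `nm`.
#' @export
selection_table <- function(selection, wavelengths_nm) {
  stopifnot(inherits(selection, "wl_selection"))
  data.frame(index = selection$selected_idx,
             nm = wavelengths_nm[selection$selected_idx])
}
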
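# Internal PLS1 (single-response NIPALS) core used by the PLSR model and by
# the CARS/UVE selectors, plus shared cross-validation helpers.
#
# For a single response the NIPALS weight step is closed-form (w = X'y up to
# normalisation), so each latent factor costs a handful of matrix-vector
# products. Coefficients are returned in the original (centered) variable
# space: B = W (P'W)^{-1} q, intercept = ybar - xbar'B.

pls1_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (sd(y) == 0) stop("zero-variance response")
  ncomp <- as.integer(min(ncomp, n - 1L, p))
  if (ncomp < 1) stop("ncomp must be >= 1")
  xbar <- colMeans(X); ybar <- mean(y)
  Xd <- sweep(X, 2, xbar); yd <- y - ybar
  W <- matrix(0, p, ncomp); Pl <- matrix(0, p, ncomp)
  Q <- numeric(ncomp); Tm <- matrix(0, n, ncomp)
  a <- 0L
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tv <- Xd %*% w
    tt <- sum(tv^2)
    if (tt < 1e-12) break
    pv <- crossprod(Xd, tv) / tt
    q <- sum(yd * tv) / tt
    Xd <- Xd - tcrossprod(tv, pv)
    yd <- yd - q * as.numeric(tv)
    W[, k] <- w; Pl[, k] <- pv; Q[k] <- q; Tm[, k] <- tv
    a <- k
  }
  if (a == 0L) stop("PLS: no usable latent factor (X'y is zero)")
  W <- W[, seq_len(a), drop = FALSE]
  Pl <- Pl[, seq_len(a), drop = FALSE]
  Q <- Q[seq_len(a)]
  B <- drop(W %*% solve(crossprod(Pl, W), Q))
  list(coefficients = B, intercept = ybar - sum(xbar * B),
       ncomp = a, xbar = xbar, ybar = ybar,
       scores = Tm[, seq_len(a), drop = FALSE],
       weights = W, loadings = Pl, yloadings = Q)
}

pls1_predict <- function(fit, Xnew) {
  drop(as.matrix(Xnew) %*% fit$coefficients) + fit$intercept
}

# deterministic k-fold assignment (stratified only by order), seeded locally
# so callers' RNG state is untouched
make_folds <- function(n, k, seed) {
  k <- min(k, n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

# RMSECV of a PLS1 model over a fixed fold assignment
pls1_rmsecv <- function(X, y, ncomp, fold_id) {
  X <- as.matrix(X)
  pred <- numeric(length(y))
  for (f in sort(unique(fold_id))) {
    te <- fold_id == f
    nc <- min(ncomp, sum(!te) - 1L, ncol(X))
    fit <- pls1_fit(X[!te, , drop = FALSE], y[!te], nc)
    pred[te] <- pls1_predict(fit, X[te, , drop = FALSE])
  }
  sqrt(mean((pred - y)^2))
}

# run a function with a locally seeded RNG, restoring caller RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}
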
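# PLSR, MLR and LS-SVM fits, hyperparameter tuning, prediction guards and
# persistence.

test_that("plsr recovers an exact linear relation with full factors", {
  set.seed(1)
  X <- matrix(rnorm(30 * 5), 30)
  y <- drop(X %*% c(1, -2, 0.5, 3, 0)) + 4
  m <- fit_plsr(X, y, n_factors = 5)
  expect_lt(max(abs(residuals(m))), 1e-8)
})

test_that("plsr at full rank equals ordinary least squares", {
  set.seed(2)
  X <- matrix(rnorm(40 * 6), 40)
  y <- drop(X %*% rnorm(6)) + rnorm(40, 0, 0.3)
  m <- fit_plsr(X, y, n_factors = 6)
  ols <- lm.fit(cbind(1, X), y)
  expect_equal(unname(fitted(m)), unname(ols$fitted.values), tolerance = 1e-6)
})

test_that("plsr scores are mutually orthogonal", {
  set.seed(3)
  X <- matrix(rnorm(50 * 20), 50)
  y <- rnorm(50)
  m <- fit_plsr(X, y, n_factors = 8)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("plsr with 1 factor on univariate X is simple linear regression", {
  set.seed(4)
  x <- rnorm(25)
  y <- 2 * x + 1 + rnorm(25, 0, 0.1)
  m <- fit_plsr(matrix(x), y, n_factors = 1)
  sl <- lm.fit(cbind(1, x), y)$coefficients
  expect_equal(unname(m$coefficients), unname(sl[2]), tolerance = 1e-10)
  expect_equal(m$intercept, unname(sl[1]), tolerance = 1e-10)
})

test_that("plsr agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(5)
  X <- matrix(rnorm(30 * 12), 30, dimnames = list(NULL, paste0("V", 1:12)))
  y <- drop(X %*% rnorm(12)) + rnorm(30)
  m <- fit_plsr(X, y, n_factors = 4)
  ref <- mixOmics::pls(X, y, ncomp = 4, mode = "regression",
                       scale = FALSE)
  ref_pred <- predict(ref, X)$predict[, 1, 4]
  expect_equal(unname(fitted(m)), unname(ref_pred), tolerance = 1e-6)
})

test_that("plsr guards degenerate inputs", {
  X <- matrix(rnorm(20 * 3), 20)
  expect_error(fit_plsr(X, rep(1, 20), n_factors = 2), "zero-variance")
  expect_error(fit_plsr(X, rnorm(20), n_factors = 10), "exceeds")
})

test_that("mlr recovers exact coefficients and guards underdetermined fits", {
  set.seed(6)
  x <- rnorm(20)
  m <- fit_mlr(matrix(x), 2 * x + 3)
  expect_equal(m$coefficients, 2, tolerance = 1e-10)
  expect_equal(m$intercept, 3, tolerance = 1e-10)
  Xw <- matrix(rnorm(10 * 12), 10)
  expect_error(fit_mlr(Xw, rnorm(10)), "wavelength selection")
  mp <- fit_mlr(Xw, rnorm(10), allow_pinv = TRUE)
  expect_true(mp$used_pinv)
})

test_that("mlr matches a pseudo-inverse oracle on a well-conditioned system", {
  set.seed(7)
  X <- matrix(rnorm(50 * 8), 50)
  y <- drop(X %*% rnorm(8)) + rnorm(50, 0, 0.2)
  m <- fit_mlr(X, y)
  Xd <- cbind(1, X)
  beta <- drop(solve(crossprod(Xd), crossprod(Xd, y)))  # normal equations
  expect_equal(c(m$intercept, m$coefficients), unname(beta), tolerance = 1e-8)
})

test_that("lssvm approaches interpolation for large gamma, kernel is PSD", {
  set.seed(8)
  X <- matrix(rnorm(20 * 2), 20)
  y <- rnorm(20)
  m <- fit_lssvm(X, y, gamma = 1e8, sigma2 = 2)
  expect_lt(max(abs(fitted(m) - y)), 1e-3)
  K <- exp(-as.matrix(dist(X))^2 / 2)
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
})

test_that("lssvm solution satisfies the KKT linear system", {
  set.seed(9)
  X <- matrix(rnorm(30 * 4), 30)
  y <- rnorm(30)
  m <- fit_lssvm(X, y, gamma = 50, sigma2 = 4)
  expect_lt(m$kkt_residual, 1e-8)
})

test_that("tuned lssvm fits a smooth function accurately", {
  set.seed(10)
  x <- matrix(sort(runif(50, 0, 2 * pi)))
  y <- sin(x[, 1])
  tuned <- tune_lssvm(x, y, gamma_grid = c(10, 100, 1000),
                      sigma2_grid = c(0.5, 1, 2), seed = 1)
  m <- fit_lssvm(x, y, tuned$gamma, tuned$sigma2)
  xt <- matrix(seq(0.2, 2 * pi - 0.2, length.out = 100))
  expect_lt(sqrt(mean((predict(m, xt) - sin(xt[, 1]))^2)), 0.05)
})

test_that("tune_lssvm honours its argmin contract", {
  set.seed(11)
  X <- matrix(rnorm(30 * 3), 30)
  y <- drop(X %*% c(1, 1, 1)) + rnorm(30, 0, 0.1)
  single <- tune_lssvm(X, y, gamma_grid = 42, sigma2_grid = 3, seed = 1)
  expect_equal(c(single$gamma, single$sigma2), c(42, 3))
  tuned <- tune_lssvm(X, y, gamma_grid = c(1, 100), sigma2_grid = c(1, 10),
                      seed = 1)
  tab <- tuned$rmsecv
  best <- tab[which.min(tab$rmsecv), ]
  expect_equal(c(tuned$gamma, tuned$sigma2), c(best$gamma, best$sigma2))
})

test_that("tune_lssvm recovers the neighbourhood of the generating kernel", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    Xtr <- matrix(runif(60, -2, 2))
    centers <- matrix(c(-1, 0, 1))
    truth_s2 <- 1
    y <- rowSums(exp(-outer(Xtr[, 1], centers[, 1], "-")^2 / truth_s2)) +
      rnorm(60, 0, 0.02)
    grid_s2 <- c(0.25, 0.5, 1, 2, 4)
    tuned <- tune_lssvm(Xtr, y, gamma_grid = c(10, 100, 1000),
                        sigma2_grid = grid_s2, seed = s)
    step <- abs(log2(tuned$sigma2) - log2(truth_s2))
    if (step <= 1) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("models are invariant to sample reordering", {
  set.seed(12)
  X <- matrix(rnorm(40 * 5), 40)
  y <- drop(X %*% rnorm(5)) + rnorm(40, 0, 0.1)
  perm <- sample(40)
  Xnew <- matrix(rnorm(10 * 5), 10)
  m1 <- fit_plsr(X, y, 3); m2 <- fit_plsr(X[perm, ], y[perm], 3)
  expect_equal(predict(m1, Xnew), predict(m2, Xnew), tolerance = 1e-10)
  m1 <- fit_mlr(X, y); m2 <- fit_mlr(X[perm, ], y[perm])
  expect_equal(predict(m1, Xnew), predict(m2, Xnew), tolerance = 1e-8)
  m1 <- fit_lssvm(X, y, 10, 4); m2 <- fit_lssvm(X[perm, ], y[perm], 10, 4)
  expect_equal(predict(m1, Xnew), predict(m2, Xnew), tolerance = 1e-8)
})

test_that("predict reproduces training fits and guards column provenance", {
  set.seed(13)
  X <- matrix(rnorm(25 * 4), 25,
              dimnames = list(NULL, paste0("w", 1:4)))
  y <- rnorm(25)
  for (m in list(fit_plsr(X, y, 2), fit_mlr(X, y), fit_lssvm(X, y, 10, 2))) {
    expect_equal(predict(m, X), unname(fitted(m)), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_error(predict(m, X[, c(2, 1, 3, 4)]), "provenance error")
    expect_error(predict(m, X[, 1:3]), "provenance error")
  }
})

test_that("save/load round trip predicts bit-identically", {
  set.seed(14)
  X <- matrix(rnorm(20 * 3), 20)
  y <- rnorm(20)
  Xnew <- matrix(rnorm(7 * 3), 7)
  for (m in list(fit_plsr(X, y, 2, wavelengths_nm = c(450, 550, 650)),
                 fit_mlr(X, y),
                 fit_lssvm(X, y, 25, 3))) {
    f <- withr::local_tempfile(fileext = ".json")
    write_model(m, f)
    back <- read_model(f)
    expect_identical(predict(back, Xnew), predict(m, Xnew))
  }
})
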
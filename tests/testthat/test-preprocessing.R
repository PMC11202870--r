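# The seven preprocessing transforms and the fit/apply dispatcher.

test_that("center subtracts column means and is idempotent", {
  expect_equal(pp_center(matrix(c(1, 3, 3, 5), 2)),
               matrix(c(-1, 1, -1, 1), 2))
  set.seed(1)
  X <- matrix(rnorm(20 * 50), 20)
  Xc <- pp_center(X)
  expect_lt(max(abs(colMeans(Xc))), 1e-12)
  expect_equal(pp_center(Xc), Xc, tolerance = 1e-10)
})

test_that("mvn autoscales columns with ddof=1 and is idempotent", {
  expect_equal(pp_mvn(matrix(c(1, 3), 2, 1)),
               matrix(c(-1, 1) / sqrt(2), 2, 1), tolerance = 1e-6)
  set.seed(2)
  X <- matrix(rnorm(15 * 8), 15)
  Z <- pp_mvn(X)
  expect_lt(max(abs(apply(Z, 2, var) - 1)), 1e-10)
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_equal(pp_mvn(Z), Z, tolerance = 1e-10)
  X[, 3] <- 5
  expect_error(pp_mvn(X), "zero-variance column")
})

test_that("nor min-max scales rows to [0,1], constant rows -> zeros + warning", {
  expect_equal(pp_nor(matrix(c(2, 4, 6), 1)), matrix(c(0, 0.5, 1), 1))
  set.seed(3)
  X <- matrix(rnorm(10 * 30), 10)
  Z <- pp_nor(X)
  expect_equal(apply(Z, 1, min), rep(0, 10))
  expect_equal(apply(Z, 1, max), rep(1, 10))
  expect_equal(pp_nor(Z), Z, tolerance = 1e-12)  # idempotent on [0,1] range
  Xf <- rbind(X, 7)
  expect_warning(Zf <- pp_nor(Xf), "constant row")
  expect_equal(Zf[11, ], rep(0, 30))
})

test_that("moving average uses shrinking symmetric edge windows", {
  expect_equal(pp_moving_average(matrix(c(1, 2, 3, 4), 1), 3),
               matrix(c(1.5, 2, 3, 3.5), 1))
  const <- matrix(3.7, 2, 9)
  expect_equal(pp_moving_average(const, 5), const)
  expect_error(pp_moving_average(matrix(1:8, 1), 4), "odd")
  # smoothing strictly reduces white-noise variance
  set.seed(4)
  drops <- replicate(20, {
    x <- matrix(rnorm(200), 1)
    var(as.numeric(pp_moving_average(x, 5))) < var(as.numeric(x))
  })
  expect_true(all(drops))
})

test_that("savitzky-golay reproduces low-degree polynomials exactly", {
  grid <- seq(-1, 1, length.out = 41)
  X <- rbind(rep(2.5, 41), 3 * grid^2 - grid + 1)
  Z <- pp_savitzky_golay(X, window = 11, polyorder = 2)
  expect_equal(Z, X, tolerance = 1e-10)
  expect_error(pp_savitzky_golay(X, window = 11, polyorder = 11), "polyorder")
  # noisy sine gets closer to the clean signal
  set.seed(5)
  closer <- replicate(20, {
    clean <- sin(seq(0, 2 * pi, length.out = 200))
    noisy <- clean + rnorm(200, 0, 0.2)
    sm <- as.numeric(pp_savitzky_golay(matrix(noisy, 1), 11, 2))
    sqrt(mean((sm - clean)^2)) < sqrt(mean((noisy - clean)^2))
  })
  expect_true(all(closer))
})

test_that("snv standardises rows (ddof=1) and collapses affine distortions", {
  expect_equal(pp_snv(matrix(c(1, 2, 3), 1)), matrix(c(-1, 0, 1), 1))
  set.seed(6)
  X <- matrix(rnorm(12 * 40), 12)
  Z <- pp_snv(X)
  expect_lt(max(abs(rowMeans(Z))), 1e-12)
  expect_lt(max(abs(apply(Z, 1, sd) - 1)), 1e-10)
  expect_equal(pp_snv(Z), Z, tolerance = 1e-10)
  s <- rnorm(40)
  fam <- rbind(s, 2.5 * s + 1, 0.3 * s - 4)
  Zf <- pp_snv(fam)
  expect_equal(Zf[2, ], Zf[1, ], tolerance = 1e-10)
  expect_equal(Zf[3, ], Zf[1, ], tolerance = 1e-10)
  expect_error(pp_snv(rbind(s, rep(1, 40))), "constant row")
})

test_that("msc inverts affine scatter against the reference", {
  set.seed(7)
  ref <- sin(seq(0, 3, length.out = 50)) + 2
  X <- rbind(2 * ref + 5, ref, 0.5 * ref - 1)
  Z <- pp_msc(X, reference = ref)
  for (i in 1:3) expect_equal(unname(Z[i, ]), ref, tolerance = 1e-10)
  # scatter-equivalence collapse: a*s+b family maps to one spectrum
  s <- rnorm(50) + 5
  fam <- rbind(s, 3 * s + 2, 0.4 * s - 1)
  Zf <- pp_msc(fam, reference = s)
  expect_equal(Zf[2, ], Zf[1, ], tolerance = 1e-10)
  expect_equal(Zf[3, ], Zf[1, ], tolerance = 1e-10)
})

test_that("msc reduces the error of scatter-corrupted synthetic spectra", {
  ds <- generate_dataset(synthetic_config("MC", n_samples = 40,
                                          n_wavelengths = 150, seed = 11))
  corrected <- pp_msc(ds$reflectance, reference = colMeans(ds$clean))
  rmse <- function(A, B) mean(sqrt(rowMeans((A - B)^2)))
  expect_lt(rmse(corrected, ds$clean), rmse(ds$reflectance, ds$clean))
})

test_that("apply_preprocess separates calibration fit from prediction apply", {
  set.seed(8)
  Xc <- matrix(rnorm(30 * 10, mean = 2), 30)
  Xp <- matrix(rnorm(10 * 10, mean = 5), 10)  # shifted prediction rows
  fit <- fit_preprocess(Xc, preprocess_spec("Center"))
  expect_equal(apply_preprocess(fit, Xc), pp_center(Xc))
  Zp <- apply_preprocess(fit, Xp)
  # prediction rows are shifted by calibration means, not their own
  expect_equal(Zp, sweep(Xp, 2, colMeans(Xc)))
  expect_gt(max(abs(colMeans(Zp))), 1)  # would be ~0 if fitted on Xp itself
  raw <- fit_preprocess(Xc, preprocess_spec("RAW"))
  expect_identical(apply_preprocess(raw, Xp), Xp)
  expect_error(apply_preprocess(preprocess_spec("Center"), Xp),
               "state error")
})

test_that("fitted MSC reference comes from the calibration set", {
  set.seed(9)
  Xc <- matrix(rnorm(20 * 15), 20) + 3
  Xp <- matrix(rnorm(5 * 15), 5) + 3
  fit <- fit_preprocess(Xc, preprocess_spec("MSC"))
  expect_equal(fit$stats$reference, colMeans(Xc))
  expect_equal(apply_preprocess(fit, Xp), pp_msc(Xp, colMeans(Xc)),
               ignore_attr = TRUE)
})
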
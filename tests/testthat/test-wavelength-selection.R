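# CARS, UVE and SPA characteristic-wavelength selection.

test_that("cars EDF endpoints and monotone retention trace", {
  ds <- planted_band_dataset(1, n = 40, p = 60)
  sel <- cars_select(ds$reflectance, ds$indicators$MC, n_iterations = 30,
                     n_pc = 5, seed = 1)
  tr <- sel$diagnostics$trace
  expect_equal(tr$n_forced[1], 60)       # starts at P
  expect_equal(tr$n_forced[30], 2)       # EDF forces down to 2
  expect_true(all(diff(tr$n_forced) <= 0))
  expect_true(all(diff(tr$n_subset) <= 0))
  # closed-form EDF endpoints at full scale
  P <- 1360; N <- 160
  a <- (P / 2)^(1 / (N - 1)); k <- log(P / 2) / (N - 1)
  expect_equal(round(a * exp(-k * 1) * P), P)
  expect_equal(round(a * exp(-k * N) * P), 2)
})

test_that("cars returns the subset at the RMSECV argmin", {
  ds <- planted_band_dataset(2, n = 50, p = 80)
  sel <- cars_select(ds$reflectance, ds$indicators$MC, n_iterations = 40,
                     n_pc = 5, seed = 2)
  tr <- sel$diagnostics$trace
  score <- ifelse(tr$degenerate, Inf, tr$rmsecv)
  best <- which.min(score)
  expect_equal(sel$diagnostics$best_iteration, best)
  expect_identical(sel$selected_idx,
                   sort(sel$diagnostics$subsets[[best]]))
})

test_that("cars is deterministic given seed and sensitive to it", {
  ds <- planted_band_dataset(3, n = 40, p = 60)
  a <- cars_select(ds$reflectance, ds$indicators$MC, n_iterations = 25,
                   n_pc = 4, seed = 7)
  b <- cars_select(ds$reflectance, ds$indicators$MC, n_iterations = 25,
                   n_pc = 4, seed = 7)
  expect_identical(a$selected_idx, b$selected_idx)
  expect_identical(a$diagnostics$trace, b$diagnostics$trace)
})

test_that("cars recovers planted informative bands", {
  hits <- 0
  for (s in 1:10) {
    ds <- planted_band_dataset(s)
    sel <- cars_select(ds$reflectance, ds$indicators$MC, seed = s)
    if (band_hits(sel$selected_idx, ds$informative_channels) >= 4)
      hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("uve always selects a near-perfect predictor column", {
  for (s in 1:10) {
    set.seed(s)
    n <- 40; p <- 30
    X <- matrix(rnorm(n * p), n)
    y <- rnorm(n)
    X[, 13] <- y + rnorm(n, 0, 1e-4)  # duplicated response, tiny noise
    sel <- suppressWarnings(uve_select(X, y, n_pc = 5, seed = s))
    expect_true(13 %in% sel$selected_idx)
  }
})

test_that("uve selects little under a pure-noise response", {
  fracs <- vapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(40 * 50), 40)
    y <- rnorm(40)
    sel <- suppressWarnings(uve_select(X, y, n_pc = 5, seed = s))
    length(sel$selected_idx) / 50
  }, 0)
  expect_lte(mean(fracs), 0.2)
})

test_that("uve cutoff equals cutoff_factor times max |noise stability|", {
  ds <- planted_band_dataset(4, n = 40, p = 60)
  sel <- uve_select(ds$reflectance, ds$indicators$MC, n_pc = 6,
                    cutoff_factor = 0.9, seed = 4)
  d <- sel$diagnostics
  expect_equal(d$cutoff, 0.9 * max(abs(d$stability_noise)))
  expect_identical(sel$selected_idx,
                   which(abs(d$stability_real) > d$cutoff))
  # noise channels live outside the real index range by construction
  expect_true(all(sel$selected_idx <= 60))
})

test_that("uve recovers planted informative bands", {
  hits <- 0
  for (s in 1:10) {
    ds <- planted_band_dataset(s)
    sel <- uve_select(ds$reflectance, ds$indicators$MC, seed = s)
    if (band_hits(sel$selected_idx, ds$informative_channels) >= 4)
      hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("spa chains match the brute-force projection oracle", {
  set.seed(5)
  X <- matrix(rnorm(6 * 4), 6)
  for (start in 1:4)
    expect_identical(leafspec:::spa_chain(X, start, 4),
                     as.integer(spa_chain_oracle(X, start, 4)))
  # larger instance
  set.seed(6)
  X2 <- matrix(rnorm(10 * 7), 10)
  for (start in 1:7)
    expect_identical(leafspec:::spa_chain(X2, start, 6),
                     as.integer(spa_chain_oracle(X2, start, 6)))
})

test_that("duplicate columns never share a chain", {
  set.seed(7)
  X <- matrix(rnorm(12 * 5), 12)
  X[, 4] <- X[, 2]
  for (start in 1:5) {
    ch <- leafspec:::spa_chain(X, start, 5)
    expect_false(all(c(2, 4) %in% ch))
  }
})

test_that("spa selected variables are linearly independent", {
  f <- spa_informative_fixture(1)
  sel <- spa_select(f$X, f$y, knee_tolerance = 0.05)
  G <- crossprod(f$X[, sel$selected_idx, drop = FALSE])
  expect_equal(qr(G)$rank, length(sel$selected_idx))
})

test_that("spa turning point lands near the informative count", {
  ok <- 0
  for (s in 1:10) {
    f <- spa_informative_fixture(100 + s)
    sel <- spa_select(f$X, f$y, knee_tolerance = 0.05)
    m <- sel$diagnostics$chosen_m
    if (m >= 3 && m <= 5) ok <- ok + 1
  }
  expect_gte(ok, 8)
})

test_that("selection results are valid and serialisable", {
  ds <- planted_band_dataset(8, n = 40, p = 60)
  sel <- uve_select(ds$reflectance, ds$indicators$MC, n_pc = 5, seed = 8)
  expect_true(all(diff(sel$selected_idx) > 0))  # sorted, unique
  expect_true(all(sel$selected_idx >= 1 & sel$selected_idx <= 60))
  tab <- selection_table(sel, ds$wavelengths_nm)
  expect_identical(tab$index, sel$selected_idx)
  expect_equal(tab$nm, ds$wavelengths_nm[sel$selected_idx])
})
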
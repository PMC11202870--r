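# Shared fixtures and independent oracles for the test suite. The oracles
# deliberately re-derive results from first principles (direct formulas,
# exhaustive greedy search) without calling the implementation under test.

# small spectral dataset with indicators for I/O round trips
toy_dataset <- function(n = 3, p = 4, seed = 42) {
  set.seed(seed)
  spectral_dataset(seq(400, 700, length.out = p),
                   matrix(round(runif(n * p), 6), n, p),
                   sample_ids = paste0("leaf", seq_len(n)),
                   indicators = list(MC = round(runif(n, 88, 97), 4)))
}

# synthetic planted-band fixture: 5 informative bands among `p` channels
planted_band_dataset <- function(seed, n = 100, p = 200, noise_sd = 0.00125) {
  cfg <- synthetic_config(
    "MC", n_samples = n, n_wavelengths = p,
    band_centers_nm = c(460, 560, 670, 760, 880),
    band_widths_nm = rep(15, 5),
    band_signs = c(-1, 1, -1, 1, -1),
    band_depths = rep(0.1, 5),
    coupling = rep(0.04, 5),
    scatter_sd = 0, offset_sd = 0, noise_sd = noise_sd, seed = seed)
  generate_dataset(cfg)
}

# how many of the planted band centers have a selected channel within +-5
band_hits <- function(selected_idx, band_channels, window = 5) {
  sum(vapply(band_channels,
             function(b) any(abs(selected_idx - b) <= window), TRUE))
}

# 3 high-variance informative variables among low-variance noise columns:
# the variance contrast is what makes the norms that drive successive
# projection track the informative set
spa_informative_fixture <- function(seed, n = 60, p = 20) {
  set.seed(seed)
  X <- matrix(rnorm(n * p, 0, 0.4), n, p)
  inf <- c(4, 11, 17)
  X[, inf] <- matrix(rnorm(n * 3, 0, 2), n, 3)
  y <- X[, 4] + X[, 11] - X[, 17] + rnorm(n, 0, 0.05)
  list(X = X, y = y, informative = inf)
}

# --- independent oracles ----------------------------------------------------

# Kennard-Stone re-implemented from the definition with explicit loops
ks_oracle <- function(X, n_cal) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  best <- c(-Inf, NA, NA)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (D[i, j] > best[1]) best <- c(D[i, j], i, j)
  sel <- c(best[2], best[3])
  while (length(sel) < n_cal) {
    cand_best <- c(-Inf, NA)
    for (c in setdiff(seq_len(n), sel)) {
      dmin <- min(D[c, sel])
      if (dmin > cand_best[1]) cand_best <- c(dmin, c)
    }
    sel <- c(sel, cand_best[2])
  }
  as.integer(sel)
}

# successive-projection chain recomputed with explicit orthogonalisation
spa_chain_oracle <- function(X, start, m_max) {
  chain <- start
  basis <- list()
  for (step in seq_len(m_max - 1)) {
    v <- X[, chain[length(chain)]]
    for (b in basis) v <- v - sum(v * b) * b
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10) break
    basis <- c(basis, list(v / nv))
    resid_norm <- rep(-1, ncol(X))
    for (j in setdiff(seq_len(ncol(X)), chain)) {
      r <- X[, j]
      for (b in basis) r <- r - sum(r * b) * b
      resid_norm[j] <- sum(r^2)
    }
    if (max(resid_norm) < 1e-10 * max(colSums(X^2))) break
    chain <- c(chain, which.max(resid_norm))
  }
  chain
}

# evaluation metrics recomputed directly from the defining formulas
metrics_oracle <- function(ycm, ycp, ypm, ypp) {
  pearson <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  rmsec <- sqrt(sum((ycm - ycp)^2) / length(ycm))
  rmsep <- sqrt(sum((ypm - ypp)^2) / length(ypm))
  stdp <- sqrt(sum((ypm - mean(ypm))^2) / (length(ypm) - 1))
  list(rc = pearson(ycm, ycp), rmsec = rmsec,
       rp = pearson(ypm, ypp), rmsep = rmsep,
       stdp = stdp, rpd = stdp / rmsep)
}
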
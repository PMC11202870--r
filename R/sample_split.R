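# Kennard-Stone calibration/prediction partitioning and per-set descriptive
# statistics.

#' Kennard-Stone sample partitioning
#'
#' Deterministic max-min greedy selection of a representative calibration set
#' in Euclidean distance on the rows of `X`: the first two picks are a most
#' distant pair; every subsequent pick maximises its minimum distance to the
#' samples already selected. Ties are broken by the smallest sample index, so
#' the split is fully reproducible. The remaining samples form the prediction
#' set.
#'
#' @param X numeric N x P matrix (typically the preprocessed spectra).
#' @param n_cal number of calibration samples, `2 <= n_cal <= N`. Alternatively
#'   supply `ratio`.
#' @param ratio calibration:prediction ratio `r` (e.g. 3 for 3:1); used when
#'   `n_cal` is missing, with `n_cal = round(N * r / (r + 1))`.
#' @return an object of class `"ks_split"`: list with `calibration_idx` (in KS
#'   selection order), `prediction_idx` (increasing), `ratio`, `n`.
#' @export
kennard_stone <- function(X, n_cal = NULL, ratio = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(n_cal)) {
    if (is.null(ratio)) stop("supply n_cal or ratio")
    n_cal <- round(n * ratio / (ratio + 1))
  }
  if (n_cal < 2 || n_cal > n)
    stop("n_cal must satisfy 2 <= n_cal <= N (got ", n_cal, " for N=", n, ")")
  D <- unname(as.matrix(dist(X)))
  # seed pair: maximum pairwise distance; ties -> lexicographically smallest (i, j)
  m <- max(D)
  hit <- which(D == m, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  sel <- as.integer(hit[1, ])
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < n_cal) {
    nxt <- unname(which(mind == max(mind))[1])  # lowest index on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  structure(list(calibration_idx = sel,
                 prediction_idx = setdiff(seq_len(n), sel),
                 ratio = if (!is.null(ratio)) ratio else n_cal / (n - n_cal),
                 n = n),
            class = "ks_split")
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("<ks_split> %d calibration / %d prediction (of %d)\n",
              length(x$calibration_idx), length(x$prediction_idx), x$n))
  invisible(x)
}

#' Per-set descriptive statistics of an indicator under a split
#'
#' Reports maximum, minimum, mean and sample standard deviation (denominator
#' N-1) of a per-sample value vector within the calibration and prediction
#' sets, in the layout of a sample-partition summary table.
#'
#' @param values numeric N-vector of indicator values.
#' @param split a [kennard_stone()] result.
#' @return data.frame with rows `calibration` and `prediction` and columns
#'   `n`, `max`, `min`, `mean`, `sd`.
#' @export
split_statistics <- function(values, split) {
  stopifnot(inherits(split, "ks_split"))
  values <- as.numeric(values)
  if (length(values) != split$n)
    stop("values length (", length(values), ") does not match split N (",
         split$n, ")")
  one <- function(idx) {
    if (!length(idx)) stop("empty sample set in split")
    v <- values[idx]
    data.frame(n = length(v), max = max(v), min = min(v),
               mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
  }
  out <- rbind(one(split$calibration_idx), one(split$prediction_idx))
  rownames(out) <- c("calibration", "prediction")
  out
}
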
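#' Time-frequency phase lag index between two channels
#'
#' For each frequency, sample and trial the phase difference is the argument
#' of `coef_a * Conj(coef_b)`; the PLI at a pixel is the absolute mean over
#' trials of its sign (`sgn(0) = 0`). Values lie in `[0, 1]`: 1 means the
#' phase difference keeps one sign across all trials, 0 means sign-balanced
#' (as produced by zero-lag, volume-conducted coupling).
#'
#' @param coeffs_a,coeffs_b `tf_coef` objects from the same bank with equal
#'   trial counts.
#' @return Numeric matrix frequencies x samples in `[0, 1]`.
#' @export
pli_timefreq <- function(coeffs_a, coeffs_b) {
  stopifnot(inherits(coeffs_a, "tf_coef"), inherits(coeffs_b, "tf_coef"))
  if (!identical(dim(coeffs_a$values), dim(coeffs_b$values))) {
    stop("shape error: coefficient arrays must agree (same bank, same trials)")
  }
  dphi <- Arg(coeffs_a$values * Conj(coeffs_b$values))
  abs(rowMeans(sign(dphi), dims = 2L))
}

#' Band- and window-averaged PLI connectivity matrix
#'
#' Computes the PLI for every unordered channel pair, averaged over the bank
#' frequencies inside `band` (inclusive ends) and the samples with
#' `t0 <= t < t1`. The wavelet coefficients are the same Morlet decomposition
#' used for the power analysis.
#'
#' @param epochs An `epoch_set`.
#' @param bank A `wavelet_bank`.
#' @param band Frequency band `(f_lo, f_hi)` in Hz; defaults to theta (4-7).
#' @param window Time window `(t0, t1)` in seconds after onset.
#' @return An object of class `pli_matrix`: symmetric `values` with zero
#'   diagonal in `[0, 1]`, plus `band`, `window`, `montage`.
#' @export
pli_matrix <- function(epochs, bank, band = c(4, 7), window = c(0.1, 0.6)) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(bank, "wavelet_bank"))
  fsel <- which(bank$freqs >= band[1] & bank$freqs <= band[2])
  if (length(fsel) == 0L) {
    stop("validation error: band contains no bank frequencies")
  }
  widx <- window_indices(epochs, window)
  d <- dim(epochs$data)
  n <- d[1]
  # one decomposition per channel, band frequencies only, window columns only
  coefs <- lapply(seq_len(n), function(ci) {
    morlet_convolve(matrix(epochs$data[ci, , ], d[2], d[3]),
                    bank$freqs[fsel], bank$cycles[fsel],
                    epochs$fs)[, widx, , drop = FALSE]
  })
  values <- matrix(0, n, n, dimnames = list(epochs$montage, epochs$montage))
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      s <- sign(Arg(coefs[[a]] * Conj(coefs[[b]])))
      values[a, b] <- values[b, a] <- mean(abs(rowMeans(s, dims = 2L)))
    }
  }
  structure(list(values = values, band = band, window = window,
                 montage = epochs$montage),
            class = "pli_matrix")
}

#' @export
print.pli_matrix <- function(x, ...) {
  cat(sprintf("<pli_matrix> %d channels, band %g-%g Hz, window [%g, %g) s\n",
              nrow(x$values), x$band[1], x$band[2], x$window[1], x$window[2]))
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("  PLI range %.3f .. %.3f (median %.3f)\n",
              min(off), max(off), stats::median(off)))
  invisible(x)
}

#' Vectorize the upper triangle of a PLI matrix
#'
#' Row-major upper triangle (`a < b` in montage order), so a 20-channel
#' matrix yields 190 features. The mapping is invertible via
#' [pli_from_features()].
#'
#' @param matrix_ A `pli_matrix`.
#' @return Data frame with columns `estimator` (`"PLI"`), `ch_a`, `ch_b`,
#'   `value`.
#' @export
vectorize_upper <- function(matrix_) {
  stopifnot(inherits(matrix_, "pli_matrix"))
  v <- matrix_$values
  if (max(abs(v - t(v))) > 0) {
    stop("validation error: PLI matrix must be exactly symmetric")
  }
  n <- nrow(v)
  ia <- integer(0); ib <- integer(0)
  for (a in seq_len(n - 1L)) {          # row-major: (1,2),(1,3),...,(n-1,n)
    ia <- c(ia, rep.int(a, n - a))
    ib <- c(ib, (a + 1L):n)
  }
  data.frame(estimator = "PLI", ch_a = matrix_$montage[ia],
             ch_b = matrix_$montage[ib], value = v[cbind(ia, ib)],
             stringsAsFactors = FALSE)
}

#' Rebuild a symmetric matrix from upper-triangle features
#'
#' @param values Feature values in [vectorize_upper()] order.
#' @param montage Channel labels.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pli_from_features <- function(values, montage) {
  n <- length(montage)
  stopifnot(length(values) == n * (n - 1) / 2)
  m <- matrix(0, n, n, dimnames = list(montage, montage))
  k <- 0L
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      k <- k + 1L
      m[a, b] <- m[b, a] <- values[k]
    }
  }
  m
}
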
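#' Trial-ensemble lag covariances
#'
#' Per trial, the windowed data are mean-centered per channel and the lag-`m`
#' covariance `R(m) = <X(n) X^T(n+m)>` is averaged over the valid sample
#' pairs (unbiased: divide by the number of contributing pairs). The returned
#' set is the mean over trials.
#'
#' @param epochs An `epoch_set`.
#' @param window Half-open time window `(t0, t1)` in seconds.
#' @param max_lag Largest lag `m` to compute.
#' @return An object of class `lag_cov`: array `R` (`N x N x (max_lag + 1)`,
#'   slice `m + 1` holding `R(m)`), `max_lag`, `n_trials`, `n_window_samples`,
#'   `fs`, `montage`, `window`.
#' @export
ensemble_covariance <- function(epochs, window = c(0.1, 0.6), max_lag) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- window_indices(epochs, window)
  nw <- length(idx)
  if (nw <= max_lag + 1L) {
    stop("validation error: window must contain more than max_lag + 1 samples")
  }
  d <- dim(epochs$data)
  n <- d[1]; n_tr <- d[3]
  r <- array(0, dim = c(n, n, max_lag + 1L))
  for (tr in seq_len(n_tr)) {
    xc <- matrix(epochs$data[, idx, tr], n, nw)
    xc <- xc - rowMeans(xc)
    for (m in 0:max_lag) {
      r[, , m + 1L] <- r[, , m + 1L] +
        tcrossprod(xc[, seq_len(nw - m), drop = FALSE],
                   xc[, (1L + m):nw, drop = FALSE]) / (nw - m)
    }
  }
  lag_cov(r / n_tr, fs = epochs$fs, montage = epochs$montage,
          n_trials = n_tr, n_window_samples = nw, window = window)
}

#' Construct a lag covariance set
#'
#' Container for `R(m) = <X(n) X^T(n+m)>`, `m = 0..max_lag`; mostly produced
#' by [ensemble_covariance()], but exposed so analytically derived covariances
#' can be fed to [fit_mvar()].
#'
#' @param r Array `N x N x (max_lag + 1)`; slice `m + 1` holds `R(m)`.
#' @param fs Sampling rate in Hz.
#' @param montage Optional channel labels.
#' @param n_trials,n_window_samples Provenance of the estimate (defaults 1).
#' @param window Optional originating time window.
#' @return An object of class `lag_cov`.
#' @export
lag_cov <- function(r, fs, montage = NULL, n_trials = 1L,
                    n_window_samples = 1L, window = NULL) {
  d <- dim(r)
  if (length(d) != 3L || d[1] != d[2]) {
    stop("shape error: `r` must be N x N x (max_lag + 1)")
  }
  if (max(abs(r[, , 1] - t(r[, , 1]))) > 1e-6 * max(1, max(abs(r[, , 1])))) {
    stop("validation error: R(0) must be symmetric")
  }
  if (is.null(montage)) montage <- paste0("ch", seq_len(d[1]))
  structure(list(R = r, max_lag = d[3] - 1L, n_trials = n_trials,
                 n_window_samples = n_window_samples, fs = fs,
                 montage = as.character(montage), window = window),
            class = "lag_cov")
}

#' Fit an MVAR model from lag covariances
#'
#' Solves the multivariate Yule-Walker system `C(k) = sum_r A_r C(k - r)`,
#' `k = 1..p`, where `C(m) = R(m)^T` is the conventional autocovariance
#' (`C(-m) = C(m)^T`), as one symmetric block-Toeplitz solve. The innovation
#' covariance is `C(0) - sum_r A_r C(r)^T`, symmetrized.
#'
#' @param covs A `lag_cov` with `max_lag >= p`.
#' @param p Model order.
#' @return An `mvar_model`; a warning (not an error) is raised if the
#'   estimated model is marginally non-stationary.
#' @export
fit_mvar <- function(covs, p) {
  stopifnot(inherits(covs, "lag_cov"))
  if (p < 1L || p > covs$max_lag) {
    stop("validation error: need 1 <= p <= max_lag")
  }
  n <- dim(covs$R)[1]
  cc <- function(m) {                    # C(m), any integer m
    if (m >= 0) t(covs$R[, , m + 1L]) else covs$R[, , -m + 1L]
  }
  g <- matrix(0, n * p, n * p)
  b <- matrix(0, n, n * p)
  for (k in seq_len(p)) {
    b[, (k - 1) * n + seq_len(n)] <- cc(k)
    for (r in seq_len(p)) {
      g[(r - 1) * n + seq_len(n), (k - 1) * n + seq_len(n)] <- cc(k - r)
    }
  }
  kap <- kappa(g, exact = FALSE)
  if (!is.finite(kap) || kap > 1e12) {
    stop(sprintf(
      "numerical error: block-Toeplitz system ill-conditioned (condition estimate %.3g)",
      kap))
  }
  a_flat <- t(solve(g, t(b)))            # N x Np
  coeffs <- array(0, dim = c(n, n, p))
  sigma <- cc(0)
  for (r in seq_len(p)) {
    ar <- a_flat[, (r - 1) * n + seq_len(n), drop = FALSE]
    coeffs[, , r] <- ar
    sigma <- sigma - ar %*% t(cc(r))
  }
  sigma <- (sigma + t(sigma)) / 2
  model <- mvar_model(coeffs, sigma, fs = covs$fs, montage = covs$montage)
  if (!is_stable(model)) {
    warning("fitted MVAR model is marginally non-stationary (companion radius >= 1)")
  }
  model
}

#' Select the MVAR order by BIC
#'
#' For each candidate order `p` the model is fitted on the windowed ensemble
#' covariances and scored with
#' `BIC(p) = ln det(Sigma_W) + p N^2 ln(n_eff) / n_eff`, where `n_eff` is the
#' total number of windowed samples across trials. Ties go to the smallest
#' order.
#'
#' @param epochs An `epoch_set`.
#' @param window Half-open time window `(t0, t1)` in seconds.
#' @param p_range Integer vector of candidate orders.
#' @return The BIC-optimal order (integer).
#' @export
select_order_bic <- function(epochs, window = c(0.1, 0.6), p_range = 1:12) {
  if (length(p_range) == 0L) stop("validation error: empty p_range")
  p_range <- sort(unique(as.integer(p_range)))
  covs <- ensemble_covariance(epochs, window, max_lag = max(p_range))
  n <- dim(covs$R)[1]
  n_eff <- covs$n_window_samples * covs$n_trials
  bic <- vapply(p_range, function(p) {
    model <- suppressWarnings(fit_mvar(covs, p))
    dt <- det(model$noise_cov)
    if (!is.finite(dt) || dt <= 0) return(Inf)
    log(dt) + p * n^2 * log(n_eff) / n_eff
  }, numeric(1))
  p_range[which.min(bic)]
}

#' MVAR spectral transfer structure at one frequency
#'
#' `A(f) = I - sum_{r=1..p} A_r exp(-2 pi i f r / fs)`: the identity minus the
#' Fourier transform of the lag coefficients.
#'
#' @param model An `mvar_model`.
#' @param f Frequency in Hz, `0 <= f < fs/2`.
#' @return Complex `N x N` matrix.
#' @export
transfer_matrix <- function(model, f) {
  stopifnot(inherits(model, "mvar_model"))
  if (f < 0 || f >= model$fs / 2) {
    stop("validation error: f must lie in [0, fs/2)")
  }
  n <- model$n_channels
  af <- diag(n) + 0i
  for (r in seq_len(model$order)) {
    af <- af - model$coeffs[, , r] * exp(-2i * pi * f * r / model$fs)
  }
  af
}

#' Partial directed coherence at one frequency
#'
#' `PDC(i, j, f) = |A_ij(f)| / sqrt(sum_k |A_kj(f)|^2)`: the influence of
#' channel `j` on channel `i`, column-normalized so each column's squared
#' entries sum to 1.
#'
#' @inheritParams transfer_matrix
#' @return Real `N x N` matrix in `[0, 1]`; entry `(i, j)` is the `j -> i`
#'   influence.
#' @export
pdc <- function(model, f) {
  af <- transfer_matrix(model, f)
  denom <- sqrt(colSums(Mod(af)^2))
  if (any(denom == 0)) {
    stop("numerical error: zero column norm in transfer structure")
  }
  sweep(Mod(af), 2, denom, "/")
}

#' Band-averaged PDC connectivity matrix
#'
#' Arithmetic mean of [pdc()] over the grid `f_lo, f_lo + step, ..., f_hi`.
#'
#' @param model An `mvar_model`.
#' @param band Frequency band `(f_lo, f_hi)` in Hz, below Nyquist.
#' @param freq_step Grid step in Hz (default 0.25, i.e. 13 points over 4-7 Hz).
#' @return An object of class `pdc_matrix`: `values` (`N x N`, entry `(i, j)`
#'   the `j -> i` influence), `band`, `montage`, `order`,
#'   `thresholded = FALSE`.
#' @export
band_average_pdc <- function(model, band = c(4, 7), freq_step = 0.25) {
  stopifnot(inherits(model, "mvar_model"))
  if (band[2] >= model$fs / 2) {
    stop("validation error: band must lie below the Nyquist frequency")
  }
  if (band[1] > band[2]) stop("validation error: empty frequency grid")
  grid <- seq(band[1], band[2], by = freq_step)
  values <- 0
  for (f in grid) values <- values + pdc(model, f)
  values <- values / length(grid)
  dimnames(values) <- list(model$montage, model$montage)
  structure(list(values = values, band = band, montage = model$montage,
                 order = model$order, thresholded = FALSE),
            class = "pdc_matrix")
}

#' @export
print.pdc_matrix <- function(x, ...) {
  off <- x$values[row(x$values) != col(x$values)]
  cat(sprintf("<pdc_matrix> %d channels, band %g-%g Hz, order %d%s\n",
              nrow(x$values), x$band[1], x$band[2], x$order,
              if (x$thresholded) ", surrogate-thresholded" else ""))
  cat(sprintf("  off-diagonal PDC range %.3f .. %.3f\n", min(off), max(off)))
  invisible(x)
}

# Phase-randomized surrogate of one signal: amplitude spectrum preserved,
# Fourier phases independent uniform, Hermitian symmetry kept so the inverse
# transform is real.
phase_randomize <- function(x) {
  n <- length(x)
  xf <- stats::fft(x)
  half <- if (n %% 2L == 0L) n / 2L else (n + 1L) / 2L
  k <- seq.int(2L, half)                 # DC untouched; even n: keep Nyquist
  if (n %% 2L == 0L) k <- k[-length(k)]
  if (length(k)) {
    ph <- stats::runif(length(k), -pi, pi)
    xf[k] <- Mod(xf[k]) * exp(1i * ph)
    xf[n + 2L - k] <- Conj(xf[k])
  }
  Re(stats::fft(xf, inverse = TRUE)) / n
}

#' Surrogate-data significance thresholds for band PDC
#'
#' Builds per-edge null distributions by repeatedly (i) randomizing the
#' Fourier phases of every channel of every trial independently (amplitude
#' spectra preserved, cross-channel phase relations destroyed), (ii) refitting
#' the MVAR model on the surrogate ensemble, and (iii) recomputing the
#' band-averaged PDC. The per-edge threshold is the `(1 - alpha)` empirical
#' quantile.
#'
#' @param epochs An `epoch_set`.
#' @param window Half-open covariance window `(t0, t1)` s.
#' @param band Frequency band `(f_lo, f_hi)` Hz.
#' @param p MVAR order used for every refit.
#' @param n_surrogates Number of surrogates (>= 100).
#' @param alpha Edge-wise significance level.
#' @param freq_step PDC grid step in Hz.
#' @param seed Optional integer seed.
#' @return An object of class `surrogate_null`: `thresholds` (`N x N`),
#'   `draws` (`N x N x n_surrogates`), `n_surrogates`, `alpha`, `band`,
#'   `montage`.
#' @export
surrogate_threshold <- function(epochs, window = c(0.1, 0.6), band = c(4, 7),
                                p, n_surrogates = 5000L, alpha = 0.05,
                                freq_step = 0.25, seed = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (n_surrogates < 100L) {
    stop("validation error: n_surrogates must be >= 100")
  }
  if (!is.null(seed)) set.seed(seed)
  d <- dim(epochs$data)
  n <- d[1]
  draws <- array(0, dim = c(n, n, n_surrogates))
  surr <- epochs
  for (s in seq_len(n_surrogates)) {
    for (tr in seq_len(d[3])) {
      for (ch in seq_len(n)) {
        surr$data[ch, , tr] <- phase_randomize(epochs$data[ch, , tr])
      }
    }
    covs <- ensemble_covariance(surr, window, max_lag = p)
    model <- suppressWarnings(fit_mvar(covs, p))
    draws[, , s] <- band_average_pdc(model, band, freq_step)$values
  }
  thresholds <- apply(draws, c(1, 2), stats::quantile, probs = 1 - alpha,
                      names = FALSE)
  structure(list(thresholds = thresholds, draws = draws,
                 n_surrogates = n_surrogates, alpha = alpha, band = band,
                 montage = epochs$montage),
            class = "surrogate_null")
}

#' Zero out PDC entries below their surrogate threshold
#'
#' @param pdcm A `pdc_matrix`.
#' @param null A `surrogate_null` for the same montage.
#' @return The `pdc_matrix` with entries at or below their edge threshold set
#'   to 0 and `thresholded = TRUE`.
#' @export
apply_threshold <- function(pdcm, null) {
  stopifnot(inherits(pdcm, "pdc_matrix"), inherits(null, "surrogate_null"))
  if (!identical(pdcm$montage, null$montage)) {
    stop("validation error: montage mismatch between PDC matrix and null")
  }
  pdcm$values[pdcm$values <= null$thresholds] <- 0
  pdcm$thresholded <- TRUE
  pdcm
}

#' Vectorize the off-diagonal of a PDC matrix
#'
#' Row-major over all ordered off-diagonal pairs, so a 20-channel matrix
#' yields 380 features. Entry `(i, j)` of the matrix is the `j -> i`
#' influence, so the descriptor records `source = montage[j]`,
#' `target = montage[i]`. Invertible via [pdc_from_features()].
#'
#' @param matrix_ A `pdc_matrix`.
#' @return Data frame with columns `estimator` (`"PDC"`), `source`, `target`,
#'   `value`.
#' @export
vectorize_directed <- function(matrix_) {
  stopifnot(inherits(matrix_, "pdc_matrix"))
  v <- matrix_$values
  n <- nrow(v)
  ii <- rep(seq_len(n), each = n)
  jj <- rep(seq_len(n), times = n)
  keep <- ii != jj                       # row-major: (1,2),(1,3),...,(n,n-1)
  data.frame(estimator = "PDC", source = matrix_$montage[jj[keep]],
             target = matrix_$montage[ii[keep]],
             value = v[cbind(ii[keep], jj[keep])], stringsAsFactors = FALSE)
}

#' Rebuild a directed matrix from off-diagonal features
#'
#' @param values Feature values in [vectorize_directed()] order.
#' @param montage Channel labels.
#' @return Numeric matrix with zero diagonal; entry `(i, j)` is `j -> i`.
#' @export
pdc_from_features <- function(values, montage) {
  n <- length(montage)
  stopifnot(length(values) == n * (n - 1))
  m <- matrix(0, n, n, dimnames = list(montage, montage))
  k <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      k <- k + 1L
      m[i, j] <- values[k]
    }
  }
  m
}
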
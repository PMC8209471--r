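#' Construct an MVAR model
#'
#' A multivariate autoregressive model of order `p` for `N` channels:
#' `X(n) = sum_{r=1..p} A_r X(n - r) + W(n)` with innovation covariance
#' `Sigma_W`. Used both as simulation ground truth and as the container for
#' fitted models.
#'
#' @param coeffs Numeric array `N x N x p` of lag coefficient matrices `A_r`
#'   (lag index last), or an `N x N` matrix for `p = 1`.
#' @param noise_cov `N x N` symmetric positive-definite innovation covariance.
#' @param fs Sampling rate in Hz.
#' @param montage Optional channel labels (length `N`).
#' @return An object of class `mvar_model`.
#' @export
mvar_model <- function(coeffs, noise_cov, fs, montage = NULL) {
  if (is.matrix(coeffs)) coeffs <- array(coeffs, dim = c(dim(coeffs), 1L))
  d <- dim(coeffs)
  if (length(d) != 3L || d[1] != d[2]) {
    stop("shape error: `coeffs` must be an N x N x p array of square matrices")
  }
  n <- d[1]
  noise_cov <- as.matrix(noise_cov)
  if (!all(dim(noise_cov) == c(n, n))) {
    stop("shape error: `noise_cov` must be N x N")
  }
  if (max(abs(noise_cov - t(noise_cov))) > 1e-8) {
    stop("validation error: `noise_cov` must be symmetric (tolerance 1e-8)")
  }
  if (is.null(montage)) montage <- paste0("ch", seq_len(n))
  structure(
    list(coeffs = coeffs, noise_cov = (noise_cov + t(noise_cov)) / 2,
         order = d[3], n_channels = n, fs = as.numeric(fs),
         montage = as.character(montage)),
    class = "mvar_model"
  )
}

companion_matrix <- function(coeffs) {
  d <- dim(coeffs)
  n <- d[1]; p <- d[3]
  top <- matrix(0, n, n * p)
  for (r in seq_len(p)) top[, (r - 1) * n + seq_len(n)] <- coeffs[, , r]
  if (p == 1L) return(top)
  rbind(top, cbind(diag(n * (p - 1)), matrix(0, n * (p - 1), n)))
}

#' Test MVAR stationarity
#'
#' A model is stationary (stable) iff the spectral radius of its companion
#' matrix is below 1.
#'
#' @param model An `mvar_model`.
#' @return `TRUE` iff the companion spectral radius is `< 1`.
#' @export
is_stable <- function(model) {
  stopifnot(inherits(model, "mvar_model"))
  spectral_radius(model$coeffs) < 1
}

spectral_radius <- function(coeffs) {
  max(Mod(eigen(companion_matrix(coeffs), only.values = TRUE)$values))
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> %d channels, order %d, fs %g Hz\n",
              x$n_channels, x$order, x$fs))
  cat(sprintf("  companion spectral radius %.4f (%s)\n",
              spectral_radius(x$coeffs),
              if (is_stable(x)) "stable" else "UNSTABLE"))
  invisible(x)
}

#' @export
coef.mvar_model <- function(object, ...) object$coeffs

#' Simulate trials from an MVAR model
#'
#' @param object A stable `mvar_model`.
#' @param nsim Number of trials.
#' @param seed Optional integer seed (identical seed, identical output).
#' @param n_samples Samples per trial (must exceed `10 * p`).
#' @param onset 1-based onset sample index for the returned `epoch_set`.
#' @param subject_id,group Metadata for the returned `epoch_set`.
#' @param ... Unused.
#' @return An `epoch_set` of independent trial realizations; a burn-in of
#'   `100 * p` samples is generated and discarded per trial.
#' @export
simulate.mvar_model <- function(object, nsim = 1, seed = NULL,
                                n_samples = 768, onset = 1L,
                                subject_id = "sim", group = NA_character_, ...) {
  simulate_mvar_trials(object, n_trials = nsim, n_samples = n_samples,
                       onset = onset, seed = seed, subject_id = subject_id,
                       group = group)
}
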
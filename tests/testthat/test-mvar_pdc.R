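# Analytic lag covariances of a stable VAR(1): C(0) solves the discrete
# Lyapunov equation, C(m) = A C(m-1); stored as R(m) = C(m)^T.
analytic_ar1_cov <- function(a, sigma, max_lag, fs = 256) {
  n <- nrow(a)
  c0 <- matrix(solve(diag(n^2) - kronecker(a, a), as.vector(sigma)), n, n)
  r <- array(0, c(n, n, max_lag + 1))
  cm <- c0
  r[, , 1] <- c0
  for (m in seq_len(max_lag)) {
    cm <- a %*% cm
    r[, , m + 1] <- t(cm)
  }
  lag_cov(r, fs = fs)
}

test_that("ensemble covariances match their closed forms", {
  # T = 1: the ensemble average is that trial's covariance sequence
  ep1 <- white_noise_epochs(2, 200, 1, seed = 51)
  cv1 <- ensemble_covariance(ep1, c(0, 200 / 256), max_lag = 2)
  x <- ep1$data[, , 1]
  xc <- x - rowMeans(x)
  r1 <- tcrossprod(xc[, 1:199], xc[, 2:200]) / 199
  expect_equal(cv1$R[, , 2], unname(r1), tolerance = 1e-12)

  # white noise: R(0) ~ I, lagged covariances ~ 0
  ep <- white_noise_epochs(3, 1000, 100, seed = 52)
  cv <- ensemble_covariance(ep, c(0, 1000 / 256), max_lag = 3)
  expect_lt(max(abs(cv$R[, , 1] - diag(3))), 0.05)
  expect_lt(max(abs(cv$R[, , 2:4])), 0.05)

  expect_error(ensemble_covariance(ep1, c(0, 0.01), max_lag = 5), "max_lag")
})

test_that("Yule-Walker fit recovers analytically generated AR coefficients", {
  a <- matrix(c(0.5, 0, 0.3, 0.4), 2, 2, byrow = TRUE)
  fit <- fit_mvar(analytic_ar1_cov(a, diag(2), max_lag = 1), p = 1)
  expect_lt(max(abs(coef(fit)[, , 1] - a)), 1e-6)
  expect_lt(max(abs(fit$noise_cov - diag(2))), 1e-6)

  # white-noise covariances give near-zero coefficients
  ep <- white_noise_epochs(2, 2000, 50, seed = 53)
  cv <- ensemble_covariance(ep, c(0, 2000 / 256), max_lag = 2)
  fit0 <- fit_mvar(cv, 2)
  expect_lt(max(abs(coef(fit0))), 3 / sqrt(2000 * 50 / 2))

  # duplicated channels make the block-Toeplitz system singular
  dup <- epoch_set(ep$data[c(1, 1), , ], 256, 1, montage = c("a", "b"))
  cvd <- ensemble_covariance(dup, c(0, 2000 / 256), max_lag = 1)
  expect_error(fit_mvar(cvd, 1), "condition")
})

test_that("simulation-estimation round trip recovers a 3-channel order-2 model", {
  a <- array(0, c(3, 3, 2))
  diag(a[, , 1]) <- 0.4
  a[2, 1, 1] <- 0.35; a[1, 3, 1] <- 0.2; a[3, 2, 2] <- -0.3
  truth <- mvar_model(a, diag(3), fs = 256)
  ep <- simulate_mvar_trials(truth, n_trials = 100, n_samples = 500,
                             seed = 54)
  fit <- fit_mvar(ensemble_covariance(ep, c(0, 500 / 256), max_lag = 2), 2)
  expect_lt(max(abs(coef(fit) - a)), 0.05)
})

test_that("BIC order selection honors its contract", {
  ep <- white_noise_epochs(2, 300, 20, seed = 55)
  expect_identical(select_order_bic(ep, c(0, 300 / 256), p_range = 5), 5L)
  expect_error(select_order_bic(ep, c(0, 300 / 256), integer(0)), "p_range")

  # white noise: the penalty drives BIC to the smallest candidate
  picks <- vapply(1:20, function(s) {
    eps <- white_noise_epochs(2, 250, 15, seed = 100 + s)
    select_order_bic(eps, c(0, 250 / 256), p_range = 1:4)
  }, integer(1))
  expect_gte(mean(picks == 1L), 0.9)
})

test_that("transfer structure and PDC match hand-evaluated cases", {
  zero <- mvar_model(array(0, c(3, 3, 2)), diag(3), fs = 256)
  expect_equal(transfer_matrix(zero, 17), diag(3) + 0i)
  expect_equal(pdc(zero, 17), diag(3))

  m <- mvar_model(matrix(c(0.3, -0.2, 0.1, 0.4), 2, 2, byrow = TRUE),
                  diag(2), fs = 256)
  expect_equal(transfer_matrix(m, 0),
               (diag(2) - matrix(c(0.3, -0.2, 0.1, 0.4), 2, 2,
                                 byrow = TRUE)) + 0i)

  uni <- mvar_model(matrix(0.5), matrix(1), fs = 256)
  expect_equal(transfer_matrix(uni, 64)[1, 1], 1 + 0.5i)

  # bivariate hand example at f = 0, against independent substitution
  biv <- mvar_model(matrix(c(0.5, 0, 0.3, 0.5), 2, 2, byrow = TRUE),
                    diag(2), fs = 256)
  p0 <- pdc(biv, 0)
  af <- diag(2) - matrix(c(0.5, 0, 0.3, 0.5), 2, 2, byrow = TRUE) # exp(0) = 1
  expect_lt(abs(p0[2, 1] - abs(af[2, 1]) / sqrt(sum(abs(af[, 1])^2))), 1e-12)
  expect_lt(abs(p0[2, 1] - 0.3 / sqrt(0.34)), 1e-12)
  expect_identical(p0[1, 2], 0)

  expect_error(transfer_matrix(uni, 200), "fs/2")
})

test_that("PDC columns are unit-normalized for fitted models at any frequency", {
  set.seed(56)
  ep <- simulate_mvar_trials(default_base_model(montage = small_study_montage()),
                             n_trials = 30, n_samples = 400, seed = 57)
  fit <- suppressWarnings(
    fit_mvar(ensemble_covariance(ep, c(0, 400 / 256), max_lag = 4), 4))
  for (f in c(0, 4, 7, 12.5, 40, 100)) {
    expect_lt(max(abs(colSums(pdc(fit, f)^2) - 1)), 1e-10)
  }
})

test_that("band averaging respects its grid and recovers directionality", {
  zero <- mvar_model(array(0, c(2, 2, 1)), diag(2), fs = 256)
  expect_equal(band_average_pdc(zero, c(4, 7))$values, diag(2),
               ignore_attr = TRUE)
  m <- mvar_model(matrix(c(0.4, 0, 0.2, 0.3), 2, 2, byrow = TRUE), diag(2),
                  fs = 256)
  single <- band_average_pdc(m, c(5, 5))
  expect_equal(single$values, pdc(m, 5), ignore_attr = TRUE)

  # planted 1 -> 2 coupling dominates the reverse direction after estimation
  a <- array(0, c(2, 2, 1)); diag(a[, , 1]) <- 0.5; a[2, 1, 1] <- 0.3
  truth <- mvar_model(a, diag(2), fs = 256, montage = c("x", "y"))
  wins <- vapply(1:20, function(s) {
    ep <- simulate_mvar_trials(truth, 48, 256, seed = 200 + s)
    fit <- suppressWarnings(
      fit_mvar(ensemble_covariance(ep, c(0, 1), max_lag = 1), 1))
    pm <- band_average_pdc(fit, c(4, 7))$values
    pm["y", "x"] > pm["x", "y"]
  }, logical(1))
  expect_gte(mean(wins), 0.95)

  expect_error(band_average_pdc(m, c(200, 300)), "Nyquist")
})

test_that("phase-randomized surrogates preserve spectra and calibrate thresholds", {
  set.seed(58)
  x <- rnorm(101)                               # odd length
  y <- eegfuse:::phase_randomize(x)
  expect_lt(max(abs(Mod(stats::fft(x)) - Mod(stats::fft(y)))), 1e-8)
  x2 <- rnorm(100)                              # even length, Nyquist bin
  y2 <- eegfuse:::phase_randomize(x2)
  expect_lt(max(abs(Mod(stats::fft(x2)) - Mod(stats::fft(y2)))), 1e-8)
  expect_lt(max(abs(Im(stats::fft(y2))[c(1, 51)])), 1e-8)

  # planted coupling survives its surrogate threshold; nulls mostly do not
  a <- array(0, c(3, 3, 1)); diag(a[, , 1]) <- 0.5; a[2, 1, 1] <- 0.4
  truth <- mvar_model(a, diag(3), fs = 256)
  ep <- simulate_mvar_trials(truth, 30, 256, seed = 59)
  null <- surrogate_threshold(ep, c(0, 1), c(4, 7), p = 1,
                              n_surrogates = 150, seed = 60)
  pm <- band_average_pdc(suppressWarnings(
    fit_mvar(ensemble_covariance(ep, c(0, 1), max_lag = 1), 1)), c(4, 7))
  expect_gt(pm$values[2, 1], null$thresholds[2, 1])
  thr <- apply_threshold(pm, null)
  expect_true(thr$thresholded)
  expect_identical(thr$values[pm$values <= null$thresholds],
                   rep(0, sum(pm$values <= null$thresholds)))

  expect_error(surrogate_threshold(ep, c(0, 1), c(4, 7), p = 1,
                                   n_surrogates = 50), "100")
})

test_that("surrogate null-edge exceedance rate is near alpha on white noise", {
  exceed <- integer(0)
  for (s in 1:10) {
    ep <- white_noise_epochs(3, 128, 20, seed = 300 + s)
    null <- surrogate_threshold(ep, c(0, 0.5), c(4, 7), p = 2,
                                n_surrogates = 120, alpha = 0.05,
                                seed = 400 + s)
    pm <- band_average_pdc(suppressWarnings(
      fit_mvar(ensemble_covariance(ep, c(0, 0.5), max_lag = 2), 2)), c(4, 7))
    off <- row(pm$values) != col(pm$values)
    exceed <- c(exceed, as.integer(pm$values[off] > null$thresholds[off]))
  }
  # 60 null edges at alpha 0.05: binomial 95% acceptance band
  expect_gte(sum(exceed), qbinom(0.025, length(exceed), 0.05))
  expect_lte(sum(exceed), qbinom(0.975, length(exceed), 0.05))
})

test_that("directed vectorization is ordered, sized, and invertible", {
  set.seed(61)
  mont20 <- default_montage()
  m20 <- fake_pdc(matrix(runif(400), 20, 20), mont20)
  f <- vectorize_directed(m20)
  expect_identical(nrow(f), 380L)

  m3 <- fake_pdc(matrix(1:9 / 10, 3, 3), c("a", "b", "c"))
  f3 <- vectorize_directed(m3)
  expect_identical(nrow(f3), 6L)
  # row-major: (i=1,j=2) means influence b -> a first
  expect_identical(f3$source[1:2], c("b", "c"))
  expect_identical(f3$target[1:2], c("a", "a"))
  expect_identical(f3$value[1], m3$values[1, 2])

  expect_identical(pdc_from_features(f$value, mont20), m20$values)

  # apply_threshold edge cases: all-zero thresholds keep, all-one zero out
  null0 <- structure(list(thresholds = matrix(0, 3, 3), alpha = 0.05,
                          montage = c("a", "b", "c")),
                     class = "surrogate_null")
  expect_identical(apply_threshold(m3, null0)$values[1, 2], m3$values[1, 2])
  null1 <- null0; null1$thresholds <- matrix(1, 3, 3)
  expect_true(all(apply_threshold(m3, null1)$values == 0))
  null_bad <- null0; null_bad$montage <- c("x", "y", "z")
  expect_error(apply_threshold(m3, null_bad), "montage")
})
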
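test_that("stationarity test follows the companion spectral radius", {
  expect_true(is_stable(mvar_model(array(0, c(3, 3, 2)), diag(3), fs = 256)))
  expect_false(is_stable(mvar_model(matrix(1.1), matrix(1), fs = 256)))
  expect_true(is_stable(mvar_model(matrix(0.5), matrix(1), fs = 256)))
  expect_error(mvar_model(array(0, c(2, 3, 1)), diag(2), fs = 256), "square")
})

test_that("simulated ensembles match closed-form white-noise and AR(1) moments", {
  # zero coefficients, identity innovation: unit variance per channel
  wn <- mvar_model(array(0, c(2, 2, 1)), diag(2), fs = 256)
  ep <- simulate_mvar_trials(wn, n_trials = 40, n_samples = 2500, seed = 21)
  v <- apply(ep$data, 1, function(x) stats::var(as.vector(x)))
  se <- sqrt(2 / (40 * 2500))
  expect_true(all(abs(v - 1) < 3 * se + 0.003))

  # AR(1) with a = 0.5: lag-1 autocorrelation 0.5
  ar <- mvar_model(matrix(0.5), matrix(1), fs = 256)
  ep1 <- simulate_mvar_trials(ar, n_trials = 40, n_samples = 2500, seed = 22)
  r1 <- mean(apply(ep1$data[1, , ], 2, function(x) {
    stats::cor(x[-1], x[-length(x)])
  }))
  expect_lt(abs(r1 - 0.5), 3 * sqrt(1 / (40 * 2500)) + 0.005)

  # unstable model is refused; too-short epochs are refused
  expect_error(simulate_mvar_trials(mvar_model(matrix(1.1), matrix(1), 256),
                                    5, 100), "stationary")
  expect_error(simulate_mvar_trials(ar, 5, 8), "n_samples")
})

test_that("every generator is bit-identical under an identical seed", {
  ar <- mvar_model(matrix(c(0.4, 0.2, 0, 0.3), 2), diag(2), fs = 256)
  expect_identical(simulate_mvar_trials(ar, 6, 64, seed = 5),
                   simulate_mvar_trials(ar, 6, 64, seed = 5))
  expect_identical(
    simulate_lagged_oscillators(6, pi / 4, 0.2, 4, 128, 256, seed = 6),
    simulate_lagged_oscillators(6, pi / 4, 0.2, 4, 128, 256, seed = 6))
  cfg <- small_study_config(seed = 7, n_per_group = 2)
  s1 <- simulate_two_group_study(cfg)
  s2 <- simulate_two_group_study(cfg)
  expect_identical(lapply(s1$subjects, `[[`, "data"),
                   lapply(s2$subjects, `[[`, "data"))
})

test_that("oscillator pairs respect the lag/jitter contract", {
  expect_error(simulate_lagged_oscillators(200, 0, 0, 4, 128, 256), "fs/2")
  expect_error(simulate_lagged_oscillators(6, 0, -1, 4, 128, 256), ">= 0")
  osc <- simulate_lagged_oscillators(6, pi / 4, 0, 8, 256, 256, seed = 8,
                                     noise_sd = 0)
  # with zero jitter and noise the analytic phase difference is the lag
  a <- osc$data[1, , 1]; b <- osc$data[2, , 1]
  ph <- function(x) Arg(stats::fft(x)[7])   # bin of 6 Hz over 1 s
  dphi <- (ph(b) - ph(a)) %% (2 * pi)
  expect_lt(abs(dphi - pi / 4), 0.05)
})

test_that("instantaneous mixing transforms samples and nothing else", {
  ep <- white_noise_epochs(2, 64, 3, seed = 9)
  expect_identical(apply_instantaneous_mixing(ep, diag(2))$data, ep$data)
  mx <- matrix(c(1, 0.5, 0.5, 1), 2)
  mixed <- apply_instantaneous_mixing(ep, mx)
  expect_equal(unname(mixed$data[, 10, 2]),
               as.vector(mx %*% ep$data[, 10, 2]))
  expect_identical(mixed$montage, ep$montage)
  expect_error(apply_instantaneous_mixing(ep, matrix(1, 3, 2)), "shape")
})

test_that("study generation enforces its config contract and stationarity", {
  expect_error(study_config(n_subjects_per_group = 0), "n_subjects_per_group")
  expect_error(study_config(group_effect_edges = list(
    list(src = "XX", dst = "Fz", delta = 0.1))), "unknown channel")

  # subject perturbation retries down to a stable model even from large jitter
  set.seed(10)
  base <- default_base_model(montage = small_study_montage())
  cand <- eegfuse:::perturb_until_stable(base$coeffs, jitter_sd = 2)
  expect_lt(eegfuse:::spectral_radius(cand), 1)

  st <- simulate_two_group_study(small_study_config(seed = 11, n_per_group = 2))
  expect_length(st$subjects, 4L)
  expect_identical(st$manifest$group, rep(c("SZ", "HC"), each = 2))
  # ground truth travels in the manifest bundle, not inside the epoch data
  expect_named(st$truth, c("directed_edges", "coupled_pairs", "seed"))
})

test_that("a study written to disk reloads identically through the manifest", {
  dir <- withr::local_tempdir()
  st <- simulate_two_group_study(small_study_config(seed = 12, n_per_group = 2),
                                 dir = dir)
  m <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_identical(nrow(m), 4L)
  back <- read_epochset(m$path[1])
  expect_identical(back$data, st$subjects[[m$subject_id[1]]]$data)
  expect_true(file.exists(file.path(dir, "ground_truth.yaml")))
})
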
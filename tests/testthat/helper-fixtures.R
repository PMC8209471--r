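# Shared fixtures: everything is generated in code at test time.

white_noise_epochs <- function(n_ch = 3, n_samples = 256, n_trials = 10,
                               fs = 256, onset = 1L, seed = 1,
                               montage = paste0("ch", seq_len(n_ch))) {
  set.seed(seed)
  epoch_set(array(rnorm(n_ch * n_samples * n_trials),
                  c(n_ch, n_samples, n_trials)),
            fs = fs, onset = onset, montage = montage)
}

# A tf_map with given power matrix (for cluster-test checks).
fake_tf_map <- function(power, fs = 50, t0 = -0.2) {
  nf <- nrow(power); nt <- ncol(power)
  structure(list(power_db = power, freqs = seq(4, 20, length.out = nf),
                 times = t0 + (seq_len(nt) - 1) / fs,
                 baseline = c(-0.2, -0.1), channels = "A"),
            class = "tf_map")
}

# Minimal connectivity-matrix stand-ins for feature-table tests.
fake_pli <- function(values, montage) {
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(montage, montage)
  structure(list(values = values, band = c(4, 7), window = c(0.1, 0.6),
                 montage = montage), class = "pli_matrix")
}

fake_pdc <- function(values, montage) {
  diag(values) <- 0
  dimnames(values) <- list(montage, montage)
  structure(list(values = values, band = c(4, 7), montage = montage,
                 order = 2L, thresholded = FALSE), class = "pdc_matrix")
}

# A complex tf_coef with prescribed phases/amplitudes (freq x sample x trial).
fake_tf_coef <- function(values, fs = 256, onset = 1L, channel = "A") {
  bank <- structure(list(freqs = seq_len(dim(values)[1]),
                         cycles = rep(7, dim(values)[1]), fs = fs),
                    class = "wavelet_bank")
  structure(list(values = values, bank = bank, channel = channel,
                 onset = onset, fs = fs), class = "tf_coef")
}

# The scaled-down two-group study used for recovery/ordering experiments:
# 10 channels, 20 + 20 subjects, 48 trials of 1.5 s, moderate planted effects
# (directed deltas 0.08 on Cz->O2 and T7->P7 in SZ; one F4-Oz theta pair
# phase-coupled in HC only).
small_study_montage <- function() {
  c("Fz", "F3", "F4", "T7", "Cz", "C4", "Pz", "P7", "Oz", "O2")
}

small_study_config <- function(seed, n_per_group = 20,
                               delta = 0.08, jitter_sd = 0.9, amp = 1.0) {
  mont <- small_study_montage()
  study_config(
    n_subjects_per_group = n_per_group, n_trials = 48, n_samples = 384,
    onset = 129, base_model = default_base_model(montage = mont),
    group_effect_edges = list(
      list(src = "Cz", dst = "O2", delta = delta, group = "SZ"),
      list(src = "T7", dst = "P7", delta = delta, group = "SZ")),
    oscillator_pairs = list(
      list(a = "F4", b = "Oz", freq = 5.5, lag = pi / 4,
           jitter_sd = jitter_sd, strong_group = "HC", amp = amp)),
    seed = seed)
}

# PLI + (unthresholded) PDC feature table for a simulated study.
study_feature_table <- function(study, order = 2L, band = c(4, 7),
                                window = c(0.1, 0.6)) {
  bank <- build_wavelet_bank(fs = study$subjects[[1]]$fs)
  pli_list <- lapply(study$subjects, pli_matrix, bank = bank, band = band,
                     window = window)
  pdc_list <- lapply(study$subjects, function(ep) {
    covs <- ensemble_covariance(ep, window, max_lag = order)
    band_average_pdc(suppressWarnings(fit_mvar(covs, order)), band)
  })
  build_feature_table(pli_list, pdc_list, study$manifest$group,
                      study$manifest$subject_id)
}
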
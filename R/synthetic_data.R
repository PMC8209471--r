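#' Simulate an ensemble of MVAR trials
#'
#' Draws independent trial realizations of a stable MVAR model with Gaussian
#' innovations. A burn-in of `100 * p` samples is simulated and discarded per
#' trial so the retained segment is stationary.
#'
#' @param model A stable `mvar_model`.
#' @param n_trials Number of trials (>= 1).
#' @param n_samples Samples kept per trial; must exceed `10 * p`.
#' @param onset 1-based onset sample index recorded in the output.
#' @param seed Optional integer seed; identical seed gives identical output.
#' @param subject_id,group Metadata for the returned `epoch_set`.
#' @return An `epoch_set` (channels x n_samples x n_trials).
#' @export
simulate_mvar_trials <- function(model, n_trials, n_samples, onset = 1L,
                                 seed = NULL, subject_id = "sim",
                                 group = NA_character_) {
  stopifnot(inherits(model, "mvar_model"))
  if (!is_stable(model)) {
    stop("validation error: model is not stationary (companion radius >= 1)")
  }
  p <- model$order
  n <- model$n_channels
  if (n_samples <= 10 * p) {
    stop("validation error: n_samples must exceed 10 * order")
  }
  if (!is.null(seed)) set.seed(seed)
  burn <- 100L * p
  total <- burn + n_samples
  lt_chol <- t(chol(model$noise_cov))   # lower-triangular factor
  x <- array(0, dim = c(n, total, n_trials))
  a <- model$coeffs
  for (tt in seq_len(total)) {
    v <- lt_chol %*% matrix(stats::rnorm(n * n_trials), n, n_trials)
    for (r in seq_len(min(p, tt - 1L))) {
      v <- v + a[, , r] %*% matrix(x[, tt - r, ], n, n_trials)
    }
    x[, tt, ] <- v
  }
  epoch_set(x[, burn + seq_len(n_samples), , drop = FALSE], fs = model$fs,
            onset = onset, montage = model$montage, subject_id = subject_id,
            group = group)
}

#' Simulate a lag-coupled oscillator pair
#'
#' Two narrow-band channels: channel 2's phase equals channel 1's phase plus
#' `lag` plus a per-trial jitter drawn from `N(0, jitter_sd^2)`. The
#' convention `jitter_sd = Inf` draws the lag uniformly on `(-pi, pi)` each
#' trial (no phase coupling). Amplitude envelopes are slow sinusoids with
#' independent random phases per channel and trial.
#'
#' @param freq Oscillation frequency in Hz, below Nyquist.
#' @param lag Phase lag in radians of channel 2 relative to channel 1.
#' @param jitter_sd Trial-to-trial SD of the lag, radians (>= 0, may be `Inf`).
#' @param n_trials,n_samples,fs Epoch geometry.
#' @param onset 1-based onset sample index.
#' @param seed Optional integer seed.
#' @param noise_sd SD of additive white noise per channel.
#' @return An `epoch_set` with channels `osc1`, `osc2`.
#' @export
simulate_lagged_oscillators <- function(freq, lag, jitter_sd, n_trials,
                                        n_samples, fs, onset = 1L,
                                        seed = NULL, noise_sd = 0.05) {
  if (!(freq > 0 && freq < fs / 2)) {
    stop("validation error: freq must lie in (0, fs/2)")
  }
  if (is.na(jitter_sd) || jitter_sd < 0) {
    stop("validation error: jitter_sd must be >= 0")
  }
  if (!is.null(seed)) set.seed(seed)
  tvec <- (seq_len(n_samples) - 1) / fs
  x <- array(0, dim = c(2L, n_samples, n_trials))
  for (m in seq_len(n_trials)) {
    phi <- stats::runif(1, -pi, pi)
    lag_m <- if (is.infinite(jitter_sd)) {
      stats::runif(1, -pi, pi)
    } else {
      lag + stats::rnorm(1, 0, jitter_sd)
    }
    env1 <- 1 + 0.3 * sin(2 * pi * 0.4 * tvec + stats::runif(1, -pi, pi))
    env2 <- 1 + 0.3 * sin(2 * pi * 0.4 * tvec + stats::runif(1, -pi, pi))
    x[1, , m] <- env1 * cos(2 * pi * freq * tvec + phi) +
      noise_sd * stats::rnorm(n_samples)
    x[2, , m] <- env2 * cos(2 * pi * freq * tvec + phi + lag_m) +
      noise_sd * stats::rnorm(n_samples)
  }
  epoch_set(x, fs = fs, onset = onset, montage = c("osc1", "osc2"),
            subject_id = "oscillators")
}

#' Apply instantaneous linear mixing (volume conduction)
#'
#' Replaces every sample vector `x` by `mixing %*% x`, emulating zero-lag
#' mixing of sources into electrodes. Metadata are unchanged.
#'
#' @param epochs An `epoch_set`.
#' @param mixing Square numeric matrix, rows = channels.
#' @return An `epoch_set` of the same shape.
#' @export
apply_instantaneous_mixing <- function(epochs, mixing) {
  mixing <- as.matrix(mixing)
  n <- dim(epochs$data)[1]
  if (nrow(mixing) != ncol(mixing) || nrow(mixing) != n) {
    stop("shape error: `mixing` must be square with rows = channels")
  }
  d <- dim(epochs$data)
  mixed <- array(mixing %*% matrix(epochs$data, n), dim = d)
  epoch_set(mixed, fs = epochs$fs, onset = epochs$onset,
            montage = epochs$montage, subject_id = epochs$subject_id,
            group = epochs$group)
}

#' Default background MVAR model for synthetic studies
#'
#' An order-2 stationary model: per-channel damped AR dynamics tuned to put
#' power in the theta range at 256 Hz, plus a sparse ring of weak lag-1 cross
#' couplings so the background has non-trivial (but group-invariant) directed
#' structure.
#'
#' @param montage Channel labels; default the 20-channel montage.
#' @param fs Sampling rate in Hz.
#' @return A stable `mvar_model`.
#' @export
default_base_model <- function(montage = default_montage(), fs = 256) {
  n <- length(montage)
  a <- array(0, dim = c(n, n, 2L))
  # AR(2) per channel: x_t = 2 r cos(w) x_{t-1} - r^2 x_{t-2}, resonant ~5.5 Hz
  r <- 0.55
  w <- 2 * pi * 5.5 / fs
  diag(a[, , 1]) <- 2 * r * cos(w)
  diag(a[, , 2]) <- -r^2
  for (i in seq_len(n)) {             # weak ring of lag-1 couplings
    a[i %% n + 1L, i, 1] <- a[i %% n + 1L, i, 1] + 0.08
  }
  mvar_model(a, diag(n), fs = fs, montage = montage)
}

#' Configure a synthetic two-group study
#'
#' Defines the conditions of a simulated cohort: per-subject stationary MVAR
#' trial ensembles with group-dependent directed coupling, superposed
#' narrow-band oscillator pairs with group-dependent phase consistency,
#' optional instantaneous mixing, and the epoch geometry of a feedback-locked
#' recording (48 trials of 768 samples at 256 Hz, onset at sample 385, i.e.
#' t in [-1.5, 1.5) s).
#'
#' @param n_subjects_per_group Subjects per group (>= 1).
#' @param n_trials Trials per subject.
#' @param n_samples Samples per trial.
#' @param fs Sampling rate in Hz.
#' @param onset 1-based onset sample index.
#' @param base_model Shared background `mvar_model`.
#' @param group_effect_edges List of directed coefficient deltas applied to
#'   one group only; each element a list with fields `src`, `dst` (channel
#'   labels), `delta` (added to the lag-1 coefficient `dst <- src`) and
#'   `group` (which group receives the delta, default `"SZ"`).
#' @param oscillator_pairs List of phase-coupled pairs; each element a list
#'   with fields `a`, `b` (channel labels), `freq` (Hz), `lag` (radians),
#'   `jitter_sd` (radians, the phase jitter of the strongly coupled group; the
#'   other group receives an uncoupled, uniform-lag oscillator), `strong_group`
#'   (default `"HC"`), and optional `amp` (amplitude scale, default 1.5).
#' @param subject_jitter_sd SD of the additive Gaussian perturbation applied
#'   to every MVAR coefficient per subject (between-subject heterogeneity).
#' @param mixing Optional square instantaneous mixing matrix.
#' @param groups Two group labels; the first is the "patient-like" group.
#' @param seed Integer seed; the whole study is a deterministic function of it.
#' @return A `study_config` list.
#' @export
study_config <- function(n_subjects_per_group = 30L,
                         n_trials = 48L,
                         n_samples = 768L,
                         fs = 256,
                         onset = 385L,
                         base_model = default_base_model(fs = fs),
                         group_effect_edges = list(
                           list(src = "Cz", dst = "O2", delta = 0.25, group = "SZ"),
                           list(src = "T7", dst = "P7", delta = 0.25, group = "SZ")
                         ),
                         oscillator_pairs = list(
                           list(a = "F8", b = "Oz", freq = 5.5, lag = pi / 4,
                                jitter_sd = 0.4, strong_group = "HC", amp = 1.5)
                         ),
                         subject_jitter_sd = 0.02,
                         mixing = NULL,
                         groups = c("SZ", "HC"),
                         seed = 1L) {
  cfg <- list(n_subjects_per_group = as.integer(n_subjects_per_group),
              n_trials = as.integer(n_trials),
              n_samples = as.integer(n_samples), fs = fs,
              onset = as.integer(onset), base_model = base_model,
              group_effect_edges = group_effect_edges,
              oscillator_pairs = oscillator_pairs,
              subject_jitter_sd = subject_jitter_sd, mixing = mixing,
              groups = as.character(groups), seed = as.integer(seed))
  class(cfg) <- "study_config"
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  if (cfg$n_subjects_per_group < 1L) {
    stop("validation error: n_subjects_per_group must be >= 1")
  }
  if (cfg$n_trials < 1L) stop("validation error: n_trials must be >= 1")
  if (!inherits(cfg$base_model, "mvar_model")) {
    stop("validation error: base_model must be an mvar_model")
  }
  if (!is_stable(cfg$base_model)) {
    stop("validation error: base_model must be stationary")
  }
  if (cfg$subject_jitter_sd < 0) {
    stop("validation error: subject_jitter_sd must be >= 0")
  }
  if (length(cfg$groups) != 2L || anyDuplicated(cfg$groups)) {
    stop("validation error: exactly two distinct group labels required")
  }
  montage <- cfg$base_model$montage
  for (e in cfg$group_effect_edges) {
    if (!all(c(e$src, e$dst) %in% montage)) {
      stop("validation error: group effect edge names unknown channel")
    }
  }
  for (o in cfg$oscillator_pairs) {
    if (!all(c(o$a, o$b) %in% montage)) {
      stop("validation error: oscillator pair names unknown channel")
    }
    if (!(o$freq > 0 && o$freq < cfg$fs / 2)) {
      stop("validation error: oscillator frequency must be in (0, fs/2)")
    }
    if (is.na(o$jitter_sd) || o$jitter_sd < 0) {
      stop("validation error: oscillator jitter_sd must be >= 0")
    }
  }
  invisible(cfg)
}

# Perturb coefficients until stationary; halve the jitter on each retry.
perturb_until_stable <- function(coeffs, jitter_sd, max_tries = 20L) {
  sd_now <- jitter_sd
  for (k in seq_len(max_tries)) {
    cand <- coeffs + array(stats::rnorm(length(coeffs), 0, sd_now),
                           dim = dim(coeffs))
    if (spectral_radius(cand) < 1) return(cand)
    sd_now <- sd_now / 2
  }
  stop("generation error: could not obtain a stationary subject model after ",
       max_tries, " retries; reduce subject_jitter_sd")
}

#' Simulate a two-group study with known ground truth
#'
#' Generates one `epoch_set` per subject. Each subject's MVAR coefficients are
#' the base model's plus Gaussian jitter (stationarity enforced with bounded
#' retries); the configured directed deltas are applied only to the designated
#' group; oscillator pairs are superposed with group-dependent phase
#' consistency; optional instantaneous mixing is applied last. The returned
#' ground truth records the planted effects but is never consumed by any
#' estimator.
#'
#' @param config A `study_config`.
#' @param dir Optional directory; when given, subject containers, a
#'   `manifest.tsv` and a `ground_truth.yaml` are written there.
#' @return A list of class `two_group_study` with elements `subjects` (list of
#'   `epoch_set`), `manifest` (data frame), `truth` (planted effects), and
#'   `config`.
#' @export
simulate_two_group_study <- function(config, dir = NULL) {
  validate_study_config(config)
  set.seed(config$seed)
  montage <- config$base_model$montage
  subjects <- list()
  rows <- list()
  k <- 0L
  for (g in config$groups) {
    for (i in seq_len(config$n_subjects_per_group)) {
      k <- k + 1L
      sid <- sprintf("%s%02d", g, i)
      coeffs <- perturb_until_stable(config$base_model$coeffs,
                                     config$subject_jitter_sd)
      for (e in config$group_effect_edges) {
        grp <- if (is.null(e$group)) config$groups[1] else e$group
        if (identical(grp, g)) {
          si <- match(e$src, montage); di <- match(e$dst, montage)
          coeffs[di, si, 1] <- coeffs[di, si, 1] + e$delta
        }
      }
      if (spectral_radius(coeffs) >= 1) {
        stop("generation error: group effect deltas destabilize the model; ",
             "reduce the deltas")
      }
      model <- mvar_model(coeffs, config$base_model$noise_cov, fs = config$fs,
                          montage = montage)
      ep <- simulate_mvar_trials(model, n_trials = config$n_trials,
                                 n_samples = config$n_samples,
                                 onset = config$onset, subject_id = sid,
                                 group = g)
      for (o in config$oscillator_pairs) {
        strong <- if (is.null(o$strong_group)) config$groups[2] else o$strong_group
        jit <- if (identical(strong, g)) o$jitter_sd else Inf
        amp <- if (is.null(o$amp)) 1.5 else o$amp
        osc <- simulate_lagged_oscillators(o$freq, o$lag, jit,
                                           n_trials = config$n_trials,
                                           n_samples = config$n_samples,
                                           fs = config$fs,
                                           onset = config$onset)
        ai <- match(o$a, montage); bi <- match(o$b, montage)
        ep$data[ai, , ] <- ep$data[ai, , ] + amp * osc$data[1, , ]
        ep$data[bi, , ] <- ep$data[bi, , ] + amp * osc$data[2, , ]
      }
      if (!is.null(config$mixing)) {
        ep <- apply_instantaneous_mixing(ep, config$mixing)
      }
      subjects[[sid]] <- ep
      rows[[sid]] <- data.frame(subject_id = sid, group = g, path = sid,
                                stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  truth <- list(
    directed_edges = lapply(config$group_effect_edges, function(e) {
      list(src = e$src, dst = e$dst, delta = e$delta,
           group = if (is.null(e$group)) config$groups[1] else e$group)
    }),
    coupled_pairs = lapply(config$oscillator_pairs, function(o) {
      list(a = o$a, b = o$b, freq = o$freq, lag = o$lag,
           jitter_sd = o$jitter_sd,
           strong_group = if (is.null(o$strong_group)) config$groups[2] else o$strong_group)
    }),
    seed = config$seed
  )
  study <- structure(list(subjects = subjects, manifest = manifest,
                          truth = truth, config = config),
                     class = "two_group_study")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(subjects)) {
      write_epochset(subjects[[sid]], file.path(dir, sid))
    }
    write_manifest(manifest, file.path(dir, "manifest.tsv"))
    yaml::write_yaml(truth, file.path(dir, "ground_truth.yaml"))
  }
  study
}

#' @export
print.two_group_study <- function(x, ...) {
  tab <- table(x$manifest$group)
  cat(sprintf("<two_group_study> %s subjects (%s)\n",
              sum(tab), paste(names(tab), tab, sep = "=", collapse = ", ")))
  cat(sprintf("  %d planted directed edge(s), %d coupled pair(s), seed %d\n",
              length(x$truth$directed_edges), length(x$truth$coupled_pairs),
              x$truth$seed))
  invisible(x)
}
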
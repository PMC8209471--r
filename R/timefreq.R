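#' Build a Morlet wavelet bank
#'
#' Center frequencies and cycle counts are linearly spaced and paired
#' index-wise. The defaults span 3.9-40 Hz over 50 points with cycles growing
#' from 3 to 11.4, so temporal resolution tightens as frequency rises.
#'
#' @param f_min,f_max First and last center frequency (Hz), `f_max` below
#'   Nyquist.
#' @param n_points Number of frequencies (>= 2).
#' @param c_min,c_max First and last cycle count.
#' @param fs Sampling rate in Hz.
#' @return An object of class `wavelet_bank` with fields `freqs`, `cycles`,
#'   `fs`.
#' @export
build_wavelet_bank <- function(f_min = 3.9, f_max = 40, n_points = 50L,
                               c_min = 3, c_max = 11.4, fs = 256) {
  if (!(f_min > 0 && f_min < f_max)) {
    stop("validation error: need 0 < f_min < f_max")
  }
  if (f_max >= fs / 2) {
    stop("validation error: f_max must be below the Nyquist frequency ", fs / 2)
  }
  if (n_points < 2L) stop("validation error: n_points must be >= 2")
  structure(list(freqs = seq(f_min, f_max, length.out = n_points),
                 cycles = seq(c_min, c_max, length.out = n_points),
                 fs = fs),
            class = "wavelet_bank")
}

# Complex Morlet kernel: Gaussian-windowed complex exponential with time-domain
# SD sigma = cycles / (2 pi f), truncated at 3.5 sigma, unit energy.
morlet_kernel <- function(freq, cycles, fs) {
  sigma <- cycles / (2 * pi * freq)
  half <- ceiling(3.5 * sigma * fs)
  tt <- (-half:half) / fs
  w <- exp(2i * pi * freq * tt) * exp(-tt^2 / (2 * sigma^2))
  w / sqrt(sum(Mod(w)^2))
}

# Same-length zero-padded convolution of every column of `x` (samples x trials)
# with each requested Morlet kernel. Returns complex array
# n_freq x n_samples x n_trials.
morlet_convolve <- function(x, freqs, cycles, fs) {
  n <- nrow(x)
  m <- ncol(x)
  kernels <- lapply(seq_along(freqs),
                    function(k) morlet_kernel(freqs[k], cycles[k], fs))
  max_len <- max(vapply(kernels, length, 1L))
  nfft <- 2^ceiling(log2(n + max_len - 1L))
  xf <- stats::mvfft(rbind(x, matrix(0, nfft - n, m)))
  out <- array(0i, dim = c(length(freqs), n, m))
  for (k in seq_along(kernels)) {
    w <- kernels[[k]]
    half <- (length(w) - 1L) / 2L
    wf <- stats::fft(c(w, rep(0, nfft - length(w))))
    y <- stats::mvfft(xf * wf, inverse = TRUE) / nfft
    out[k, , ] <- y[half + seq_len(n), ]
  }
  out
}

#' Morlet wavelet transform of one channel
#'
#' Convolves every trial of the chosen channel with each wavelet of the bank
#' (same-length convolution with zero padding), returning complex coefficients.
#'
#' @param epochs An `epoch_set`.
#' @param bank A `wavelet_bank` built for `epochs$fs`.
#' @param channel Channel label.
#' @return An object of class `tf_coef`: complex `values`
#'   (frequencies x samples x trials), plus `bank`, `channel`, `onset`, `fs`.
#' @export
morlet_transform <- function(epochs, bank, channel) {
  stopifnot(inherits(bank, "wavelet_bank"))
  ci <- match(channel, epochs$montage)
  if (is.na(ci)) stop("lookup error: unknown channel label: ", channel)
  d <- dim(epochs$data)
  vals <- morlet_convolve(matrix(epochs$data[ci, , ], d[2], d[3]),
                          bank$freqs, bank$cycles, epochs$fs)
  structure(list(values = vals, bank = bank, channel = channel,
                 onset = epochs$onset, fs = epochs$fs),
            class = "tf_coef")
}

#' @export
print.tf_coef <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<tf_coef> channel %s: %d freqs x %d samples x %d trials\n",
              x$channel, d[1], d[2], d[3]))
  invisible(x)
}

coef_times <- function(coeffs) {
  (seq_len(dim(coeffs$values)[2]) - coeffs$onset) / coeffs$fs
}

#' Baseline-normalized time-frequency power map
#'
#' Power (`|coefficient|^2`) is averaged over trials and over the supplied
#' channels, then each frequency row is expressed as
#' `10 * log10(power / mean baseline power)` with the baseline taken over the
#' half-open window `[t0, t1)`, which must precede stimulus onset.
#'
#' @param coeffs A `tf_coef` or a list of them (one per channel, same bank and
#'   geometry).
#' @param baseline Numeric `(t0, t1)` in seconds with `t1 <= 0`.
#' @return An object of class `tf_map`: `power_db` (frequencies x samples),
#'   `freqs`, `times`, `baseline`, `channels`.
#' @export
power_db <- function(coeffs, baseline = c(-0.2, -0.1)) {
  if (inherits(coeffs, "tf_coef")) coeffs <- list(coeffs)
  stopifnot(length(coeffs) >= 1L, all(vapply(coeffs, inherits, TRUE, "tf_coef")))
  if (baseline[2] > 0) {
    stop("validation error: baseline window must precede stimulus onset")
  }
  pow <- 0
  for (cf in coeffs) {
    pow <- pow + rowMeans(Mod(cf$values)^2, dims = 2L)
  }
  pow <- pow / length(coeffs)
  times <- coef_times(coeffs[[1]])
  idx <- which(times >= baseline[1] & times < baseline[2])
  if (length(idx) == 0L) {
    stop("validation error: baseline window contains no samples")
  }
  base <- rowMeans(pow[, idx, drop = FALSE])
  if (any(base <= 0)) {
    stop("validation error: zero baseline power; cannot normalize")
  }
  structure(list(power_db = 10 * log10(pow / base),
                 freqs = coeffs[[1]]$bank$freqs, times = times,
                 baseline = baseline,
                 channels = vapply(coeffs, `[[`, "", "channel")),
            class = "tf_map")
}

#' One-call per-subject time-frequency map
#'
#' Convenience wrapper: Morlet transform of each requested channel followed by
#' [power_db()].
#'
#' @inheritParams morlet_transform
#' @param channels Channel labels averaged into the map.
#' @param baseline Baseline window `(t0, t1)` seconds, `t1 <= 0`.
#' @return A `tf_map`.
#' @export
tf_power_map <- function(epochs, bank, channels = c("F3", "F4"),
                         baseline = c(-0.2, -0.1)) {
  power_db(lapply(channels, function(ch) morlet_transform(epochs, bank, ch)),
           baseline = baseline)
}

# Pooled-variance two-sample t statistics for every pixel (columns of `x`).
# `grp` is logical, TRUE = first group. Zero pooled variance with equal means
# gives t = 0.
pixel_t <- function(x, grp) {
  n1 <- sum(grp); n2 <- sum(!grp)
  m1 <- colMeans(x[grp, , drop = FALSE])
  m2 <- colMeans(x[!grp, , drop = FALSE])
  v1 <- colSums(sweep(x[grp, , drop = FALSE], 2, m1)^2)
  v2 <- colSums(sweep(x[!grp, , drop = FALSE], 2, m2)^2)
  sp2 <- (v1 + v2) / (n1 + n2 - 2)
  denom <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / denom
  tt[denom == 0 & m1 == m2] <- 0
  tt[denom == 0 & m1 != m2] <- sign(m1 - m2)[denom == 0 & m1 != m2] * Inf
  tt
}

# Sizes (and optionally memberships) of 4-connected components of `mask`
# (frequencies x times logical matrix), split by the sign of `tmat`.
supra_clusters <- function(mask, tmat, keep_members = FALSE) {
  out <- list()
  for (sgn in c(1, -1)) {
    sel <- which(mask & sign(tmat) == sgn)
    if (length(sel) == 0L) next
    nf <- nrow(mask)
    ri <- (sel - 1L) %% nf + 1L
    ci <- (sel - 1L) %/% nf + 1L
    key <- ci * (nf + 2L) + ri                  # unique grid key
    pos <- stats::setNames(seq_along(sel), key)
    edges <- integer(0)
    for (dk in c(1L, nf + 2L)) {                # down-neighbor, right-neighbor
      nb <- pos[as.character(key + dk)]
      hit <- which(!is.na(nb))
      if (length(hit)) edges <- c(edges, rbind(hit, nb[hit]))
    }
    g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(sel) - igraph::vcount(g)))
    comp <- igraph::components(g)
    for (cid in seq_len(comp$no)) {
      members <- sel[comp$membership == cid]
      out[[length(out) + 1L]] <- list(
        size = length(members), sign = sgn,
        pixels = if (keep_members) members else NULL)
    }
  }
  out
}

largest_cluster_size <- function(mask, tmat) {
  cl <- supra_clusters(mask, tmat)
  if (length(cl) == 0L) 0L else max(vapply(cl, `[[`, 1L, "size"))
}

#' Cluster-based permutation comparison of group power maps
#'
#' Pixelwise pooled-variance two-sample t tests on the maps restricted to
#' `time_window`; pixels with two-sided `p < pixel_alpha` form 4-connected
#' clusters (adjacent in time or frequency, same t sign). The null
#' distribution collects the largest cluster size under `n_perm` random
#' relabelings of the subjects; observed clusters are kept iff their size
#' exceeds the `(1 - fw_alpha)` percentile of that null.
#'
#' @param maps_a,maps_b Lists of `tf_map` objects sharing one grid.
#' @param n_perm Number of permutations (>= 100).
#' @param pixel_alpha Uncorrected two-sided pixel threshold.
#' @param fw_alpha Family-wise alpha for cluster retention.
#' @param time_window Half-open `(t0, t1)` in seconds restricting the
#'   statistical grid.
#' @param seed Optional integer seed.
#' @return An object of class `cluster_test`: `sig_mask` (logical
#'   frequencies x retained samples), `clusters` (list of retained clusters
#'   with pixel indices and sizes), `all_clusters`, `null_largest_sizes`
#'   (length `n_perm`), `crit_size`, `t_map`, `freqs`, `times`, `fw_alpha`.
#' @export
cluster_permutation_test <- function(maps_a, maps_b, n_perm = 10000L,
                                     pixel_alpha = 0.01, fw_alpha = 0.05,
                                     time_window = c(-0.2, 1.0), seed = NULL) {
  if (length(maps_a) == 0L || length(maps_b) == 0L) {
    stop("validation error: both map lists must be non-empty")
  }
  if (n_perm < 100L) {
    stop("validation error: n_perm must be >= 100 for a stable percentile")
  }
  stopifnot(all(vapply(c(maps_a, maps_b), inherits, TRUE, "tf_map")))
  times <- maps_a[[1]]$times
  freqs <- maps_a[[1]]$freqs
  keep <- which(times >= time_window[1] & times < time_window[2])
  if (length(keep) == 0L) {
    stop("validation error: time_window contains no samples")
  }
  nf <- length(freqs); nt <- length(keep)
  stack <- t(vapply(c(maps_a, maps_b),
                    function(m) as.vector(m$power_db[, keep, drop = FALSE]),
                    numeric(nf * nt)))
  grp <- rep(c(TRUE, FALSE), c(length(maps_a), length(maps_b)))
  df <- length(grp) - 2L
  tcrit <- stats::qt(1 - pixel_alpha / 2, df)
  if (!is.null(seed)) set.seed(seed)
  # Permutations relabel subjects without replacement. They are drawn against
  # a canonical content-ordering of the pooled maps (not the argument order),
  # and a bipartition's largest supra-threshold cluster is invariant to which
  # side is called "group a", so the whole test is exactly label-symmetric.
  ord <- order(rowSums(stack), stack[, 1])
  n_min <- min(sum(grp), sum(!grp))
  null_sizes <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    gp <- logical(length(grp))
    gp[ord[sample(length(grp), n_min)]] <- TRUE
    tv <- pixel_t(stack, gp)
    null_sizes[b] <- largest_cluster_size(
      matrix(abs(tv) > tcrit, nf, nt), matrix(tv, nf, nt))
  }
  tv <- pixel_t(stack, grp)
  tmat <- matrix(tv, nf, nt)
  all_clusters <- supra_clusters(matrix(abs(tv) > tcrit, nf, nt), tmat,
                                 keep_members = TRUE)
  crit <- stats::quantile(null_sizes, 1 - fw_alpha, names = FALSE)
  kept <- Filter(function(cl) cl$size > crit, all_clusters)
  sig <- matrix(FALSE, nf, nt)
  for (cl in kept) sig[cl$pixels] <- TRUE
  structure(list(sig_mask = sig, clusters = kept, all_clusters = all_clusters,
                 null_largest_sizes = null_sizes, crit_size = crit,
                 t_map = tmat, freqs = freqs, times = times[keep],
                 pixel_alpha = pixel_alpha, fw_alpha = fw_alpha),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> grid %d freqs x %d samples, %d permutations\n",
              nrow(x$t_map), ncol(x$t_map), length(x$null_largest_sizes)))
  cat(sprintf("  critical cluster size (fw alpha %.3g): > %g pixels\n",
              x$fw_alpha, x$crit_size))
  if (length(x$clusters) == 0L) {
    cat("  no significant clusters\n")
  } else {
    sizes <- vapply(x$clusters, `[[`, 1L, "size")
    cat(sprintf("  %d significant cluster(s), sizes: %s\n", length(sizes),
                paste(sizes, collapse = ", ")))
  }
  invisible(x)
}

#' Plot a time-frequency map or the cluster significance mask
#'
#' @param x A `tf_map`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.tf_map <- function(x, ...) {
  graphics::image(x$times, x$freqs, t(x$power_db), xlab = "time (s)",
                  ylab = "frequency (Hz)",
                  main = paste("10log10 power vs baseline:",
                               paste(x$channels, collapse = ", ")), ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
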
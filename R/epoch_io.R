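#' Default 20-channel montage
#'
#' Ordered channel labels used throughout the analysis. Order is significant:
#' every matrix, feature vector and descriptor downstream follows it.
#'
#' @return Character vector of 20 channel labels.
#' @export
default_montage <- function() {
  c("FP1", "FP2", "Fz", "F3", "F4", "F7", "T7", "T8", "C3", "C4",
    "Cz", "Pz", "P4", "P3", "F8", "P8", "P7", "Oz", "O2", "O1")
}

#' Construct an epoched EEG set
#'
#' Bundles one subject's trials (channels x samples x trials, microvolts) with
#' its sampling rate, stimulus-onset sample and montage. Sample `i` maps to
#' time `(i - onset) / fs` seconds; all windows downstream are half-open
#' `[t0, t1)` in that convention.
#'
#' @param data Numeric array, channels x samples x trials. All values finite.
#' @param fs Sampling rate in Hz.
#' @param onset 1-based sample index at which t = 0 (stimulus onset).
#' @param montage Character vector of unique channel labels, one per row of
#'   `data`. Defaults to `dimnames(data)[[1]]`.
#' @param subject_id Subject identifier string.
#' @param group Group label (e.g. `"SZ"` or `"HC"`).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, onset, montage = NULL,
                      subject_id = "subject", group = NA_character_) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array (channels x samples x trials)")
  }
  storage.mode(data) <- "double"
  if (is.null(montage)) montage <- dimnames(data)[[1]]
  if (is.null(montage)) {
    stop("`montage` is required when `data` has no channel dimnames")
  }
  x <- structure(
    list(data = data, fs = as.numeric(fs), onset = as.integer(onset),
         montage = as.character(montage),
         subject_id = as.character(subject_id), group = as.character(group)),
    class = "epoch_set"
  )
  validate_epoch_set(x)
  dimnames(x$data) <- list(x$montage, NULL, NULL)
  x
}

validate_epoch_set <- function(x) {
  d <- dim(x$data)
  if (any(!is.finite(x$data))) {
    stop("validation error: epoch data contain non-finite values")
  }
  if (!is.finite(x$fs) || x$fs <= 0) stop("validation error: fs must be > 0")
  if (x$onset < 1L || x$onset > d[2]) {
    stop("validation error: onset must lie within 1..samples")
  }
  if (length(x$montage) != d[1]) {
    stop("validation error: montage length must equal channel rows")
  }
  if (anyDuplicated(x$montage) || any(!nzchar(x$montage))) {
    stop("validation error: montage labels must be unique, non-empty strings")
  }
  if (d[3] < 1L) stop("validation error: at least one trial required")
  invisible(x)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> subject %s (group %s)\n", x$subject_id, x$group))
  cat(sprintf("  %d channels x %d samples x %d trials @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  time %.3f .. %.3f s (onset at sample %d)\n",
              (1 - x$onset) / x$fs, (d[2] - x$onset) / x$fs, x$onset))
  invisible(x)
}

#' Epoch time axis
#'
#' @param epochs An `epoch_set`.
#' @return Numeric vector of per-sample times in seconds (0 at onset).
#' @export
epoch_times <- function(epochs) {
  (seq_len(dim(epochs$data)[2]) - epochs$onset) / epochs$fs
}

# Sample indices with t0 <= t < t1 (half-open window).
window_indices <- function(epochs, window) {
  t <- epoch_times(epochs)
  idx <- which(t >= window[1] & t < window[2])
  if (length(idx) == 0L) {
    stop(sprintf("validation error: window [%g, %g) contains no samples",
                 window[1], window[2]))
  }
  idx
}

#' Write an epoched EEG set to disk
#'
#' The on-disk container is a pair of files sharing a stem: `<path>.meta`, a
#' UTF-8 `key: value` text document, and `<path>.dat`, the raw samples as
#' little-endian 64-bit floats with the channel index varying fastest, then
#' sample, then trial (the array's native column-major order).
#'
#' @param epochs A valid `epoch_set`.
#' @param path File stem (no extension) to write to; existing files are
#'   replaced.
#' @return `path`, invisibly.
#' @export
write_epochset <- function(epochs, path) {
  validate_epoch_set(epochs)
  d <- dim(epochs$data)
  meta <- c(
    "format: eegfuse-epochs-1",
    paste0("subject_id: ", epochs$subject_id),
    paste0("group: ", epochs$group),
    paste0("fs: ", format(epochs$fs, digits = 17)),
    paste0("onset: ", epochs$onset),
    paste0("n_channels: ", d[1]),
    paste0("n_samples: ", d[2]),
    paste0("n_trials: ", d[3]),
    paste0("channels: ", paste(epochs$montage, collapse = ","))
  )
  meta_path <- paste0(path, ".meta")
  dat_path <- paste0(path, ".dat")
  ok <- tryCatch({
    writeLines(meta, meta_path, useBytes = TRUE)
    con <- file(dat_path, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(as.vector(epochs$data), con, size = 8L, endian = "little")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing '", path, "': ", conditionMessage(ok))
  invisible(path)
}

read_meta_file <- function(meta_path) {
  if (!file.exists(meta_path)) {
    stop("format error: metadata file not found: ", meta_path)
  }
  lines <- readLines(meta_path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) if (length(p) > 1L) p[2L] else "", ""))
  stats::setNames(as.list(vals), keys)
}

meta_get <- function(meta, key, path) {
  if (is.null(meta[[key]]) || !nzchar(meta[[key]])) {
    stop(sprintf("format error: metadata of '%s' is missing key \"%s\"",
                 path, key))
  }
  meta[[key]]
}

#' Read an epoched EEG set from disk
#'
#' Inverse of [write_epochset()]; the round-trip is bit-exact.
#'
#' @param path File stem written by [write_epochset()].
#' @return An `epoch_set`.
#' @export
read_epochset <- function(path) {
  meta <- read_meta_file(paste0(path, ".meta"))
  fs <- as.numeric(meta_get(meta, "fs", path))
  onset <- as.integer(meta_get(meta, "onset", path))
  n_ch <- as.integer(meta_get(meta, "n_channels", path))
  n_s <- as.integer(meta_get(meta, "n_samples", path))
  n_tr <- as.integer(meta_get(meta, "n_trials", path))
  channels <- strsplit(meta_get(meta, "channels", path), ",", fixed = TRUE)[[1]]
  subject_id <- meta_get(meta, "subject_id", path)
  group <- meta_get(meta, "group", path)
  if (any(is.na(c(fs, onset, n_ch, n_s, n_tr)))) {
    stop("format error: non-numeric metadata field in '", path, "'")
  }
  if (length(channels) != n_ch) {
    stop("integrity error: channel list length disagrees with n_channels in '",
         path, "'")
  }
  dat_path <- paste0(path, ".dat")
  if (!file.exists(dat_path)) stop("integrity error: payload file missing: ", dat_path)
  n_expected <- as.numeric(n_ch) * n_s * n_tr
  size <- file.info(dat_path)$size
  if (size != 8 * n_expected) {
    stop(sprintf(
      "integrity error: payload '%s' holds %g values but metadata promises %g",
      dat_path, size / 8, n_expected))
  }
  con <- file(dat_path, "rb")
  on.exit(close(con), add = TRUE)
  values <- readBin(con, "double", n = n_expected, size = 8L, endian = "little")
  epoch_set(array(values, dim = c(n_ch, n_s, n_tr)), fs = fs, onset = onset,
            montage = channels, subject_id = subject_id, group = group)
}

#' Select channels from an epoch set
#'
#' Returns the requested channels in the requested order; samples and trials
#' are unchanged. Selecting `[a, b]` then `[b]` equals selecting `[b]`.
#'
#' @param epochs An `epoch_set`.
#' @param labels Channel labels to keep, all present in the montage.
#' @return An `epoch_set` with `length(labels)` channels.
#' @export
select_channels <- function(epochs, labels) {
  idx <- match(labels, epochs$montage)
  if (anyNA(idx)) {
    stop("lookup error: unknown channel label(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  epoch_set(epochs$data[idx, , , drop = FALSE], fs = epochs$fs,
            onset = epochs$onset, montage = labels,
            subject_id = epochs$subject_id, group = epochs$group)
}

#' Write a study manifest
#'
#' @param manifest Data frame with columns `subject_id`, `group`, `path`
#'   (container stems, relative paths resolved against the manifest location).
#' @param path Destination TSV file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("subject_id", "group", "path") %in% names(manifest)))
  utils::write.table(manifest[, c("subject_id", "group", "path")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a study manifest
#'
#' @param path Manifest TSV written by [write_manifest()].
#' @return Data frame with columns `subject_id`, `group`, `path`; relative
#'   container stems are resolved against the manifest directory.
#' @export
read_manifest <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = "character")
  for (k in c("subject_id", "group", "path")) {
    if (is.null(m[[k]])) stop("format error: manifest is missing column \"", k, "\"")
  }
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}
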
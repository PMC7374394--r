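#' Five respiration pattern classes
#'
#' Eupnea (normal breathing, 15-20 breaths/min), bradypnea (slow, shallow,
#' <= 12 breaths/min), tachypnea (rapid shallow, >= 20 breaths/min), apnea
#' (airflow reduced by more than 90% of the subject's normal amplitude) and
#' moving (body movement: large irregular baseline displacement that
#' overwhelms the respiratory oscillation).
#'
#' @return Character vector of the five class labels, in canonical order.
#' @export
pattern_types <- function() {
  c("EUPNEA", "BRADYPNEA", "TACHYPNEA", "APNEA", "MOVING")
}

#' Per-subject acquisition profile
#'
#' Captures between-subject variability: a baseline chest-displacement
#' amplitude (arbitrary sensor units), a breathing-rate offset added to the
#' class rate before clamping to the class range, and a sensor noise level.
#'
#' @param id subject identifier (integer).
#' @param amplitude baseline eupnea amplitude, > 0.
#' @param rate_offset breaths/min added to the class-typical rate.
#' @param noise standard deviation of additive Gaussian sensor noise, >= 0.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(id, amplitude = 1, rate_offset = 0, noise = 0.05) {
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (noise < 0) stop("noise must be >= 0")
  structure(list(id = as.integer(id), amplitude = amplitude,
                 rate_offset = rate_offset, noise = noise),
            class = "subject_profile")
}

# class-conditional rate ranges (breaths/min) and amplitude factors relative
# to the subject's eupnea amplitude
pattern_params <- function(pattern) {
  switch(pattern,
         EUPNEA = list(rate = c(15, 20), amp = 1.0),
         BRADYPNEA = list(rate = c(8, 12), amp = 0.6),
         TACHYPNEA = list(rate = c(22, 30), amp = 0.35),
         APNEA = list(rate = c(15, 20), amp = 0.04),
         MOVING = list(rate = c(15, 20), amp = 1.0),
         stop(sprintf("unknown pattern '%s'", pattern)))
}

# Asymmetric raised sinusoid: inspiration rises faster than expiration
# decays.  The phase-modulation term skews the sine without changing the
# fundamental period, so spectral rate estimates stay at the breathing rate.
breath_waveform <- function(t, rate_bpm, phase, asym = 0.3) {
  theta <- 2 * pi * (rate_bpm / 60) * t + phase
  sin(theta + asym * sin(theta))
}

#' Generate one fixed-length respiration signal piece
#'
#' Produces a quasi-sinusoidal chest-displacement waveform with
#' class-conditional rate and depth: eupnea breathes at 15-20 breaths/min at
#' full subject amplitude; bradypnea at <= 12 breaths/min with reduced depth
#' (the longer cycle follows from the lower rate); tachypnea at >= 20
#' breaths/min and shallow; apnea retains under 10% of the subject's eupnea
#' amplitude; moving superimposes a smoothed random-walk baseline drift of at
#' least 3x the respiratory amplitude.  Gaussian sensor noise is added at the
#' subject's noise level and each piece gets a random phase.
#'
#' @param pattern one of [pattern_types()].
#' @param subject a [subject_profile()].
#' @param fs sampling rate in Hz, > 0.
#' @param duration piece duration in seconds, > 0.
#' @param rate_bpm optional forced breathing rate (breaths/min), overriding
#'   the class-conditional draw.
#' @param asym waveform asymmetry parameter (0 = pure sine).
#' @return An object of class `signal_piece`: list with `samples` (numeric
#'   vector of length `round(duration * fs)`), `label`, `subject_id`,
#'   `rate_bpm` (the generating rate), `fs` and `duration`.
#' @export
generate_piece <- function(pattern, subject, fs = 20, duration = 10,
                           rate_bpm = NULL, asym = 0.3) {
  if (fs <= 0) stop("fs must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  pattern <- match.arg(pattern, pattern_types())
  pp <- pattern_params(pattern)
  if (is.null(rate_bpm)) {
    rate_bpm <- stats::runif(1, pp$rate[1], pp$rate[2]) + subject$rate_offset
    rate_bpm <- min(max(rate_bpm, pp$rate[1]), pp$rate[2])
  }
  n <- round(duration * fs)
  t <- seq_len(n) / fs
  phase <- stats::runif(1, 0, 2 * pi)
  amp <- subject$amplitude * pp$amp
  x <- amp * breath_waveform(t, rate_bpm, phase, asym)
  if (pattern == "MOVING") {
    # smoothed random-walk body-movement drift, >= 3x respiratory amplitude
    drift <- cumsum(stats::rnorm(n))
    win <- max(1L, round(fs / 2))
    drift <- stats::filter(drift, rep(1 / win, win), sides = 2)
    drift[is.na(drift)] <- 0
    span <- max(drift) - min(drift)
    if (span > 0) drift <- drift / span
    x <- x + 3.5 * subject$amplitude * (drift - mean(drift))
  }
  x <- x + stats::rnorm(n, 0, subject$noise)
  structure(list(samples = as.numeric(x), label = pattern,
                 subject_id = subject$id, rate_bpm = rate_bpm,
                 fs = fs, duration = duration),
            class = "signal_piece")
}

#' Estimate breathing rate from a signal piece by spectral peak
#'
#' Zero-pads the mean-removed signal to a fine frequency grid, computes the
#' periodogram and returns the peak frequency within the plausible
#' respiration band, converted to breaths per minute.
#'
#' @param samples numeric signal vector.
#' @param fs sampling rate in Hz.
#' @param band frequency band searched, in Hz (default 0.05-1.0 Hz, i.e.
#'   3-60 breaths/min).
#' @return Estimated rate in breaths per minute.
#' @export
estimate_rate_bpm <- function(samples, fs, band = c(0.05, 1.0)) {
  x <- samples - mean(samples)
  nfft <- 2^ceiling(log2(max(length(x) * 16, 4096)))
  spec <- Mod(stats::fft(c(x, numeric(nfft - length(x)))))^2
  freq <- (seq_len(nfft) - 1) * fs / nfft
  keep <- freq >= band[1] & freq <= band[2]
  freq[keep][which.max(spec[keep])] * 60
}

#' Generate a labelled multi-subject respiration dataset
#'
#' Emulates the acquisition protocol of a multi-subject radar study: each of
#' `n_subjects` subjects gets a profile drawn once (amplitude, rate offset,
#' noise), then contributes `pieces_per_type` pieces of each of the five
#' pattern classes, giving `n_subjects * 5 * pieces_per_type` pieces with
#' exactly balanced labels.
#'
#' @param n_subjects number of subjects.
#' @param pieces_per_type pieces per pattern class per subject.
#' @param fs sampling rate in Hz.
#' @param duration piece duration in seconds.
#' @param noise sensor noise standard deviation (scaled per subject by a
#'   factor in \[0.5, 1.5\]).
#' @param seed optional integer seed.
#' @return An object of class `respiration_dataset`: list with `signals`
#'   (pieces x samples matrix), `labels` (factor over [pattern_types()]),
#'   `subject` (integer vector), `rate_bpm` (generating rates), `fs`,
#'   `duration` and `split` (`NULL` until [split_dataset()] is applied).
#' @export
generate_dataset <- function(n_subjects = 10, pieces_per_type = 50,
                             fs = 20, duration = 10, noise = 0.05,
                             seed = NULL) {
  if (n_subjects < 1 || pieces_per_type < 1)
    stop("n_subjects and pieces_per_type must be positive")
  if (!is.null(seed)) set.seed(seed)
  subjects <- lapply(seq_len(n_subjects), function(i)
    subject_profile(i,
                    amplitude = stats::runif(1, 0.8, 1.2),
                    rate_offset = stats::runif(1, -1.5, 1.5),
                    noise = noise * stats::runif(1, 0.5, 1.5)))
  n_total <- n_subjects * 5L * pieces_per_type
  n_samples <- round(duration * fs)
  signals <- matrix(0, n_total, n_samples)
  labels <- character(n_total)
  subject_id <- integer(n_total)
  rates <- numeric(n_total)
  row <- 0L
  for (s in subjects) {
    for (pattern in pattern_types()) {
      for (p in seq_len(pieces_per_type)) {
        row <- row + 1L
        piece <- generate_piece(pattern, s, fs = fs, duration = duration)
        signals[row, ] <- piece$samples
        labels[row] <- piece$label
        subject_id[row] <- s$id
        rates[row] <- piece$rate_bpm
      }
    }
  }
  structure(list(signals = signals,
                 labels = factor(labels, levels = pattern_types()),
                 subject = subject_id, rate_bpm = rates,
                 fs = fs, duration = duration, split = NULL),
            class = "respiration_dataset")
}

#' @export
print.respiration_dataset <- function(x, ...) {
  cat(sprintf("Respiration dataset: %d pieces x %d samples (fs=%g Hz, %gs), %d subjects\n",
              nrow(x$signals), ncol(x$signals), x$fs, x$duration,
              length(unique(x$subject))))
  print(table(x$labels))
  if (!is.null(x$split)) print(table(x$split))
  invisible(x)
}

#' Assign train / validation / test splits
#'
#' Randomly selects `n_train_pool` pieces as the learning pool, splits the
#' pool randomly with `val_fraction` going to validation and the rest to
#' training, and assigns all remaining pieces to the held-out test set.  The
#' three splits are disjoint and exhaustive.  With the defaults of the
#' emulated protocol (2500 pieces, pool 1500, fraction 0.2) this yields
#' 1200 / 300 / 1000 train / validation / test pieces.
#'
#' @param ds a [generate_dataset()] result.
#' @param n_train_pool size of the learning pool (train + validation).
#' @param val_fraction fraction of the pool held out for validation,
#'   strictly between 0 and 1.
#' @param seed optional integer seed.
#' @return The dataset with its `split` factor
#'   (`train` / `validation` / `test`) filled in.
#' @export
split_dataset <- function(ds, n_train_pool = 1500, val_fraction = 0.2,
                          seed = NULL) {
  n <- nrow(ds$signals)
  if (n_train_pool > n) stop("n_train_pool exceeds the number of pieces")
  if (n_train_pool < 1) stop("n_train_pool must be positive")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must lie strictly between 0 and 1")
  if (!is.null(seed)) set.seed(seed)
  pool <- sample.int(n, n_train_pool)
  n_val <- round(val_fraction * n_train_pool)
  val <- pool[sample.int(n_train_pool, n_val)]
  split <- rep("test", n)
  split[pool] <- "train"
  split[val] <- "validation"
  if (!any(split == "test"))
    warning("learning pool covers the whole dataset; test set is empty")
  ds$split <- factor(split, levels = c("train", "validation", "test"))
  ds
}

#' Subset a dataset to one split
#'
#' @param ds a split [generate_dataset()] result.
#' @param which one or more of `"train"`, `"validation"`, `"test"`.
#' @return List with `x` (signal matrix) and `y` (label factor).
#' @export
dataset_split <- function(ds, which) {
  if (is.null(ds$split)) stop("dataset has no split; call split_dataset() first")
  keep <- ds$split %in% which
  list(x = ds$signals[keep, , drop = FALSE], y = ds$labels[keep])
}

#' Write a dataset as delimited text with checksums
#'
#' Writes `signals.csv` (piece id + samples), `labels.csv` (piece id,
#' subject, label, split) and a `manifest.yaml` carrying dimensions and MD5
#' checksums for round-trip verification.
#'
#' @param ds a [generate_dataset()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig_path <- file.path(dir, "signals.csv")
  lab_path <- file.path(dir, "labels.csv")
  sig <- cbind(piece_id = seq_len(nrow(ds$signals)),
               as.data.frame(ds$signals))
  names(sig)[-1] <- paste0("s", seq_len(ncol(ds$signals)))
  utils::write.csv(sig, sig_path, row.names = FALSE)
  lab <- data.frame(piece_id = seq_len(nrow(ds$signals)),
                    subject = ds$subject,
                    label = as.character(ds$labels),
                    split = if (is.null(ds$split)) NA_character_
                            else as.character(ds$split),
                    rate_bpm = ds$rate_bpm)
  utils::write.csv(lab, lab_path, row.names = FALSE)
  manifest <- list(n_pieces = nrow(ds$signals),
                   n_samples = ncol(ds$signals),
                   fs = ds$fs, duration = ds$duration,
                   md5 = list(signals = unname(tools::md5sum(sig_path)),
                              labels = unname(tools::md5sum(lab_path))))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' Verifies the manifest checksums before reconstructing the dataset object.
#'
#' @param dir directory containing `signals.csv`, `labels.csv` and
#'   `manifest.yaml`.
#' @return A `respiration_dataset`.
#' @export
read_dataset <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  sig_path <- file.path(dir, "signals.csv")
  lab_path <- file.path(dir, "labels.csv")
  if (!identical(unname(tools::md5sum(sig_path)), manifest$md5$signals) ||
      !identical(unname(tools::md5sum(lab_path)), manifest$md5$labels))
    stop("dataset files do not match their manifest checksums")
  sig <- utils::read.csv(sig_path)
  lab <- utils::read.csv(lab_path)
  split <- if (all(is.na(lab$split))) NULL
           else factor(lab$split, levels = c("train", "validation", "test"))
  structure(list(signals = unname(as.matrix(sig[, -1])),
                 labels = factor(lab$label, levels = pattern_types()),
                 subject = lab$subject, rate_bpm = lab$rate_bpm,
                 fs = manifest$fs, duration = manifest$duration,
                 split = split),
            class = "respiration_dataset")
}
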
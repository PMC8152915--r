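# SSVEP preprocessing and extraction.
#
# Pipeline per participant and condition: cut trials into 1-s epochs
# (discard the first, detrend), reject artifact epochs by peak-to-peak
# threshold, re-reference to the scalp average and select the analysis
# channel (Iz), average epochs of the same hue sector and concatenate the
# 24 sector means back into a 24-s signal, Gabor-transform at 5 Hz, and
# convert the complex amplitude to amplitude and phase-derived latency
# profiles over hue.

# Residual maker for linear detrending of a fixed-length epoch.
# The trend (intercept + slope) is estimated on flicker-cycle means (one
# mean per 200 ms on/off cycle), which makes the removed line exactly
# orthogonal to the 5 Hz component and its harmonics: a naive per-sample
# linear fit would absorb up to ~2.4% of a 5 Hz sinusoid (at sine phase)
# and bias the extracted amplitude.
detrend_projector <- function(n, cycle = n %/% SSVEP_HZ) {
  n_cyc <- n %/% cycle
  A <- matrix(0, n_cyc, n)
  for (k in seq_len(n_cyc)) A[k, (k - 1L) * cycle + seq_len(cycle)] <- 1 / cycle
  tc <- (seq_len(n_cyc) - 0.5) * cycle + 0.5  # cycle-center sample index
  Xc <- cbind(1, tc)
  Xf <- cbind(1, seq_len(n))
  diag(n) - Xf %*% solve(crossprod(Xc), t(Xc)) %*% A
}

#' Cut a recording into labeled 1-s epochs
#'
#' Each 25-s trial yields 25 one-second epochs; the first is discarded to
#' let the SSVEP stabilize, leaving 24 epochs that jointly cover all 24 hue
#' sectors exactly once. Each epoch is labeled with the sector its second
#' of stimulation covered (from the trial's start sector and sweep
#' direction) and linearly detrended per channel.
#'
#' @param recording An `eeg_recording` from [simulate_trial()].
#' @return An `eeg_epochs`: list with `data` (channels x 250 x epochs
#'   array), `labels` tibble (`epoch`, `second`, `sector`, `contrast`,
#'   `direction`, `start_sector`, `artifact`), `montage`, `fs`.
#' @export
epoch_and_label <- function(recording) {
  fs <- recording$fs
  sched <- recording$schedule
  trial_s <- attr(sched, "trial_s")
  if (trial_s < 25) stop("trial shorter than 25 s")
  n_sec <- floor(trial_s)
  if (ncol(recording$samples) < n_sec * fs) stop("recording shorter than trial")
  keep_sec <- seq(1L, n_sec - 1L)  # 0-based seconds 1..24; second 0 discarded
  n_ch <- nrow(recording$samples)
  P <- detrend_projector(fs)
  data <- array(NA_real_, dim = c(n_ch, fs, length(keep_sec)),
                dimnames = list(rownames(recording$samples), NULL, NULL))
  for (i in seq_along(keep_sec)) {
    seg <- recording$samples[, keep_sec[i] * fs + seq_len(fs), drop = FALSE]
    data[, , i] <- seg %*% t(P)  # per-channel linear detrend
  }
  dir <- attr(sched, "direction")
  s0 <- attr(sched, "start_sector")
  labels <- tibble::tibble(
    epoch = seq_along(keep_sec),
    second = keep_sec,
    sector = sector_at_second(dir, s0, keep_sec),
    contrast = attr(sched, "level")$name,
    direction = dir,
    start_sector = s0,
    artifact = FALSE
  )
  structure(list(data = data, labels = labels, montage = recording$montage,
                 fs = fs), class = "eeg_epochs")
}

#' Flag artifact epochs by peak-to-peak amplitude
#'
#' An epoch is flagged when any channel's (EEG or EOG) peak-to-peak
#' amplitude exceeds the threshold; flagged epochs are excluded from all
#' downstream averaging.
#'
#' @param epochs An `eeg_epochs`.
#' @param peak_to_peak_threshold_uv Rejection threshold in microvolts.
#' @return The `eeg_epochs` with updated `labels$artifact`.
#' @export
reject_artifacts <- function(epochs, peak_to_peak_threshold_uv = 100) {
  p2p <- apply(epochs$data, c(1, 3), function(x) max(x) - min(x))
  epochs$labels$artifact <- apply(p2p > peak_to_peak_threshold_uv, 2, any)
  epochs
}

#' Re-reference to the scalp average and select the analysis channel
#'
#' Subtracts the mean across EEG channels (EOG excluded) from every EEG
#' channel at each sample, then extracts the requested channel. Also
#' reports, as a diagnostic, the channel with the largest mean 5 Hz Fourier
#' amplitude across retained epochs (expected: Iz for an occipital SSVEP).
#'
#' @param epochs An `eeg_epochs` (ideally after [reject_artifacts()]).
#' @param channel Analysis channel name (default `"Iz"`).
#' @return A `selected_epochs`: list with `amp` (epochs x 250 matrix for
#'   the selected channel), `labels`, `fs`, `channel`, `peak_channel`,
#'   `amp_5hz_by_channel`.
#' @export
rereference_and_select <- function(epochs, channel = "Iz") {
  eeg_idx <- which(epochs$montage$type == "eeg")
  if (length(eeg_idx) < 2L) stop("need at least 2 EEG channels")
  if (!channel %in% rownames(epochs$data[, , 1, drop = FALSE])) {
    if (!channel %in% epochs$montage$channel) stop("channel not in montage: ", channel)
  }
  data <- epochs$data
  ref <- colMeans(data[eeg_idx, , , drop = FALSE])      # 250 x epochs
  for (ci in eeg_idx) data[ci, , ] <- data[ci, , ] - ref
  retained <- !epochs$labels$artifact
  bin5 <- SSVEP_HZ + 1L  # 1-s epochs: 1 Hz resolution, DC at bin 1
  amp5 <- vapply(eeg_idx, function(ci) {
    m <- data[ci, , retained, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 1)
    mean(abs(apply(m, 2, function(x) stats::fft(x)[bin5])) * 2 / epochs$fs)
  }, numeric(1))
  names(amp5) <- epochs$montage$channel[eeg_idx]
  ci <- which(epochs$montage$channel == channel)
  structure(list(
    amp = t(data[ci, , , drop = TRUE]),
    labels = epochs$labels, fs = epochs$fs, channel = channel,
    peak_channel = names(amp5)[which.max(amp5)],
    amp_5hz_by_channel = amp5
  ), class = "selected_epochs")
}

#' Combine selected epochs from several trials of one condition
#' @param sel_list List of `selected_epochs` (same condition).
#' @return One pooled `selected_epochs`.
#' @export
pool_epochs <- function(sel_list) {
  structure(list(
    amp = do.call(rbind, lapply(sel_list, `[[`, "amp")),
    labels = dplyr::bind_rows(lapply(sel_list, `[[`, "labels")),
    fs = sel_list[[1]]$fs, channel = sel_list[[1]]$channel,
    peak_channel = sel_list[[1]]$peak_channel,
    amp_5hz_by_channel = Reduce(`+`, lapply(sel_list, `[[`, "amp_5hz_by_channel")) /
      length(sel_list)
  ), class = "selected_epochs")
}

#' Average epochs per hue sector and reconstruct a 24-s signal
#'
#' Retained epochs of the same hue sector are averaged; the 24 sector means
#' are concatenated in sweep order (ascending hue for counterclockwise,
#' descending for clockwise) into one 6000-sample signal, with a
#' continuously advancing hue (15 deg/s) assigned per sample.
#'
#' @param sel A `selected_epochs` holding one participant x contrast x
#'   direction condition (pooled over trials).
#' @return A `reconstruction`: list with `signal` (6000), `hue_deg` (6000),
#'   `direction`, `fs`, `n_epochs_per_sector`.
#' @export
average_and_reconstruct <- function(sel) {
  fs <- sel$fs
  keep <- !sel$labels$artifact
  direction <- unique(sel$labels$direction)
  stopifnot(length(direction) == 1L)
  counts <- integer(24)
  means <- matrix(NA_real_, nrow = 24, ncol = fs)
  for (k in 0:23) {
    idx <- which(keep & sel$labels$sector == k)
    if (length(idx) == 0L) stop("no retained epochs for sector ", k)
    counts[k + 1L] <- length(idx)
    means[k + 1L, ] <- colMeans(sel$amp[idx, , drop = FALSE])
  }
  # Per-sample hue advances continuously at 15 deg/s, shifted by -1.5 deg
  # (half the 3-deg per-on-phase step) so labels are centered on the hue
  # staircase actually displayed. Both directions draw their labels from
  # the same precomputed grid (bit-identical values) so profiles can be
  # matched sample-for-sample across directions.
  n <- 24L * fs
  grid <- (0.06 * (0:(n - 1L)) - 1.5) %% 360
  if (direction == "counterclockwise") {
    order_k <- 0:23
    hue <- grid                                # ascending in sweep order
  } else {
    order_k <- 23:0
    hue <- grid[c(1L, n:2L)]                   # descending from the top
  }
  signal <- as.vector(t(means[order_k + 1L, ]))
  structure(list(signal = signal, hue_deg = hue, direction = direction,
                 fs = fs, n_epochs_per_sector = counts),
            class = "reconstruction")
}

#' Complex Gabor transform at the stimulation frequency
#'
#' Circular convolution with a unit-gain complex Gabor: implemented in the
#' frequency domain as multiplication with a Gaussian
#' `2 * exp(-(f - f0)^2 / (2 * sigma_f^2))` over positive frequencies
#' (negative frequencies suppressed). The time-domain envelope SD is
#' `1 / (2 * pi * sigma_f)` (~637 ms at 0.25 Hz); the convolution is
#' circular because the reconstructed 24-s signal is periodic in hue.
#' A pure `cos(2*pi*f0*t)` of amplitude 1 yields modulus 1 everywhere.
#'
#' @param signal Real signal (e.g. 6000-sample reconstruction).
#' @param fs Sampling rate in Hz.
#' @param f0 Center frequency (default 5 Hz).
#' @param sigma_f Frequency-domain SD (default 0.25 Hz).
#' @return Complex vector, same length as `signal`.
#' @export
gabor_transform <- function(signal, fs = SAMPLING_RATE_HZ, f0 = SSVEP_HZ,
                            sigma_f = 0.25) {
  n <- length(signal)
  f <- (seq_len(n) - 1L) * fs / n
  H <- 2 * exp(-(f - f0)^2 / (2 * sigma_f^2))
  H[f > fs / 2] <- 0  # suppress negative-frequency half
  stats::fft(stats::fft(signal) * H, inverse = TRUE) / n
}

#' Half-width of the Gabor envelope at half maximum
#' @param sigma_f Frequency-domain SD in Hz.
#' @return Half the full width at half maximum of the time envelope, s.
#' @export
gabor_time_halfwidth <- function(sigma_f = 0.25) {
  sqrt(2 * log(2)) / (2 * pi * sigma_f)
}

#' Hue-domain resolution of the temporal filter
#'
#' Converts a temporal half-width to hue degrees at the sweep rate
#' (15 deg/s for a 24-s hue cycle).
#'
#' @param half_width_s Temporal half-width in seconds.
#' @param sweep_rate_deg_s Hue sweep rate, deg/s.
#' @return Half-width in degrees of hue.
#' @export
hue_resolution_deg <- function(half_width_s, sweep_rate_deg_s = 15) {
  half_width_s * sweep_rate_deg_s
}

#' Amplitude and phase-derived latency from a complex SSVEP profile
#'
#' Amplitude is the modulus. The phase phi of the complex SSVEP amplitude
#' is measured relative to the stimulation cycle: the Gabor output is
#' demodulated by the 5 Hz carrier (`z * exp(-2i*pi*f0*t)`, with t the
#' within-reconstruction time; epochs are cut on 1-s boundaries so the
#' carrier phase is consistent across the reconstruction). Latency is then
#' `L = -(phi - pi/2) / (2 * pi * f)`, reported in milliseconds and
#' unwrapped into one 200 ms stimulation cycle `[0, 200)`; the `pi/2`
#' offset accounts for the phase of stimulation.
#'
#' @param z Complex vector (output of [gabor_transform()]), or directly a
#'   demodulated phase if `demodulate = FALSE` finds `z` already baseband.
#' @param f0 Stimulation frequency in Hz.
#' @param fs Sampling rate in Hz (for demodulation).
#' @param demodulate Remove the carrier before reading the phase
#'   (default TRUE; set FALSE if `z` is already a baseband complex
#'   amplitude).
#' @return List with `amplitude` and `latency_ms`.
#' @export
complex_to_amplitude_latency <- function(z, f0 = SSVEP_HZ,
                                         fs = SAMPLING_RATE_HZ,
                                         demodulate = TRUE) {
  if (demodulate) {
    t <- (seq_along(z) - 1L) / fs
    z <- z * exp(-2i * pi * f0 * t)
  }
  phi <- Arg(z)
  latency_ms <- (-(phi - pi / 2) / (2 * pi * f0) * 1000) %% (1000 / f0)
  list(amplitude = Mod(z), latency_ms = latency_ms)
}

#' Amplitude and latency profile of one condition, ascending in hue
#'
#' Runs the Gabor transform on a reconstruction and returns per-sample
#' amplitude and latency reordered to an ascending hue grid (clockwise
#' reconstructions are reversed; the reversed grids of the two directions
#' coincide sample-for-sample).
#'
#' @param recon A `reconstruction`.
#' @param sigma_f Gabor frequency SD.
#' @return Tibble with `hue_deg`, `amplitude`, `latency_ms`.
#' @export
condition_profile <- function(recon, sigma_f = 0.25) {
  z <- gabor_transform(recon$signal, fs = recon$fs, sigma_f = sigma_f)
  al <- complex_to_amplitude_latency(z)
  out <- tibble::tibble(hue_deg = recon$hue_deg,
                        amplitude = al$amplitude,
                        latency_ms = al$latency_ms)
  out[order(out$hue_deg), ]
}

#' Full extraction for one participant's recordings
#'
#' Epochs, rejects, re-references and reconstructs every contrast x
#' direction condition of one participant, returning tidy profiles.
#'
#' @param recordings List of `eeg_recording` (all trials of one participant).
#' @param channel Analysis channel.
#' @param peak_to_peak_threshold_uv Artifact rejection threshold.
#' @param sigma_f Gabor frequency SD.
#' @return List with `profiles` (tibble: contrast, direction, hue_deg,
#'   amplitude, latency_ms), `rejection_rate`, `peak_channel`.
#' @export
extract_participant <- function(recordings, channel = "Iz",
                                peak_to_peak_threshold_uv = 100,
                                sigma_f = 0.25) {
  sels <- lapply(recordings, function(rec) {
    ep <- reject_artifacts(epoch_and_label(rec), peak_to_peak_threshold_uv)
    rereference_and_select(ep, channel)
  })
  labs <- dplyr::bind_rows(lapply(sels, `[[`, "labels"))
  conds <- unique(labs[, c("contrast", "direction")])
  profs <- lapply(seq_len(nrow(conds)), function(i) {
    sub <- Filter(function(s) {
      s$labels$contrast[1] == conds$contrast[i] &&
        s$labels$direction[1] == conds$direction[i]
    }, sels)
    pr <- condition_profile(average_and_reconstruct(pool_epochs(sub)),
                            sigma_f = sigma_f)
    pr$contrast <- conds$contrast[i]
    pr$direction <- conds$direction[i]
    pr
  })
  amp5 <- Reduce(`+`, lapply(sels, `[[`, "amp_5hz_by_channel")) / length(sels)
  list(
    profiles = dplyr::bind_rows(profs),
    rejection_rate = mean(labs$artifact),
    peak_channel = names(amp5)[which.max(amp5)],
    amp_5hz_by_channel = amp5
  )
}

#' Normalize amplitudes within participants and average
#'
#' Divides each participant's amplitudes by a single scalar: the mean over
#' all samples of all three contrast conditions (both directions), so the
#' participant's overall amplitude has mean 1 and per-participant gain
#' cancels. Direction conditions are then averaged on the shared hue grid
#' and the grand mean across participants is returned (latency averaged
#' without normalization).
#'
#' @param profiles Tibble with `participant`, `contrast`, `direction`,
#'   `hue_deg`, `amplitude`, `latency_ms` (from [extract_participant()],
#'   one per participant, row-bound with a participant column).
#' @return List with `participant` (per-participant, direction-averaged,
#'   normalized tibble) and `grand` (contrast x hue grand-mean tibble).
#' @export
normalize_and_average <- function(profiles) {
  stopifnot(length(unique(profiles$contrast)) == 3L)
  norm <- profiles |>
    dplyr::group_by(.data$participant) |>
    dplyr::mutate(amplitude = {
      m <- mean(.data$amplitude)
      if (m == 0) stop("zero mean amplitude; cannot normalize")
      .data$amplitude / m
    }) |>
    dplyr::ungroup()
  by_p <- norm |>
    dplyr::group_by(.data$participant, .data$contrast, .data$hue_deg) |>
    dplyr::summarise(amplitude = mean(.data$amplitude),
                     latency_ms = mean(.data$latency_ms), .groups = "drop")
  grand <- by_p |>
    dplyr::group_by(.data$contrast, .data$hue_deg) |>
    dplyr::summarise(amplitude = mean(.data$amplitude),
                     latency_ms = mean(.data$latency_ms), .groups = "drop")
  list(participant = by_p, grand = grand)
}

#' Correct a hue profile for the Gabor filter's hue-domain smoothing
#'
#' The Gabor filter's Gaussian frequency response smooths the extracted
#' profile along hue (at 15 deg/s sweep, hue harmonic k corresponds to a
#' frequency offset of k/24 Hz and is attenuated by
#' `exp(-(k/24)^2 / (2*sigma_f^2))`, about 5% for the elliptical second
#' harmonic). When recovering the *generating* tuning parameters of
#' synthetic data this known kernel can be divided out exactly (circular
#' deconvolution of the full-circle profile). Harmonics whose gain falls
#' below `min_gain` are left untouched to avoid noise amplification. Do
#' not apply when reporting profiles on the measurement's own terms.
#'
#' @param values Profile samples over one full hue circle (ascending hue,
#'   uniform grid).
#' @param sigma_f Gabor frequency SD in Hz.
#' @param cycle_s Duration of one hue cycle in seconds (default 24).
#' @param min_gain Smallest harmonic gain that is corrected.
#' @return Deconvolved profile samples.
#' @export
deconvolve_profile <- function(values, sigma_f = 0.25, cycle_s = 24,
                               min_gain = 0.05) {
  n <- length(values)
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))  # signed harmonic numbers
  g <- exp(-(k / cycle_s)^2 / (2 * sigma_f^2))
  g[g < min_gain] <- 1
  Re(stats::fft(stats::fft(values) / g, inverse = TRUE)) / n
}

#' Amplitude spectrum of a reconstructed signal
#' @param signal Real signal.
#' @param fs Sampling rate, Hz.
#' @return Tibble `freq_hz`, `amplitude` (single-sided, amplitude units).
#' @export
amplitude_spectrum <- function(signal, fs = SAMPLING_RATE_HZ) {
  n <- length(signal)
  half <- seq_len(floor(n / 2) + 1L)
  amp <- Mod(stats::fft(signal))[half] * 2 / n
  amp[1] <- amp[1] / 2
  tibble::tibble(freq_hz = (half - 1L) * fs / n, amplitude = amp)
}

#' Contrast-response summary: amplitude vs log cone contrast
#'
#' Ordinary least-squares slope of mean 5 Hz amplitude against log10
#' contrast scale per participant, with a one-sample t-test on the slopes
#' across participants (positive slope = amplitude grows with contrast).
#'
#' @param participant_profiles Tibble with `participant`, `contrast`,
#'   `amplitude` (per-sample or pre-averaged).
#' @return List with `slopes` tibble (participant, slope), `t_test`
#'   (htest, or NULL for a single participant).
#' @export
contrast_response_summary <- function(participant_profiles) {
  scales <- c(quarter = 0.25, half = 0.5, full = 1.0)
  means <- participant_profiles |>
    dplyr::group_by(.data$participant, .data$contrast) |>
    dplyr::summarise(amplitude = mean(.data$amplitude), .groups = "drop")
  if (length(unique(means$contrast)) < 3L) stop("need 3 contrast levels")
  means$log_contrast <- log10(scales[means$contrast])
  slopes <- means |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(slope = stats::coef(
      stats::lm(amplitude ~ log_contrast,
                data = dplyr::pick(dplyr::everything())))[["log_contrast"]],
      .groups = "drop")
  t_test <- if (nrow(slopes) > 1L && stats::sd(slopes$slope) > 0) {
    stats::t.test(slopes$slope)
  } else {
    NULL  # single participant or identical slopes: no group test
  }
  list(slopes = slopes, t_test = t_test)
}

#' Write extracted profiles to CSV
#' @param profiles Tibble of profiles.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(as.data.frame(profiles), path, row.names = FALSE)
  invisible(path)
}
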
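# Synthetic multichannel EEG with a hue-tuned 5 Hz SSVEP.
#
# The generator embeds, at each occipitally weighted channel, a 5 Hz
# sinusoid whose instantaneous amplitude and phase follow ground-truth
# hue-tuning profiles A(theta) and Lat(theta), plus 1/f background noise
# and blink-like artifacts. The phase convention is chosen so that the
# phase-to-latency relation L = -(phi - pi/2)/(2*pi*f) applied to the
# generated signal returns the generating latency.

SAMPLING_RATE_HZ <- 250
SSVEP_HZ <- 5

#' Ground-truth hue-tuning profile for the generator
#'
#' Amplitude (in microvolts at the source) and latency (ms within one
#' 200 ms stimulation cycle) as smooth elliptical functions of hue.
#'
#' @param amp_ellipse `ellipse_params` whose polar radius (times `gain`)
#'   gives the SSVEP amplitude in microvolts.
#' @param lat_ellipse `ellipse_params` whose polar radius is read as
#'   latency in milliseconds (must stay within `[0, 200)`).
#' @param gain Overall source amplitude scale in microvolts (>= 0; zero
#'   disables the SSVEP source entirely, useful for noise-floor checks).
#' @return A `tuning_profile` with functions `amplitude_fn(theta)` and
#'   `latency_fn(theta)` and the generating parameters.
#' @export
make_tuning_profile <- function(amp_ellipse, lat_ellipse, gain = 1) {
  if (gain < 0) stop("gain must be nonnegative")
  if (lat_ellipse$a >= 200) stop("latency ellipse leaves the 200 ms cycle")
  force(amp_ellipse); force(lat_ellipse); force(gain)
  structure(list(
    amplitude_fn = function(theta) gain * radius_at(amp_ellipse, theta),
    latency_fn = function(theta) radius_at(lat_ellipse, theta),
    amp_ellipse = amp_ellipse, lat_ellipse = lat_ellipse, gain = gain
  ), class = "tuning_profile")
}

#' Noise and artifact specification
#'
#' @param pink_sigma Standard deviation of the 1/f background per channel
#'   (microvolts; 0 disables noise).
#' @param slope Spectral exponent of the background (power ~ 1/f^slope).
#' @param line_hz Optional mains frequency to add (NULL = none).
#' @param line_amp Mains amplitude in microvolts.
#' @param artifact_rate Probability of a blink artifact per 1-s epoch.
#'   The default, with the default blink amplitude and a 100 uV
#'   peak-to-peak rejection threshold, yields a rejection rate near 9%.
#' @param artifact_amp Peak blink amplitude in microvolts.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(pink_sigma = 8, slope = 1, line_hz = NULL,
                       line_amp = 0, artifact_rate = 0.09,
                       artifact_amp = 300) {
  stopifnot(pink_sigma >= 0, slope >= 0, artifact_rate >= 0,
            artifact_rate <= 1, artifact_amp >= 0, line_amp >= 0)
  structure(list(pink_sigma = pink_sigma, slope = slope, line_hz = line_hz,
                 line_amp = line_amp, artifact_rate = artifact_rate,
                 artifact_amp = artifact_amp), class = "noise_spec")
}

#' Default 32-channel montage
#'
#' 29 scalp channels plus 3 EOG channels. Each channel has a gain in
#' `[0, 1]` for the occipital SSVEP source; the maximum (1.0) is at Iz,
#' falling off toward anterior sites. EOG channels carry no SSVEP but
#' receive blink artifacts, as do the frontopolar channels.
#'
#' @return A `montage` tibble with columns `channel`, `type` ("eeg"/"eog"),
#'   `ssvep_gain`, `blink_gain`.
#' @export
default_montage <- function() {
  eeg <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
           "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
           "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
           "O1", "Oz", "O2", "Iz")
  # anterior-posterior position index 0 (frontal) .. 1 (inion)
  ap <- c(0, 0, .15, .15, .15, .15, .15, .3, .3, .3, .3, .45, .45, .45, .45,
          .45, .6, .6, .6, .6, .75, .75, .75, .75, .75, .9, .9, .9, 1)
  tibble::tibble(
    channel = c(eeg, "EOGl", "EOGr", "EOGb"),
    type = c(rep("eeg", length(eeg)), rep("eog", 3)),
    ssvep_gain = c(0.05 + 0.95 * ap^2, 0, 0, 0),
    blink_gain = c(ifelse(eeg %in% c("Fp1", "Fp2"), 0.6, 0), 1, 1, 1)
  )
}

# deterministic 1/f^slope noise, one channel, via spectral shaping
pink_noise <- function(n, sigma, slope) {
  if (sigma == 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, n - 1) * (1 / n)
  f <- pmin(f, 1 - f)            # two-sided frequency magnitudes
  shape <- c(0, 1 / f[-1]^(slope / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x * sigma / stats::sd(x)
}

# half-sine blink deflection, fully contained in one epoch
blink_waveform <- function(fs, dur_s = 0.35, amp = 300) {
  n <- round(dur_s * fs)
  amp * sin(pi * seq(0, 1, length.out = n))
}

#' Simulate one hue-sweep trial of multichannel EEG
#'
#' The SSVEP component at channel c is
#' `gain_c * A(theta(t)) * cos(2*pi*5*t + phi(t))` with
#' `phi(t) = pi/2 - 2*pi*5*Lat(theta(t))/1000`, where `theta(t)` is the
#' schedule's current (per-on-phase) hue, held through off phases: the
#' 100 ms on/off flicker is the cause of the 5 Hz response, so the response
#' itself is modeled as a continuous sinusoid for the whole trial. Pink
#' noise is added per channel and blink artifacts are injected on EOG and
#' frontopolar channels in randomly chosen 1-s epochs.
#'
#' @param schedule A `sweep_schedule`.
#' @param profile A `tuning_profile`.
#' @param noise A `noise_spec` (use `noise_spec(0, artifact_rate = 0)` for
#'   a noiseless trial).
#' @param montage A montage tibble (default [default_montage()]).
#' @param seed Integer seed; the same seed yields a bit-identical trial.
#' @return An `eeg_recording`: list with `samples` (channels x time matrix,
#'   microvolts), `fs`, `montage`, `schedule`, and `ground_truth` (profile
#'   plus artifact epoch indices).
#' @export
simulate_trial <- function(schedule, profile, noise = noise_spec(),
                           montage = default_montage(), seed = 1L) {
  fs <- SAMPLING_RATE_HZ
  trial_s <- attr(schedule, "trial_s")
  n <- round(trial_s * fs)
  t <- (seq_len(n) - 1L) / fs
  theta <- schedule_hue_at_time(schedule, t)
  A <- profile$amplitude_fn(theta)
  phi <- pi / 2 - 2 * pi * SSVEP_HZ * profile$latency_fn(theta) / 1000
  src <- A * cos(2 * pi * SSVEP_HZ * t + phi)

  set.seed(seed)
  n_ch <- nrow(montage)
  samples <- montage$ssvep_gain %o% src
  if (noise$pink_sigma > 0) {
    for (ci in seq_len(n_ch)) {
      samples[ci, ] <- samples[ci, ] +
        pink_noise(n, noise$pink_sigma, noise$slope)
    }
  }
  if (noise$line_amp > 0 && !is.null(noise$line_hz)) {
    samples <- samples + rep(1, n_ch) %o%
      (noise$line_amp * sin(2 * pi * noise$line_hz * t))
  }
  artifact_epochs <- integer(0)
  if (noise$artifact_rate > 0 && noise$artifact_amp > 0) {
    n_ep <- floor(trial_s)
    hit <- which(stats::runif(n_ep) < noise$artifact_rate)
    bw <- blink_waveform(fs, amp = noise$artifact_amp)
    for (e in hit) {
      start <- (e - 1L) * fs + sample.int(fs - length(bw), 1L)
      idx <- start + seq_along(bw)
      samples[, idx] <- samples[, idx] + montage$blink_gain %o% bw
    }
    artifact_epochs <- hit - 1L  # 0-based trial seconds, matching epoch labels
  }
  rownames(samples) <- montage$channel
  structure(list(
    samples = samples, fs = fs, montage = montage, schedule = schedule,
    ground_truth = list(profile = profile, artifact_epochs = artifact_epochs,
                        seed = seed)
  ), class = "eeg_recording")
}

#' Build the trial design of a full experiment
#'
#' Each session holds all 3 contrast x 2 direction conditions 6 times each;
#' the 6 repetitions of a condition within a session use 6 evenly spaced
#' start sectors, rotated by one sector per session so that the 4 sessions
#' jointly cover all 24 start sectors once per condition. Trial order within
#' a session is randomized.
#'
#' @param n_participants Number of participants (cohort analysed: 16).
#' @param sessions Sessions per participant (default 4).
#' @param trials_per_session Default 36 (= 6 conditions x 6 starts).
#' @param seed Seed for the per-session trial-order shuffles.
#' @return Tibble with one row per trial: participant, session, trial,
#'   contrast, direction, start_sector.
#' @export
experiment_design <- function(n_participants = 16L, sessions = 4L,
                              trials_per_session = 36L, seed = 1L) {
  if (trials_per_session %% 6L != 0L) {
    stop("trials_per_session must divide into 6 conditions x 6 start sectors")
  }
  reps <- trials_per_session %/% 6L
  set.seed(seed)
  rows <- list()
  for (p in seq_len(n_participants)) {
    for (s in seq_len(sessions)) {
      cond <- expand.grid(
        contrast = c("quarter", "half", "full"),
        direction = c("counterclockwise", "clockwise"),
        rep = seq_len(reps), stringsAsFactors = FALSE
      )
      # evenly spaced start sectors, rotated per session
      cond$start_sector <- ((s - 1L) + 4L * (cond$rep - 1L)) %% 24L
      cond <- cond[sample.int(nrow(cond)), ]
      cond$participant <- p
      cond$session <- s
      cond$trial <- seq_len(nrow(cond))
      rows[[length(rows) + 1L]] <- cond
    }
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  out[, c("participant", "session", "trial", "contrast", "direction",
          "start_sector")]
}

#' Simulate a full (possibly scaled-down) experiment
#'
#' Generates every trial of [experiment_design()] with the given per-contrast
#' tuning profiles. Per-participant gain variability multiplies each
#' participant's source amplitude by a lognormal factor.
#'
#' @param profiles Named list (`quarter`, `half`, `full`) of
#'   `tuning_profile` objects.
#' @param n_participants,sessions,trials_per_session Design counts.
#' @param noise A `noise_spec`.
#' @param montage Montage tibble.
#' @param gain_sd_log SD of the per-participant log gain factor (0 = none).
#' @param seed Master seed; trial seeds are derived deterministically.
#' @return List with `design` (tibble, one row per trial including the
#'   participant gain factor) and `recordings` (list of `eeg_recording`
#'   in design row order).
#' @export
simulate_experiment <- function(profiles,
                                n_participants = 16L, sessions = 4L,
                                trials_per_session = 36L,
                                noise = noise_spec(),
                                montage = default_montage(),
                                gain_sd_log = 0.2, seed = 1L) {
  stopifnot(all(c("quarter", "half", "full") %in% names(profiles)))
  design <- experiment_design(n_participants, sessions, trials_per_session,
                              seed = seed)
  set.seed(seed + 1L)
  pgain <- exp(stats::rnorm(n_participants, 0, gain_sd_log))
  design$participant_gain <- pgain[design$participant]
  trial_seeds <- sample.int(.Machine$integer.max %/% 2L, nrow(design))
  recordings <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    prof0 <- profiles[[row$contrast]]
    prof <- make_tuning_profile(prof0$amp_ellipse, prof0$lat_ellipse,
                                gain = prof0$gain * row$participant_gain)
    sched <- build_sweep_schedule(row$direction, row$start_sector,
                                  level = row$contrast)
    recordings[[i]] <- simulate_trial(sched, prof, noise, montage,
                                      seed = trial_seeds[i])
  }
  list(design = design, recordings = recordings)
}

#' Default generating profiles per contrast condition
#'
#' Amplitude ellipses follow the published grand-mean fits (orientations
#' 15.6 / 18.8 / 28.3 deg for quarter / half / full, modest aspect ratios),
#' and latency ellipses the published radii: quarter (129, 109), half
#' (113, 99), full (103, 88) ms, oriented ~82 deg (longest latencies near
#' the S axis). Source gains are spaced so the 5 Hz amplitude is linear in
#' log contrast.
#'
#' @param base_gain Full-contrast source amplitude in microvolts.
#' @return Named list of `tuning_profile`s (quarter, half, full).
#' @export
default_profiles <- function(base_gain = 2.0) {
  # equal log-contrast steps: amplitude linear in log contrast
  g <- base_gain * c(quarter = 0.5, half = 0.75, full = 1.0)
  list(
    quarter = make_tuning_profile(
      ellipse_params(15.6, 1.15, 1.0), ellipse_params(82.1, 129, 109),
      gain = g[["quarter"]]),
    half = make_tuning_profile(
      ellipse_params(18.8, 1.2, 1.0), ellipse_params(81.66, 113, 99),
      gain = g[["half"]]),
    full = make_tuning_profile(
      ellipse_params(28.3, 1.25, 1.0), ellipse_params(82.7, 103, 88),
      gain = g[["full"]])
  )
}
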
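quiet_noise <- function() noise_spec(pink_sigma = 0, artifact_rate = 0)

noiseless_epochs <- function(direction = "counterclockwise", s0 = 3,
                             profile = default_profiles()$full) {
  rec <- simulate_trial(build_sweep_schedule(direction, s0), profile,
                        quiet_noise(), seed = 1)
  epoch_and_label(rec)
}

test_that("trials split into 24 retained, sector-labeled, detrended epochs", {
  ep <- noiseless_epochs("counterclockwise", 3)
  expect_equal(dim(ep$data), c(32, 250, 24))
  expect_equal(ep$labels$second, 1:24)                 # first second discarded
  expect_equal(ep$labels$sector, (3 + 1:24) %% 24)
  ep2 <- noiseless_epochs("clockwise", 3)
  expect_equal(ep2$labels$sector, (3 - 1:24) %% 24)
  # linear drift is removed without touching the 5 Hz content
  rec <- simulate_trial(build_sweep_schedule("counterclockwise", 0),
                        default_profiles()$full, quiet_noise(), seed = 1)
  drift <- matrix(rep(seq(0, 50, length.out = ncol(rec$samples)),
                      each = nrow(rec$samples)), nrow = nrow(rec$samples))
  rec_d <- rec; rec_d$samples <- rec$samples + drift
  epd <- epoch_and_label(rec_d)
  ep0 <- epoch_and_label(rec)
  expect_equal(epd$data, ep0$data, tolerance = 1e-8)
})

test_that("short recordings are rejected", {
  rec <- simulate_trial(build_sweep_schedule("counterclockwise", 0),
                        default_profiles()$full, quiet_noise(), seed = 1)
  rec$schedule <- build_sweep_schedule("counterclockwise", 0, trial_s = 20)
  attr(rec$schedule, "trial_s") <- 20
  expect_error(epoch_and_label(rec), "shorter")
})

test_that("peak-to-peak rejection flags injected blinks and spares clean data", {
  prof <- default_profiles()$full
  rec <- simulate_trial(build_sweep_schedule("counterclockwise", 0), prof,
                        noise_spec(pink_sigma = 2, artifact_rate = 0.3,
                                   artifact_amp = 300), seed = 21)
  ep <- reject_artifacts(epoch_and_label(rec))
  truth_epochs <- rec$ground_truth$artifact_epochs   # 0-based trial seconds
  flagged <- ep$labels$second[ep$labels$artifact]
  expect_setequal(flagged, intersect(truth_epochs, 1:24))
  clean <- simulate_trial(build_sweep_schedule("counterclockwise", 0), prof,
                          noise_spec(pink_sigma = 2, artifact_rate = 0),
                          seed = 3)
  expect_false(any(reject_artifacts(epoch_and_label(clean))$labels$artifact))
})

test_that("default generator settings reject about 9% of epochs", {
  sim <- simulate_experiment(default_profiles(), n_participants = 1,
                             sessions = 1, trials_per_session = 36, seed = 5)
  rates <- vapply(sim$recordings, function(rec) {
    mean(reject_artifacts(epoch_and_label(rec))$labels$artifact)
  }, numeric(1))
  expect_gt(mean(rates), 0.07)
  expect_lt(mean(rates), 0.11)
})

test_that("average re-referencing removes common offsets and is idempotent", {
  ep <- noiseless_epochs()
  ep_off <- ep
  ep_off$data <- ep$data + 40                        # common offset everywhere
  s1 <- rereference_and_select(ep, "Iz")
  s2 <- rereference_and_select(ep_off, "Iz")
  expect_equal(s2$amp, s1$amp, tolerance = 1e-10)
  # re-referencing twice equals once: rebuild epochs from referenced data
  ep_ref <- ep
  eeg <- which(ep$montage$type == "eeg")
  ref <- colMeans(ep$data[eeg, , , drop = FALSE])
  for (ci in eeg) ep_ref$data[ci, , ] <- ep_ref$data[ci, , ] - ref
  s3 <- rereference_and_select(ep_ref, "Iz")
  expect_equal(s3$amp, s1$amp, tolerance = 1e-10)
  expect_error(rereference_and_select(ep, "Nope"), "montage")
})

test_that("the 5 Hz diagnostic singles out Iz for an occipital source", {
  ep <- noiseless_epochs()
  s <- rereference_and_select(ep, "Oz")
  expect_equal(s$peak_channel, "Iz")
  expect_equal(names(which.max(s$amp_5hz_by_channel)), "Iz")
})

test_that("sector means concatenate into a 6000-sample hue-labeled signal", {
  ep <- noiseless_epochs("counterclockwise", 7)
  sel <- rereference_and_select(ep, "Iz")
  recon <- average_and_reconstruct(sel)
  expect_length(recon$signal, 6000)
  expect_length(recon$hue_deg, 6000)
  expect_equal(recon$n_epochs_per_sector, rep(1L, 24))
  # single epochs: reconstruction is a re-ordering of the epochs themselves
  k <- ep$labels$sector[1]
  expect_equal(recon$signal[k * 250 + 1:250], sel$amp[1, ])
  # identical epochs average to any one of them
  sel2 <- sel
  sel2$amp <- matrix(rep(sel$amp[1, ], 24), nrow = 24, byrow = TRUE)
  sel2$labels$sector <- 0:23
  recon2 <- average_and_reconstruct(sel2)
  expect_equal(unname(recon2$signal[1:250]), unname(sel$amp[1, ]))
  # an empty sector is a named error
  sel3 <- sel
  sel3$labels$artifact[sel3$labels$sector == 9] <- TRUE
  expect_error(average_and_reconstruct(sel3), "sector 9")
})

test_that("Gabor modulus matches FFT amplitude for stationary sinusoids", {
  t <- (0:5999) / 250
  for (a in c(1, 2.5)) {
    x <- a * cos(2 * pi * 5 * t + 0.7)
    z <- gabor_transform(x)
    expect_equal(Mod(z), rep(a, 6000), tolerance = 1e-6)
    sp <- amplitude_spectrum(x)
    expect_equal(sp$amplitude[sp$freq_hz == 5], a, tolerance = 1e-6)
  }
})

test_that("Gabor tracks slow amplitude modulation and kills remote frequencies", {
  t <- (0:5999) / 250
  A <- 1 + 0.3 * sin(2 * pi * t / 24)               # 24-s modulation period
  z <- gabor_transform(A * cos(2 * pi * 5 * t))
  expect_lt(max(abs(Mod(z) - A) / A), 0.02)
  # a 1 Hz component is 4 Hz away: attenuated by exp(-(4)^2/(2*0.25^2)) ~ 0
  z1 <- gabor_transform(cos(2 * pi * 1 * t))
  expect_lt(max(Mod(z1)), 1e-10)
})

test_that("phase converts to latency within one 200 ms cycle", {
  mk <- function(phi) complex(modulus = 1, argument = phi)
  out <- complex_to_amplitude_latency(mk(pi / 2), demodulate = FALSE)
  expect_equal(out$latency_ms, 0)
  expect_equal(complex_to_amplitude_latency(mk(-pi / 2),
                                            demodulate = FALSE)$latency_ms, 100)
  expect_equal(complex_to_amplitude_latency(mk(pi / 2 - 2 * pi * 5 * 0.13),
                                            demodulate = FALSE)$latency_ms, 130)
  # any phase lands in [0, 200)
  phis <- seq(-10, 10, by = 0.1)
  lat <- complex_to_amplitude_latency(mk(1) * exp(1i * phis),
                                      demodulate = FALSE)$latency_ms
  expect_true(all(lat >= 0 & lat < 200))
})

test_that("noiseless pipeline recovers the generating tuning profile", {
  rt <- noiseless_roundtrip(psi = 28.3, aspect = 1.25)
  expect_lt(max(abs(rt$amp - rt$amp_true) / rt$amp_true), 0.02)
  expect_lt(max(abs(rt$lat - rt$lat_true)), 2)
  expect_true(all(rt$lat >= 0 & rt$lat < 200))
  expect_true(all(rt$amp >= 0))
})

test_that("direction averaging cancels a hue-independent temporal lag", {
  prof <- make_tuning_profile(ellipse_params(30, 1.5, 1),
                              study_latency_ellipse(), gain = 2)
  shift_n <- 5                                       # 20 ms at 250 Hz
  prof_shift <- function(rec) {
    rec$samples <- cbind(rec$samples[, 1:shift_n],
                         rec$samples[, 1:(ncol(rec$samples) - shift_n)])
    rec
  }
  get_amp <- function(shift) {
    prs <- lapply(c("counterclockwise", "clockwise"), function(d) {
      rec <- simulate_trial(build_sweep_schedule(d, 0), prof, quiet_noise(),
                            seed = 1)
      if (shift) rec <- prof_shift(rec)
      ep <- rereference_and_select(epoch_and_label(rec), "Iz")
      condition_profile(average_and_reconstruct(ep))
    })
    list(single = prs[[1]]$amplitude,
         avg = (prs[[1]]$amplitude + prs[[2]]$amplitude) / 2)
  }
  ref <- get_amp(FALSE)
  lag <- get_amp(TRUE)
  err_single <- max(abs(lag$single - ref$single) / ref$single)
  err_avg <- max(abs(lag$avg - ref$avg) / ref$avg)
  expect_lt(err_avg, err_single / 3)
  expect_lt(err_avg, 0.005)
})

test_that("normalization sets each participant's overall mean to 1", {
  th <- (0:359) * 1.0
  base <- tibble::tibble(
    hue_deg = rep(th, 6),
    contrast = rep(rep(c("quarter", "half", "full"), each = 360), 2),
    direction = rep(c("counterclockwise", "clockwise"), each = 3 * 360),
    latency_ms = 100
  )
  mk <- function(gain) {
    p <- base
    p$amplitude <- gain * rep(rep(c(0.5, 1.0, 1.5), each = 360), 2)
    p
  }
  profs <- dplyr::bind_rows(
    dplyr::mutate(mk(1), participant = 1),
    dplyr::mutate(mk(7), participant = 2)   # 7x overall gain
  )
  out <- normalize_and_average(profs)
  for (p in 1:2) {
    expect_equal(mean(out$participant$amplitude[out$participant$participant == p]),
                 1)
  }
  # gain factor cancels: both participants normalize to the same profile
  a1 <- out$participant$amplitude[out$participant$participant == 1]
  a2 <- out$participant$amplitude[out$participant$participant == 2]
  expect_equal(a1, a2)
  # {1, 3} normalizes to {0.5, 1.5}
  tiny <- tibble::tibble(
    participant = 1,
    hue_deg = rep(c(0, 180), 3),
    contrast = rep(c("quarter", "half", "full"), each = 2),
    direction = "counterclockwise",
    amplitude = rep(c(1, 3), 3), latency_ms = 100
  )
  out2 <- normalize_and_average(tiny)
  expect_equal(sort(unique(out2$participant$amplitude)), c(0.5, 1.5))
})

test_that("contrast response slopes behave for flat and log-linear amplitudes", {
  flat <- tibble::tibble(participant = rep(1:2, each = 3),
                         contrast = rep(c("quarter", "half", "full"), 2),
                         amplitude = 1)
  cr <- contrast_response_summary(flat)
  expect_equal(cr$slopes$slope, c(0, 0))
  loglin <- dplyr::mutate(flat,
    amplitude = 2 + 1.5 * log10(c(quarter = 0.25, half = 0.5, full = 1)[contrast]))
  cr2 <- contrast_response_summary(loglin)
  expect_equal(cr2$slopes$slope, c(1.5, 1.5), tolerance = 1e-9)
  expect_error(contrast_response_summary(flat[flat$contrast != "half", ]),
               "3 contrast")
})

test_that("the amplitude spectrum peaks at the stimulation frequency", {
  t <- (0:5999) / 250
  sp <- amplitude_spectrum(2 * cos(2 * pi * 5 * t) + 0.5 * cos(2 * pi * 9 * t))
  expect_equal(sp$freq_hz[which.max(sp$amplitude)], 5)
  expect_equal(max(sp$amplitude), 2, tolerance = 1e-9)
})

test_that("profile deconvolution undoes the filter's hue smoothing", {
  hue <- (0:5999) * 0.06
  prof <- radius_at(ellipse_params(40, 1.6, 1), hue)
  k <- c(0:3000, -(2999:1))
  g <- exp(-(k / 24)^2 / (2 * 0.25^2))
  smoothed <- Re(fft(fft(prof) * g, inverse = TRUE)) / 6000
  expect_gt(max(abs(smoothed - prof) / prof), 0.015)  # smoothing does bias
  fixed <- deconvolve_profile(smoothed)
  expect_lt(max(abs(fixed - prof) / prof), 1e-4)
})
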
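quiet_noise <- function() noise_spec(pink_sigma = 0, artifact_rate = 0)

test_that("tuning profiles expose elliptical amplitude and latency", {
  p <- make_tuning_profile(ellipse_params(0, 1, 1),
                           ellipse_params(82, 103, 88), gain = 2)
  th <- seq(0, 359, by = 1)
  expect_equal(p$amplitude_fn(th), rep(2, 360))        # circle: hue-invariant
  expect_true(all(p$latency_fn(th) >= 88 & p$latency_fn(th) <= 103))
  p2 <- make_tuning_profile(ellipse_params(30, 1.5, 1),
                            ellipse_params(82, 103, 88), gain = 1)
  expect_equal(max(p2$amplitude_fn(th)) / min(p2$amplitude_fn(th)), 1.5,
               tolerance = 1e-3)
  expect_error(make_tuning_profile(ellipse_params(0, 1, 1),
                                   ellipse_params(82, 103, 88), gain = -1))
})

test_that("the default montage peaks at Iz and carries 3 EOG channels", {
  m <- default_montage()
  expect_equal(nrow(m), 32)
  expect_equal(sum(m$type == "eog"), 3)
  expect_equal(m$channel[which.max(m$ssvep_gain)], "Iz")
  expect_true(all(m$ssvep_gain >= 0 & m$ssvep_gain <= 1))
})

test_that("trials are bit-identical under a fixed seed", {
  prof <- default_profiles()$full
  sched <- build_sweep_schedule("counterclockwise", 2)
  r1 <- simulate_trial(sched, prof, noise_spec(), seed = 99)
  r2 <- simulate_trial(sched, prof, noise_spec(), seed = 99)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$ground_truth$artifact_epochs,
                   r2$ground_truth$artifact_epochs)
  r3 <- simulate_trial(sched, prof, noise_spec(), seed = 100)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("a zero-gain profile leaves no 5 Hz signature above the noise", {
  prof0 <- make_tuning_profile(ellipse_params(0, 1, 1),
                               ellipse_params(82, 103, 88), gain = 0)
  sched <- build_sweep_schedule("counterclockwise", 0)
  amps <- sapply(1:20, function(s) {
    rec <- simulate_trial(sched, prof0, noise_spec(artifact_rate = 0),
                          montage = mini_montage(), seed = s)
    x <- rec$samples["Iz", 1:6000]
    sp <- amplitude_spectrum(x)
    c(at5 = sp$amplitude[which.min(abs(sp$freq_hz - 5))],
      near = mean(sp$amplitude[abs(sp$freq_hz - 5) > 0.2 &
                                 abs(sp$freq_hz - 5) < 1]))
  })
  # 5 Hz bin indistinguishable from neighboring frequencies
  expect_lt(abs(mean(amps["at5", ]) - mean(amps["near", ])),
            3 * sd(amps["at5", ]) / sqrt(20) + 3 * sd(amps["near", ]) / sqrt(20))
})

test_that("SSVEP amplitude scales linearly with source gain", {
  sched <- build_sweep_schedule("counterclockwise", 0)
  amp_at <- function(g) {
    prof <- make_tuning_profile(ellipse_params(20, 1.2, 1),
                                ellipse_params(82, 103, 88), gain = g)
    rec <- simulate_trial(sched, prof, quiet_noise(), seed = 1)
    max(abs(rec$samples["Iz", ]))
  }
  expect_equal(amp_at(3) / amp_at(1), 3, tolerance = 1e-9)
})

test_that("pink noise leaves the 5 Hz complex mean unbiased", {
  sched <- build_sweep_schedule("counterclockwise", 0)
  prof <- make_tuning_profile(ellipse_params(0, 1, 1),
                              ellipse_params(0, 100, 100), gain = 1)
  t <- (0:6249) / 250
  carrier <- exp(-2i * pi * 5 * t)
  z <- sapply(1:100, function(s) {
    rec <- simulate_trial(sched, prof, noise_spec(pink_sigma = 8,
                                                  artifact_rate = 0),
                          montage = mini_montage(), seed = s)
    mean(rec$samples["Iz", ] * carrier) * 2
  })
  gain_iz <- mini_montage()$ssvep_gain[mini_montage()$channel == "Iz"]
  # demodulated complex mean of the clean source over an integer number of
  # cycles: amplitude times exp(i * phase), phase = pi/2 - 2*pi*5*0.1
  truth <- gain_iz * prof$amplitude_fn(0) * exp(1i * (pi / 2 - pi))
  bias <- mean(z) - truth
  se <- sd(Re(z)) / sqrt(100) + sd(Im(z)) / sqrt(100)
  expect_lt(Mod(bias), 3 * se)
})

test_that("blink artifacts land on frontal and EOG channels in flagged epochs", {
  prof <- default_profiles()$full
  sched <- build_sweep_schedule("counterclockwise", 0)
  rec <- simulate_trial(sched, prof,
                        noise_spec(pink_sigma = 0, artifact_rate = 0.5),
                        seed = 12)
  hit <- rec$ground_truth$artifact_epochs
  expect_gt(length(hit), 0)
  e <- hit[1]
  idx <- (e - 1) * 250 + 1:250
  expect_gt(max(rec$samples["EOGl", idx]) - min(rec$samples["EOGl", idx]), 100)
  expect_lt(max(abs(rec$samples["Iz", idx])),
            50)  # no blink leakage into occipital channels (noiseless)
})

test_that("the experiment design balances conditions, starts and sectors", {
  d <- experiment_design(n_participants = 16, sessions = 4,
                         trials_per_session = 36, seed = 2)
  expect_equal(nrow(d), 16 * 4 * 36)
  one <- d[d$participant == 1, ]
  counts <- table(one$contrast, one$direction)
  expect_true(all(counts == 24))  # 24 trials per contrast x direction
  # each hue sector measured 48 times per contrast: every trial covers each
  # sector once among its retained epochs, so measurements = trials
  per_contrast <- table(one$contrast)
  expect_true(all(per_contrast == 48))
  # start sectors within a condition cover all 24 across the 4 sessions
  sub <- one[one$contrast == "full" & one$direction == "clockwise", ]
  expect_setequal(sub$start_sector, 0:23)
  expect_error(experiment_design(trials_per_session = 35), "6 conditions")
})

test_that("simulated experiments honor the design and per-participant gain", {
  sim <- simulate_experiment(default_profiles(), n_participants = 2,
                             sessions = 1, trials_per_session = 6,
                             noise = quiet_noise(), gain_sd_log = 0.3,
                             seed = 7)
  expect_equal(length(sim$recordings), nrow(sim$design))
  expect_equal(nrow(sim$design), 12)
  g <- unique(sim$design[, c("participant", "participant_gain")])
  expect_equal(nrow(g), 2)
  expect_false(g$participant_gain[1] == g$participant_gain[2])
  # recorded ground truth carries the scaled gain
  i <- which(sim$design$participant == 2 & sim$design$contrast == "full")[1]
  expect_equal(sim$recordings[[i]]$ground_truth$profile$gain,
               default_profiles()$full$gain * g$participant_gain[2])
})
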
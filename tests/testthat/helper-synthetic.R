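# Shared fixtures: all synthetic, built in code at test time.

# effective Iz gain after average re-referencing of the default montage
iz_effective_gain <- function() {
  m <- default_montage()
  m$ssvep_gain[m$channel == "Iz"] - mean(m$ssvep_gain[m$type == "eeg"])
}

# small montage for fast noise-only simulations
mini_montage <- function() {
  m <- default_montage()
  m[m$channel %in% c("Iz", "Oz", "Fp1", "EOGl"), ]
}

study_latency_ellipse <- function() ellipse_params(82.7, 103, 88)

# Noiseless simulate -> extract round trip for one generating amplitude
# ellipse, both sweep directions averaged; returns ground truth and the
# extracted (kernel-corrected) profile plus its ellipse fit.
noiseless_roundtrip <- function(psi, aspect, gain = 2,
                                lat_ellipse = study_latency_ellipse(),
                                start_sector = 0) {
  prof <- make_tuning_profile(ellipse_params(psi, aspect, 1), lat_ellipse,
                              gain = gain)
  prs <- lapply(c("counterclockwise", "clockwise"), function(d) {
    rec <- simulate_trial(build_sweep_schedule(d, start_sector), prof,
                          noise_spec(pink_sigma = 0, artifact_rate = 0),
                          seed = 1)
    ep <- rereference_and_select(reject_artifacts(epoch_and_label(rec)), "Iz")
    condition_profile(average_and_reconstruct(ep))
  })
  stopifnot(max(abs(prs[[1]]$hue_deg - prs[[2]]$hue_deg)) == 0)
  hue <- prs[[1]]$hue_deg
  amp <- deconvolve_profile((prs[[1]]$amplitude + prs[[2]]$amplitude) / 2)
  lat <- (prs[[1]]$latency_ms + prs[[2]]$latency_ms) / 2
  fit <- fit_profile_ellipse(hue, amp)
  list(
    hue = hue, amp = amp, lat = lat, fit = fit, profile = prof,
    amp_true = iz_effective_gain() * prof$amplitude_fn(hue),
    lat_true = prof$latency_fn(hue)
  )
}

# smallest absolute axial (period-180) angular difference in degrees
axial_abs_diff <- function(x, y) {
  d <- abs((x - y) %% 180)
  pmin(d, 180 - d)
}

# Brute-force oracle for origin-centered ellipse fitting: grid over
# (psi, aspect) with the closed-form optimal scale, minimizing the radial
# (geometric) RSS. Independent of the conic algebra in fit_ellipse.
grid_search_ellipse <- function(hue_deg, radius,
                                psi_grid = seq(0, 179, by = 1),
                                aspect_grid = seq(1, 2, by = 0.01)) {
  best <- list(rss = Inf)
  for (q in aspect_grid) {
    for (psi in psi_grid) {
      g <- radius_at(ellipse_params(psi, q, 1), hue_deg)  # unit minor axis
      b <- sum(radius * g) / sum(g^2)
      rss <- sum((radius - b * g)^2)
      if (rss < best$rss) best <- list(rss = rss, psi = psi, a = q * b, b = b)
    }
  }
  best
}

# Synthetic "chips": reflectance spectra whose cone-contrast locus is an
# exact ellipse around the EEW background, for munsell_ellipse tests.
synthetic_chip_set <- function(psi, aspect, scale = 0.05, n_chips = 40) {
  wl <- seq(400, 700, by = 10)
  gauss <- function(mu, sd) exp(-(wl - mu)^2 / (2 * sd^2))
  fund <- cbind(L = gauss(570, 50), M = gauss(540, 45), S = gauss(445, 30))
  theta <- seq(0, 360, length.out = n_chips + 1)[-(n_chips + 1)]
  e <- ellipse_params(psi, aspect, 1)
  r <- radius_at(e, theta)
  # cone contrasts on an exact ellipse in the axis-normalized plane
  dL <- 0.08 * scale * r * cos(theta * pi / 180) / max(r)
  dS <- 0.80 * scale * r * sin(theta * pi / 180) / max(r)
  # each chip is the flat background reflectance plus the least-norm
  # spectral perturbation p solving t(fund) %*% p = target excitations
  bg <- colSums(fund)
  refl <- sapply(seq_along(theta), function(i) {
    target <- c(L = dL[i] * bg[["L"]], M = 0, S = dS[i] * bg[["S"]])
    p <- fund %*% solve(crossprod(fund), target)
    1 + as.vector(p)
  })
  list(reflectance = refl, fundamentals = fund, theta = theta,
       truth = list(psi = psi, aspect = aspect))
}
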
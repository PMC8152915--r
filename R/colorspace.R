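# Cone-contrast color space, hue sectors and hue-sweep stimulus schedules.
#
# Hues live in a 2-D cone-contrast plane with axes dL/L (L-M opponent) and
# dS/S (S opponent). The two axes are scaled 1:10 (full-contrast maxima 8%
# L-cone and 80% S-cone contrast), and hue angle theta is the azimuth in the
# axis-normalized plane: 0 deg = +L ("red"), 90 deg = +S ("lavender").

#' Maximum cone contrasts of the full-contrast hue circle
#'
#' The full-contrast stimulus locus reaches 8% L-cone contrast on the L-M
#' axis and 80% S-cone contrast on the S axis (a 1:10 axis scaling).
#' @keywords internal
MAX_L_CONTRAST <- 0.08

#' @rdname MAX_L_CONTRAST
#' @keywords internal
MAX_S_CONTRAST <- 0.80

#' Chromatic contrast levels
#'
#' The three chromatic contrast conditions scale the full-contrast hue
#' circle by 1, 1/2 and 1/4.
#'
#' @param name One of `"full"`, `"half"`, `"quarter"`.
#' @return A `contrast_level` object with fields `name` and `scale`.
#' @examples
#' contrast_level("half")$scale  # 0.5
#' @export
contrast_level <- function(name = c("full", "half", "quarter")) {
  name <- match.arg(name)
  scale <- c(full = 1.0, half = 0.5, quarter = 0.25)[[name]]
  structure(list(name = name, scale = scale), class = "contrast_level")
}

#' All three contrast levels, in increasing contrast order
#' @return List of `contrast_level` objects named quarter, half, full.
#' @export
contrast_levels <- function() {
  lv <- lapply(c("quarter", "half", "full"), contrast_level)
  names(lv) <- c("quarter", "half", "full")
  lv
}

wrap_deg <- function(theta) theta %% 360

#' Map a hue angle to cone-contrast coordinates
#'
#' The hue circle at a given contrast level is an ellipse in raw cone
#' contrast: `(0.08 * scale * cos(theta), 0.80 * scale * sin(theta))`.
#'
#' @param theta Hue angle(s) in degrees (wrapped mod 360).
#' @param level A `contrast_level` (or its name).
#' @return A tibble with columns `dL_over_L` and `dS_over_S`.
#' @export
hue_to_cone_contrast <- function(theta, level = contrast_level("full")) {
  if (is.character(level)) level <- contrast_level(level)
  th <- wrap_deg(theta) * pi / 180
  tibble::tibble(
    dL_over_L = MAX_L_CONTRAST * level$scale * cos(th),
    dS_over_S = MAX_S_CONTRAST * level$scale * sin(th)
  )
}

#' Recover the hue angle of a cone-contrast point
#'
#' Inverse of [hue_to_cone_contrast()] up to contrast scale: the angle is
#' computed in axis-normalized coordinates (each axis divided by its
#' full-contrast maximum), so the full-contrast locus is a unit circle.
#'
#' @param dL_over_L,dS_over_S Cone contrasts of the point(s).
#' @return Hue angle(s) in degrees in `[0, 360)`.
#' @export
cone_contrast_to_hue <- function(dL_over_L, dS_over_S) {
  if (any(dL_over_L == 0 & dS_over_S == 0)) {
    stop("hue is undefined at the achromatic origin")
  }
  wrap_deg(atan2(dS_over_S / MAX_S_CONTRAST, dL_over_L / MAX_L_CONTRAST) * 180 / pi)
}

#' Hue sector of a hue angle
#'
#' The hue circle is divided into 24 contiguous 15-deg sectors; sector k
#' covers the half-open range `[15k, 15(k+1))`, so a boundary hue belongs to
#' the upper sector.
#'
#' @param theta Hue angle(s) in degrees.
#' @return Integer sector index 0-23.
#' @export
sector_of <- function(theta) {
  as.integer(floor(wrap_deg(theta) / 15)) %% 24L
}

#' Build a hue-sweep stimulus schedule
#'
#' A trial is a sequence of 100 ms on phases alternating with 100 ms off
#' phases (5 Hz flicker), always starting with an on phase. Each on phase
#' shows a single static hue, advanced by 3 deg from the previous on phase
#' (no advancement during off phases), so 120 on phases traverse the full
#' hue circle in 24 s. Counterclockwise sweeps increase hue starting at the
#' start sector's lower boundary; clockwise sweeps decrease hue starting one
#' step below the upper boundary, so that each 1-s stimulation second stays
#' within a single 15-deg sector in either direction.
#'
#' @param direction `"counterclockwise"` (hue increases) or `"clockwise"`.
#' @param start_sector Integer 0-23; the sector where the sweep begins.
#' @param trial_s Trial duration in seconds (default 25).
#' @param level Contrast level of the trial (stored as metadata).
#' @return A `sweep_schedule`: a tibble of phases (`onset_s`, `duration_s`,
#'   `state`, `hue_deg`) with attributes `direction`, `start_sector`,
#'   `trial_s`, `cycle_s` and `level`.
#' @export
build_sweep_schedule <- function(direction = c("counterclockwise", "clockwise"),
                                 start_sector = 0L, trial_s = 25,
                                 level = contrast_level("full")) {
  direction <- match.arg(direction)
  if (is.character(level)) level <- contrast_level(level)
  start_sector <- as.integer(start_sector)
  if (is.na(start_sector) || start_sector < 0L || start_sector > 23L) {
    stop("start_sector must be an integer in 0-23")
  }
  n_on <- as.integer(round(trial_s / 0.2))  # one on-off cycle per 200 ms
  j <- seq_len(n_on) - 1L
  hue <- if (direction == "counterclockwise") {
    wrap_deg(15 * start_sector + 3 * j)
  } else {
    wrap_deg(15 * (start_sector + 1L) - 3 * (j + 1L))
  }
  phases <- tibble::tibble(
    onset_s = rep(j * 0.2, each = 2L) + c(0, 0.1),
    duration_s = 0.1,
    state = rep(c("on", "off"), times = n_on),
    hue_deg = rep(hue, each = 2L)
  )
  phases$hue_deg[phases$state == "off"] <- NA_real_
  structure(phases,
    class = c("sweep_schedule", class(phases)),
    direction = direction, start_sector = start_sector,
    trial_s = trial_s, cycle_s = 24, level = level
  )
}

#' Sector stimulated during each second of a sweep trial
#'
#' Second `i` (0-based) of a counterclockwise trial starting at sector `s`
#' stimulates sector `(s + i) mod 24`; a clockwise trial stimulates
#' `(s - i) mod 24`.
#'
#' @param direction Sweep direction.
#' @param start_sector Starting sector 0-23.
#' @param second 0-based second index (vectorized).
#' @return Integer sector indices.
#' @export
sector_at_second <- function(direction, start_sector, second) {
  s <- as.integer(start_sector)
  if (direction == "counterclockwise") (s + as.integer(second)) %% 24L
  else (s - as.integer(second)) %% 24L
}

#' Continuous hue at a given time within a sweep trial
#'
#' The analysis maps each sample to a continuously advancing hue at
#' 15 deg/s; the difference from the 3-deg per-on-phase staircase is well
#' below the hue resolution of the 5 Hz Gabor filter.
#'
#' @param schedule A `sweep_schedule`.
#' @param t_s Time(s) in seconds from trial onset.
#' @return Hue angle(s) in degrees.
#' @export
hue_at_time <- function(schedule, t_s) {
  s <- attr(schedule, "start_sector")
  if (attr(schedule, "direction") == "counterclockwise") {
    wrap_deg(15 * s + 15 * t_s)
  } else {
    wrap_deg(15 * (s + 1L) - 15 * t_s)
  }
}

# Staircase hue actually displayed at time t (per on-phase; off phases hold
# the upcoming value irrelevant as the generator carries the response through).
schedule_hue_at_time <- function(schedule, t_s) {
  on <- schedule[schedule$state == "on", ]
  idx <- pmin(findInterval(t_s, on$onset_s), nrow(on))
  idx[idx < 1L] <- 1L
  on$hue_deg[idx]
}

#' Observer calibration for the luminance channel
#'
#' The luminance channel is modeled as the weighted cone sum L + phi * M;
#' phi is the observer's relative M-cone weight, measured by heterochromatic
#' flicker photometry (not simulated here; phi is supplied per observer).
#'
#' @param phi Relative M-cone luminance weight (> 0), default 0.5.
#' @return An `observer_calibration` object.
#' @export
observer_calibration <- function(phi = 0.5) {
  stopifnot(phi > 0)
  structure(list(phi = phi), class = "observer_calibration")
}

#' Residual luminance of a nominally isoluminant stimulus
#'
#' Stimuli are constructed to silence the luminance channel L + phi * M
#' under the observer's calibrated phi. If the calibration deviates from the
#' true phi, the L-M component of the stimulus leaks into luminance: the
#' M-cone contrast is set to cancel luminance under `phi_true`
#' (dM = -dL / phi_true), so the residual under the calibration is
#' `dL * (1 - phi_calib / phi_true)`. S-cone contrast never contributes
#' (S input is irrelevant to the luminance channel), so the residual is zero
#' on the S axis and symmetric in magnitude about the 90-270 deg axis.
#'
#' @param c A tibble/list with `dL_over_L` (and `dS_over_S`, unused).
#' @param calib An `observer_calibration` (the phi used to build stimuli).
#' @param phi_true The observer's actual M-cone luminance weight.
#' @return Dimensionless luminance-channel residual(s).
#' @export
luminance_residual <- function(c, calib, phi_true) {
  c$dL_over_L * (1 - calib$phi / phi_true)
}

#' Serialize a sweep schedule to CSV with a JSON sidecar
#'
#' Writes the phase table (`onset_s`, `duration_s`, `state`, `hue_deg`) as
#' CSV and the trial metadata (direction, start sector, contrast level) as
#' a JSON sidecar next to it.
#'
#' @param schedule A `sweep_schedule`.
#' @param path CSV file path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  meta <- list(
    direction = attr(schedule, "direction"),
    start_sector = attr(schedule, "start_sector"),
    trial_s = attr(schedule, "trial_s"),
    cycle_s = attr(schedule, "cycle_s"),
    level = attr(schedule, "level")$name
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read back a schedule written by [write_schedule()]
#' @param path CSV file path written by [write_schedule()].
#' @return A `sweep_schedule`.
#' @export
read_schedule <- function(path) {
  phases <- tibble::as_tibble(utils::read.csv(path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(phases,
    class = c("sweep_schedule", class(phases)),
    direction = meta$direction, start_sector = as.integer(meta$start_sector),
    trial_s = meta$trial_s, cycle_s = meta$cycle_s,
    level = contrast_level(meta$level)
  )
}
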
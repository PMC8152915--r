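# Candidate models for the "purely chromatic" hue-tuning profile
# (full minus quarter contrast difference), compared by AIC.
#
# M1 cardinal vector-sum : sqrt((aL cos t)^2 + (aS sin t)^2)
# M2 cardinal scalar-sum : |aL cos t| + |aS sin t|
# M3 perceptual          : gain * radius of the fixed Munsell iso-Chroma
#                          ellipse (orientation 61.03 deg, aspect 2.05),
#                          normalized to unit mean radius
# M4 mixed (P + vector)  : gain * (w * Pn + (1-w) * C1n(aspect))
# M5 mixed (P + scalar)  : gain * (w * Pn + (1-w) * C2n(aspect))
#
# Pn and the cardinal components Cn are normalized to unit mean over the hue
# circle before mixing, so the perceptual weight w is identifiable against
# the overall gain. The cardinal component's rotation is fixed at 0 (its
# axes are the cardinal axes by definition); parameter counts k follow the
# published model table: (2, 2, 1, 4, 4).

#' Fixed shape of the perceptual (Munsell iso-Chroma) model
#'
#' Orientation and aspect ratio of the ellipse traced by equal-Chroma
#' Munsell chips in the scaled cone-contrast plane. These built-in constants
#' are used when no reflectance data are supplied to [munsell_ellipse()].
#' @return An `ellipse_params` with unit mean radius.
#' @export
perceptual_ellipse <- function() {
  e <- ellipse_params(psi = 61.03, a = 2.05, b = 1)
  m <- mean_radius(e)
  ellipse_params(psi = e$psi, a = e$a / m, b = e$b / m)
}

#' Model specifications for the hue-tuning comparison
#'
#' @param name One of `"cardinal_vector"`, `"cardinal_scalar"`,
#'   `"perceptual"`, `"mixed_vector"`, `"mixed_scalar"`.
#' @return A `model_spec` with the model's name, label and parameter count.
#' @export
model_spec <- function(name = c("cardinal_vector", "cardinal_scalar",
                                "perceptual", "mixed_vector", "mixed_scalar")) {
  name <- match.arg(name)
  k <- c(cardinal_vector = 2L, cardinal_scalar = 2L, perceptual = 1L,
         mixed_vector = 4L, mixed_scalar = 4L)[[name]]
  label <- c(cardinal_vector = "M1 cardinal (vector-sum)",
             cardinal_scalar = "M2 cardinal (scalar-sum)",
             perceptual = "M3 perceptual",
             mixed_vector = "M4 mixed (perceptual + vector-sum)",
             mixed_scalar = "M5 mixed (perceptual + scalar-sum)")[[name]]
  structure(list(name = name, label = label, k = k), class = "model_spec")
}

#' All five model specs in canonical M1..M5 order
#' @return Named list of `model_spec` objects.
#' @export
model_specs <- function() {
  nm <- c("cardinal_vector", "cardinal_scalar", "perceptual",
          "mixed_vector", "mixed_scalar")
  stats::setNames(lapply(nm, model_spec), nm)
}

# raw (unnormalized) cardinal shapes
cardinal_vector_shape <- function(theta, aL, aS) {
  th <- theta * pi / 180
  sqrt((aL * cos(th))^2 + (aS * sin(th))^2)
}
cardinal_scalar_shape <- function(theta, aL, aS) {
  th <- theta * pi / 180
  abs(aL * cos(th)) + abs(aS * sin(th))
}

# mean of each cardinal shape over the hue circle, for unit-mean mixing;
# closed forms exist only via elliptic integrals, so integrate numerically
# on a fine fixed grid (error << 1e-10 for these smooth/piecewise shapes).
.shape_grid <- seq(0, 360, length.out = 14401L)[-14401L]
cardinal_mean <- function(shape_fn, aL, aS) mean(shape_fn(.shape_grid, aL, aS))

#' Evaluate a hue-tuning model
#'
#' @param spec A `model_spec` (or model name).
#' @param params Named list/vector of parameters:
#'   M1/M2 `aL`, `aS` (nonnegative cardinal gains);
#'   M3 `gain`;
#'   M4/M5 `gain`, `omega` (perceptual weight in `[0, 1]`) and `aspect`
#'   (cardinal component aspect ratio, > 0; values < 1 put the longer
#'   cardinal axis on the S axis).
#' @param theta Hue angle(s) in degrees.
#' @param P Optional perceptual `ellipse_params` overriding the built-in
#'   shape (e.g. from [munsell_ellipse()]).
#' @return Predicted amplitude(s), same length as `theta`.
#' @export
eval_model <- function(spec, params, theta, P = perceptual_ellipse()) {
  if (is.character(spec)) spec <- model_spec(spec)
  p <- as.list(params)
  switch(spec$name,
    cardinal_vector = cardinal_vector_shape(theta, p$aL, p$aS),
    cardinal_scalar = cardinal_scalar_shape(theta, p$aL, p$aS),
    perceptual = p$gain * radius_at(P, theta) / mean_radius(P),
    mixed_vector = ,
    mixed_scalar = {
      if (p$omega < 0 || p$omega > 1) stop("omega must lie in [0, 1]")
      shape_fn <- if (spec$name == "mixed_vector") cardinal_vector_shape
                  else cardinal_scalar_shape
      Cn <- shape_fn(theta, 1, 1 / p$aspect) /
        cardinal_mean(shape_fn, 1, 1 / p$aspect)
      Pn <- radius_at(P, theta) / mean_radius(P)
      p$gain * (p$omega * Pn + (1 - p$omega) * Cn)
    }
  )
}

#' Akaike information criterion from a residual sum of squares
#'
#' `AIC = n * log(RSS / n) + 2k` (least-squares form, up to an additive
#' constant shared by all models on the same data).
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of data points.
#' @param k Number of model parameters.
#' @return The AIC value; `-Inf` with a warning when `rss == 0`.
#' @export
aic <- function(rss, n, k) {
  stopifnot(rss >= 0, n >= 1)
  if (rss == 0) {
    warning("RSS is exactly zero; AIC is -Inf")
    return(-Inf)
  }
  n * log(rss / n) + 2 * k
}

#' Difference profile between two contrast conditions
#'
#' The "purely chromatic" response: pointwise full-contrast amplitude minus
#' quarter-contrast amplitude on a shared hue grid.
#'
#' @param full,quarter Tibbles/data frames with `hue_deg` and `amplitude`.
#' @return Tibble with `hue_deg` and `amplitude` (the difference).
#' @export
diff_profile <- function(full, quarter) {
  if (length(full$hue_deg) != length(quarter$hue_deg) ||
      max(abs(full$hue_deg - quarter$hue_deg)) > 1e-9) {
    stop("hue grids of the two profiles do not match")
  }
  tibble::tibble(hue_deg = full$hue_deg,
                 amplitude = full$amplitude - quarter$amplitude)
}

#' Fit one hue-tuning model to a difference profile
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) with multi-start:
#' `n_starts` starting points are spread over the bounded parameter ranges
#' (deterministic jitter from `seed`) and the best converged RSS is kept.
#' The perceptual model's single gain has a closed-form solution.
#' Goodness of fit is `100 * (1 - RSS/TSS)` with TSS the total sum of
#' squares of the profile about its mean.
#'
#' @param profile Tibble with `hue_deg`, `amplitude` (the difference profile).
#' @param spec A `model_spec` or model name.
#' @param n_starts Number of multi-start initializations (>= 8).
#' @param seed Seed for start-point jitter.
#' @param P Optional perceptual shape override.
#' @return A `model_fit`: list with `spec`, `params`, `rss`, `n`,
#'   `gof_percent`, `aic`.
#' @export
fit_model <- function(profile, spec, n_starts = 8L, seed = 1L,
                      P = perceptual_ellipse()) {
  if (is.character(spec)) spec <- model_spec(spec)
  theta <- profile$hue_deg
  y <- profile$amplitude
  n <- length(y)
  if (stats::sd(y) == 0) stop("profile is constant; model fit is undefined")
  Pn <- radius_at(P, theta) / mean_radius(P)

  if (spec$name == "perceptual") {
    gain <- sum(y * Pn) / sum(Pn^2)
    pars <- list(gain = gain)
    rss <- sum((y - gain * Pn)^2)
  } else {
    mixed <- spec$name %in% c("mixed_vector", "mixed_scalar")
    shape_fn <- if (spec$name %in% c("cardinal_vector", "mixed_vector")) {
      cardinal_vector_shape
    } else {
      cardinal_scalar_shape
    }
    if (mixed) {
      resid_fn <- function(p) {
        Cn <- shape_fn(theta, 1, 1 / p[3]) / cardinal_mean(shape_fn, 1, 1 / p[3])
        y - p[1] * (p[2] * Pn + (1 - p[2]) * Cn)
      }
      lower <- c(gain = 1e-8, omega = 0, aspect = 0.2)
      upper <- c(gain = Inf, omega = 1, aspect = 5)
      base_start <- c(gain = mean(y), omega = 0.5, aspect = 1)
    } else {
      resid_fn <- function(p) y - shape_fn(theta, p[1], p[2])
      lower <- c(aL = 0, aS = 0)
      upper <- c(aL = Inf, aS = Inf)
      # data-driven start: radii near the two cardinal axes
      a0 <- max(mean(abs(y[wrap_deg(theta) < 10 | wrap_deg(theta) > 350])), 1e-3)
      s0 <- max(mean(abs(y[abs(wrap_deg(theta) - 90) < 10])), 1e-3)
      base_start <- c(aL = a0, aS = s0)
    }
    set.seed(seed)
    n_starts <- max(8L, n_starts)
    starts <- lapply(seq_len(n_starts), function(i) {
      if (i == 1L) return(base_start)
      jit <- stats::runif(length(base_start), 0.3, 2.5)
      p <- base_start * jit
      if (length(p) == 3L) p[2] <- stats::runif(1, 0, 1)  # omega uniform
      pmin(pmax(p, lower + 1e-6), ifelse(is.finite(upper), upper - 1e-6, p))
    })
    fits <- lapply(starts, function(st) {
      tryCatch(
        minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                           fn = resid_fn,
                           control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL
      )
    })
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) == 0L) stop("model fit failed to converge from any start")
    rs <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
    best <- fits[[which.min(rs)]]
    pars <- as.list(best$par)
    rss <- min(rs)
  }
  tss <- sum((y - mean(y))^2)
  structure(list(
    spec = spec, params = pars, rss = rss, n = n,
    gof_percent = 100 * (1 - rss / tss),
    aic = aic(rss, n, spec$k)
  ), class = "model_fit")
}

#' Fit and rank all five models on a difference profile
#'
#' Fits M1-M5 by least squares and ranks them by AIC (ascending; ties broken
#' by lower RSS then lower k).
#'
#' @inheritParams fit_model
#' @return A tibble with one row per model: `model`, `label`, `k`, the
#'   fitted parameters (list column), `rss`, `gof_percent`, `aic`, `rank`,
#'   sorted by AIC.
#' @export
compare_models <- function(profile, n_starts = 8L, seed = 1L,
                           P = perceptual_ellipse()) {
  fits <- lapply(model_specs(), function(sp)
    fit_model(profile, sp, n_starts = n_starts, seed = seed, P = P))
  tab <- tibble::tibble(
    model = vapply(fits, function(f) f$spec$name, character(1)),
    label = vapply(fits, function(f) f$spec$label, character(1)),
    k = vapply(fits, function(f) f$spec$k, integer(1)),
    params = lapply(fits, function(f) f$params),
    rss = vapply(fits, function(f) f$rss, numeric(1)),
    gof_percent = vapply(fits, function(f) f$gof_percent, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1))
  )
  ord <- order(tab$aic, tab$rss, tab$k)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  tab
}

#' Write a model-comparison table as CSV (params flattened to JSON strings)
#' @param tab Output of [compare_models()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_model_table <- function(tab, path) {
  out <- tab
  out$params <- vapply(tab$params, function(p)
    as.character(jsonlite::toJSON(p, auto_unbox = TRUE, digits = 8)),
    character(1))
  utils::write.csv(as.data.frame(out), path, row.names = FALSE)
  invisible(path)
}

#' Ellipse of equal-Chroma Munsell chips in cone-contrast space
#'
#' Computes the chromaticity of each reflectance sample (e.g. the 40 Munsell
#' matte chips at value 4 / Chroma 4) under an equal-energy-white (EEW)
#' illuminant and the given cone fundamentals, expresses each chip as cone
#' contrast against the EEW background, rescales to the 1:10 axis-normalized
#' plane, and fits an ellipse. Used to (re)derive the perceptual model's
#' fixed shape; without external reflectance data the pipeline uses the
#' built-in constants of [perceptual_ellipse()].
#'
#' @param reflectance Matrix/data frame, wavelengths x chips (reflectance
#'   0-1), rows aligned with `fundamentals`.
#' @param fundamentals Matrix/data frame with columns `L`, `M`, `S`: cone
#'   sensitivities at the same wavelengths.
#' @param illuminant Illuminant spectral power at the same wavelengths
#'   (default flat = EEW).
#' @return An `ellipse_params` for the chip locus (axis-normalized plane).
#' @export
munsell_ellipse <- function(reflectance, fundamentals,
                            illuminant = rep(1, nrow(fundamentals))) {
  refl <- as.matrix(reflectance)
  fund <- as.matrix(fundamentals)[, c("L", "M", "S")]
  if (nrow(refl) != nrow(fund)) stop("wavelength grids do not match")
  if (any(!is.finite(refl)) || any(refl < 0)) stop("malformed reflectance data")
  # cone excitations of each chip and of the background (perfect diffuser)
  E <- t(fund * illuminant) %*% refl          # 3 x chips
  bg <- colSums(fund * illuminant)            # L, M, S of the EEW background
  dL <- (E["L", ] - bg[["L"]]) / bg[["L"]]
  dS <- (E["S", ] - bg[["S"]]) / bg[["S"]]
  # axis-normalized (1:10 scaled) coordinates; chips need not be centered,
  # but the equal-Chroma locus circles the background point
  x <- dL / MAX_L_CONTRAST
  y <- dS / MAX_S_CONTRAST
  fit_ellipse(x, y)
}
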
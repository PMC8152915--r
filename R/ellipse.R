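# Ellipse fitting for polar hue-tuning profiles.
#
# Amplitude and latency profiles are treated as polar curves r(theta) about
# the origin of the scaled cone-contrast plane; ellipses summarize them by
# an orientation psi (axial, mod 180 deg) and semi-axes a >= b.

#' Construct ellipse parameters
#'
#' @param psi Orientation of the major axis in degrees, reduced to `[0, 180)`.
#' @param a Semi-major axis (a >= b > 0).
#' @param b Semi-minor axis.
#' @param center Optional (x, y) center, diagnostic only; radii are always
#'   evaluated about the origin.
#' @return An `ellipse_params` object.
#' @export
ellipse_params <- function(psi, a, b, center = c(0, 0)) {
  if (b <= 0 || a < b) stop("ellipse requires a >= b > 0")
  structure(list(psi = psi %% 180, a = a, b = b, center = center),
            class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf("ellipse: psi = %.2f deg, a = %.4g, b = %.4g (aspect %.3f)\n",
              x$psi, x$a, x$b, x$a / x$b))
  invisible(x)
}

#' Polar radius of a centered ellipse
#'
#' `r(theta) = a*b / sqrt((b*cos(theta - psi))^2 + (a*sin(theta - psi))^2)`.
#'
#' @param e An `ellipse_params`.
#' @param theta Hue angle(s) in degrees.
#' @return Radius at each angle.
#' @export
radius_at <- function(e, theta) {
  d <- (theta - e$psi) * pi / 180
  e$a * e$b / sqrt((e$b * cos(d))^2 + (e$a * sin(d))^2)
}

#' Mean polar radius of an ellipse (over a uniform angle grid)
#' @keywords internal
mean_radius <- function(e, n = 3600L) {
  mean(radius_at(e, seq(0, 360, length.out = n + 1L)[-(n + 1L)]))
}

#' Fit an ellipse to 2-D points by direct least squares
#'
#' Numerically stable direct least-squares conic fit constrained to
#' ellipses (Halir-Flusser formulation of the Fitzgibbon method): minimizes
#' algebraic distance subject to 4AC - B^2 = 1, which guarantees an
#' elliptical solution. The conic's center is returned as a diagnostic;
#' orientation is reported in `[0, 180)` with psi = 0 meaning the major axis
#' lies on the L-M axis. A circle (a == b within floating point) reports
#' psi = 0 by convention.
#'
#' @param x,y Point coordinates (typically `r * cos(theta)`, `r * sin(theta)`
#'   from a polar profile). At least 6 distinct, non-collinear points.
#' @param center `"free"` fits the full 6-parameter conic; `"origin"`
#'   constrains the ellipse center to the origin (4 parameters), the
#'   appropriate model for polar tuning profiles, and much better
#'   conditioned when the radial modulation is small relative to noise
#'   (a free center lets low-order noise harmonics masquerade as large
#'   center offsets).
#' @return An `ellipse_params`.
#' @export
fit_ellipse <- function(x, y, center = c("free", "origin")) {
  center <- match.arg(center)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 6L) stop("ellipse fit needs at least 6 distinct points")
  x <- pts[, 1]; y <- pts[, 2]
  if (center == "origin") return(fit_ellipse_origin(x, y))
  # center and scale for conditioning
  mx <- mean(x); my <- mean(y)
  sx <- max(stats::sd(x), .Machine$double.eps)
  sy <- max(stats::sd(y), .Machine$double.eps)
  xs <- (x - mx) / sx; ys <- (y - my) / sy

  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  if (rcond(S3) < 1e-12) stop("degenerate (collinear) input points")
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  # premultiply by inv(C), C the constraint matrix for 4AC - B^2
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  idx <- which(cond > 0)
  if (length(idx) == 0L) stop("no elliptical solution; degenerate input")
  a1 <- evec[, idx[1]]
  coef_s <- c(a1, as.vector(Tm %*% a1))  # A B C D E F in scaled frame
  # undo the scaling back to the original frame
  A <- coef_s[1] / sx^2
  B <- coef_s[2] / (sx * sy)
  C <- coef_s[3] / sy^2
  D <- -2 * coef_s[1] * mx / sx^2 - coef_s[2] * my / (sx * sy) + coef_s[4] / sx
  E <- -coef_s[2] * mx / (sx * sy) - 2 * coef_s[3] * my / sy^2 + coef_s[5] / sy
  F <- coef_s[1] * mx^2 / sx^2 + coef_s[2] * mx * my / (sx * sy) +
    coef_s[3] * my^2 / sy^2 - coef_s[4] * mx / sx - coef_s[5] * my / sy +
    coef_s[6]
  conic_to_ellipse(c(A, B, C, D, E, F))
}

# Direct least-squares fit of an origin-centered ellipse:
# minimize ||A x^2 + B xy + C y^2 + F|| subject to 4AC - B^2 = 1.
fit_ellipse_origin <- function(x, y) {
  s <- max(stats::sd(x), stats::sd(y), .Machine$double.eps)
  xs <- x / s; ys <- y / s
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- matrix(1, length(xs), 1L)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)  # inv(constraint) %*% M
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  idx <- which(cond > 0)
  if (length(idx) == 0L) stop("no elliptical solution; degenerate input")
  v <- evec[, idx[1]]
  F0 <- as.numeric(Tm %*% v)
  conic_to_ellipse(c(v / s^2, 0, 0, F0))
}

# Geometric parameters (center, axes, orientation) of the conic
# A x^2 + B xy + C y^2 + D x + E y + F = 0, assumed elliptical.
conic_to_ellipse <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("conic is not an ellipse")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  # constant term after translating to the center
  Fc <- F + (D * cx + E * cy) / 2
  # semi-axes from the eigenvalues of [[A, B/2], [B/2, C]]
  tr <- A + C
  disc <- sqrt((A - C)^2 + B^2)
  lam1 <- (tr - disc) / 2  # smaller |.| eigenvalue -> major axis
  lam2 <- (tr + disc) / 2
  s <- -Fc
  if (s / lam1 <= 0 || s / lam2 <= 0) stop("conic is not a real ellipse")
  a <- sqrt(s / lam1)
  b <- sqrt(s / lam2)
  if (abs(disc) < 1e-12 * max(abs(tr), 1)) {
    psi <- 0  # circle: orientation undefined, report 0 by convention
  } else {
    psi <- atan2(B, A - C) / 2 * 180 / pi + 90
  }
  if (a < b) { tmp <- a; a <- b; b <- tmp; psi <- psi + 90 }
  ellipse_params(psi = psi %% 180, a = a, b = b, center = c(cx, cy))
}

#' Fit an ellipse to a polar profile
#'
#' Convenience wrapper: converts `(hue_deg, radius)` samples to Cartesian
#' points and calls [fit_ellipse()].
#'
#' @param hue_deg Hue angles in degrees.
#' @param radius Nonnegative radii (amplitude or latency).
#' @param center Passed to [fit_ellipse()]; profiles are origin-centered
#'   polar curves, so the centered fit is the default.
#' @return An `ellipse_params`.
#' @export
fit_profile_ellipse <- function(hue_deg, radius, center = "origin") {
  th <- hue_deg * pi / 180
  fit_ellipse(radius * cos(th), radius * sin(th), center = center)
}

# axial circular mean of orientations in degrees (period 180)
axial_mean <- function(psi_deg) {
  z <- exp(2i * psi_deg * pi / 180)
  (Arg(mean(z)) * 180 / pi / 2) %% 180
}

# signed axial deviation from a reference orientation, in (-90, 90]
axial_dev <- function(psi_deg, ref) {
  d <- (psi_deg - ref) %% 180
  ifelse(d > 90, d - 180, d)
}

#' Bootstrap ellipse parameters over participants
#'
#' Resamples participants with replacement `B` times; for each resample the
#' participant profiles are averaged, an ellipse fitted to the mean profile,
#' and the parameters recorded. Orientations are axial (period 180 deg) and
#' are averaged and summarized on the doubled-angle circle.
#'
#' @param profiles Numeric matrix, participants x hue samples (radii).
#' @param hue_deg Hue angle of each column, degrees.
#' @param B Number of bootstrap resamples (default 2000).
#' @param seed Integer seed for reproducibility.
#' @param fit_n Number of evenly spaced profile samples used per fit
#'   (default 360; the full 6000-sample grid is redundant for a 3-parameter
#'   ellipse and slows the 2000 resamples down).
#' @return A `bootstrap_result`: list with the point fit on the grand mean,
#'   per-parameter bootstrap means and 95% percentile CIs, `B` and `seed`.
#' @export
bootstrap_ellipse <- function(profiles, hue_deg, B = 2000L, seed = 1L,
                              fit_n = 360L) {
  if (B < 1L) stop("B must be >= 1")
  profiles <- as.matrix(profiles)
  n_p <- nrow(profiles)
  if (n_p < 2L) stop("bootstrap needs at least 2 participants")
  sub <- unique(round(seq(1L, ncol(profiles), length.out = fit_n)))
  hsub <- hue_deg[sub]

  point <- fit_profile_ellipse(hsub, colMeans(profiles)[sub])

  set.seed(seed)
  draws <- matrix(sample.int(n_p, n_p * B, replace = TRUE), nrow = B)
  fits <- vapply(seq_len(B), function(bi) {
    m <- colMeans(profiles[draws[bi, ], , drop = FALSE])[sub]
    e <- fit_profile_ellipse(hsub, m)
    c(psi = e$psi, a = e$a, b = e$b, aspect = e$a / e$b)
  }, numeric(4))

  psi_mean <- axial_mean(fits["psi", ])
  dev <- axial_dev(fits["psi", ], psi_mean)
  psi_ci <- (psi_mean + stats::quantile(dev, c(0.025, 0.975), names = FALSE)) %% 180
  ci <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  structure(list(
    point = point,
    mean = list(psi = psi_mean, a = mean(fits["a", ]), b = mean(fits["b", ]),
                aspect = mean(fits["aspect", ])),
    ci95 = list(psi = psi_ci, a = ci(fits["a", ]), b = ci(fits["b", ]),
                aspect = ci(fits["aspect", ])),
    B = B, seed = seed
  ), class = "bootstrap_result")
}

#' Serialize a bootstrap ellipse result to JSON
#' @param res A `bootstrap_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_bootstrap_json <- function(res, path) {
  out <- list(
    psi_deg = res$mean$psi, a = res$mean$a, b = res$mean$b,
    aspect = res$mean$aspect,
    ci95 = res$ci95, B = res$B, seed = res$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
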
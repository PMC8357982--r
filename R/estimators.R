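#' @title Plasmonic-angle estimators
#' @description Three measurement methods locate the plasmonic position
#'   \eqn{n_0\sin\theta_p} on quadrant (or full) BFP images: the deep-learning
#'   phase-gradient method, 3rd-degree polynomial fitting of the intensity
#'   line-scan dip, and azimuthal angle averaging of rotated line scans.
#' @name estimators
NULL

# Cubic fit around a discrete extremum with sub-sample localization.
# x, y: data; i0: index of the discrete extremum; window: half width in samples.
# x is centred and scaled before fitting for conditioning; the extremum of
# the fitted cubic is the closed-form root of its derivative lying inside the
# window with the right curvature sign; if none exists we fall back to the
# discrete extremum and flag the estimate.
fit_extremum_poly3 <- function(x, y, i0, window = 4, what = c("min", "max")) {
  what <- match.arg(what)
  n <- length(x)
  lo <- max(1L, i0 - window)
  hi <- min(n, i0 + window)
  clipped <- (lo > i0 - window) || (hi < i0 + window)
  xw <- x[lo:hi]; yw <- y[lo:hi]
  xc <- mean(xw); xs <- max(diff(range(xw)), .Machine$double.eps)
  u <- (xw - xc) / xs
  cf <- stats::coef(stats::lm(yw ~ u + I(u^2) + I(u^3)))
  if (any(!is.finite(cf)))  # under-determined window (too few points)
    return(list(location = x[i0], low_confidence = TRUE))
  # derivative roots of c1 + 2 c2 u + 3 c3 u^2; a cubic coefficient that is
  # negligible against the others is treated as exactly zero so that a
  # (near-)parabolic window falls through to the stable vertex formula
  scale <- max(abs(cf[2:4]), .Machine$double.eps)
  cubic_ok <- is.finite(cf[4]) && abs(cf[4]) > 1e-9 * scale
  disc <- (2 * cf[3])^2 - 4 * (3 * cf[4]) * cf[2]
  low_conf <- clipped || (i0 == lo) || (i0 == hi)
  loc <- x[i0]
  if (cubic_ok && is.finite(disc) && disc >= 0) {
    rts <- (-2 * cf[3] + c(-1, 1) * sqrt(disc)) / (2 * 3 * cf[4])
    curv <- 2 * cf[3] + 6 * cf[4] * rts
    keep <- rts >= min(u) & rts <= max(u) &
      (if (what == "min") curv > 0 else curv < 0)
    if (any(keep)) {
      r <- rts[keep]
      loc <- (r[which.min(abs(r - (x[i0] - xc) / xs))]) * xs + xc
    } else low_conf <- TRUE
  } else if (!cubic_ok && abs(cf[3]) > 1e-9 * scale) {
    # degenerate cubic: quadratic vertex
    v <- -cf[2] / (2 * cf[3])
    ok <- v >= min(u) && v <= max(u) &&
      (if (what == "min") cf[3] > 0 else cf[3] < 0)
    if (ok) loc <- v * xs + xc else low_conf <- TRUE
  } else low_conf <- TRUE
  list(location = unname(loc), low_confidence = low_conf)
}

as_quadrant_list <- function(q) {
  if (is.matrix(q)) list(q) else q
}

new_angle_estimate <- function(beta_p, per_quadrant, method, low_confidence) {
  structure(list(beta_p = beta_p, per_quadrant = per_quadrant,
                 method = method, low_confidence = low_confidence),
            class = "angle_estimate")
}

#' @export
print.angle_estimate <- function(x, ...) {
  cat("Plasmonic position (", x$method, "): n0*sin(theta_p) = ",
      format(x$beta_p, digits = 6), " from ", length(x$per_quadrant),
      " quadrant(s)", if (x$low_confidence) " [low confidence]", "\n",
      sep = "")
  invisible(x)
}

#' Plasmonic angle from retrieved phase quadrants (deep-learning method)
#'
#' For each quadrant the pure p-polarization edge row \eqn{\phi(\beta)} is
#' extracted, unwrapped along \eqn{\beta}, differentiated by central finite
#' differences, and the position of the largest local phase gradient is
#' refined by a 3rd-degree polynomial fit within a window around the peak.
#' Available quadrant estimates are averaged.
#'
#' @param phase_quadrants One phase image (matrix, rad) or a list of up to 4.
#' @param grid The \code{pupil_grid} the quadrants were cropped from.
#' @param beta_min Lower \eqn{\beta} bound of the search (use
#'   \code{ns + 0.01} to skip the critical-angle feature); \code{0} searches
#'   everywhere.
#' @param beta_max Upper bound of the gradient search. The pupil rim is an
#'   aperture discontinuity (amplitude and phase drop to zero outside the
#'   NA disc) that retrieved phase images reproduce as a spurious steep
#'   gradient, so the default keeps a small margin inside the rim.
#' @param window Half-width of the cubic fit window in samples (default 4).
#' @param line_rows Number of adjacent quadrant rows averaged into the line
#'   scan. For phase the default is 1: near the critical-coupling thickness
#'   the unwrap branch of slightly off-axis rows can differ by 2\eqn{\pi}
#'   (the reflection zero sits close to the real-\eqn{\beta} axis), which
#'   corrupts a multi-row average; intensity has no such topology and uses 3.
#' @return An \code{angle_estimate}.
#' @export
dl_plasmonic_angle <- function(phase_quadrants, grid, beta_min = 0,
                               beta_max = grid$na - 3 * grid$delta_beta,
                               window = 4, line_rows = 1) {
  qs <- as_quadrant_list(phase_quadrants)
  stopifnot(length(qs) >= 1, length(qs) <= 4, inherits(grid, "pupil_grid"))
  ba <- grid$beta_axis
  res <- lapply(qs, function(q) {
    stopifnot(ncol(q) == length(ba))
    k <- min(line_rows, nrow(q))
    # unwrap each row along beta, then average the k near-axis rows
    phi <- rowMeans(vapply(seq_len(k), function(r) unwrap_phase(q[r, ]),
                           numeric(ncol(q))))
    g <- c(phi[2] - phi[1],
           (phi[-(1:2)] - phi[-((length(phi) - 1):length(phi))]) / 2,
           phi[length(phi)] - phi[length(phi) - 1]) / grid$delta_beta
    sel <- which(ba > beta_min & ba <= beta_max)
    if (length(sel) < 2 * window + 1 || all(abs(g[sel]) < 1e-12))
      return(list(location = NA_real_, low_confidence = TRUE))
    i0 <- which.max(abs(g[sel]))
    sgn <- sign(g[sel][i0])
    # the fit stays inside the search domain so that rim artifacts beyond
    # beta_max cannot leak into the polynomial
    fit_extremum_poly3(ba[sel], sgn * g[sel], i0, window, "max")
  })
  per_q <- vapply(res, `[[`, numeric(1), "location")
  new_angle_estimate(mean(per_q), per_q, "dl_phase",
                     any(vapply(res, `[[`, logical(1), "low_confidence")))
}

#' Plasmonic angle from an intensity line-scan dip (poly-3 method)
#'
#' The conventional SPR dip measurement: the minimum of the pure
#' p-polarization edge-row intensity line scan, restricted to
#' \eqn{\beta > } \code{beta_min}, localized to sub-sample precision with a
#' 3rd-degree polynomial fit. Quadrant estimates are averaged.
#'
#' @param intensity_quadrants One non-negative intensity image or a list of
#'   up to 4 quadrants.
#' @inheritParams dl_plasmonic_angle
#' @return An \code{angle_estimate}.
#' @export
intensity_dip_angle <- function(intensity_quadrants, grid, beta_min = 0,
                                window = 4, line_rows = 3) {
  qs <- as_quadrant_list(intensity_quadrants)
  stopifnot(length(qs) >= 1, length(qs) <= 4, inherits(grid, "pupil_grid"))
  ba <- grid$beta_axis
  res <- lapply(qs, function(q) {
    stopifnot(ncol(q) == length(ba))
    y <- colMeans(q[seq_len(min(line_rows, nrow(q))), , drop = FALSE])
    sel <- which(ba > beta_min)
    i0 <- sel[which.min(y[sel])]
    fit_extremum_poly3(ba, y, i0, window, "min")
  })
  per_q <- vapply(res, `[[`, numeric(1), "location")
  new_angle_estimate(mean(per_q), per_q, "intensity_poly3",
                     any(vapply(res, `[[`, logical(1), "low_confidence")))
}

# Bilinear sampling of a full BFP image along a ray at azimuth `theta_rad`
# from the grid centre, at integer radii 0..half-1 (pixel units).
sample_ray <- function(img, grid, theta_rad) {
  half <- grid$size_px / 2L
  t <- 0:(half - 1)
  rr <- grid$center + t * sin(theta_rad)
  cc <- grid$center + t * cos(theta_rad)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  r1 <- pmin(r0 + 1, grid$size_px); c1 <- pmin(c0 + 1, grid$size_px)
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c1)] * (1 - fr) * fc +
    img[cbind(r1, c1)] * fr * fc
}

#' Plasmonic angle by azimuthal angle averaging
#'
#' Emulates rotating the full BFP image in 1-degree steps over the azimuth
#' range \code{angles_deg} (default \eqn{-45^\circ..45^\circ}, 91 rotations,
#' bilinear interpolation about the true grid centre) and extracting the
#' positive-x axis line scan of every rotation. The 91 line scans are summed
#' and the dip of the summed scan is localized with a 3rd-degree polynomial
#' fit.
#'
#' @param intensity Full-size non-negative intensity image
#'   (\code{size_px} square).
#' @param grid The matching \code{pupil_grid}.
#' @param angles_deg Rotation angles in degrees.
#' @inheritParams dl_plasmonic_angle
#' @return An \code{angle_estimate}; \code{per_quadrant} holds the single
#'   summed-scan estimate.
#' @export
azimuthal_average_angle <- function(intensity, grid, beta_min = 0,
                                    angles_deg = seq(-45, 45, by = 1),
                                    window = 4) {
  stopifnot(inherits(grid, "pupil_grid"), is.matrix(intensity),
            nrow(intensity) == grid$size_px,
            ncol(intensity) == grid$size_px)
  scans <- vapply(angles_deg,
                  function(a) sample_ray(intensity, grid, a * pi / 180),
                  numeric(grid$size_px / 2L))
  y <- rowSums(scans)
  ba <- grid$beta_axis
  sel <- which(ba > beta_min)
  i0 <- sel[which.min(y[sel])]
  fit <- fit_extremum_poly3(ba, y, i0, window, "min")
  new_angle_estimate(fit$location, fit$location, "azimuthal_avg",
                     fit$low_confidence)
}
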
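#' Define a multilayer optical stack for SPR back-focal-plane simulation
#'
#' Describes the Kretschmann-type system seen from the immersion side: a
#' semi-infinite incidence medium of index \code{n0} (immersion oil/glass,
#' typically 1.52), an ordered list of thin layers (each a complex refractive
#' index and a thickness in nm, e.g. a gold film), and a semi-infinite sample
#' medium of real index \code{ns}. The illumination wavelength and the
#' objective numerical aperture complete the description.
#'
#' @param n0 Real refractive index of the incidence medium (default 1.52).
#' @param layers List of layers, each \code{list(n = <complex index>, d =
#'   <thickness nm>)}, ordered from the incidence side. May be empty
#'   (two-media Fresnel interface).
#' @param ns Real refractive index of the semi-infinite sample medium.
#' @param wavelength_nm Vacuum wavelength in nm.
#' @param na Numerical aperture of the objective; must satisfy
#'   \code{0 < na <= n0}.
#' @return An object of class \code{layer_stack}.
#' @examples
#' st <- layer_stack(layers = list(list(n = 0.18 + 3.44i, d = 50)), ns = 1.33)
#' @export
layer_stack <- function(n0 = 1.52, layers = list(), ns = 1.33,
                        wavelength_nm = 633, na = 1.49) {
  stopifnot(is.numeric(n0), n0 > 0, is.numeric(ns), ns > 0,
            is.numeric(wavelength_nm), wavelength_nm > 0,
            is.numeric(na), na > 0, na <= n0, is.list(layers))
  for (ly in layers) {
    if (!is.list(ly) || is.null(ly$n) || is.null(ly$d))
      stop("each layer must be list(n = <index>, d = <thickness nm>)")
    if (ly$d < 0) stop("layer thickness must be >= 0")
    if (Im(as.complex(ly$n)) < 0)
      stop("layer indices must have Im(n) >= 0 (passive-medium convention)")
  }
  structure(list(n0 = n0, layers = layers, ns = ns,
                 wavelength_nm = wavelength_nm, na = na),
            class = "layer_stack")
}

#' Convenience constructor for a single gold-film SPR stack
#'
#' @param dm_nm Gold thickness in nm.
#' @param ns Sample refractive index.
#' @param wavelength_nm Vacuum wavelength in nm (default 633, He-Ne).
#' @param nm Complex refractive index of gold (default 0.18 + 3.44i at 633 nm).
#' @param n0 Incidence-medium index (default 1.52).
#' @param na Numerical aperture (default 1.49).
#' @return A \code{layer_stack} with one gold layer.
#' @export
gold_stack <- function(dm_nm, ns = 1.33, wavelength_nm = 633,
                       nm = 0.18 + 3.44i, n0 = 1.52, na = 1.49) {
  layer_stack(n0 = n0, layers = list(list(n = nm, d = dm_nm)), ns = ns,
              wavelength_nm = wavelength_nm, na = na)
}

#' @export
print.layer_stack <- function(x, ...) {
  cat("Multilayer stack: n0 =", x$n0, "| ns =", x$ns,
      "| lambda =", x$wavelength_nm, "nm | NA =", x$na, "\n")
  if (length(x$layers) == 0) cat("  (no layers: two-media interface)\n")
  for (ly in x$layers)
    cat("  layer: n =", format(ly$n), ", d =", ly$d, "nm\n")
  invisible(x)
}

# Principal sqrt with the branch forced to Im >= 0 (decaying evanescent waves).
kz_branch <- function(z) {
  s <- sqrt(as.complex(z))
  flip <- Im(s) < 0
  s[flip] <- -s[flip]
  s
}

#' Complex amplitude reflection coefficients of a multilayer stack
#'
#' Transfer-matrix (characteristic matrix) computation of the p- and
#' s-polarized reflection coefficients at in-plane momentum
#' \eqn{\beta = n_0 \sin\theta_0}. The normal wavevector in each medium is
#' \eqn{k_z = (2\pi/\lambda)\sqrt{n^2 - \beta^2}} with the branch chosen so
#' that \eqn{Im(k_z) \ge 0}.
#'
#' @param stack A \code{layer_stack}.
#' @param beta Numeric vector of \eqn{n_0 \sin\theta_0} values, all in
#'   \code{[0, n0)}.
#' @return A list with complex vectors \code{r_p} and \code{r_s}, one entry
#'   per element of \code{beta}.
#' @examples
#' rc <- reflection_coefficients(gold_stack(50), beta = 1.40)
#' Mod(rc$r_p)
#' @export
reflection_coefficients <- function(stack, beta) {
  stopifnot(inherits(stack, "layer_stack"), is.numeric(beta))
  if (any(beta < 0) || any(beta >= stack$n0))
    stop("beta must satisfy 0 <= beta < n0 (propagating in incidence medium)")
  k0 <- 2 * pi / stack$wavelength_nm
  b2 <- beta^2

  ref_one_pol <- function(p_pol) {
    # admittance q: s-pol q = kz/k0, p-pol q = kz/(k0 n^2)
    adm <- function(n) {
      qt <- kz_branch(n^2 - b2)
      if (p_pol) qt / n^2 else qt
    }
    q0 <- adm(stack$n0 + 0i)
    qs <- adm(stack$ns + 0i)
    # characteristic matrix product over layers
    m11 <- rep(1 + 0i, length(beta)); m12 <- rep(0 + 0i, length(beta))
    m21 <- m12; m22 <- m11
    for (ly in stack$layers) {
      n <- as.complex(ly$n)
      qt <- kz_branch(n^2 - b2)
      qi <- if (p_pol) qt / n^2 else qt
      delta <- k0 * qt * ly$d
      cd <- cos(delta); sd <- sin(delta)
      a11 <- cd;            a12 <- -1i * sd / qi
      a21 <- -1i * qi * sd; a22 <- cd
      t11 <- m11 * a11 + m12 * a21; t12 <- m11 * a12 + m12 * a22
      t21 <- m21 * a11 + m22 * a21; t22 <- m21 * a12 + m22 * a22
      m11 <- t11; m12 <- t12; m21 <- t21; m22 <- t22
    }
    num <- q0 * (m11 + m12 * qs) - (m21 + m22 * qs)
    den <- q0 * (m11 + m12 * qs) + (m21 + m22 * qs)
    num / den
  }
  list(r_p = ref_one_pol(TRUE), r_s = ref_one_pol(FALSE))
}

#' p-polarized reflectance spectrum
#'
#' @param stack A \code{layer_stack}.
#' @param betas Numeric vector of \eqn{n_0 \sin\theta_0} values.
#' @return Numeric vector \eqn{|r_p|^2}, same length as \code{betas}.
#' @export
reflectance_spectrum <- function(stack, betas) {
  Mod(reflection_coefficients(stack, betas)$r_p)^2
}

#' Back-focal-plane pupil coordinate grid
#'
#' Builds the momentum-space coordinate maps of a square BFP image of even
#' side \code{size_px}. The grid is linear in \eqn{\beta = n_0\sin\theta_0},
#' zero at the centre pixel and exactly \code{na} on the inscribed circle
#' through the edge pixel centres, so the pixel pitch is
#' \code{na / (size_px/2 - 1)}. The centre pixel sits at matrix position
#' \code{(size_px/2 + 1, size_px/2 + 1)} so that the positive-x axis (azimuth
#' \eqn{\varphi = 0}, pure p-polarization) falls exactly on a pixel row.
#'
#' @param size_px Even side length in pixels (default 512).
#' @param na Numerical aperture mapped to the inscribed circle (default 1.49).
#' @return An object of class \code{pupil_grid} with fields \code{size_px},
#'   \code{na}, \code{delta_beta}, \code{beta_map}, \code{phi_map},
#'   \code{inside_mask} and \code{beta_axis} (the quadrant edge-row
#'   \eqn{\beta} values, length \code{size_px/2}).
#' @export
pupil_grid <- function(size_px = 512, na = 1.49) {
  stopifnot(size_px %% 2 == 0, size_px >= 8, na > 0)
  half <- size_px / 2L
  ctr <- half + 1L                      # matrix index of beta = 0
  coord <- seq_len(size_px) - ctr       # -half .. half-1 pixel offsets
  db <- na / (half - 1)
  x <- matrix(coord, size_px, size_px, byrow = TRUE)
  y <- matrix(coord, size_px, size_px, byrow = FALSE)
  r <- sqrt(x^2 + y^2)
  beta_map <- r * db
  phi_map <- atan2(y, x)
  phi_map[phi_map <= -pi] <- pi         # keep phi in (-pi, pi]
  structure(list(size_px = size_px, na = na, delta_beta = db,
                 center = ctr, beta_map = beta_map, phi_map = phi_map,
                 inside_mask = beta_map <= na + 1e-12,
                 beta_axis = (0:(half - 1)) * db),
            class = "pupil_grid")
}

#' @export
print.pupil_grid <- function(x, ...) {
  cat("Pupil grid:", x$size_px, "x", x$size_px, "px, NA =", x$na,
      ", delta_beta =", signif(x$delta_beta, 5), "\n")
  invisible(x)
}

#' Synthesize the complex back-focal-plane field of a stack
#'
#' Computes the reflected pupil field under the crossed x-polarizer model:
#' each pupil point is decomposed into its radial (p) and tangential (s)
#' component, reflected with the transfer-matrix coefficients, and projected
#' back onto the x analyzer, giving
#' \eqn{E(\beta,\varphi) = r_p(\beta)\cos^2\varphi + r_s(\beta)\sin^2\varphi}
#' with unit uniform illumination inside the NA and zero outside. Along the
#' \eqn{\varphi = 0} axis the field is exactly \eqn{r_p(\beta)}.
#'
#' @param stack A \code{layer_stack}.
#' @param grid A \code{pupil_grid}.
#' @param apodization \code{"uniform"} (default) or \code{"aplanatic"}
#'   (multiplies the illumination by \eqn{\sqrt{\cos\theta_0}}).
#' @return An object of class \code{bfp_field}: list with the complex
#'   \code{field} matrix and the \code{grid}.
#' @export
synthesize_bfp <- function(stack, grid, apodization = c("uniform", "aplanatic")) {
  stopifnot(inherits(stack, "layer_stack"), inherits(grid, "pupil_grid"))
  apodization <- match.arg(apodization)
  if (grid$na > stack$n0) stop("grid NA exceeds incidence index of the stack")
  field <- matrix(0 + 0i, grid$size_px, grid$size_px)
  idx <- which(grid$inside_mask)
  betas <- grid$beta_map[idx]
  rc <- reflection_coefficients(stack, betas)
  cphi2 <- cos(grid$phi_map[idx])^2
  f <- rc$r_p * cphi2 + rc$r_s * (1 - cphi2)
  if (apodization == "aplanatic") {
    cos_t0 <- sqrt(pmax(0, 1 - (betas / stack$n0)^2))
    f <- f * sqrt(cos_t0)
  }
  field[idx] <- f
  structure(list(field = field, grid = grid, stack = stack),
            class = "bfp_field")
}

#' @export
print.bfp_field <- function(x, ...) {
  cat("BFP field:", x$grid$size_px, "x", x$grid$size_px,
      "px complex pupil field\n")
  invisible(x)
}

# Row/column index sets of the four quadrants of a full BFP image; the first
# row/col of every returned quadrant is the pure-p axis (y = 0 or its mirror)
# and beta increases along both axes away from the centre pixel.
quadrant_signs <- list(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))

#' Crop one quadrant of a BFP field into amplitude and phase images
#'
#' The returned quadrant is oriented so that its first row is the pure
#' p-polarization line (\eqn{\varphi = 0} axis or its mirror image) with
#' \eqn{\beta} increasing along the columns from 0 at the first column, i.e.
#' the image-centre corner of the quadrant is element \code{[1, 1]}. Phase is
#' the wrapped argument in \eqn{(-\pi, \pi]}.
#'
#' @param field A \code{bfp_field} (or a plain square matrix, complex or
#'   real, together with \code{grid}).
#' @param quadrant Integer 1--4: (+x,+y), (-x,+y), (-x,-y), (+x,-y).
#' @param grid Required if \code{field} is a plain matrix.
#' @return List with \code{amplitude} and \code{phase} matrices of side
#'   \code{size_px/2} (phase only when the input is complex).
#' @export
crop_quadrant <- function(field, quadrant = 1, grid = NULL) {
  if (inherits(field, "bfp_field")) {
    grid <- field$grid
    field <- field$field
  }
  if (is.null(grid)) stop("grid must be supplied for a plain matrix input")
  if (!quadrant %in% 1:4) stop("quadrant must be 1, 2, 3 or 4")
  stopifnot(nrow(field) == grid$size_px, ncol(field) == grid$size_px)
  half <- grid$size_px / 2L
  sg <- quadrant_signs[[quadrant]]
  ri <- grid$center + sg[2] * (0:(half - 1))
  ci <- grid$center + sg[1] * (0:(half - 1))
  q <- field[ri, ci, drop = FALSE]
  if (is.complex(q)) {
    ph <- Arg(q)
    ph[ph <= -pi] <- pi
    list(amplitude = Mod(q), phase = ph)
  } else {
    list(amplitude = q)
  }
}

#' Extract all four quadrants of an image or field
#'
#' @param field A \code{bfp_field} or plain matrix.
#' @param grid A \code{pupil_grid} if \code{field} is a plain matrix.
#' @return List of four \code{crop_quadrant()} results.
#' @export
crop_all_quadrants <- function(field, grid = NULL) {
  lapply(1:4, function(q) crop_quadrant(field, q, grid))
}

#' Unwrap a 1-D phase sequence
#'
#' Removes 2\eqn{\pi} jumps along a phase line scan so finite differences
#' reflect the true local gradient.
#'
#' @param phi Numeric vector of wrapped phases in rad.
#' @return Unwrapped phase vector starting at \code{phi[1]}.
#' @export
unwrap_phase <- function(phi) {
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(phi[1], d))
}

#' Wrap phase values to the interval (-pi, pi]
#'
#' @param phi Numeric vector or matrix in rad.
#' @return Wrapped values in \eqn{(-\pi, \pi]}.
#' @export
wrap_phase <- function(phi) {
  w <- phi - 2 * pi * round(phi / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}
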
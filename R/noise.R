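#' Photon energy at a given wavelength, in pJ
#'
#' @param wavelength_nm Vacuum wavelength in nm.
#' @return \eqn{hc/\lambda} in picojoules.
#' @export
photon_energy_pJ <- function(wavelength_nm) {
  stopifnot(wavelength_nm > 0)
  h <- 6.62607015e-34   # J s
  cc <- 2.99792458e8    # m/s
  h * cc / (wavelength_nm * 1e-9) * 1e12
}

#' Camera shot-noise configuration
#'
#' Describes the photon budget of a Poisson shot-noise camera model: the
#' total optical energy deposited in the image, the camera quantum
#' efficiency, and the wavelength fixing the energy per photon. The
#' \code{scope} records whether the stated total energy refers to the full
#' BFP image or to one analyzed quadrant.
#'
#' @param total_energy_pJ Total optical image energy in pJ (> 0).
#' @param quantum_efficiency Fraction of photons converted to
#'   photo-electrons, in (0, 1] (default 0.6, a typical CCD).
#' @param wavelength_nm Illumination wavelength in nm (default 633).
#' @param scope \code{"quadrant"} (default): the stated energy is deposited
#'   in each analyzed quadrant, so every measurement method sees the same
#'   photon budget; \code{"full"}: the energy is that of the full BFP image
#'   and each quadrant carries a quarter of it.
#' @return An object of class \code{noise_config}.
#' @export
noise_config <- function(total_energy_pJ, quantum_efficiency = 0.6,
                         wavelength_nm = 633,
                         scope = c("quadrant", "full")) {
  stopifnot(total_energy_pJ > 0, quantum_efficiency > 0,
            quantum_efficiency <= 1, wavelength_nm > 0)
  structure(list(total_energy_pJ = total_energy_pJ,
                 quantum_efficiency = quantum_efficiency,
                 wavelength_nm = wavelength_nm,
                 scope = match.arg(scope)),
            class = "noise_config")
}

#' @export
print.noise_config <- function(x, ...) {
  cat("Shot-noise model: E =", x$total_energy_pJ, "pJ (", x$scope,
      "image ), QE =", x$quantum_efficiency, ", lambda =",
      x$wavelength_nm, "nm\n")
  invisible(x)
}

#' Expected photo-electron count for a given optical energy
#'
#' @param total_energy_pJ Optical energy in pJ.
#' @param cfg A \code{noise_config} (supplies QE and wavelength).
#' @return Expected number of detected photo-electrons,
#'   \eqn{QE \cdot E / (hc/\lambda)}.
#' @export
energy_to_electrons <- function(total_energy_pJ, cfg) {
  stopifnot(inherits(cfg, "noise_config"), all(total_energy_pJ >= 0))
  cfg$quantum_efficiency * total_energy_pJ /
    photon_energy_pJ(cfg$wavelength_nm)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Add Poisson shot noise to a clean intensity image
#'
#' The clean image is rescaled so that its total optical energy equals
#' \code{cfg$total_energy_pJ}; the expected detected photo-electron count of
#' pixel \eqn{i} is then \eqn{\mu_i = QE \cdot E_i / (hc/\lambda)} and the
#' output draws \eqn{Poisson(\mu_i)} independently per pixel. Intensity
#' (photon flux \eqn{\propto |E|^2}), never amplitude, should be passed in.
#'
#' @param clean_image Non-negative intensity matrix with at least one
#'   positive pixel.
#' @param cfg A \code{noise_config}.
#' @param seed Optional integer seed; when given, draws are reproducible and
#'   the caller's RNG state is restored afterwards.
#' @return A list of class \code{shot_noise_image}: \code{counts} (raw
#'   integer photo-electron counts), \code{normalized} (counts divided by
#'   their maximum, in [0, 1]), and \code{expected} (the Poisson means).
#' @export
add_shot_noise <- function(clean_image, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "noise_config"), is.numeric(clean_image),
            all(clean_image >= 0))
  s <- sum(clean_image)
  if (s <= 0) stop("clean image is identically zero; cannot set its energy")
  mu <- energy_to_electrons(cfg$total_energy_pJ, cfg) * clean_image / s
  counts <- with_seed(seed, {
    matrix(stats::rpois(length(mu), mu), nrow(clean_image))
  })
  structure(list(counts = counts,
                 normalized = counts / max(counts, 1),
                 expected = mu),
            class = "shot_noise_image")
}

#' @export
print.shot_noise_image <- function(x, ...) {
  cat("Shot-noise image:", nrow(x$counts), "x", ncol(x$counts),
      "px,", format(sum(x$counts), big.mark = ","), "detected electrons\n")
  invisible(x)
}
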
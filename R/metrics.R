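#' Offset-minimized root-mean-square phase error
#'
#' Computes the minimum over a constant phase offset \eqn{c \in [0, 2\pi)} of
#' the root-mean-square wrapped difference between a predicted and a
#' reference phase image: the offset absorbs the arbitrary global phase of a
#' retrieved profile. The minimum is located by a grid search (step
#' \code{grid_step}) refined by the closed-form mean-difference minimizer
#' within the best wrap branch.
#'
#' @param predicted Phase image (matrix or vector), rad.
#' @param reference Reference phase image of the same shape, rad.
#' @param grid_step Offset grid resolution in rad (default 1e-3).
#' @return List of class \code{rmse_result}: \code{rmse_rad},
#'   \code{best_offset_rad} in \eqn{[0, 2\pi)}, \code{n_pixels}.
#' @export
phase_rmse <- function(predicted, reference, grid_step = 1e-3) {
  if (!identical(dim(predicted), dim(reference)) ||
      length(predicted) != length(reference))
    stop("predicted and reference must have the same shape")
  d <- sort(wrap_phase(as.numeric(predicted) - as.numeric(reference)))
  n <- length(d)
  s1 <- cumsum(d); s2 <- cumsum(d^2)
  S1 <- s1[n]; S2 <- s2[n]
  cs <- seq(0, 2 * pi - grid_step, by = grid_step)
  # residual r_i = d_i + c - 2*pi*[d_i > pi - c]; m = #\{d_i <= pi - c\}
  m <- findInterval(pi - cs, d)
  s1m <- c(0, s1)[m + 1]; s2m <- c(0, s2)[m + 1]
  f <- (s2m + 2 * cs * s1m + m * cs^2 +
          (S2 - s2m) + 2 * (cs - 2 * pi) * (S1 - s1m) +
          (n - m) * (cs - 2 * pi)^2) / n
  ib <- which.min(f)
  best_c <- cs[ib]; best_f <- f[ib]
  # closed-form refinement within the wrap branch of the best grid point
  mb <- m[ib]
  c_star <- -(S1 - 2 * pi * (n - mb)) / n
  c_star <- c_star %% (2 * pi)
  exact <- function(c) mean(wrap_phase(d + c)^2)
  f_star <- exact(c_star)
  if (f_star < best_f) {
    best_c <- c_star; best_f <- f_star
  }
  structure(list(rmse_rad = sqrt(best_f), best_offset_rad = best_c,
                 n_pixels = n),
            class = "rmse_result")
}

#' @export
print.rmse_result <- function(x, ...) {
  cat("Offset-minimized phase RMSE:", format(x$rmse_rad, digits = 4),
      "rad (offset", format(x$best_offset_rad, digits = 4), "rad,",
      x$n_pixels, "pixels)\n")
  invisible(x)
}

# Clean-image plasmonic position of a stack with a chosen estimator.
# method "phase" runs the phase-gradient localizer on the exact transfer-
# matrix phase (the infinite-training limit of the DL route).
clean_beta_p <- function(stack, method, grid, model = NULL, window = 4) {
  field <- synthesize_bfp(stack, grid)
  bmin <- stack$ns + 0.01
  switch(method,
    poly3 = {
      q <- crop_quadrant(field, 1)
      intensity_dip_angle(q$amplitude^2, grid, bmin, window)
    },
    azimuthal = azimuthal_average_angle(Mod(field$field)^2, grid, bmin,
                                        window = window),
    phase = {
      q <- crop_quadrant(field, 1)
      dl_plasmonic_angle(q$phase, grid, bmin, window = window)
    },
    dl = {
      if (is.null(model)) stop("method 'dl' requires a trained model")
      q <- crop_quadrant(field, 1)
      amp <- q$amplitude / max(q$amplitude)
      dl_plasmonic_angle(predict_phase(model, amp), grid, bmin,
                         window = window)
    },
    stop("unknown method: ", method)
  )
}

#' Refractive-index sensitivity of a plasmonic-angle estimator
#'
#' \eqn{S = \Delta(n_0\sin\theta_p) / \Delta n_s} between two stacks that
#' differ only in the sample refractive index, measured on clean (noise-free)
#' simulated images.
#'
#' @param stack_a,stack_b \code{layer_stack}s differing only in \code{ns}.
#' @param method One of \code{"poly3"}, \code{"azimuthal"}, \code{"dl"},
#'   \code{"phase"} (phase-gradient localizer on the exact simulated phase).
#' @param grid A \code{pupil_grid} (default 512 px).
#' @param model A trained CAN, required for \code{method = "dl"}.
#' @param window Cubic-fit half window in samples.
#' @return Sensitivity S (dimensionless, RIU/RIU).
#' @export
spr_sensitivity <- function(stack_a, stack_b, method = "poly3",
                            grid = pupil_grid(512), model = NULL,
                            window = 4) {
  stopifnot(inherits(stack_a, "layer_stack"), inherits(stack_b, "layer_stack"))
  if (stack_a$ns == stack_b$ns)
    stop("stacks have identical sample index; sensitivity undefined")
  same <- identical(stack_a[c("n0", "layers", "wavelength_nm", "na")],
                    stack_b[c("n0", "layers", "wavelength_nm", "na")])
  if (!same) stop("stacks must differ only in the sample refractive index")
  ba <- clean_beta_p(stack_a, method, grid, model, window)$beta_p
  bb <- clean_beta_p(stack_b, method, grid, model, window)$beta_p
  (bb - ba) / (stack_b$ns - stack_a$ns)
}

with_ns <- function(stack, ns) {
  layer_stack(n0 = stack$n0, layers = stack$layers, ns = ns,
              wavelength_nm = stack$wavelength_nm, na = stack$na)
}

# One noisy measurement of the plasmonic position. `field` is the clean
# complex full BFP field; intensity is |field|^2. Returns beta_p.
noisy_beta_p <- function(field, grid, method, cfg, model, window,
                         quadrant_average, bmin) {
  quads <- if (quadrant_average) 1:4 else 1L
  if (method == "azimuthal") {
    e_full <- if (is.null(cfg) || cfg$scope == "full") cfg
              else noise_config(4 * cfg$total_energy_pJ,
                                cfg$quantum_efficiency, cfg$wavelength_nm)
    img <- Mod(field$field)^2
    if (!is.null(cfg)) img <- add_shot_noise(img, e_full)$normalized
    return(azimuthal_average_angle(img, grid, bmin, window = window))
  }
  if (is.null(cfg) || cfg$scope == "full") {
    img <- Mod(field$field)^2
    if (!is.null(cfg)) img <- add_shot_noise(img, cfg)$normalized
    qi <- lapply(quads, function(q) crop_quadrant(img, q, grid)$amplitude)
  } else {
    qi <- lapply(quads, function(q) {
      iq <- crop_quadrant(field, q)$amplitude^2
      add_shot_noise(iq, cfg)$normalized
    })
  }
  if (method == "poly3")
    return(intensity_dip_angle(qi, grid, bmin, window))
  if (method == "dl") {
    ph <- lapply(qi, function(iq) {
      amp <- sqrt(iq)
      predict_phase(model, amp / max(amp))
    })
    return(dl_plasmonic_angle(ph, grid, bmin, window = window))
  }
  if (method == "phase") {
    # exact-phase route is noise-free by construction; used for baselines
    q <- crop_quadrant(field, 1)
    return(dl_plasmonic_angle(q$phase, grid, bmin, window = window))
  }
  stop("unknown method: ", method)
}

#' Monte Carlo limit of detection of a plasmonic-angle estimator
#'
#' Synthesizes the clean BFP once, then repeatedly applies seeded Poisson
#' shot noise, runs the chosen estimator, and summarizes the spread of the
#' measured plasmonic positions. The limit of detection is
#' \eqn{LOD = 3.3\sigma / S} (99.9\% confidence), where the sensitivity S is
#' measured on clean images at \eqn{n_s \pm} \code{delta_ns} with the same
#' estimator.
#'
#' @param stack The operating \code{layer_stack}.
#' @param method \code{"poly3"}, \code{"azimuthal"} or \code{"dl"}.
#' @param noise_cfg A \code{noise_config}, or \code{NULL} for the noise-free
#'   (infinite-energy) limit.
#' @param n_trials Number of Monte Carlo repetitions (>= 30).
#' @param grid A \code{pupil_grid}.
#' @param model Trained CAN for \code{method = "dl"}.
#' @param seed Integer seed driving all trial noise.
#' @param delta_ns Half-spacing of the sensitivity evaluation (default 0.005,
#'   i.e. S over \eqn{\Delta n_s = 0.01}).
#' @param window Cubic-fit half window.
#' @param quadrant_average Average the four quadrant estimates per trial
#'   (default TRUE, as the measurement methods prescribe); FALSE uses only
#'   quadrant 1.
#' @return List of class \code{lod_result}: \code{energy_pJ}, \code{method},
#'   \code{mean_beta}, \code{sigma_beta}, \code{sensitivity},
#'   \code{lod_riu}, \code{n_trials}, \code{n_failed}, \code{beta_samples}.
#' @export
monte_carlo_lod <- function(stack, method, noise_cfg, n_trials = 500,
                            grid = pupil_grid(512), model = NULL, seed = 1,
                            delta_ns = 0.005, window = 4,
                            quadrant_average = TRUE) {
  stopifnot(inherits(stack, "layer_stack"), n_trials >= 30)
  if (!is.null(noise_cfg)) stopifnot(inherits(noise_cfg, "noise_config"))
  S <- spr_sensitivity(with_ns(stack, stack$ns - delta_ns),
                       with_ns(stack, stack$ns + delta_ns),
                       method = if (method == "dl") "dl" else method,
                       grid = grid, model = model, window = window)
  field <- synthesize_bfp(stack, grid)
  bmin <- stack$ns + 0.01
  betas <- with_seed(seed, {
    vapply(seq_len(n_trials), function(i) {
      est <- noisy_beta_p(field, grid, method, noise_cfg, model, window,
                          quadrant_average, bmin)
      est$beta_p
    }, numeric(1))
  })
  failed <- !is.finite(betas)
  if (mean(failed) > 0.10)
    stop(sprintf("estimator '%s' failed on %d/%d trials (> 10%%)",
                 method, sum(failed), n_trials))
  ok <- betas[!failed]
  sigma <- stats::sd(ok)
  structure(list(
    energy_pJ = if (is.null(noise_cfg)) Inf else noise_cfg$total_energy_pJ,
    method = method, mean_beta = mean(ok), sigma_beta = sigma,
    sensitivity = S, lod_riu = 3.3 * sigma / abs(S),
    n_trials = n_trials, n_failed = sum(failed), beta_samples = betas),
    class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf(
    "LOD (%s, %s pJ): 3.3 sigma / S = 3.3 x %.3g / %.4f = %.3g RIU (%d trials)\n",
    x$method, format(x$energy_pJ), x$sigma_beta, x$sensitivity, x$lod_riu,
    x$n_trials))
  invisible(x)
}

#' Limit-of-detection benchmark over an energy grid
#'
#' Runs \code{\link{monte_carlo_lod}} for each method at each photon energy
#' and returns the results as a tidy table (one row per method/energy cell).
#'
#' @param stack Operating \code{layer_stack}.
#' @param methods Character vector from \code{"poly3"}, \code{"azimuthal"},
#'   \code{"dl"}.
#' @param energies_pJ Numeric vector of total image energies in pJ.
#' @param n_trials Monte Carlo repetitions per cell.
#' @param grid A \code{pupil_grid}.
#' @param model Trained CAN for the \code{"dl"} method.
#' @param seed Base seed; each cell uses a distinct derived seed.
#' @param quantum_efficiency,scope Passed to \code{\link{noise_config}}.
#' @param on_failure \code{"stop"} (default) propagates an estimator that
#'   fails its Monte Carlo; \code{"na"} records an NA row instead (useful
#'   for coarse wiring runs where an estimator cannot resolve the dip).
#' @param plot Draw a log-log LOD-vs-energy overview (base graphics).
#' @param ... Further arguments to \code{\link{monte_carlo_lod}}.
#' @return \code{data.frame} with columns method, energy_pJ, mean_beta,
#'   sigma_beta, sensitivity, lod_riu, n_trials, n_failed.
#' @export
lod_curve <- function(stack, methods = c("poly3", "azimuthal"),
                      energies_pJ = c(90, 500, 1000, 2000, 2600),
                      n_trials = 500, grid = pupil_grid(512), model = NULL,
                      seed = 1, quantum_efficiency = 0.6,
                      scope = "quadrant", on_failure = c("stop", "na"),
                      plot = FALSE, ...) {
  stopifnot(all(energies_pJ > 0))
  cells <- expand.grid(method = methods, energy_pJ = energies_pJ,
                       stringsAsFactors = FALSE)
  on_failure <- match.arg(on_failure)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- noise_config(cells$energy_pJ[i], quantum_efficiency,
                        stack$wavelength_nm, scope)
    r <- tryCatch(
      monte_carlo_lod(stack, cells$method[i], cfg, n_trials, grid,
                      model, seed = seed + 7919L * i, ...),
      error = function(e) {
        if (on_failure == "stop") stop(e)
        warning("LOD cell (", cells$method[i], ", ", cells$energy_pJ[i],
                " pJ) failed: ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(r))
      return(data.frame(method = cells$method[i],
                        energy_pJ = cells$energy_pJ[i], mean_beta = NA_real_,
                        sigma_beta = NA_real_, sensitivity = NA_real_,
                        lod_riu = NA_real_, n_trials = n_trials,
                        n_failed = n_trials))
    data.frame(method = r$method, energy_pJ = r$energy_pJ,
               mean_beta = r$mean_beta, sigma_beta = r$sigma_beta,
               sensitivity = r$sensitivity, lod_riu = r$lod_riu,
               n_trials = r$n_trials, n_failed = r$n_failed)
  })
  out <- do.call(rbind, rows)
  if (plot) {
    sp <- split(out, out$method)
    graphics::matplot(energies_pJ,
                      sapply(sp, function(d) d$lod_riu[order(d$energy_pJ)]),
                      type = "b", log = "xy", pch = 1:length(sp),
                      xlab = "total image energy (pJ)", ylab = "LOD (RIU)")
    graphics::legend("topright", names(sp), pch = 1:length(sp),
                     col = seq_along(sp), lty = seq_along(sp))
  }
  out
}
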
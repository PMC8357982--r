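test_that("offset-minimized RMSE absorbs constant phase shifts", {
  set.seed(11)
  ref <- matrix(runif(400, -pi, pi), 20, 20)
  r0 <- phase_rmse(ref, ref)
  expect_equal(r0$rmse_rad, 0)
  expect_equal(r0$best_offset_rad, 0, tolerance = 1e-9)
  expect_equal(r0$n_pixels, 400)
  for (shift in c(1.0, 2.5, 4.7, -0.8)) {
    r <- phase_rmse(wrap_phase(ref + shift), ref)
    expect_lt(r$rmse_rad, 2e-3)
    expect_equal(wrap_phase(r$best_offset_rad + shift), 0, tolerance = 2e-3)
  }
  expect_error(phase_rmse(ref, ref[, 1:10]), "shape")
})

test_that("the offset search matches a brute-force scan", {
  set.seed(23)
  for (i in 1:5) {
    pred <- matrix(runif(144, -pi, pi), 12, 12)
    ref <- wrap_phase(pred + rnorm(144, sd = 0.4) + runif(1, 0, 2 * pi))
    fast <- phase_rmse(pred, ref)
    cs <- seq(0, 2 * pi, by = 1e-4)
    d <- wrap_phase(as.numeric(pred) - as.numeric(ref))
    brute <- sqrt(min(vapply(cs, function(c) mean(wrap_phase(d + c)^2),
                             numeric(1))))
    expect_lt(abs(fast$rmse_rad - brute), 2e-3)
  }
})

test_that("sensitivity is symmetric in its arguments and guards its domain", {
  g <- grid512()
  a <- gold_stack(50, 1.33)
  b <- gold_stack(50, 1.34)
  s_ab <- spr_sensitivity(a, b, "poly3", g)
  s_ba <- spr_sensitivity(b, a, "poly3", g)
  expect_equal(s_ab, s_ba)
  expect_gt(s_ab, 1.0)
  expect_lt(s_ab, 1.4)
  expect_error(spr_sensitivity(a, a, "poly3", g), "identical")
  expect_error(spr_sensitivity(a, gold_stack(45, 1.34), "poly3", g),
               "differ only")
})

test_that("plasmonic position rises monotonically with the sample index", {
  g <- grid512()
  for (method in c("poly3", "phase", "azimuthal")) {
    bp <- vapply(c(1.00, 1.10, 1.20, 1.30, 1.37), function(ns)
      clean_beta_p(gold_stack(50, ns), method, g)$beta_p, numeric(1))
    expect_true(all(diff(bp) > 0))
  }
})

test_that("noise-free Monte Carlo collapses to zero spread", {
  r <- monte_carlo_lod(gold_stack(50, 1.33), "poly3", noise_cfg = NULL,
                       n_trials = 30, grid = grid256(), seed = 4)
  expect_equal(r$sigma_beta, 0)
  expect_equal(r$lod_riu, 0)
  expect_equal(r$n_failed, 0)
  expect_true(is.infinite(r$energy_pJ))
})

test_that("LOD estimates are stable in the trial count", {
  st <- gold_stack(50, 1.33)
  cfg <- noise_config(2500)
  g <- grid256()
  l1 <- monte_carlo_lod(st, "poly3", cfg, n_trials = 200, grid = g, seed = 9)
  l2 <- monte_carlo_lod(st, "poly3", cfg, n_trials = 400, grid = g, seed = 9)
  expect_lt(abs(l2$lod_riu - l1$lod_riu) / l1$lod_riu, 0.15)
  expect_identical(
    monte_carlo_lod(st, "poly3", cfg, n_trials = 50, grid = g,
                    seed = 12)$beta_samples,
    monte_carlo_lod(st, "poly3", cfg, n_trials = 50, grid = g,
                    seed = 12)$beta_samples)
})

test_that("averaging four quadrants shrinks the measurement variance", {
  st <- gold_stack(50, 1.33)
  cfg <- noise_config(2000)
  g <- grid256()
  r4 <- monte_carlo_lod(st, "poly3", cfg, n_trials = 200, grid = g,
                        seed = 31, quadrant_average = TRUE)
  r1 <- monte_carlo_lod(st, "poly3", cfg, n_trials = 200, grid = g,
                        seed = 32, quadrant_average = FALSE)
  ratio <- (r4$sigma_beta / r1$sigma_beta)^2
  expect_lt(ratio, 0.5)   # independent quadrants would give 1/4
  expect_gt(ratio, 0.1)
})

test_that("the LOD benchmark table is tidy and falls with energy", {
  st <- gold_stack(50, 1.33)
  tab <- lod_curve(st, methods = "poly3", energies_pJ = c(300, 2400),
                   n_trials = 120, grid = grid256(), seed = 77)
  expect_s3_class(tab, "data.frame")
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("method", "energy_pJ", "mean_beta", "sigma_beta",
                      "sensitivity", "lod_riu", "n_trials", "n_failed"))
  expect_lt(tab$lod_riu[tab$energy_pJ == 2400],
            tab$lod_riu[tab$energy_pJ == 300])
})
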
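test_that("cubic refinement recovers an exact vertex placed on a sample", {
  g <- grid256()
  ba <- g$beta_axis
  i0 <- 80
  y <- (ba - ba[i0])^2 + 0.05          # symmetric parabola, vertex on-grid
  img <- matrix(rep(y, each = 3), nrow = 3, byrow = FALSE)
  img <- rbind(img, img)               # any rows beyond line_rows are unused
  est <- intensity_dip_angle(rbind(img, matrix(1, 122, length(ba))), g)
  expect_equal(est$beta_p, ba[i0], tolerance = 1e-10)
  expect_false(est$low_confidence)
})

test_that("phase and intensity estimators agree on clean images", {
  g <- grid512()
  for (case in list(c(50, 1.33), c(45, 1.00), c(40, 1.33))) {
    st <- gold_stack(case[1], case[2])
    q <- crop_quadrant(synthesize_bfp(st, g), 1)
    bmin <- case[2] + 0.01
    p3 <- intensity_dip_angle(q$amplitude^2, g, bmin)
    ph <- dl_plasmonic_angle(q$phase, g, bmin)
    expect_lt(abs(p3$beta_p - ph$beta_p), 0.005)
    # both stay within one pixel of the dense 1-D reflectance oracle
    oracle <- dense_dip(st)
    expect_lt(abs(p3$beta_p - oracle), g$delta_beta)
    expect_lt(abs(ph$beta_p - oracle), 1.5 * g$delta_beta)
  }
})

test_that("azimuthal averaging carries a small coherent-model offset", {
  # off-axis line scans mix r_p and r_s coherently, which drags their dip
  # towards lower beta; the summed-scan estimate therefore sits a few
  # thousandths below the pure-p methods (a systematic, not noise)
  g <- grid512()
  st <- gold_stack(50, 1.33)
  f <- synthesize_bfp(st, g)
  az <- azimuthal_average_angle(Mod(f$field)^2, g, beta_min = 1.34)
  p3 <- intensity_dip_angle(crop_quadrant(f, 1)$amplitude^2, g, 1.34)
  expect_lt(az$beta_p, p3$beta_p)
  expect_lt(abs(az$beta_p - p3$beta_p), 0.02)
})

test_that("the degenerate single-rotation config reduces to the line dip", {
  g <- grid256()
  f <- synthesize_bfp(gold_stack(50, 1.33), g)
  img <- Mod(f$field)^2
  az0 <- azimuthal_average_angle(img, g, beta_min = 1.34, angles_deg = 0)
  line <- intensity_dip_angle(crop_quadrant(f, 1)$amplitude^2, g,
                              beta_min = 1.34, line_rows = 1)
  expect_equal(az0$beta_p, line$beta_p, tolerance = 1e-12)
})

test_that("the default rotation set is 91 one-degree steps over +-45", {
  expect_equal(eval(formals(azimuthal_average_angle)$angles_deg),
               seq(-45, 45, by = 1))
  expect_length(eval(formals(azimuthal_average_angle)$angles_deg), 91)
})

test_that("quadrant averaging equals the mean of per-quadrant estimates", {
  g <- grid256()
  q <- crop_quadrant(synthesize_bfp(gold_stack(45, 1.33), g), 1)
  single <- intensity_dip_angle(q$amplitude^2, g, 1.34)
  four <- intensity_dip_angle(rep(list(q$amplitude^2), 4), g, 1.34)
  expect_equal(four$beta_p, single$beta_p)
  expect_equal(four$per_quadrant, rep(single$beta_p, 4))
})

test_that("degenerate inputs are flagged rather than silently estimated", {
  g <- grid256()
  flat <- matrix(0.5, 128, 128)
  est <- dl_plasmonic_angle(flat, g, beta_min = 1.1)
  expect_true(est$low_confidence)
  # extremum pushed against the search boundary is low-confidence
  ramp <- matrix(rep(seq(1, 0, length.out = 128), each = 128), 128)
  est2 <- intensity_dip_angle(ramp, g, beta_min = 1.1)
  expect_true(est2$low_confidence)
})

test_that("a shifted dip moves the estimate by the matching amount", {
  g <- grid512()
  st_a <- gold_stack(50, 1.330)
  st_b <- gold_stack(50, 1.345)
  est_a <- clean_beta_p(st_a, "poly3", g)$beta_p
  est_b <- clean_beta_p(st_b, "poly3", g)$beta_p
  true_shift <- dense_dip(st_b) - dense_dip(st_a)
  expect_lt(abs((est_b - est_a) - true_shift), 0.1 * true_shift)
})
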
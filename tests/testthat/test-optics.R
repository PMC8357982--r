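test_that("empty and zero-thickness stacks reduce to two-media Fresnel", {
  n0 <- 1.52
  for (ns in c(1.00, 1.33, 1.40)) {
    empty <- layer_stack(n0 = n0, layers = list(), ns = ns)
    zerod <- layer_stack(n0 = n0,
                         layers = list(list(n = 0.18 + 3.44i, d = 0)),
                         ns = ns)
    betas <- seq(0, 1.49, length.out = 41)
    rc <- reflection_coefficients(empty, betas)
    rz <- reflection_coefficients(zerod, betas)
    # textbook Fresnel coefficients, written independently of the
    # transfer-matrix recursion (admittance form, Im(kz) >= 0 branch)
    kz <- function(n) {
      s <- sqrt(as.complex(n^2 - betas^2))
      ifelse(Im(s) < 0, -s, s)
    }
    k0 <- kz(n0); ks <- kz(ns)
    rs_ref <- (k0 - ks) / (k0 + ks)
    rp_ref <- (k0 / n0^2 - ks / ns^2) / (k0 / n0^2 + ks / ns^2)
    expect_lt(max(Mod(rc$r_s - rs_ref)), 1e-14)
    expect_lt(max(Mod(rc$r_p - rp_ref)), 1e-14)
    expect_lt(max(Mod(rz$r_s - rs_ref)), 1e-14)
    expect_lt(max(Mod(rz$r_p - rp_ref)), 1e-14)
  }
})

test_that("a homogeneous medium reflects nothing", {
  st <- layer_stack(n0 = 1.52, layers = list(list(n = 1.52 + 0i, d = 0)),
                    ns = 1.52, na = 1.49)
  rc <- reflection_coefficients(st, seq(0, 1.4, length.out = 11))
  expect_lt(max(Mod(rc$r_p)), 1e-14)
  expect_lt(max(Mod(rc$r_s)), 1e-14)
})

test_that("passivity holds for random absorbing stacks", {
  set.seed(42)
  betas <- seq(0, 1.5, length.out = 101)
  for (i in 1:20) {
    nl <- sample(0:3, 1)
    layers <- replicate(nl, list(n = complex(real = runif(1, 0.1, 4),
                                             imaginary = runif(1, 0, 4)),
                                 d = runif(1, 0, 300)),
                        simplify = FALSE)
    st <- layer_stack(n0 = 1.52, layers = layers,
                      ns = runif(1, 1.0, 1.45), na = 1.49,
                      wavelength_nm = runif(1, 500, 700))
    rc <- reflection_coefficients(st, betas[betas < st$n0])
    expect_lt(max(Mod(rc$r_p)), 1 + 1e-12)
    expect_lt(max(Mod(rc$r_s)), 1 + 1e-12)
  }
})

test_that("thick-film dip matches the semi-infinite SPP dispersion", {
  # 100 nm is ~4 skin depths: the film is optically thick but the
  # resonance is still resolvable as an interior local minimum
  st <- gold_stack(100, ns = 1.33)
  b <- seq(1.36, 1.49, by = 1e-4)
  R <- reflectance_spectrum(st, b)
  locmin <- which(diff(sign(diff(R))) > 0) + 1
  expect_length(locmin, 1)
  eps_m <- (0.18 + 3.44i)^2
  eps_s <- 1.33^2
  beta_spp <- Re(sqrt(eps_m * eps_s / (eps_m + eps_s)))
  expect_lt(abs(b[locmin] - beta_spp), 0.01)
})

test_that("45 nm film shows a single plasmonic dip beyond the critical angle", {
  b <- seq(1.33, 1.49, by = 1e-3)
  R <- reflectance_spectrum(gold_stack(45, 1.33), b)
  expect_true(all(R <= 1))
  locmin <- which(diff(sign(diff(R))) > 0) + 1
  expect_length(locmin, 1)
})

test_that("phase excursion grows towards 2*pi below critical coupling", {
  b <- seq(1.34, 1.49, by = 1e-4)
  excursion <- function(dm) {
    ph <- unwrap_phase(Arg(reflection_coefficients(gold_stack(dm, 1.33),
                                                   b)$r_p))
    diff(range(ph))
  }
  e20 <- excursion(20); e30 <- excursion(30); e45 <- excursion(45)
  expect_lt(e20, e30)
  expect_lt(e30, e45)
  expect_lt(e45, 2 * pi)
  expect_gt(e45, 0.7 * 2 * pi)
})

test_that("invalid inputs are rejected", {
  st <- gold_stack(50)
  expect_error(reflection_coefficients(st, 1.52), "beta")
  expect_error(reflection_coefficients(st, -0.1), "beta")
  expect_error(layer_stack(na = 1.6), "na")
  expect_error(layer_stack(layers = list(list(n = 1 - 0.5i, d = 10))),
               "Im")
  expect_error(crop_quadrant(synthesize_bfp(st, grid64()), 5), "quadrant")
})

test_that("pupil grid maps the NA to the inscribed circle", {
  g <- grid64()
  expect_equal(g$beta_map[g$center, g$center], 0)
  expect_equal(g$beta_map[g$center, g$size_px], g$na)
  expect_equal(max(g$beta_map[g$inside_mask]), g$na)
  expect_true(all(g$phi_map > -pi & g$phi_map <= pi))
  # radial symmetry about the centre pixel
  half <- g$size_px / 2
  sub <- g$beta_map[(g$center - half + 1):(g$center + half - 1),
                    (g$center - half + 1):(g$center + half - 1)]
  expect_equal(sub, sub[rev(seq_len(nrow(sub))), ])
  expect_equal(sub, sub[, rev(seq_len(ncol(sub)))])
})

test_that("synthesized field is pure r_p on the phi = 0 axis and symmetric", {
  g <- grid256()
  st <- gold_stack(45, 1.00)
  f <- synthesize_bfp(st, g)
  axis_vals <- f$field[g$center, g$center:(g$size_px)]
  rp <- reflection_coefficients(st, g$beta_axis)$r_p
  expect_equal(axis_vals[seq_along(g$beta_axis)], rp, tolerance = 1e-14)
  # zero outside the NA, reflection symmetry inside
  expect_true(all(f$field[!g$inside_mask] == 0))
  amp <- Mod(f$field)
  for (q in 2:4) {
    expect_equal(crop_quadrant(f, q)$amplitude, crop_quadrant(f, 1)$amplitude)
  }
  # determinism: identical inputs give bit-identical fields
  expect_identical(f$field, synthesize_bfp(st, g)$field)
})

test_that("quadrant cropping partitions the image and preserves the axis", {
  g <- grid256()
  f <- synthesize_bfp(gold_stack(45, 1.00), g)
  q1 <- crop_quadrant(f, 1)
  half <- g$size_px / 2
  expect_equal(dim(q1$amplitude), c(half, half))
  expect_equal(dim(q1$phase), c(half, half))
  expect_true(all(q1$phase > -pi & q1$phase <= pi))
  expect_equal(q1$amplitude[1, ],
               Mod(reflection_coefficients(f$stack, g$beta_axis)$r_p))
  # reassembling the four quadrants through their symmetry maps restores
  # the full amplitude image (row/col 1 lie outside the pupil and are 0)
  amp <- Mod(f$field)
  rebuilt <- matrix(0, g$size_px, g$size_px)
  signs <- list(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  for (q in 1:4) {
    sg <- signs[[q]]
    ri <- g$center + sg[2] * (0:(half - 1))
    ci <- g$center + sg[1] * (0:(half - 1))
    rebuilt[ri, ci] <- crop_quadrant(f, q)$amplitude
  }
  expect_equal(rebuilt, amp)
})

test_that("2-D amplitude dip sits on the 1-D reflectance dip", {
  g <- grid512()
  st <- gold_stack(45, 1.00)
  q <- crop_quadrant(synthesize_bfp(st, g), 1)
  sel <- which(g$beta_axis > 1.01)
  dip_2d <- g$beta_axis[sel][which.min(q$amplitude[1, sel])]
  dip_1d <- g$beta_axis[sel][which.min(
    reflectance_spectrum(st, g$beta_axis[sel]))]
  expect_lt(abs(dip_2d - dip_1d), g$delta_beta + 1e-12)
})

test_that("phase wrap and unwrap are consistent", {
  set.seed(7)
  for (i in 1:10) {
    smooth <- cumsum(runif(200, -1.2, 1.2))
    w <- wrap_phase(smooth)
    expect_true(all(w > -pi & w <= pi))
    u <- unwrap_phase(w)
    expect_equal(diff(u), diff(smooth), tolerance = 1e-12)
  }
})
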
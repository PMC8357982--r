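test_that("parameter draws are reproducible and respect their ranges", {
  a <- sample_parameters(seed = 123)
  b <- sample_parameters(seed = 123)
  expect_identical(a[c("dm_nm", "wavelength_nm", "nm", "ns")],
                   b[c("dm_nm", "wavelength_nm", "nm", "ns")])
  set.seed(99)
  draws <- replicate(2000, sample_parameters(), simplify = FALSE)
  dm <- vapply(draws, `[[`, numeric(1), "dm_nm")
  wl <- vapply(draws, `[[`, numeric(1), "wavelength_nm")
  ns <- vapply(draws, `[[`, numeric(1), "ns")
  nm <- vapply(draws, `[[`, complex(1), "nm")
  expect_true(all(dm >= 20 & dm <= 60))
  expect_true(all(wl >= 550 & wl <= 650))
  expect_true(all(ns >= 1.0 & ns <= 1.4))
  expect_true(all(Re(nm) >= 0.18 * 0.9 & Re(nm) <= 0.18 * 1.1))
  expect_true(all(Im(nm) >= 3.44 * 0.9 & Im(nm) <= 3.44 * 1.1))
  # CLT check on the thickness mean: sd of the mean is 40/sqrt(12)/sqrt(n)
  expect_lt(abs(mean(dm) - 40), 4 * 40 / sqrt(12) / sqrt(length(dm)))
})

test_that("parameter marginals pass Kolmogorov-Smirnov at alpha = 0.01", {
  set.seed(2024)
  n <- 10000
  draws <- replicate(n, sample_parameters(), simplify = FALSE)
  pull <- function(f) vapply(draws, f, numeric(1))
  checks <- list(
    list(pull(function(p) p$dm_nm), 20, 60),
    list(pull(function(p) p$wavelength_nm), 550, 650),
    list(pull(function(p) p$ns), 1.0, 1.4),
    list(pull(function(p) Re(p$nm)), 0.18 * 0.9, 0.18 * 1.1),
    list(pull(function(p) Im(p$nm)), 3.44 * 0.9, 3.44 * 1.1))
  for (ch in checks) {
    p <- suppressWarnings(
      stats::ks.test(ch[[1]], "punif", ch[[2]], ch[[3]])$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("test-grid collisions are recognized and excluded", {
  mk <- function(dm, wl) structure(list(dm_nm = dm, wavelength_nm = wl,
                                        nm = 0.18 + 3.44i, ns = 1.2),
                                   class = "parameter_sample")
  expect_true(is_test_configuration(mk(30.4, 633.9)))
  expect_true(is_test_configuration(mk(50, 633)))
  expect_false(is_test_configuration(mk(30.4, 640)))   # wavelength clear
  expect_false(is_test_configuration(mk(35, 633)))     # thickness clear
  expect_false(is_test_configuration(mk(46, 633)))     # 46 nm never held out
  ds <- generate_dataset(60, seed = 5, size_px = 64)
  expect_false(any(vapply(ds$records, function(r)
    is_test_configuration(r$params), logical(1))))
})

test_that("splits are exact, disjoint and reproducible", {
  for (n in c(10, 20, 47)) {
    ds <- generate_dataset(n, seed = 11, size_px = 64)
    splits <- vapply(ds$records, `[[`, character(1), "split")
    expect_equal(sum(splits == "train"), floor(0.9 * n))
    expect_equal(sum(splits == "val"), n - floor(0.9 * n))
  }
  a <- generate_dataset(12, seed = 31, size_px = 64)
  b <- generate_dataset(12, seed = 31, size_px = 64)
  expect_identical(a, b)
  c <- generate_dataset(12, seed = 32, size_px = 64)
  expect_false(identical(a$records[[1]]$params, c$records[[1]]$params))
})

test_that("records carry normalized amplitude inputs and wrapped labels", {
  ds <- generate_dataset(10, seed = 3, size_px = 64)
  for (r in ds$records) {
    expect_equal(dim(r$input), c(32, 32))
    expect_equal(dim(r$label), c(32, 32))
    expect_equal(max(r$input), 1)
    expect_gte(min(r$input), 0)
    expect_true(all(r$label > -pi & r$label <= pi))
  }
})

test_that("the held-out test grid matches the study design", {
  ts <- build_test_set(size_px = 64)
  expect_true(all(vapply(ts$records, `[[`, character(1), "split") == "test"))
  dm <- vapply(ts$records, function(r) r$params$dm_nm, numeric(1))
  ns <- vapply(ts$records, function(r) r$params$ns, numeric(1))
  wl <- vapply(ts$records, function(r) r$params$wavelength_nm, numeric(1))
  expect_setequal(unique(dm), c(30, 40, 45, 50))
  expect_true(all(wl == 633))
  expect_true(all(ns >= 1.00 & ns <= 1.372))
  # the six reference cases are present; 46 nm is not on the grid
  for (case in list(c(30, 1.00), c(40, 1.00), c(50, 1.00),
                    c(30, 1.33), c(40, 1.33), c(50, 1.33))) {
    expect_true(any(dm == case[1] & ns == case[2]))
  }
  expect_false(any(dm == 46))
  # labels round-trip against a fresh optics computation
  r <- ts$records[[7]]
  g <- pupil_grid(64)
  q <- crop_quadrant(synthesize_bfp(
    gold_stack(r$params$dm_nm, r$params$ns, r$params$wavelength_nm), g), 1)
  expect_identical(r$label, q$phase)
  expect_identical(r$input, q$amplitude / max(q$amplitude))
})

test_that("dataset containers round-trip bit-identically", {
  ds <- generate_dataset(10, seed = 8, size_px = 64)
  path <- tempfile(fileext = ".rds")
  write_dataset(ds, path)
  expect_identical(read_dataset(path), ds)
  unlink(path)
})
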
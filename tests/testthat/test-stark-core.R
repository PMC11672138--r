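# Closed-form frequency/TDM model: Stark term, angular factor, distance
# laws, combined blueshift surface, additivity.

test_that("VSE frequency: zero-field identity, linear/quadratic forms, sign", {
  p <- vse_params(nu0 = 2230, dmu = 0.5, dalpha = 0.002)
  expect_equal(vse_frequency(0, p), 2230)

  # with dalpha = 0 the quadratic form reduces exactly to the linear one
  p_lin <- vse_params(nu0 = 2230, dmu = 0.5, dalpha = 0)
  F <- seq(-120, 120, by = 7.5)
  expect_identical(vse_frequency(F, p_lin), 2230 + 0.5 * F)

  # negative condensed-phase fields red-shift
  expect_lt(vse_frequency(-60, p_lin), p_lin$nu0)

  # parameters derived from two printed (field, frequency) pairs reproduce
  # both pairs
  expect_equal(vse_frequency(-78, derived_vse), 2215.5, tolerance = 1e-10)
  expect_equal(vse_frequency(-64.9, derived_vse), 2219.1, tolerance = 1e-10)

  expect_error(vse_frequency(NaN, p), "finite")
})

test_that("TDM model is linear in field and spans a realistic range", {
  p <- vse_params(tdm0 = 0.05, tdm_polarizability = 1e-4)
  expect_equal(vse_tdm(0, p), 0.05)
  expect_equal(vse_tdm(50, p), 0.055)
  # default parameters: TDMs over the calibration fields stay within the
  # physically observed 0.037-0.060 D window
  F <- seq(-80, 0, length.out = 50)
  tdm <- vse_tdm(F, vse_params())
  expect_true(all(tdm >= 0.037 & tdm <= 0.060))
  # monotone for fixed-sign polarizability
  expect_true(all(diff(vse_tdm(F, p)) > 0))
})

test_that("angular factor: head-on normalization, monotonicity, zero crossings", {
  for (m in c(0.7, 0.82, 0.91, 1.0))
    expect_equal(angular_factor(180, m), 1)

  th <- seq(70, 180, by = 0.5)
  expect_true(all(diff(angular_factor(th, 0.82)) > 0))

  # numerical roots match the analytic zero crossing 180 - 90 / m
  r82 <- uniroot(function(t) angular_factor(t, 0.82), c(60, 120),
                 tol = 1e-10)$root
  r91 <- uniroot(function(t) angular_factor(t, 0.91), c(60, 120),
                 tol = 1e-10)$root
  expect_equal(r82, 180 - 90 / 0.82, tolerance = 1e-6)
  expect_equal(r82, 70.24, tolerance = 1e-3)
  expect_equal(r91, 81.10, tolerance = 1e-3)

  expect_error(angular_factor(0, 0.9), "theta")
  expect_error(angular_factor(181, 0.9), "theta")
})

test_that("head-on term: power ratio, exponential variant, asymptotic decay", {
  bp <- canonical_blue
  # (2.5/5.0)^-4 = 16 exactly for the fixed n1 = -4
  expect_equal(headon_term(2.5, bp) / headon_term(5, bp), 16)
  expect_equal(headon_term(bp$d0, bp), bp$dnu_d0)
  expect_equal(headon_term(bp$d0, bp, "exponential"), bp$dnu_d0)
  # short-distance head-on blueshift is of order 50 cm^-1
  expect_gt(headon_term(2.5, bp), 45)
  expect_lt(headon_term(2.5, bp), 56)
  # decay below any tolerance far out
  expect_lt(headon_term(50, bp), 1e-3)
  expect_lt(headon_term(50, bp, "exponential"), 1e-3)
  expect_true(all(diff(headon_term(seq(2.5, 5, 0.1), bp)) < 0))
  expect_error(headon_term(-1, bp), "positive")
})

test_that("side-on term: zero at d0, negative well, long-range decay, bound", {
  bp <- canonical_blue
  expect_equal(sideon_term(bp$d0, bp), 0)
  # negative minimum between d0 and ~4.5 A
  opt <- optimize(function(d) sideon_term(d, bp), c(bp$d0, 4.5))
  expect_lt(opt$objective, -1)
  expect_gt(opt$minimum, bp$d0)
  expect_lt(opt$minimum, 4.5)
  # nearly negligible at long range
  expect_lt(abs(sideon_term(8, bp)), 0.5)
  expect_error(sideon_term(2.0, bp), "2.5")
})

test_that("blueshift surface: asymptotics, monotonicities, range, anchors' scale", {
  bp <- canonical_blue
  # decay to zero at d = 50 for every angle
  for (th in c(70, 90, 120, 150, 175, 180))
    expect_lt(abs(suppressWarnings(hb_blueshift(50, th, bp))), 0.01)

  # monotone decreasing in d for head-on-like approach
  d <- seq(2.5, 5, by = 0.05)
  expect_true(all(diff(as.numeric(hb_blueshift(d, 175, bp))) < 0))

  # increasing in angle at d = 3.0 from side-on to head-on
  th <- seq(90, 175, by = 1)
  expect_true(all(diff(as.numeric(hb_blueshift(3.0, th, bp))) > 0))

  # surface range over the calibrated grid: spans roughly -4 to 54 cm^-1
  grid <- expand.grid(d = seq(2.5, 5, length.out = 60),
                      theta = seq(70, 175, length.out = 60))
  v <- as.numeric(hb_blueshift(grid$d, grid$theta, bp))
  expect_gt(min(v), -6); expect_lt(min(v), -2)
  expect_gt(max(v), 50); expect_lt(max(v), 56)

  # out-of-range distances warn and carry the extrapolation flag
  expect_warning(res <- hb_blueshift(c(3.0, 9.5), c(170, 170), bp),
                 "extrapolated")
  expect_identical(attr(res, "extrapolated"), c(FALSE, TRUE))
  expect_error(hb_blueshift(3.0, 200, bp), "theta")
})

test_that("total frequency: decomposition, exact additivity, HB count limit", {
  g1 <- data.frame(d = 2.93, theta = 169)
  g2 <- data.frame(d = 3.4, theta = 120)
  no_hb <- total_frequency(-78, NULL, derived_vse, canonical_blue)
  expect_identical(no_hb, vse_frequency(-78, derived_vse))

  both <- total_frequency(-78, rbind(g1, g2), derived_vse, canonical_blue)
  expect_equal(both - no_hb,
               as.numeric(hb_blueshift(2.93, 169, canonical_blue)) +
                 as.numeric(hb_blueshift(3.4, 120, canonical_blue)))

  twice <- total_frequency(-78, rbind(g1, g1), derived_vse, canonical_blue)
  expect_equal(twice - no_hb,
               2 * as.numeric(hb_blueshift(2.93, 169, canonical_blue)))

  # single head-on HB lands within the model's residual scale of the
  # observed protein band
  one <- total_frequency(-78, g1, derived_vse, canonical_blue)
  expect_lt(abs(one - 2241.3), 3)

  expect_error(total_frequency(-78, rbind(g1, g1, g2), derived_vse,
                               canonical_blue), "2 simultaneous")
})

test_that("parameter objects validate and round-trip through config files", {
  expect_error(vse_params(nu0 = -1), "nu0")
  expect_error(blueshift_params(m = 1.5), "m")
  expect_error(blueshift_params(b = -2), "b")

  path <- tempfile(fileext = ".yaml")
  write_params(vse_params(nu0 = 2231, dmu = 0.3), blueshift_params(m = 0.88),
               path)
  cfg <- read_params(path)
  expect_equal(cfg$vse$nu0, 2231)
  expect_equal(cfg$blueshift$m, 0.88)

  # the bundled default config reproduces the canonical parameter set
  bundled <- read_params(system.file("extdata", "default_params.yaml",
                                     package = "vsemap"))
  expect_equal(unclass(bundled$blueshift), unclass(blueshift_params()))
  expect_equal(unclass(bundled$vse), unclass(vse_params()))
})

test_that("field projection uses the unit probe axis", {
  expect_equal(field_projection(c(0, 0, -60), c(0, 0, 2)), -60)
  expect_equal(field_projection(c(3, 4, 0), c(0, 0, 1)), 0)
  expect_error(field_projection(c(1, 2, 3), c(0, 0, 0)), "non-zero")
})
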
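test_that("univariate profiles evaluate to their defining formulas", {
  expect_equal(ustar_minimum(0.5, 1), 0.5)
  expect_equal(ustar_minimum(0.0, 1), 0.0)
  expect_equal(ustar_minimum(0.3, 0.8), 0.24)

  expect_equal(ustar_harmonic(0.5, 2), 0.5)
  expect_equal(ustar_harmonic(0.5, 1), 0.25)   # half the adults unmated
  expect_equal(ustar_harmonic(0.25, 2), 0.375) # exceeds min(0.25, 0.75)

  expect_equal(ustar_minharmonic(0.5, 0.8), 0.40)  # = e/2 at balance
  expect_equal(ustar_minharmonic(0.3, 0.9), 0.30)  # min branch
  expect_equal(ustar_minharmonic(0.5, 1.0), 0.50)  # minimum of parameter 1
  expect_equal(ustar_minharmonic(0.5, 0.4), 0.20)  # harmonic p = 2e branch
})

test_that("profiles reject out-of-range arguments", {
  expect_error(ustar_minimum(-0.1, 1), "fstar")
  expect_error(ustar_harmonic(1.2, 1), "fstar")
  expect_error(ustar_minharmonic(0.5, 1.5), "'e'")
  expect_error(mating_function("minharmonic", e = -0.2), "'e'")
  expect_error(mating_function("minimum", p = -1), "'p'")
  expect_error(unions(-1, 10, "minimum"), "non-negative")
})

test_that("bivariate unions follow the homogeneity reduction", {
  mh8 <- mating_function("minharmonic", e = 0.8)
  mh9 <- mating_function("minharmonic", e = 0.9)
  expect_equal(unions(100, 100, mh8), 80)
  expect_equal(unions(70, 30, mh9), 30)   # every female mates
  expect_equal(unions(0, 50, mh8), 0)
  expect_equal(unions(50, 0, "harmonic"), 0)
  expect_equal(unions(0, 0, "minimum"), 0) # extinct pool, no division
})

test_that("modified harmonic mean caps pairs by the female count only", {
  expect_equal(unions(100, 100, "modified_harmonic"), 100)
  expect_equal(unions(10, 1000, "modified_harmonic"), 2 * 10 * 1000 / 1010)
  expect_gt(unions(10, 1000, "modified_harmonic"), 10)  # exceeds the males
  expect_equal(unions(0, 100, "modified_harmonic"), 0)
  expect_error(ustar("modified_harmonic", 0.5), "univariate")
})

test_that("mating efficiency is unions over the limiting sex", {
  expect_equal(mating_efficiency(100, 100,
                                 mating_function("minharmonic", e = 0.8)),
               0.8)
  expect_equal(mating_efficiency(100, 100,
                                 mating_function("harmonic", p = 2)), 1.0)
  expect_equal(mating_efficiency(70, 30,
                                 mating_function("minharmonic", e = 0.9)),
               1.0)
  expect_error(mating_efficiency(0, 30, "minimum"), "undefined")
})

test_that("efficiency at balance is e, p, and p/2 by family", {
  expect_equal(efficiency_at_balance(mating_function("minimum", p = 0.8)),
               0.8)
  expect_equal(efficiency_at_balance(mating_function("harmonic", p = 1.6)),
               0.8)
  expect_equal(efficiency_at_balance(mating_function("minharmonic",
                                                     e = 0.37)), 0.37)
})

fs <- seq(1e-3, 1 - 1e-3, length.out = 1001)

test_that("every family is symmetric about the balanced OSR", {
  for (fn in list(mating_function("minimum", p = 0.7),
                  mating_function("harmonic", p = 2),
                  mating_function("minharmonic", e = 0.3),
                  mating_function("minharmonic", e = 0.8))) {
    expect_equal(ustar(fn, fs), ustar(fn, 1 - fs), tolerance = 1e-14,
                 info = format(fn))
  }
})

test_that("minharmonic obeys the Pollak bound, tight on the outer branches", {
  g <- c(0.5, 1, 7, 30, 100, 1234, 1e4)
  mf <- expand.grid(m = g, f = g)
  for (e in seq(0, 1, by = 0.1)) {
    fn <- mating_function("minharmonic", e = e)
    u <- unions(mf$m, mf$f, fn)
    expect_true(all(u <= pmin(mf$m, mf$f) + 1e-10), info = paste("e =", e))
  }
  # equality on the outer (minimum) branches: OSR beyond the mixing zone
  u <- unions(900, 100, mating_function("minharmonic", e = 0.8))
  expect_equal(u, 100)  # f* = 0.1 <= e - 0.5
})

test_that("minharmonic limits coincide with minimum and harmonic families", {
  expect_equal(ustar_minharmonic(fs, 1), ustar_minimum(fs, 1))
  expect_equal(ustar_minharmonic(fs, 0.5), ustar_harmonic(fs, 1))
  expect_equal(ustar_minharmonic(fs, 0.3), ustar_harmonic(fs, 0.6))
})

test_that("minharmonic branches join with equal value and slope", {
  for (e in seq(0.55, 0.95, by = 0.05)) {
    b <- e - 0.5
    # value: both branch formulas agree at the joint
    expect_equal((b * (1 - b) - (e - 0.5)^2) / (2 * (1 - e)),
                 min(b, 1 - b), tolerance = 1e-12)
    # slope: outer branch has slope 1; middle branch (1 - 2f*)/(2(1-e))
    expect_equal((1 - 2 * b) / (2 * (1 - e)), 1, tolerance = 1e-12)
    # numerically visible as a smooth profile across both joints
    for (joint in c(b, 1.5 - e)) {
      d <- 1e-6
      left  <- (ustar_minharmonic(joint, e) -
                  ustar_minharmonic(joint - d, e)) / d
      right <- (ustar_minharmonic(joint + d, e) -
                  ustar_minharmonic(joint, e)) / d
      expect_lt(abs(left - right), 1e-4)
    }
  }
})

test_that("minharmonic efficiency is 1 at the extremes, e at balance, and
           monotone towards balance", {
  for (e in c(0.5, 0.6, 0.8, 0.95)) {
    fn <- mating_function("minharmonic", e = e)
    eff <- ustar(fn, fs) / pmin(fs, 1 - fs)
    # exactly 1 on the min branch (e > 0.5); for e = 0.5 the min branch
    # is empty and the efficiency only tends to 1 at the extremes
    tol_end <- if (e > 0.5) 1e-10 else 2 * fs[1]
    expect_equal(eff[1], 1, tolerance = tol_end)
    expect_equal(eff[length(fs)], 1, tolerance = tol_end)
    expect_equal(mating_efficiency(1, 1, fn), e)
    left <- eff[fs <= 0.5]
    expect_true(all(diff(left) <= 1e-12))
    right <- eff[fs >= 0.5]
    expect_true(all(diff(right) >= -1e-12))
  }
  # below e = 0.5 the harmonic form caps the extreme-OSR efficiency at 2e
  eff0 <- ustar(mating_function("minharmonic", e = 0.3), fs) /
    pmin(fs, 1 - fs)
  expect_equal(max(eff0), 2 * 0.3 * (1 - fs[1]), tolerance = 1e-10)
})

test_that("unions are homogeneous of degree one in the sexes", {
  cases <- expand.grid(m = c(3, 47, 1000), f = c(1, 52, 880))
  for (fn in list(mating_function("minharmonic", e = 0.75),
                  mating_function("harmonic", p = 1),
                  mating_function("modified_harmonic"))) {
    u <- unions(cases$m, cases$f, fn)
    for (k in c(2, 10, 0.5)) {
      expect_equal(unions(k * cases$m, k * cases$f, fn), k * u,
                   tolerance = 1e-12, info = paste(format(fn), "k =", k))
    }
  }
})

test_that("specification objects are strict about their parameters", {
  expect_error(mating_function("minharmonic", p = 1), "'e'")
  expect_error(mating_function("minimum", e = 0.5), "'e'")
  expect_error(mating_function("modified_harmonic", p = 1), "no free")
  expect_identical(as_mating_function("harmonic")$p, 2)
  expect_identical(as_mating_function("minimum")$p, 1)
  expect_output(print(mating_function("minharmonic", e = 0.8)),
                "minharmonic")
})
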
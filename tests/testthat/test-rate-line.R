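test_that("published PEI rates reproduce the reported k_on and k_off", {
  r <- pei_rates()
  line <- fit_rate_line(r$conc_uM, r$k_obs, basis = "polymeric")
  expect_equal(line$slope, 0.0370588, tolerance = 1e-5)
  expect_equal(line$intercept, 0.0142983, tolerance = 1e-4)
  p <- kinetic_params_from_line(line)
  expect_equal(p$k_on, line$slope)
  expect_equal(p$k_off, line$intercept)
  expect_equal(dissociation_constant(p), 386, tolerance = 1e-3)
})

test_that("published PAZO rates give the monomeric-basis slope alpha", {
  r <- pazo_rates()
  line <- fit_rate_line(r$conc_mM, r$k_obs, basis = "monomeric")
  expect_equal(line$slope, 0.0577157, tolerance = 1e-5)
  expect_equal(line$intercept, 0.0279292, tolerance = 1e-4)
})

test_that("rate line validates its design", {
  line <- fit_rate_line(c(0, 1, 2), c(1, 2, 3), basis = "polymeric")
  expect_equal(unname(coef(line)), c(1, 1))
  expect_equal(line$r_squared, 1)
  expect_error(fit_rate_line(c(0, 1), c(1, 2)), "at least 3")
  expect_error(fit_rate_line(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(fit_rate_line(c(-1, 0, 1), c(1, 2, 3)), "non-negative")
  expect_error(fit_rate_line(c(0, 1, 2), c(1, 2, 3), weights = c(1, -1, 1)),
               "positive")
})

test_that("least squares agrees with the normal-equation oracle", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    x <- abs(rnorm(n, 1, 0.5)); y <- rnorm(n)
    if (diff(range(x)) == 0) next
    line <- fit_rate_line(x, y, basis = "polymeric")
    oracle <- ols_oracle(x, y)
    scale <- max(abs(y)) + 1
    expect_lt(abs(line$slope - oracle["slope"]), 1e-12 * scale)
    expect_lt(abs(line$intercept - oracle["intercept"]), 1e-12 * scale)
  }
})

test_that("rate line obeys shift, scale and weighting identities", {
  x <- c(0.1, 0.4, 0.9, 1.7, 2.2)
  y <- c(0.02, 0.03, 0.05, 0.08, 0.1)
  base <- fit_rate_line(x, y, basis = "polymeric")
  shifted <- fit_rate_line(x, y + 0.5, basis = "polymeric")
  expect_equal(shifted$slope, base$slope, tolerance = 1e-12)
  expect_equal(shifted$intercept, base$intercept + 0.5, tolerance = 1e-12)

  scaled <- fit_rate_line(x * 4, y, basis = "polymeric")
  expect_equal(scaled$slope, base$slope / 4, tolerance = 1e-12)
  expect_equal(scaled$intercept, base$intercept, tolerance = 1e-12)

  weighted <- fit_rate_line(x, y, weights = rep(2.5, 5), basis = "polymeric")
  expect_equal(weighted$slope, base$slope, tolerance = 1e-12)
  expect_equal(weighted$intercept, base$intercept, tolerance = 1e-12)
})

test_that("kinetic parameter extraction enforces basis and clamps", {
  mono <- fit_rate_line(c(1, 0.5, 0.25), c(0.08, 0.06, 0.05),
                        basis = "monomeric")
  expect_error(kinetic_params_from_line(mono), "monomeric")

  neg <- fit_rate_line(c(0.5, 1, 2), c(0.0004, 0.001, 0.002),
                       basis = "polymeric")
  expect_lt(neg$intercept, 0)
  expect_warning(p <- kinetic_params_from_line(neg), "clamped")
  expect_equal(p$k_off, 0)
  expect_equal(attr(p, "raw_intercept"), neg$intercept)

  expect_equal(dissociation_constant(kinetic_params(1, 0)), 0)
  expect_equal(dissociation_constant(kinetic_params(0.02, 0.02)), 1000)
})

test_that("linearity check flags linear buildup and rejects noise", {
  exact <- linearity_check(1:5, 2 * (1:5) + 3)
  expect_equal(exact$r_squared, 1)
  expect_equal(exact$slope, 2)

  b <- simulate_multilayer(5, delta_ru = 500, noise_sd = 1, seed = 0)
  expect_gt(linearity_check(b$bilayer, b$ru)$r_squared, 0.999)

  r2_noise <- vapply(1:100, function(s) {
    set.seed(s)
    linearity_check(1:5, rnorm(5))$r_squared
  }, numeric(1))
  expect_lt(median(r2_noise), 0.5)
})
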
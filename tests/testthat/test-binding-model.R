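test_that("observed rate is affine in chain concentration", {
  p <- kinetic_params(0.0370588, 0.0142983)
  expect_equal(observed_rate(0, p), p$k_off)
  expect_equal(observed_rate(1.72, p), 0.0780394, tolerance = 1e-5)
  expect_equal(observed_rate(1, kinetic_params(1, 0)), 1)
  expect_error(observed_rate(-0.1, p), "non-negative")
  # affinity: increments depend only on the concentration step
  for (a in c(0, 0.3, 2.5)) {
    expect_equal(observed_rate(a + 1.7, p) - observed_rate(a, p),
                 p$k_on * 1.7, tolerance = 1e-12)
  }
})

test_that("association response follows the integrated 1:1 model", {
  p <- kinetic_params(0.0370588, 0.0142983)
  expect_equal(association_response(0, 1.72, p, 1000), 0)
  # zero off-rate: saturation at r_max
  p0 <- kinetic_params(0.05, 0)
  expect_equal(association_response(1e5, 1, p0, 800), 800, tolerance = 1e-8)
  # equilibrium amplitude R_eq = r_max * C / (C + K_D)
  expect_equal(association_response(1e4, 1.72, p, 1000),
               1000 * 0.0637411 / 0.0780394, tolerance = 1e-4)
  expect_error(association_response(-1, 1.72, p, 1000), ">= 0")
  expect_equal(association_response(c(10, 20), 0, p, 1000), c(0, 0))
})

test_that("association response is monotone in time and concentration", {
  p <- kinetic_params(0.04, 0.01)
  t <- seq(0, 600, by = 5)
  for (conc in c(0.1, 0.5, 2)) {
    expect_true(all(diff(association_response(t, conc, p, 1000)) >= 0))
  }
  concs <- seq(0, 3, by = 0.25)
  for (tt in c(10, 100, 400)) {
    r <- vapply(concs, function(cc) association_response(tt, cc, p, 1000),
                numeric(1))
    expect_true(all(diff(r) >= 0))
  }
})

test_that("dissociation response decays exponentially from r_end", {
  expect_equal(dissociation_response(0, 800, 0.0142983), 800)
  expect_equal(dissociation_response(c(0, 100, 1e4), 800, 0),
               rep(800, 3))
  # half-life identity: t = ln(2)/k_off halves the response
  expect_equal(dissociation_response(log(2) / 0.0142983, 800, 0.0142983),
               400, tolerance = 1e-10)
  t <- seq(0, 300, by = 1)
  expect_true(all(diff(dissociation_response(t, 800, 0.02)) <= 0))
  expect_error(dissociation_response(-5, 800, 0.01), ">= 0")
})

test_that("simulated association and dissociation join continuously", {
  cfg <- quiet_cfg(baseline = 0, bulk_shift = 0)
  s <- simulate_sensorgram(cfg, conc_mM = 1)
  i_end <- which(s$time == cfg$baseline_duration + cfg$association_duration)
  # the dissociation phase starts exactly at the association end value and
  # the first washout step is bounded by the single-step decay
  conc_uM <- monomeric_to_polymeric(1, cfg$polymer)
  r_end <- association_response(cfg$association_duration, conc_uM,
                                cfg$params, cfg$r_max)
  expect_equal(dissociation_response(0, r_end, cfg$params$k_off),
               s$active[i_end])
  expect_lte(abs(s$active[i_end + 1L] - s$active[i_end]),
             r_end * (1 - exp(-cfg$params$k_off / cfg$sample_rate)) + 1e-9)
})

test_that("response units convert linearly to bound mass", {
  expect_equal(ru_to_mass(1000), 100)
  expect_equal(ru_to_mass(0), 0)
  expect_equal(ru_to_mass(250), 25)
})

test_that("parameter containers validate their invariants", {
  expect_error(kinetic_params(-1, 0.1), "positive")
  expect_error(kinetic_params(0.1, -1), "non-negative")
  expect_error(kinetic_params(0.1, 0.1, se_k_on = -2), ">= 0")
  expect_error(polymer("x", -1), "positive")
  expect_error(polymer("x", 100, 50), ">=")
  expect_error(sensorgram(c(0, 1, 1, 2), rep(0, 4), injection_start = 0,
                          injection_end = 2), "strictly increasing")
  expect_error(sensorgram(0:10, rep(0, 11), injection_start = 5,
                          injection_end = 20), "injection")
})
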
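test_that("simulation is deterministic given a seed", {
  cfg <- simulation_config(truth_params(), pei_polymer(), seed = 99L)
  a <- simulate_sensorgram(cfg, 1)
  b <- simulate_sensorgram(cfg, 1)
  expect_identical(a$active, b$active)
  expect_identical(a$reference, b$reference)
  c <- simulate_sensorgram(cfg, 1, seed = 100L)
  expect_false(identical(a$active, c$active))
})

test_that("noiseless simulation equals the closed-form model", {
  cfg <- quiet_cfg(baseline = 0, bulk_shift = 0)
  s <- simulate_sensorgram(cfg, 1)
  conc_uM <- monomeric_to_polymeric(1, cfg$polymer)
  t0 <- cfg$baseline_duration
  sel <- s$time >= t0 & s$time <= t0 + cfg$association_duration
  expect_equal(s$active[sel],
               association_response(s$time[sel] - t0, conc_uM, cfg$params,
                                    cfg$r_max))
  expect_equal(s$reference, rep(0, length(s$time)))
})

test_that("gradient produces one trace per concentration per replicate", {
  cfg <- simulation_config(truth_params(), pei_polymer(), replicates = 2,
                           seed = 3L)
  g <- simulate_gradient(cfg)
  expect_length(g, 10)
  expect_equal(vapply(g, function(s) s$conc_mM, numeric(1)),
               rep(cfg$concentrations, each = 2))

  cfg2 <- simulation_config(truth_params(), pei_polymer(),
                            concentrations = c(1, 0.5), seed = 3L)
  expect_error(simulate_gradient(cfg2), "at least 3")
})

test_that("noiseless gradient yields an exactly affine rate line", {
  cfg <- quiet_cfg()
  rates <- rates_from_sensorgrams(simulate_gradient(cfg))
  conc_uM <- monomeric_to_polymeric(rates$conc_mM, cfg$polymer)
  line <- fit_rate_line(conc_uM, rates$k_obs, basis = "polymeric")
  expect_equal(line$slope, cfg$params$k_on, tolerance = 1e-6)
  expect_equal(line$intercept, cfg$params$k_off, tolerance = 1e-6)
  expect_gt(line$r_squared, 1 - 1e-10)
})

test_that("multilayer buildup is linear with per-step increments", {
  clean <- simulate_multilayer(5, delta_ru = 500)
  expect_equal(clean$ru, c(500, 1000, 1500, 2000, 2500))
  expect_equal(linearity_check(clean$bilayer, clean$ru)$r_squared, 1)

  noisy <- simulate_multilayer(5, delta_ru = 500, noise_sd = 10, seed = 0)
  expect_gt(linearity_check(noisy$bilayer, noisy$ru)$r_squared, 0.99)
  expect_error(simulate_multilayer(0), ">= 1")
})

test_that("transport-limited curve converges to reaction control", {
  cfg <- quiet_cfg(baseline = 0, bulk_shift = 0)
  k_scale <- cfg$params$k_on * cfg$r_max
  s_r <- simulate_sensorgram(cfg, 1)
  s_fast <- simulate_transport_limited(cfg, 1, k_m = 1e6 * k_scale)
  conc_uM <- monomeric_to_polymeric(1, cfg$polymer)
  r_eq <- cfg$r_max * conc_uM /
    (conc_uM + cfg$params$k_off / cfg$params$k_on)
  expect_lt(max(abs(s_fast$active - s_r$active)), 0.001 * r_eq)

  # strong transport limitation depresses the initial association slope
  s_slow <- simulate_transport_limited(cfg, 1, k_m = 0.01 * k_scale)
  t0 <- cfg$baseline_duration
  i <- which(s_r$time > t0 & s_r$time <= t0 + 10)
  expect_lt(max(diff(s_slow$active[i])), 0.2 * max(diff(s_r$active[i])))
  expect_error(simulate_transport_limited(cfg, 1, k_m = 0), "positive")
})

test_that("reference correction removes the bulk pulse from a blank run", {
  cfg <- simulation_config(truth_params(), pei_polymer(), noise_sd = 2,
                           bulk_shift = 25, seed = 17L)
  blank <- simulate_sensorgram(cfg, conc_mM = 0)
  corr <- zero_baseline(subtract_reference(blank))
  during <- corr$time >= cfg$baseline_duration &
    corr$time <= cfg$baseline_duration + cfg$association_duration
  # channel-difference noise has SD sqrt(2)*2 RU; the in-window mean of
  # ~300 samples (plus the baseline-window offset) stays within ~3 SD
  expect_lt(abs(mean(corr$active[during])), 3)
})

test_that("fitted-rate spread grows with the noise level", {
  cfg0 <- quiet_cfg()
  spread <- vapply(c(0.5, 2, 8), function(sigma) {
    ks <- vapply(1:50, function(s) {
      cfg <- quiet_cfg(noise_sd = sigma, seed = 1000L + s)
      tr <- preprocess_sensorgram(simulate_sensorgram(cfg, 0.25))
      fit_transient(tr)$k_obs
    }, numeric(1))
    stats::sd(ks)
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})
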
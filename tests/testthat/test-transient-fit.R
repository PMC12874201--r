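test_that("one-phase fit recovers generating parameters on exact data", {
  t <- 0:300
  for (C in c(200, 500, 800, 1000, 1500)) {
    for (k in c(0.005, 0.02, 0.05, 0.1, 0.3)) {
      tr <- as_transient(t, C * (1 - exp(-k * t)))
      fit <- fit_transient(tr)
      expect_lt(abs(fit$k_obs - k) / k, 1e-6)
      expect_lt(abs(fit$plateau - C) / C, 1e-6)
      expect_gt(fit$r_squared, 1 - 1e-12)
    }
  }
})

test_that("one-phase fit handles noise and degenerate inputs", {
  t <- 0:300
  set.seed(0)
  tr <- as_transient(t, 800 * (1 - exp(-0.075 * t)) + rnorm(301, 0, 2))
  fit <- fit_transient(tr)
  expect_lt(abs(fit$k_obs - 0.075), 3 * fit$se_k_obs)
  expect_gt(fit$r_squared, 0.99)

  expect_error(fit_transient(as_transient(t, rep(0, 301))), "degenerate")
  expect_error(fit_transient(as_transient(0:3, c(0, 1, 2, 3))), "at least 5")
})

test_that("two-phase fit recovers biphasic truth and flags degeneracy", {
  t <- 0:400
  y <- 400 * (1 - exp(-0.1 * t)) + 400 * (1 - exp(-0.01 * t))
  fit <- fit_transient(as_transient(t, y), model = "two_phase")
  expect_equal(fit$model, "two_phase")
  expect_gte(fit$k_fast, fit$k_slow)
  expect_lt(abs(fit$k_fast - 0.1) / 0.1, 1e-4)
  expect_lt(abs(fit$k_slow - 0.01) / 0.01, 1e-4)
  expect_false(fit$degenerate)

  # single-exponential truth: the second phase is unidentifiable
  y1 <- 800 * (1 - exp(-0.05 * t))
  fit1 <- fit_transient(as_transient(t, y1), model = "two_phase")
  expect_true(fit1$degenerate || fit1$fallback)

  expect_error(fit_transient(as_transient(0:5, (0:5)^0.5), "two_phase"),
               "at least 7")
})

test_that("fits are equivariant under response and time rescaling", {
  t <- 0:300
  y <- 600 * (1 - exp(-0.04 * t))
  base <- fit_transient(as_transient(t, y))
  scaled <- fit_transient(as_transient(t, 3.7 * y))
  expect_equal(scaled$k_obs, base$k_obs, tolerance = 1e-8)
  expect_equal(scaled$plateau, 3.7 * base$plateau, tolerance = 1e-8)

  stretched <- fit_transient(as_transient(t * 2, y))
  expect_equal(stretched$k_obs, base$k_obs / 2, tolerance = 1e-8)
})

test_that("model comparison prefers the generating model", {
  t <- 0:300
  cmp_self <- local({
    f <- fit_transient(as_transient(t, 500 * (1 - exp(-0.05 * t)) + 0.01))
    compare_models(f, f)
  })
  expect_equal(cmp_self$delta_r_squared, 0)
  expect_equal(cmp_self$delta_aicc, 0)

  pick <- function(y) {
    tr <- as_transient(t, y)
    f1 <- fit_transient(tr, "one_phase")
    f2 <- fit_transient(tr, "two_phase")
    if (f2$fallback) return("fit1")   # degenerate two-phase collapses
    compare_models(f1, f2)$preferred
  }
  n_seeds <- 40
  mono <- vapply(seq_len(n_seeds), function(s) {
    set.seed(s)
    pick(700 * (1 - exp(-0.06 * t)) + rnorm(length(t), 0, 3))
  }, character(1))
  expect_gt(mean(mono == "fit1"), 0.5)

  biph <- vapply(seq_len(n_seeds), function(s) {
    set.seed(s)
    pick(400 * (1 - exp(-0.15 * t)) + 400 * (1 - exp(-0.008 * t)) +
           rnorm(length(t), 0, 3))
  }, character(1))
  expect_gt(mean(biph == "fit2"), 0.5)

  f_a <- fit_transient(as_transient(t, 500 * (1 - exp(-0.05 * t)) + 0.01))
  f_b <- fit_transient(as_transient(t, 400 * (1 - exp(-0.05 * t)) + 0.01))
  expect_error(compare_models(f_a, f_b), "same transient")
})

test_that("replicate aggregation gives mean and SEM", {
  a <- aggregate_replicates(c(2, 4))
  expect_equal(a$mean_k_obs, 3)
  expect_equal(a$sem_k_obs, 1)

  b <- aggregate_replicates(c(0.07, 0.08))
  expect_equal(b$mean_k_obs, 0.075)
  expect_equal(b$sem_k_obs, 0.005)

  single <- aggregate_replicates(0.05)
  expect_equal(single$mean_k_obs, 0.05)
  expect_true(is.na(single$sem_k_obs))
  expect_false(single$sem_defined)

  expect_error(aggregate_replicates(numeric(0)), "no replicate")
})
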
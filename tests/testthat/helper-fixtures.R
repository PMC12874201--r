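# shared fixtures: ground-truth kinetics and quick simulator configs

truth_params <- function() kinetic_params(k_on = 0.037, k_off = 0.014)

# unknown-polymer truth used in recovery tests: DP = 642 repeat units
pazo_true <- function() polymer("PAZO", M_o = 401, M_n = 642 * 401)

quiet_cfg <- function(params = truth_params(), poly = pei_polymer(),
                      noise_sd = 0, replicates = 1, seed = 1L, ...) {
  simulation_config(params, poly, noise_sd = noise_sd,
                    replicates = replicates, seed = seed, ...)
}

# independent closed-form OLS oracle (centered normal equations)
ols_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(intercept = my - slope * mx, slope = slope)
}
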
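# evaluate expr under a fixed seed without disturbing the caller's RNG
with_seed_ <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Configuration for the synthetic sensorgram generator
#'
#' Bundles the ground-truth kinetics and the acquisition protocol used to
#' generate synthetic dual-channel sensorgrams. Defaults mirror the
#' reference experiment: 300 s association followed by 300 s dissociation
#' sampled at 1 Hz, monomeric concentration series
#' {1, 0.5, 0.25, 0.125, 0.0625} mM in duplicate, plus a 60 s pre-injection
#' baseline segment so that baseline zeroing has data to work with.
#' `r_max` = 1000 RU and Gaussian noise of 2 RU are nominal values for a
#' benchtop LSPR instrument (published traces do not report either).
#'
#' @param params Ground-truth [kinetic_params()].
#' @param polymer Ground-truth analyte [polymer()] (with `M_n`), used to
#'   convert the monomeric concentrations of `concentrations` to chain uM.
#' @param r_max Saturation response, RU.
#' @param concentrations Monomeric concentrations, mM.
#' @param noise_sd Gaussian noise SD per sample, RU.
#' @param bulk_shift Bulk refractive-index square pulse during injection,
#'   RU (appears in both channels).
#' @param baseline Constant instrument offset, RU (both channels).
#' @param sample_rate Samples per second, Hz.
#' @param baseline_duration,association_duration,dissociation_duration
#'   Segment lengths, seconds.
#' @param replicates Injections per concentration.
#' @param seed Integer seed; recorded in every simulated sensorgram.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(params, polymer,
                              r_max = 1000,
                              concentrations = c(1, 0.5, 0.25, 0.125, 0.0625),
                              noise_sd = 2, bulk_shift = 25, baseline = 37.5,
                              sample_rate = 1,
                              baseline_duration = 60,
                              association_duration = 300,
                              dissociation_duration = 300,
                              replicates = 2, seed = 1L) {
  stopifnot(inherits(params, "kinetic_params"), inherits(polymer, "polymer"))
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (sample_rate <= 0) stop("'sample_rate' must be positive", call. = FALSE)
  if (any(c(baseline_duration, association_duration,
            dissociation_duration) <= 0)) {
    stop("segment durations must be positive", call. = FALSE)
  }
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  structure(list(params = params, polymer = polymer, r_max = r_max,
                 concentrations = as.numeric(concentrations),
                 noise_sd = noise_sd, bulk_shift = bulk_shift,
                 baseline = baseline, sample_rate = sample_rate,
                 baseline_duration = baseline_duration,
                 association_duration = association_duration,
                 dissociation_duration = dissociation_duration,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

sim_time_grid <- function(cfg) {
  total <- cfg$baseline_duration + cfg$association_duration +
    cfg$dissociation_duration
  seq(0, total, by = 1 / cfg$sample_rate)
}

# deterministic (noise-free, offset-free) binding component on the grid
sim_binding_signal <- function(cfg, conc_uM, time) {
  t0 <- cfg$baseline_duration
  t1 <- t0 + cfg$association_duration
  resp <- numeric(length(time))
  assoc <- time >= t0 & time <= t1
  resp[assoc] <- association_response(time[assoc] - t0, conc_uM,
                                      cfg$params, cfg$r_max)
  r_end <- association_response(cfg$association_duration, conc_uM,
                                cfg$params, cfg$r_max)
  dis <- time > t1
  resp[dis] <- dissociation_response(time[dis] - t1, r_end, cfg$params$k_off)
  resp
}

#' Simulate a dual-channel sensorgram
#'
#' Active channel = baseline offset + bulk square pulse during the
#' injection + closed-form 1:1 binding response (association then washout
#' dissociation) + i.i.d. Gaussian noise. Reference channel = baseline +
#' the same bulk pulse + independent noise (no binding). Deterministic for
#' a given seed.
#'
#' @param cfg A [simulation_config()].
#' @param conc_mM Monomeric analyte concentration, mM.
#' @param seed Seed for this trace; defaults to `cfg$seed`.
#' @return A dual-channel [sensorgram()].
#' @examples
#' cfg <- simulation_config(kinetic_params(0.037, 0.014), pei_polymer(),
#'                          seed = 7)
#' s <- simulate_sensorgram(cfg, conc_mM = 1)
#' @export
simulate_sensorgram <- function(cfg, conc_mM, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  time <- sim_time_grid(cfg)
  conc_uM <- monomeric_to_polymeric(conc_mM, cfg$polymer)
  t0 <- cfg$baseline_duration
  t1 <- t0 + cfg$association_duration
  pulse <- cfg$bulk_shift * (time >= t0 & time <= t1)
  binding <- sim_binding_signal(cfg, conc_uM, time)
  noise <- with_seed_(seed, {
    list(active = stats::rnorm(length(time), 0, cfg$noise_sd),
         reference = stats::rnorm(length(time), 0, cfg$noise_sd))
  })
  sensorgram(time = time,
             active = cfg$baseline + pulse + binding + noise$active,
             reference = cfg$baseline + pulse + noise$reference,
             injection_start = t0, injection_end = t1,
             analyte = cfg$polymer, conc_mM = conc_mM,
             flow_rate = 30)
}

#' Simulate a concentration gradient
#'
#' One dual-channel sensorgram per concentration per replicate; trace seeds
#' are derived deterministically from `cfg$seed`.
#'
#' @param cfg A [simulation_config()] with at least 3 concentrations.
#' @return A list of [sensorgram()]s with attributes `conc_mM` and
#'   `replicate` per element.
#' @export
simulate_gradient <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (length(cfg$concentrations) < 3L) {
    stop("need at least 3 concentrations", call. = FALSE)
  }
  out <- list()
  idx <- 0L
  for (conc in cfg$concentrations) {
    for (rep in seq_len(cfg$replicates)) {
      idx <- idx + 1L
      s <- simulate_sensorgram(cfg, conc,
                               seed = (cfg$seed + 7919L * idx) %% 2147483647L)
      attr(s, "replicate") <- rep
      out[[idx]] <- s
    }
  }
  out
}

#' Simulate layer-by-layer multilayer buildup
#'
#' Cumulative response after each deposited bilayer: `i * delta_ru` plus
#' Gaussian noise, emulating a linear layer-by-layer polyelectrolyte
#' multilayer assembly.
#'
#' @param n_bilayers Number of bilayers, >= 1.
#' @param delta_ru Response increment per bilayer, RU.
#' @param noise_sd Gaussian noise SD, RU.
#' @param seed Optional seed.
#' @return Data frame with `bilayer` and `ru`.
#' @export
simulate_multilayer <- function(n_bilayers, delta_ru = 500, noise_sd = 0,
                                seed = NULL) {
  if (n_bilayers < 1) stop("'n_bilayers' must be >= 1", call. = FALSE)
  i <- seq_len(n_bilayers)
  noise <- with_seed_(seed, stats::rnorm(n_bilayers, 0, noise_sd))
  data.frame(bilayer = i, ru = i * delta_ru + noise)
}

#' Simulate a mass-transport-limited sensorgram
#'
#' Two-compartment model with a quasi-steady surface concentration: the
#' binding flux `dR/dt = k_on C_s (R_max - R) - k_off R` is balanced
#' against delivery `k_m (C_bulk - C_s)`, giving
#' `C_s = (k_m C_bulk + k_off R) / (k_m + k_on (R_max - R))`. The ODE is
#' integrated over the injection (and, with `C_bulk = 0`, the washout).
#' `k_m` has units RU/(uM s); as `k_m -> Inf` the curve converges to the
#' reaction-limited closed form of [simulate_sensorgram()]. Smaller `k_m`
#' (lower flow rate) depresses the initial association slope.
#'
#' @param cfg A [simulation_config()].
#' @param conc_mM Monomeric concentration, mM.
#' @param k_m Transport coefficient, RU/(uM s), positive. Compare with the
#'   reaction-limited flux scale `k_on * r_max`.
#' @param seed Seed for the additive noise; defaults to `cfg$seed`.
#' @return A dual-channel [sensorgram()].
#' @export
simulate_transport_limited <- function(cfg, conc_mM, k_m, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.finite(k_m) || k_m <= 0) stop("'k_m' must be positive", call. = FALSE)
  time <- sim_time_grid(cfg)
  conc_uM <- monomeric_to_polymeric(conc_mM, cfg$polymer)
  k_on <- cfg$params$k_on; k_off <- cfg$params$k_off; r_max <- cfg$r_max
  deriv <- function(t, y, parms) {
    R <- y[1L]
    cs <- (k_m * parms$cb + k_off * R) / (k_m + k_on * (r_max - R))
    list(k_on * cs * (r_max - R) - k_off * R)
  }
  t0 <- cfg$baseline_duration
  t1 <- t0 + cfg$association_duration
  binding <- numeric(length(time))
  assoc_t <- unique(c(0, time[time >= t0 & time <= t1] - t0,
                      cfg$association_duration))
  sol_a <- deSolve::ode(c(R = 0), assoc_t, deriv, list(cb = conc_uM),
                        method = "lsoda", rtol = 1e-10, atol = 1e-8)
  if (attr(sol_a, "istate")[1L] < 0) {
    stop("transport ODE integration failed in the association phase",
         call. = FALSE)
  }
  in_assoc <- time >= t0 & time <= t1
  binding[in_assoc] <- stats::approx(sol_a[, 1L], sol_a[, 2L],
                                     xout = time[in_assoc] - t0)$y
  r_end <- sol_a[nrow(sol_a), 2L]
  dis <- time > t1
  if (any(dis)) {
    dis_t <- unique(c(0, time[dis] - t1))
    sol_d <- deSolve::ode(c(R = r_end), dis_t, deriv, list(cb = 0),
                          method = "lsoda", rtol = 1e-10, atol = 1e-8)
    binding[dis] <- stats::approx(sol_d[, 1L], sol_d[, 2L],
                                  xout = time[dis] - t1)$y
  }
  pulse <- cfg$bulk_shift * (time >= t0 & time <= t1)
  noise <- with_seed_(seed, {
    list(active = stats::rnorm(length(time), 0, cfg$noise_sd),
         reference = stats::rnorm(length(time), 0, cfg$noise_sd))
  })
  sensorgram(time = time,
             active = cfg$baseline + pulse + binding + noise$active,
             reference = cfg$baseline + pulse + noise$reference,
             injection_start = t0, injection_end = t1,
             analyte = cfg$polymer, conc_mM = conc_mM, flow_rate = 30)
}
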
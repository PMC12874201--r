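#' Kinetic rate constants of a 1:1 polymer-pair interaction
#'
#' Bundles the bimolecular association rate constant `k_on` (per-uM of
#' polymer chains, per second) and the unimolecular dissociation rate
#' constant `k_off` (per second), with optional standard errors.
#'
#' @param k_on Association rate constant, 1/(uM s), chain (polymeric) basis.
#' @param k_off Dissociation rate constant, 1/s.
#' @param se_k_on,se_k_off Optional standard errors (same units).
#' @return An object of class `"kinetic_params"`.
#' @examples
#' kinetic_params(k_on = 0.03705, k_off = 0.01430)
#' @export
kinetic_params <- function(k_on, k_off, se_k_on = NA_real_, se_k_off = NA_real_) {
  k_on <- as.numeric(k_on); k_off <- as.numeric(k_off)
  if (!is.finite(k_on) || k_on <= 0) stop("'k_on' must be positive", call. = FALSE)
  if (!is.finite(k_off) || k_off < 0) stop("'k_off' must be non-negative", call. = FALSE)
  for (se in c(se_k_on, se_k_off)) {
    if (!is.na(se) && se < 0) stop("standard errors must be >= 0", call. = FALSE)
  }
  structure(list(k_on = k_on, k_off = k_off,
                 se_k_on = as.numeric(se_k_on), se_k_off = as.numeric(se_k_off)),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  fmt <- function(v, se) {
    if (is.na(se)) format(v, digits = 5) else
      paste0(format(v, digits = 5), " +/- ", format(se, digits = 3))
  }
  cat("Kinetic parameters (1:1 pseudo-first-order model)\n")
  cat("  k_on  =", fmt(x$k_on, x$se_k_on), "1/(uM s)  [chain basis]\n")
  cat("  k_off =", fmt(x$k_off, x$se_k_off), "1/s\n")
  cat("  K_D   =", format(dissociation_constant(x), digits = 4), "nM\n")
  invisible(x)
}

#' Observed pseudo-first-order rate constant
#'
#' Under pseudo-first-order conditions (analyte held at constant
#' concentration by continuous flow) the association transient is a single
#' exponential whose observed rate is affine in analyte concentration:
#' `k_obs = k_on * C + k_off`.
#'
#' @param conc_polymeric Analyte chain concentration in uM. Non-negative.
#' @param params A [kinetic_params()].
#' @return `k_obs` in 1/s.
#' @examples
#' observed_rate(1.72, kinetic_params(0.0370588, 0.0142983))
#' @export
observed_rate <- function(conc_polymeric, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(!is.finite(conc_polymeric)) || any(conc_polymeric < 0)) {
    stop("'conc_polymeric' must be non-negative (uM)", call. = FALSE)
  }
  params$k_on * conc_polymeric + params$k_off
}

#' Closed-form association and dissociation responses
#'
#' `association_response()` evaluates the integrated 1:1 pseudo-first-order
#' binding model `R(t) = R_eq * (1 - exp(-k_obs t))` with equilibrium
#' amplitude `R_eq = R_max * C / (C + K_D)` and `k_obs = k_on C + k_off`.
#' `dissociation_response()` evaluates the washout decay
#' `R(t) = R_end * exp(-k_off t)` after the analyte is replaced by buffer.
#'
#' @param t Time since injection start, seconds (vectorized, `t >= 0`).
#' @param conc_polymeric Analyte chain concentration in uM.
#' @param params A [kinetic_params()].
#' @param r_max Surface saturation response `R_max` in RU, positive.
#' @return Response in RU.
#' @examples
#' p <- kinetic_params(0.0370588, 0.0142983)
#' association_response(c(0, 30, 300), 1.72, p, r_max = 1000)
#' dissociation_response(c(0, 48.5), r_end = 800, k_off = 0.0142983)
#' @export
association_response <- function(t, conc_polymeric, params, r_max) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(!is.finite(t)) || any(t < 0)) stop("'t' must be >= 0 s", call. = FALSE)
  if (!is.finite(r_max) || r_max <= 0) stop("'r_max' must be positive", call. = FALSE)
  if (!is.finite(conc_polymeric) || conc_polymeric < 0) {
    stop("'conc_polymeric' must be non-negative (uM)", call. = FALSE)
  }
  if (conc_polymeric == 0) return(rep(0, length(t)))
  kd <- params$k_off / params$k_on              # uM
  r_eq <- r_max * conc_polymeric / (conc_polymeric + kd)
  k_obs <- observed_rate(conc_polymeric, params)
  r_eq * (1 - exp(-k_obs * t))
}

#' @rdname association_response
#' @param t_since_end Time since end of injection, seconds (`>= 0`).
#' @param r_end Response at the end of the association phase, RU.
#' @param k_off Dissociation rate constant, 1/s.
#' @export
dissociation_response <- function(t_since_end, r_end, k_off) {
  if (any(!is.finite(t_since_end)) || any(t_since_end < 0)) {
    stop("'t_since_end' must be >= 0 s", call. = FALSE)
  }
  if (k_off < 0) stop("'k_off' must be >= 0", call. = FALSE)
  r_end * exp(-k_off * t_since_end)
}

#' Convert response units to bound mass
#'
#' The instrument response is linearly proportional to bound surface mass;
#' 1000 RU corresponds to roughly 100 pg, i.e. 0.1 pg per RU.
#'
#' @param response Response in RU (vectorized).
#' @return Bound mass in picograms.
#' @examples
#' ru_to_mass(1000)
#' @export
ru_to_mass <- function(response) 0.1 * response
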
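#' Convert monomeric to polymeric concentration
#'
#' `[Polymeric] = [Monomeric] * M_o / M_n = [Monomeric] / DP`, converted
#' from mM (repeat units) to uM (chains). Requires the polymer's `M_n`.
#'
#' @param conc_mM Monomeric concentration(s) in mM.
#' @param polymer A [polymer()] with known `M_n`.
#' @return Polymeric (chain) concentration in uM.
#' @examples
#' monomeric_to_polymeric(1, pei_polymer())   # ~1.72 uM
#' @export
monomeric_to_polymeric <- function(conc_mM, polymer) {
  dp <- degree_of_polymerization(polymer)
  1000 * as.numeric(conc_mM) / dp
}

#' Degree of polymerization from the two-orientation slope ratio
#'
#' When the same pair is measured in both orientations, the polymeric-basis
#' slope of the characterized partner gives `k_on`, and the monomeric-basis
#' slope of the uncharacterized partner gives `alpha = k_on / DP` (the
#' intrinsic `k_on` being orientation-symmetric). Hence `DP = k_on / alpha`
#' and `M_n = DP * M_o`.
#'
#' @param k_on Association rate constant, 1/(uM s) (chain basis).
#' @param alpha Monomeric-basis slope in 1/(uM s) (per uM of repeat units).
#' @return `solve_dp()`: the dimensionless degree of polymerization.
#' @examples
#' solve_dp(0.0370588, 5.7716e-5)   # ~642
#' @export
solve_dp <- function(k_on, alpha) {
  if (!is.finite(k_on) || k_on <= 0) stop("'k_on' must be positive", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be positive", call. = FALSE)
  k_on / alpha
}

#' @rdname solve_dp
#' @param dp Degree of polymerization.
#' @param M_o Repeat-unit molar mass, g/mol.
#' @return `solve_mn()`: the number-average molecular weight in g/mol.
#' @export
solve_mn <- function(dp, M_o) {
  if (!is.finite(M_o) || M_o <= 0) stop("'M_o' must be positive", call. = FALSE)
  if (dp < 1) warning("DP < 1: sub-monomer chain is unphysical", call. = FALSE)
  dp * M_o
}

#' First-order uncertainty on the determined molecular weight
#'
#' Delta-method propagation through `M_n = M_o * k_on / alpha` assuming
#' independent errors (the two slopes come from separate experiments):
#' `se_DP / DP = sqrt((se_kon/k_on)^2 + (se_alpha/alpha)^2)` and
#' `se_Mn = M_o * se_DP`.
#'
#' @param k_on,se_k_on Chain-basis slope and its SE, 1/(uM s).
#' @param alpha,se_alpha Monomeric-basis slope and its SE, 1/(uM s).
#' @param M_o Repeat-unit molar mass of the unknown polymer, g/mol.
#' @return List with `se_dp` and `se_mn`.
#' @export
propagate_mn_uncertainty <- function(k_on, se_k_on, alpha, se_alpha, M_o) {
  if (any(c(se_k_on, se_alpha) < 0, na.rm = TRUE)) {
    stop("standard errors must be >= 0", call. = FALSE)
  }
  dp <- solve_dp(k_on, alpha)
  rel <- sqrt((se_k_on / k_on)^2 + (se_alpha / alpha)^2)
  se_dp <- dp * rel
  list(se_dp = se_dp, se_mn = M_o * se_dp)
}

#' Determine the molecular weight of an uncharacterized polyelectrolyte
#'
#' Combines a polymeric-basis rate line for the characterized partner
#' (slope `k_on`) with a monomeric-basis rate line for the unknown partner
#' (slope `alpha`) under the orientation-symmetric `k_on` assumption, and
#' returns DP and `M_n` with delta-method standard errors.
#'
#' @param known_line `"rate_line"` on the polymeric basis (uM chains).
#' @param unknown_line `"rate_line"` on the monomeric basis (mM repeat
#'   units).
#' @param M_o_unknown Repeat-unit molar mass of the unknown polymer, g/mol.
#' @return Object of class `"mn_result"`: `dp`, `mn` (g/mol), `se_dp`,
#'   `se_mn`, `k_on_used`, `alpha_used` (1/(uM s), monomeric), `params`
#'   (the [kinetic_params()] of the known orientation), `kd_nM`, and
#'   rounded conveniences `dp_rounded` (nearest integer) and `mn_rounded`
#'   (nearest 100 g/mol).
#' @examples
#' pei <- pei_rates(); pazo <- pazo_rates()
#' known <- fit_rate_line(monomeric_to_polymeric(pei$conc_mM, pei_polymer()),
#'                        pei$k_obs, basis = "polymeric")
#' unknown <- fit_rate_line(pazo$conc_mM, pazo$k_obs, basis = "monomeric")
#' determine_mn(known, unknown, M_o_unknown = 401)
#' @export
determine_mn <- function(known_line, unknown_line, M_o_unknown) {
  stopifnot(inherits(known_line, "rate_line"),
            inherits(unknown_line, "rate_line"))
  if (unknown_line$basis != "monomeric") {
    stop("'unknown_line' must be on the monomeric (mM) basis", call. = FALSE)
  }
  params <- kinetic_params_from_line(known_line)
  alpha <- unknown_line$slope / 1000      # 1/(mM s) -> 1/(uM s) monomeric
  se_alpha <- unknown_line$se_slope / 1000
  dp <- solve_dp(params$k_on, alpha)
  mn <- solve_mn(dp, M_o_unknown)
  se <- propagate_mn_uncertainty(params$k_on, params$se_k_on, alpha, se_alpha,
                                 M_o_unknown)
  structure(list(
    dp = dp, mn = mn, se_dp = se$se_dp, se_mn = se$se_mn,
    k_on_used = params$k_on, alpha_used = alpha,
    params = params, kd_nM = dissociation_constant(params),
    M_o_unknown = M_o_unknown,
    dp_rounded = round(dp), mn_rounded = round(mn / 100) * 100,
    provenance = list(known_line = known_line, unknown_line = unknown_line)
  ), class = "mn_result")
}

#' @export
print.mn_result <- function(x, ...) {
  cat("Calibration-free molecular weight determination\n")
  cat("  k_on  =", format(x$k_on_used, digits = 5), "1/(uM s);  k_off =",
      format(x$params$k_off, digits = 5), "1/s;  K_D =",
      format(x$kd_nM, digits = 4), "nM\n")
  cat("  alpha =", format(x$alpha_used, digits = 5), "1/(uM s) (monomeric)\n")
  cat("  DP  =", format(x$dp, digits = 6), "+/-", format(x$se_dp, digits = 3),
      " (reported:", x$dp_rounded, "repeat units)\n")
  cat("  M_n =", format(x$mn, digits = 7), "+/-", format(x$se_mn, digits = 3),
      "g/mol  (reported:", format(x$mn_rounded, big.mark = ","), "g/mol)\n")
  invisible(x)
}
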
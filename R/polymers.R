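#' Describe a polyelectrolyte
#'
#' A `polymer` records the repeat-unit molar mass `M_o` and, when known, the
#' number-average chain molar mass `M_n`. `M_n` is left `NA` for the polymer
#' whose molecular weight is to be determined.
#'
#' @param name Polymer name (free text).
#' @param M_o Repeat-unit molar mass in g/mol. Must be positive.
#' @param M_n Number-average molecular weight in g/mol, or `NA` if unknown.
#'   When given it must be at least `M_o` (a chain has at least one repeat
#'   unit).
#'
#' @return An object of class `"polymer"`.
#' @examples
#' pei <- polymer("PEI", M_o = 43.07, M_n = 25000)
#' degree_of_polymerization(pei)
#' @export
polymer <- function(name, M_o, M_n = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  M_o <- as.numeric(M_o)
  M_n <- as.numeric(M_n)
  if (!is.finite(M_o) || M_o <= 0) {
    stop("'M_o' must be a positive repeat-unit molar mass (g/mol)", call. = FALSE)
  }
  if (!is.na(M_n)) {
    if (!is.finite(M_n) || M_n < M_o) {
      stop("'M_n' must be >= 'M_o' (a chain has at least one repeat unit)",
           call. = FALSE)
    }
  }
  structure(list(name = name, M_o = M_o, M_n = M_n), class = "polymer")
}

#' @export
print.polymer <- function(x, ...) {
  cat("Polymer:", x$name, "\n")
  cat("  M_o =", format(x$M_o), "g/mol")
  if (!is.na(x$M_n)) {
    cat(";  M_n =", format(x$M_n), "g/mol;  DP =",
        format(degree_of_polymerization(x), digits = 5))
  } else {
    cat(";  M_n unknown")
  }
  cat("\n")
  invisible(x)
}

#' Degree of polymerization
#'
#' `DP = M_n / M_o`, the average number of repeat units per chain.
#'
#' @param polymer A [polymer()] with `M_n` known.
#' @return The dimensionless degree of polymerization.
#' @examples
#' degree_of_polymerization(polymer("PEI", 43.07, 25000))
#' @export
degree_of_polymerization <- function(polymer) {
  stopifnot(inherits(polymer, "polymer"))
  if (is.na(polymer$M_n)) {
    stop("'M_n' of ", polymer$name, " is unknown; cannot compute DP",
         call. = FALSE)
  }
  polymer$M_n / polymer$M_o
}

#' Built-in polymer descriptions for the PEI/PAZO system
#'
#' `pei_polymer()` is branched/linear poly(ethylenimine) with repeat-unit
#' mass 43.07 g/mol and a nominal number-average molecular weight of
#' 25,000 g/mol (the value consistent with the published monomeric-to-
#' polymeric concentration conversions; vendor characterization of this
#' material is ambiguous, so `M_n` is an argument). `pazo_polymer()` is the
#' azobenzene polyanion PAZO with repeat-unit mass 401 g/mol and unknown
#' `M_n` — the quantity the two-orientation analysis determines.
#'
#' @param M_n Number-average molecular weight of PEI in g/mol.
#' @return A [polymer()].
#' @examples
#' pei_polymer()
#' pazo_polymer()
#' @export
pei_polymer <- function(M_n = 25000) polymer("PEI", M_o = 43.07, M_n = M_n)

#' @rdname pei_polymer
#' @export
pazo_polymer <- function() polymer("PAZO", M_o = 401)

#' Published observed-rate tables for the PEI/PAZO system
#'
#' Duplicate-mean observed pseudo-first-order rate constants (`k_obs`, 1/s,
#' mean of n = 2 with SEM) measured by LSPR at monomeric analyte
#' concentrations of 1, 0.5, 0.25, 0.125 and 0.0625 mM. `pei_rates()` is PEI
#' flowed over a PAZO-coated surface; `pazo_rates()` is PAZO flowed over a
#' PEI-coated surface. These tables are the reproducible input surface of
#' the published experiment and drive the worked examples.
#'
#' For PEI the published polymeric (chain) concentrations are included as
#' `conc_uM`; they were derived from the monomeric series with PEI's
#' nominal `M_n` and are kept as printed (1 mM -> 1.7200 uM, i.e. an
#' implied DP of 581.4, about 0.16% away from the 25,000/43.07 ratio).
#'
#' @return A data frame with columns `conc_mM` (monomeric), `k_obs` (1/s),
#'   `sem` (1/s) and `n`; `pei_rates()` additionally has `conc_uM`
#'   (polymeric).
#' @examples
#' pei_rates()
#' @export
pei_rates <- function() {
  data.frame(
    conc_mM = c(1, 0.5, 0.25, 0.125, 0.0625),
    conc_uM = c(1.72, 0.86, 0.43, 0.215, 0.1075),
    k_obs   = c(0.07527, 0.05154, 0.03287, 0.01830, 0.01701),
    sem     = c(0.01028, 0.00669, 0.00628, 0.00044, 0.00076),
    n       = 2L
  )
}

#' @rdname pei_rates
#' @export
pazo_rates <- function() {
  data.frame(
    conc_mM = c(1, 0.5, 0.25, 0.125, 0.0625),
    k_obs   = c(0.08162, 0.06280, 0.04830, 0.03560, 0.02315),
    sem     = c(0.01599, 0.01245, 0.01123, 0.01076, 0.00953),
    n       = 2L
  )
}
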
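#' Fit every sensorgram of a gradient and aggregate replicates
#'
#' Preprocesses each sensorgram ([preprocess_sensorgram()]), fits the
#' association transient ([fit_transient()]), then aggregates replicate
#' `k_obs` values per concentration ([aggregate_replicates()]).
#'
#' @param sgrams List of [sensorgram()]s (replicates share `conc_mM`).
#' @param model Passed to [fit_transient()].
#' @param use_reference Passed to [preprocess_sensorgram()].
#' @return Data frame with one row per concentration: `conc_mM`, `k_obs`
#'   (replicate mean), `sem`, `n`.
#' @export
rates_from_sensorgrams <- function(sgrams, model = "one_phase",
                                   use_reference = TRUE) {
  stopifnot(length(sgrams) >= 1L)
  ks <- vapply(sgrams, function(s) {
    fit <- fit_transient(preprocess_sensorgram(s, use_reference), model)
    if (fit$model == "one_phase") fit$k_obs else fit$k_fast
  }, numeric(1))
  conc <- vapply(sgrams, function(s) s$conc_mM, numeric(1))
  out <- do.call(rbind, lapply(split(ks, conc), function(v) {
    agg <- aggregate_replicates(v)
    data.frame(k_obs = agg$mean_k_obs, sem = agg$sem_k_obs, n = agg$n)
  }))
  out <- data.frame(conc_mM = as.numeric(rownames(out)), out,
                    row.names = NULL)
  out[order(-out$conc_mM), , drop = FALSE]
}

#' Run the full two-orientation molecular weight pipeline
#'
#' End-to-end procedure: for each orientation, obtain replicate-mean
#' observed rates (either given directly as a rates table, or by
#' preprocessing and fitting a list of sensorgrams); regress the known
#' orientation on the polymeric (chain, uM) basis and the unknown
#' orientation on the monomeric (mM) basis; then solve for the unknown
#' polymer's DP and number-average molecular weight via
#' [determine_mn()].
#'
#' Both `known` and `unknown` accept either a data frame with columns
#' `conc_mM` and `k_obs` (monomeric mM, replicate means — the
#' "rates-table" mode matching the published tables) or a list of
#' [sensorgram()]s. If the known-orientation table already carries a
#' polymeric `conc_uM` column (as [pei_rates()] does, reproducing the
#' published conversion exactly) it is used as-is; otherwise chain
#' concentrations are derived from `conc_mM` via the known polymer's
#' `M_n`.
#'
#' @param known Rates table or sensorgram list for the characterized
#'   polymer flowed over the unknown-coated surface.
#' @param unknown Same, for the unknown polymer flowed over the
#'   known-coated surface.
#' @param known_polymer [polymer()] with `M_n` (the characterized partner).
#' @param unknown_polymer [polymer()] of the unknown partner (`M_o` used).
#' @param model,use_reference Fitting options for sensorgram inputs.
#' @return An `"mn_result"` (see [determine_mn()]); the per-orientation
#'   rates tables are attached as attribute `"rates"`.
#' @examples
#' run_full_pipeline(pei_rates(), pazo_rates(),
#'                   known_polymer = pei_polymer(),
#'                   unknown_polymer = pazo_polymer())
#' @export
run_full_pipeline <- function(known, unknown, known_polymer, unknown_polymer,
                              model = "one_phase", use_reference = TRUE) {
  stopifnot(inherits(known_polymer, "polymer"),
            inherits(unknown_polymer, "polymer"))
  if (is.na(known_polymer$M_n)) {
    stop("pipeline stage 'convert': known polymer must have M_n",
         call. = FALSE)
  }
  as_rates <- function(x, label) {
    if (is.data.frame(x)) {
      if (!all(c("conc_mM", "k_obs") %in% names(x))) {
        stop("pipeline stage 'input': ", label,
             " rates table needs columns conc_mM, k_obs", call. = FALSE)
      }
      x
    } else if (is.list(x) && length(x) && inherits(x[[1L]], "sensorgram")) {
      rates_from_sensorgrams(x, model, use_reference)
    } else {
      stop("pipeline stage 'input': ", label,
           " must be a rates table or a list of sensorgrams", call. = FALSE)
    }
  }
  known_rates <- as_rates(known, "known")
  unknown_rates <- as_rates(unknown, "unknown")
  conc_uM <- if (!is.null(known_rates$conc_uM)) known_rates$conc_uM else
    monomeric_to_polymeric(known_rates$conc_mM, known_polymer)
  known_line <- fit_rate_line(conc_uM, known_rates$k_obs, basis = "polymeric")
  unknown_line <- fit_rate_line(unknown_rates$conc_mM, unknown_rates$k_obs,
                                basis = "monomeric")
  res <- determine_mn(known_line, unknown_line, unknown_polymer$M_o)
  attr(res, "rates") <- list(known = known_rates, unknown = unknown_rates)
  res
}

#' Write a machine- and human-readable analysis report
#'
#' Serializes pipeline results (an `"mn_result"`, or a named list of
#' `"rate_line"` / `"kinetic_params"` / `"mn_result"` objects) to JSON with
#' explicit units, and writes a plain-text summary alongside it.
#'
#' @param results Result object(s); must be non-empty.
#' @param path Output JSON path; the text summary goes to the same path
#'   with extension `.txt`.
#' @param seed Optional seed to echo into the report provenance.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, seed = NULL) {
  if (is.null(results) || (is.list(results) && length(results) == 0L)) {
    stop("empty result set", call. = FALSE)
  }
  to_list <- function(x) {
    if (inherits(x, "mn_result")) {
      list(type = "mn_result",
           k_on_per_uM_s = x$k_on_used, k_off_per_s = x$params$k_off,
           se_k_on = x$params$se_k_on, se_k_off = x$params$se_k_off,
           kd_nM = x$kd_nM,
           alpha_per_uM_s = x$alpha_used,
           dp = x$dp, se_dp = x$se_dp,
           mn_g_mol = x$mn, se_mn = x$se_mn,
           dp_rounded = x$dp_rounded, mn_rounded = x$mn_rounded,
           M_o_unknown = x$M_o_unknown)
    } else if (inherits(x, "rate_line")) {
      list(type = "rate_line", basis = x$basis, slope = x$slope,
           intercept = x$intercept, se_slope = x$se_slope,
           se_intercept = x$se_intercept, r_squared = x$r_squared,
           n_points = x$n_points)
    } else if (inherits(x, "kinetic_params")) {
      list(type = "kinetic_params", k_on_per_uM_s = x$k_on,
           k_off_per_s = x$k_off, se_k_on = x$se_k_on,
           se_k_off = x$se_k_off,
           kd_nM = dissociation_constant(x))
    } else x
  }
  payload <- if (inherits(results, c("mn_result", "rate_line",
                                     "kinetic_params"))) {
    to_list(results)
  } else lapply(results, to_list)
  payload <- c(payload, list(provenance = list(
    package = "lsprkin",
    version = as.character(utils::packageVersion("lsprkin")),
    seed = seed)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  txt <- sub("\\.json$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  objs <- if (inherits(results, c("mn_result", "rate_line",
                                  "kinetic_params"))) list(results) else results
  writeLines(unlist(lapply(objs, function(o) utils::capture.output(print(o)))),
             txt)
  invisible(path)
}
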
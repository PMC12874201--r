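#' Reference-channel correction
#'
#' Subtracts the reference channel from the active channel point by point,
#' cancelling the bulk refractive-index shift of the analyte solution
#' (substantial for chromophore-bearing polyelectrolytes). The returned
#' sensorgram has no reference channel; all metadata is preserved.
#'
#' @param s A dual-channel [sensorgram()].
#' @return A single-channel [sensorgram()] with corrected response.
#' @export
subtract_reference <- function(s) {
  stopifnot(inherits(s, "sensorgram"))
  if (is.null(s$reference)) {
    stop("sensorgram has no reference channel", call. = FALSE)
  }
  s$active <- s$active - s$reference
  s$reference <- NULL
  s
}

#' Baseline zeroing
#'
#' Subtracts the mean response over a pre-injection window from the whole
#' series (both channels if a reference is present). The default window is
#' the 10 s immediately preceding the injection. The window is half-open,
#' `[from, to)`, so a window ending at `injection_start` excludes the first
#' in-injection sample (which already carries the bulk shift).
#'
#' @param s A [sensorgram()].
#' @param window Length-2 numeric `c(from, to)` in seconds; must end at or
#'   before `injection_start` and contain at least 3 samples.
#' @return The baselined [sensorgram()].
#' @export
zero_baseline <- function(s, window = c(s$injection_start - 10, s$injection_start)) {
  stopifnot(inherits(s, "sensorgram"), length(window) == 2L)
  if (window[2L] > s$injection_start) {
    stop("baseline window must end at or before injection_start", call. = FALSE)
  }
  sel <- s$time >= window[1L] & s$time < window[2L]
  if (sum(sel) < 3L) {
    stop("baseline window contains fewer than 3 samples", call. = FALSE)
  }
  s$active <- s$active - mean(s$active[sel])
  if (!is.null(s$reference)) {
    s$reference <- s$reference - mean(s$reference[sel])
  }
  s
}

#' Extract the association transient
#'
#' Returns the in-injection samples of a (typically baselined and
#' reference-corrected) sensorgram, with time rebased so the first sample
#' is at t = 0. This is the input to [fit_transient()].
#'
#' @param s A [sensorgram()].
#' @return An object of class `"transient"`: a list with `time` (s, from 0),
#'   `response` (RU), `conc_mM` and `source` metadata.
#' @export
extract_association <- function(s) {
  stopifnot(inherits(s, "sensorgram"))
  sel <- s$time >= s$injection_start & s$time <= s$injection_end
  if (sum(sel) < 5L) {
    stop("fewer than 5 samples inside the injection window", call. = FALSE)
  }
  t <- s$time[sel]
  structure(list(time = t - t[1L], response = s$active[sel],
                 conc_mM = s$conc_mM,
                 source = list(analyte = s$analyte,
                               injection = c(s$injection_start, s$injection_end))),
            class = "transient")
}

#' @export
print.transient <- function(x, ...) {
  cat("Association transient:", length(x$time), "samples over",
      format(max(x$time)), "s")
  if (!is.na(x$conc_mM)) cat(";", format(x$conc_mM), "mM (monomeric)")
  cat("\n")
  invisible(x)
}

#' Preprocess a raw sensorgram to a fit-ready transient
#'
#' Convenience chain: reference subtraction (when a reference channel is
#' present and `use_reference = TRUE`), baseline zeroing, association-phase
#' extraction.
#'
#' @param s A [sensorgram()].
#' @param use_reference Subtract the reference channel when present.
#' @param baseline_window Passed to [zero_baseline()].
#' @return A `"transient"`.
#' @export
preprocess_sensorgram <- function(s, use_reference = TRUE,
                                  baseline_window = NULL) {
  if (use_reference && !is.null(s$reference)) s <- subtract_reference(s)
  s <- if (is.null(baseline_window)) zero_baseline(s) else
    zero_baseline(s, baseline_window)
  extract_association(s)
}
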
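#' Dual-channel sensorgram
#'
#' Container for one injection's raw time series: active-channel response,
#' optional reference-channel response (used to cancel the bulk
#' refractive-index shift of the analyte solution), the injection window,
#' and analyte metadata.
#'
#' @param time Time in seconds, strictly increasing.
#' @param active Active-channel response in RU, same length as `time`.
#' @param reference Optional reference-channel response in RU, same length.
#' @param injection_start,injection_end Injection window in seconds;
#'   `injection_start < injection_end <= max(time)`.
#' @param analyte A [polymer()] describing the flowed analyte.
#' @param conc_mM Monomeric analyte concentration in mM.
#' @param flow_rate Flow rate in uL/min (metadata only).
#'
#' @return An object of class `"sensorgram"`.
#' @export
sensorgram <- function(time, active, reference = NULL,
                       injection_start, injection_end,
                       analyte = NULL, conc_mM = NA_real_,
                       flow_rate = NA_real_) {
  time <- as.numeric(time); active <- as.numeric(active)
  if (length(time) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(diff(time) <= 0)) {
    bad <- which(diff(time) <= 0)[1L] + 1L
    stop("'time' must be strictly increasing (first violation at sample ",
         bad, ")", call. = FALSE)
  }
  if (length(active) != length(time)) {
    stop("'active' and 'time' lengths differ", call. = FALSE)
  }
  if (!is.null(reference)) {
    reference <- as.numeric(reference)
    if (length(reference) != length(time)) {
      stop("'reference' and 'time' lengths differ", call. = FALSE)
    }
  }
  if (!(injection_start < injection_end && injection_end <= max(time))) {
    stop("require injection_start < injection_end <= max(time)", call. = FALSE)
  }
  if (!is.null(analyte)) stopifnot(inherits(analyte, "polymer"))
  structure(list(time = time, active = active, reference = reference,
                 injection_start = as.numeric(injection_start),
                 injection_end = as.numeric(injection_end),
                 analyte = analyte, conc_mM = as.numeric(conc_mM),
                 flow_rate = as.numeric(flow_rate)),
            class = "sensorgram")
}

#' @export
print.sensorgram <- function(x, ...) {
  cat("Sensorgram:", length(x$time), "samples,",
      if (is.null(x$reference)) "single channel" else "dual channel", "\n")
  cat("  time span ", format(min(x$time)), "-", format(max(x$time)),
      " s; injection [", format(x$injection_start), ", ",
      format(x$injection_end), "] s\n", sep = "")
  if (!is.null(x$analyte)) {
    cat("  analyte:", x$analyte$name, "at", format(x$conc_mM),
        "mM (monomeric)\n")
  }
  invisible(x)
}

#' @export
plot.sensorgram <- function(x, ...) {
  graphics::plot(x$time, x$active, type = "l", xlab = "time (s)",
                 ylab = "response (RU)", ...)
  if (!is.null(x$reference)) {
    graphics::lines(x$time, x$reference, lty = 2, col = "grey40")
  }
  graphics::abline(v = c(x$injection_start, x$injection_end),
                   lty = 3, col = "grey60")
  invisible(x)
}

# CSV dialect: leading `# key=value` metadata lines, then a
# `time_s,ru_active[,ru_reference]` header. UTF-8, '.' decimal separator.

#' Read and write sensorgram CSV files
#'
#' The on-disk format is a plain CSV with self-describing metadata in
#' leading comment lines (`# key=value`): `analyte`, `analyte_Mo_g_mol`,
#' `analyte_Mn_g_mol` (optional), `monomeric_concentration_mM`,
#' `injection_start_s`, `injection_end_s`, `flow_rate_uL_min`; followed by
#' a `time_s,ru_active,ru_reference` header (`ru_reference` optional).
#' Writing then re-reading yields an identical sensorgram, and a second
#' write is byte-identical to the first.
#'
#' @param path File path.
#' @return `read_sensorgram_csv()` returns a [sensorgram()];
#'   `write_sensorgram_csv()` returns `path` invisibly.
#' @export
read_sensorgram_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  n_meta <- if (any(!is_meta)) which(!is_meta)[1L] - 1L else length(lines)
  meta <- list()
  for (ln in lines[seq_len(n_meta)]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  body <- lines[!is_meta]
  if (length(body) < 2L) stop("no data rows in ", path, call. = FALSE)
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  required <- c("time_s", "ru_active")
  if (!all(required %in% header)) {
    stop("missing required columns: ",
         paste(setdiff(required, header), collapse = ", "), call. = FALSE)
  }
  df <- utils::read.csv(text = body, header = TRUE)
  num <- function(key) {
    v <- meta[[key]]
    if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
  }
  for (key in c("injection_start_s", "injection_end_s")) {
    if (is.na(num(key))) {
      stop("unparseable or missing metadata '", key, "'", call. = FALSE)
    }
  }
  if (any(diff(df$time_s) <= 0)) {
    bad <- which(diff(df$time_s) <= 0)[1L] + 1L
    stop("'time_s' not strictly increasing at data row ", bad,
         " (file line ", n_meta + 1L + bad, ")", call. = FALSE)
  }
  analyte <- NULL
  if (!is.null(meta$analyte) && !is.na(num("analyte_Mo_g_mol"))) {
    analyte <- polymer(meta$analyte, num("analyte_Mo_g_mol"),
                       num("analyte_Mn_g_mol"))
  }
  sensorgram(time = df$time_s, active = df$ru_active,
             reference = if ("ru_reference" %in% header) df$ru_reference,
             injection_start = num("injection_start_s"),
             injection_end = num("injection_end_s"),
             analyte = analyte,
             conc_mM = num("monomeric_concentration_mM"),
             flow_rate = num("flow_rate_uL_min"))
}

#' @rdname read_sensorgram_csv
#' @param s A [sensorgram()].
#' @export
write_sensorgram_csv <- function(s, path) {
  stopifnot(inherits(s, "sensorgram"))
  fmt <- function(x) formatC(x, digits = 10, format = "g")
  meta <- c(
    if (!is.null(s$analyte)) c(
      paste0("# analyte=", s$analyte$name),
      paste0("# analyte_Mo_g_mol=", fmt(s$analyte$M_o)),
      if (!is.na(s$analyte$M_n)) paste0("# analyte_Mn_g_mol=", fmt(s$analyte$M_n))
    ),
    if (!is.na(s$conc_mM)) paste0("# monomeric_concentration_mM=", fmt(s$conc_mM)),
    paste0("# injection_start_s=", fmt(s$injection_start)),
    paste0("# injection_end_s=", fmt(s$injection_end)),
    if (!is.na(s$flow_rate)) paste0("# flow_rate_uL_min=", fmt(s$flow_rate))
  )
  has_ref <- !is.null(s$reference)
  header <- paste(c("time_s", "ru_active", if (has_ref) "ru_reference"),
                  collapse = ",")
  rows <- paste(fmt(s$time), fmt(s$active), sep = ",")
  if (has_ref) rows <- paste(rows, fmt(s$reference), sep = ",")
  writeLines(c(meta, header, rows), path, useBytes = TRUE)
  invisible(path)
}
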
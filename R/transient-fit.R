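#' Build a transient from raw vectors
#'
#' @param time Seconds from injection start, strictly increasing, first
#'   element 0 (rebased otherwise).
#' @param response Baselined response in RU.
#' @param conc_mM Monomeric analyte concentration (metadata).
#' @return A `"transient"` as produced by [extract_association()].
#' @export
as_transient <- function(time, response, conc_mM = NA_real_) {
  time <- as.numeric(time); response <- as.numeric(response)
  stopifnot(length(time) == length(response), all(diff(time) > 0))
  structure(list(time = time - time[1L], response = response,
                 conc_mM = as.numeric(conc_mM), source = NULL),
            class = "transient")
}

#' Fit an exponential association model to a transient
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of the association
#' phase. The one-phase model is `R(t) = C (1 - exp(-k_obs t))`, the
#' integrated 1:1 pseudo-first-order binding law; the two-phase model is
#' `R(t) = A_fast (1 - exp(-k_fast t)) + A_slow (1 - exp(-k_slow t))`, with
#' rates canonically ordered `k_fast >= k_slow`. An additive offset is fixed
#' at 0 by default (the transient is assumed baselined); set
#' `free_offset = TRUE` to estimate it.
#'
#' Starting values follow the standard heuristic: `C0` is the maximum
#' response and `k0 = 1/t63`, where `t63` is the first time the response
#' exceeds `0.632 * C0`. Rates are bounded in (1e-6, 10] 1/s and amplitudes
#' are non-negative. A two-phase fit that fails to converge or is
#' rank-deficient (`k_fast ~ k_slow`, or a vanishing slow amplitude) is
#' flagged `degenerate` and falls back, reportably, to the one-phase fit.
#'
#' @param tr A `"transient"` ([extract_association()] or [as_transient()]).
#' @param model `"one_phase"` or `"two_phase"`.
#' @param free_offset Estimate an additive offset instead of fixing it at 0.
#' @return An object of class `"transient_fit"` with components `model`,
#'   `k_obs` (one-phase) or `k_fast`/`k_slow`/`A_fast`/`A_slow` (two-phase),
#'   `plateau`, `offset`, `r_squared`, `se_k_obs`, `residuals`, `fitted`,
#'   `degenerate`, plus the underlying data. Standard methods (`print`,
#'   `summary`, `coef`, `predict`, `residuals`, `fitted`, `plot`) apply.
#' @examples
#' p <- kinetic_params(0.037, 0.014)
#' t <- 0:300
#' tr <- as_transient(t, association_response(t, 1.72, p, 1000))
#' fit <- fit_transient(tr)
#' coef(fit)
#' @export
fit_transient <- function(tr, model = c("one_phase", "two_phase"),
                          free_offset = FALSE) {
  stopifnot(inherits(tr, "transient"))
  model <- match.arg(model)
  n_min <- if (model == "one_phase") 5L else 7L
  if (length(tr$time) < n_min) {
    stop("need at least ", n_min, " samples for a ", model, " fit",
         call. = FALSE)
  }
  if (stats::sd(tr$response) == 0) {
    stop("degenerate data: response is constant", call. = FALSE)
  }
  if (model == "one_phase") fit_one_phase_(tr, free_offset)
  else fit_two_phase_(tr, free_offset)
}

# starting-value heuristic shared by both models
start_heuristic <- function(tr) {
  C0 <- max(tr$response)
  if (C0 <= 0) C0 <- max(abs(tr$response))
  i63 <- which(tr$response >= 0.632 * C0)
  t63 <- if (length(i63)) tr$time[i63[1L]] else max(tr$time) / 2
  if (t63 <= 0) t63 <- tr$time[2L]
  list(C0 = C0, k0 = min(max(1 / t63, 1e-5), 10))
}

nls_control <- function() {
  minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, maxiter = 1000)
}

r_squared_ <- function(obs, fitted) {
  1 - sum((obs - fitted)^2) / sum((obs - mean(obs))^2)
}

fit_one_phase_ <- function(tr, free_offset) {
  s <- start_heuristic(tr)
  df <- data.frame(t = tr$time, y = tr$response)
  fml <- if (free_offset) y ~ C * (1 - exp(-k * t)) + b else
    y ~ C * (1 - exp(-k * t))
  start <- c(list(C = s$C0, k = s$k0), if (free_offset) list(b = 0))
  lower <- c(C = 1e-12, k = 1e-6, if (free_offset) c(b = -Inf))
  upper <- c(C = Inf, k = 10, if (free_offset) c(b = Inf))
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = df, start = start, lower = lower,
                      upper = upper, control = nls_control()),
    error = function(e) {
      stop("one-phase fit failed to converge: ", conditionMessage(e),
           call. = FALSE)
    })
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, length(cf)))
  fv <- stats::fitted(fit)
  structure(list(
    model = "one_phase",
    k_obs = unname(cf["k"]), plateau = unname(cf["C"]),
    offset = if (free_offset) unname(cf["b"]) else 0,
    se_k_obs = unname(se[which(names(cf) == "k")]),
    se_plateau = unname(se[which(names(cf) == "C")]),
    r_squared = r_squared_(tr$response, fv),
    fitted = as.numeric(fv), residuals = as.numeric(tr$response - fv),
    degenerate = FALSE, fallback = FALSE,
    n = length(tr$time), data = tr, nls = fit
  ), class = "transient_fit")
}

fit_two_phase_ <- function(tr, free_offset) {
  s <- start_heuristic(tr)
  df <- data.frame(t = tr$time, y = tr$response)
  fml <- if (free_offset)
    y ~ A1 * (1 - exp(-k1 * t)) + A2 * (1 - exp(-k2 * t)) + b else
    y ~ A1 * (1 - exp(-k1 * t)) + A2 * (1 - exp(-k2 * t))
  start <- c(list(A1 = s$C0 / 2, k1 = min(s$k0 * 3, 10),
                  A2 = s$C0 / 2, k2 = s$k0 / 3),
             if (free_offset) list(b = 0))
  lower <- c(A1 = 0, k1 = 1e-6, A2 = 0, k2 = 1e-6, if (free_offset) c(b = -Inf))
  upper <- c(A1 = Inf, k1 = 10, A2 = Inf, k2 = 10, if (free_offset) c(b = Inf))
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = df, start = start, lower = lower,
                      upper = upper, control = nls_control()),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- fit_one_phase_(tr, free_offset)
    out$fallback <- TRUE
    out$degenerate <- TRUE
    return(out)
  }
  cf <- stats::coef(fit)
  # canonical ordering: fast phase first
  if (cf["k1"] < cf["k2"]) {
    cf <- cf[c("A2", "k2", "A1", "k1", if (free_offset) "b")]
    names(cf)[1:4] <- c("A1", "k1", "A2", "k2")
  }
  total <- cf["A1"] + cf["A2"]
  degenerate <- cf["k1"] < 1.05 * cf["k2"] ||
    cf["A2"] < 1e-4 * total || cf["A1"] < 1e-4 * total
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, length(cf)))
  fv <- stats::fitted(fit)
  structure(list(
    model = "two_phase",
    k_fast = unname(cf["k1"]), k_slow = unname(cf["k2"]),
    A_fast = unname(cf["A1"]), A_slow = unname(cf["A2"]),
    plateau = unname(total),
    offset = if (free_offset) unname(cf["b"]) else 0,
    se_k_obs = NA_real_,
    r_squared = r_squared_(tr$response, fv),
    fitted = as.numeric(fv), residuals = as.numeric(tr$response - fv),
    degenerate = unname(degenerate), fallback = FALSE,
    n = length(tr$time), data = tr, nls = fit
  ), class = "transient_fit")
}

#' @export
print.transient_fit <- function(x, ...) {
  cat("Exponential association fit (", x$model, ")\n", sep = "")
  if (x$model == "one_phase") {
    cat("  k_obs =", format(x$k_obs, digits = 5), "1/s",
        if (!is.na(x$se_k_obs)) paste("+/-", format(x$se_k_obs, digits = 3)),
        "\n")
    cat("  plateau C =", format(x$plateau, digits = 5), "RU\n")
  } else {
    cat("  k_fast =", format(x$k_fast, digits = 5),
        " k_slow =", format(x$k_slow, digits = 5), "1/s\n")
    cat("  A_fast =", format(x$A_fast, digits = 5),
        " A_slow =", format(x$A_slow, digits = 5), "RU\n")
  }
  if (x$offset != 0) cat("  offset =", format(x$offset, digits = 4), "RU\n")
  cat("  R-squared =", format(x$r_squared, digits = 5),
      " (n =", x$n, "samples)\n")
  if (x$fallback) cat("  NOTE: two-phase fit degenerate; one-phase fallback\n")
  else if (x$degenerate) cat("  NOTE: fit flagged degenerate\n")
  invisible(x)
}

#' @export
summary.transient_fit <- function(object, ...) {
  print(object)
  cat("\nresidual SD =", format(stats::sd(object$residuals), digits = 4),
      "RU\n")
  invisible(object)
}

#' @export
coef.transient_fit <- function(object, ...) {
  if (object$model == "one_phase") {
    c(k_obs = object$k_obs, C = object$plateau,
      if (object$offset != 0) c(offset = object$offset))
  } else {
    c(k_fast = object$k_fast, k_slow = object$k_slow,
      A_fast = object$A_fast, A_slow = object$A_slow,
      if (object$offset != 0) c(offset = object$offset))
  }
}

#' @export
fitted.transient_fit <- function(object, ...) object$fitted

#' @export
residuals.transient_fit <- function(object, ...) object$residuals

#' @export
predict.transient_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time else
    if (is.list(newdata)) newdata$t %||% newdata$time else as.numeric(newdata)
  if (object$model == "one_phase") {
    object$plateau * (1 - exp(-object$k_obs * t)) + object$offset
  } else {
    object$A_fast * (1 - exp(-object$k_fast * t)) +
      object$A_slow * (1 - exp(-object$k_slow * t)) + object$offset
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
plot.transient_fit <- function(x, ...) {
  graphics::plot(x$data$time, x$data$response, pch = 16, cex = 0.4,
                 col = "grey50", xlab = "time (s)", ylab = "response (RU)",
                 ...)
  graphics::lines(x$data$time, x$fitted, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Compare one- and two-phase fits of the same transient
#'
#' Reports the gain in R-squared, the small-sample-corrected Akaike
#' information criterion (AICc) difference, and a Wald-Wolfowitz
#' residual-sign runs z statistic for each fit (systematically asymmetric
#' residuals give strongly negative z). Negative `delta_aicc` favours
#' `fit2`.
#'
#' @param fit1,fit2 Two `"transient_fit"` objects fitted to the same data.
#' @return A list of class `"model_comparison"` with `delta_r_squared`
#'   (`fit2 - fit1`), `aicc1`, `aicc2`, `delta_aicc` (`aicc2 - aicc1`),
#'   `preferred` (`"fit1"` or `"fit2"`), and `runs_z1`, `runs_z2`.
#' @export
compare_models <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "transient_fit"), inherits(fit2, "transient_fit"))
  if (!isTRUE(all.equal(fit1$data$time, fit2$data$time)) ||
      !isTRUE(all.equal(fit1$data$response, fit2$data$response))) {
    stop("fits are not on the same transient", call. = FALSE)
  }
  aicc <- function(f) {
    n <- f$n
    p <- length(stats::coef(f$nls)) + 1   # + residual variance
    rss <- sum(f$residuals^2)
    n * log(rss / n) + 2 * p + 2 * p * (p + 1) / max(n - p - 1, 1)
  }
  runs_z <- function(res) {
    sgn <- sign(res)[sign(res) != 0]
    n1 <- sum(sgn > 0); n2 <- sum(sgn < 0); n <- n1 + n2
    if (n1 == 0 || n2 == 0) return(NA_real_)
    runs <- 1 + sum(diff(sgn) != 0)
    mu <- 2 * n1 * n2 / n + 1
    v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
    (runs - mu) / sqrt(v)
  }
  a1 <- aicc(fit1); a2 <- aicc(fit2)
  structure(list(
    delta_r_squared = fit2$r_squared - fit1$r_squared,
    aicc1 = a1, aicc2 = a2, delta_aicc = a2 - a1,
    preferred = if (a2 < a1) "fit2" else "fit1",
    runs_z1 = runs_z(fit1$residuals), runs_z2 = runs_z(fit2$residuals)
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (fit2 - fit1)\n")
  cat("  delta R-squared =", format(x$delta_r_squared, digits = 4), "\n")
  cat("  delta AICc =", format(x$delta_aicc, digits = 5),
      "-> preferred:", x$preferred, "\n")
  cat("  residual runs z: fit1 =", format(x$runs_z1, digits = 3),
      ", fit2 =", format(x$runs_z2, digits = 3), "\n")
  invisible(x)
}

#' Aggregate replicate rate constants
#'
#' Mean and standard error of the mean (sample SD / sqrt(n)) over replicate
#' `k_obs` estimates, matching the duplicate-injection design of the
#' experiment. With a single replicate the SEM is undefined and returned as
#' `NA` with `sem_defined = FALSE`.
#'
#' @param values Numeric vector of replicate `k_obs` values (1/s), n >= 1.
#' @return A list of class `"replicate_summary"`: `mean_k_obs`, `sem_k_obs`,
#'   `n`, `sem_defined`.
#' @examples
#' aggregate_replicates(c(0.07, 0.08))
#' @export
aggregate_replicates <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("no replicate values supplied", call. = FALSE)
  n <- length(values)
  structure(list(
    mean_k_obs = mean(values),
    sem_k_obs = if (n > 1L) stats::sd(values) / sqrt(n) else NA_real_,
    n = n, sem_defined = n > 1L
  ), class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat("k_obs =", format(x$mean_k_obs, digits = 5),
      if (x$sem_defined) paste("+/-", format(x$sem_k_obs, digits = 3), "(SEM)")
      else "(SEM undefined, n = 1)",
      " n =", x$n, "\n")
  invisible(x)
}
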
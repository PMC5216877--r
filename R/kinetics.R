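# ATPase kinetics: Michaelis-Menten and hyperbolic-inhibition fits,
# Cheng-Prusoff inhibition constants with propagated standard errors,
# and turnover bookkeeping.

#' Dose-response dataset
#'
#' Concentration/activity/SD triples, e.g. ATP titrations (activity in
#' nmol Pi/min/mg) or inhibition series (activity as % of the uninhibited
#' rate), with per-point standard deviations from technical replicates.
#'
#' @param conc_uM concentrations in uM, non-negative.
#' @param activity activities (assay units or percent).
#' @param sd per-point standard deviations (0 if unknown).
#' @param n_rep number of technical replicates behind each point.
#' @return object of class `dose_response`.
#' @export
dose_response <- function(conc_uM, activity, sd = rep(0, length(conc_uM)),
                          n_rep = 3L) {
  if (length(activity) != length(conc_uM) || length(sd) != length(conc_uM)) {
    stop_input("conc_uM, activity and sd must have equal length")
  }
  if (any(conc_uM < 0)) stop_input("concentrations must be non-negative")
  if (any(sd < 0)) stop_input("sd must be non-negative")
  structure(list(conc_uM = as.numeric(conc_uM),
                 activity = as.numeric(activity),
                 sd = as.numeric(sd), n_rep = as.integer(n_rep)),
            class = "dose_response")
}

fit_se <- function(fit) {
  # standard errors from the fit covariance s^2 (J'J)^-1 at the optimum
  summary(fit)$coefficients[, "Std. Error"]
}

#' Michaelis-Menten fit of an ATP titration
#'
#' Nonlinear least squares of `v = vmax x / (Km + x)`; initialization uses
#' `vmax <- max(y)` and `Km <-` the concentration whose activity is closest
#' to half of that. Standard errors come from the fit covariance
#' `s^2 (J'J)^-1`. Unweighted by default; `weighted = TRUE` applies
#' 1/SD^2 weights.
#'
#' @param data a `dose_response` with at least 4 distinct concentrations.
#' @param weighted logical; weight points by `1/sd^2` (points with sd = 0
#'   are given the median weight).
#' @return object of class `mm_fit`: `vmax`, `km`, `se_vmax`, `se_km`,
#'   and the underlying `nls` fit.
#' @export
fit_michaelis_menten <- function(data, weighted = FALSE) {
  stopifnot(inherits(data, "dose_response"))
  x <- data$conc_uM; y <- data$activity
  if (length(unique(x)) < 4L) {
    stop_input("need >= 4 distinct concentrations for a Michaelis-Menten fit")
  }
  vmax0 <- max(y)
  km0 <- x[which.min(abs(y - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(x[x > 0])
  w <- if (weighted) inverse_variance_weights(data$sd) else rep(1, length(x))
  df <- data.frame(x = x, y = y)
  fit <- minpack.lm::nlsLM(y ~ vmax * x / (km + x), data = df,
                           start = list(vmax = vmax0, km = km0),
                           lower = c(vmax = 0, km = 1e-12),
                           weights = w,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit); se <- fit_se(fit)
  if (cf[["km"]] <= 1e-10) warning("Km estimate at lower bound", call. = FALSE)
  structure(list(vmax = cf[["vmax"]], km = cf[["km"]],
                 se_vmax = se[["vmax"]], se_km = se[["km"]], fit = fit),
            class = "mm_fit")
}

inverse_variance_weights <- function(sd) {
  w <- rep(NA_real_, length(sd))
  ok <- sd > 0
  w[ok] <- 1 / sd[ok]^2
  w[!ok] <- if (any(ok)) stats::median(w[ok]) else 1
  w
}

#' Hyperbolic-decay fit of an inhibition dose response
#'
#' Fits `f = y0 + a IC50 / (IC50 + x)` where `f` is the activity as percent
#' of the uninhibited rate, `y0` the residual activity at infinite
#' inhibitor, and `a` the maximal degree of inhibition (for fully
#' normalized data `a + y0 = 100`; deviations beyond 10 are flagged with a
#' warning). A negative fitted `y0` triggers a clip-at-zero refit with a
#' warning.
#'
#' @param data a `dose_response` with activities normalized to 100% at zero
#'   inhibitor and at least 5 inhibitor concentrations.
#' @param weighted logical; 1/SD^2 weighting.
#' @return object of class `ic50_fit`: `y0`, `a`, `ic50`, `se_ic50`,
#'   `se_y0`, `se_a`, and the underlying `nls` fit.
#' @export
fit_hyperbolic_inhibition <- function(data, weighted = FALSE) {
  stopifnot(inherits(data, "dose_response"))
  x <- data$conc_uM; y <- data$activity
  if (length(unique(x)) < 5L) {
    stop_input("need >= 5 inhibitor concentrations for an IC50 fit")
  }
  w <- if (weighted) inverse_variance_weights(data$sd) else rep(1, length(x))
  y00 <- max(min(y), 0)
  a0 <- max(y) - y00
  half <- y00 + a0 / 2
  ic0 <- x[x > 0][which.min(abs(y[x > 0] - half))]
  if (!length(ic0) || !is.finite(ic0) || ic0 <= 0) ic0 <- stats::median(x[x > 0])
  df <- data.frame(x = x, y = y)
  do_fit <- function(lower_y0) {
    minpack.lm::nlsLM(y ~ y0 + a * ic50 / (ic50 + x), data = df,
                      start = list(y0 = max(y00, lower_y0), a = a0, ic50 = ic0),
                      lower = c(y0 = lower_y0, a = 0, ic50 = 1e-12),
                      weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  fit <- do_fit(-Inf)
  cf <- stats::coef(fit)
  if (cf[["y0"]] < 0) {
    warning("fitted y0 negative; refitting with y0 clipped at zero",
            call. = FALSE)
    fit <- do_fit(0)
    cf <- stats::coef(fit)
  }
  se <- fit_se(fit)
  if (abs(cf[["y0"]] + cf[["a"]] - 100) > 10) {
    warning(sprintf("y0 + a = %.1f deviates from 100%% by more than 10; check normalization",
                    cf[["y0"]] + cf[["a"]]), call. = FALSE)
  }
  structure(list(y0 = cf[["y0"]], a = cf[["a"]], ic50 = cf[["ic50"]],
                 se_y0 = se[["y0"]], se_a = se[["a"]], se_ic50 = se[["ic50"]],
                 fit = fit),
            class = "ic50_fit")
}

#' Predicted activity of a fitted inhibition curve
#'
#' @param object an `ic50_fit`.
#' @param conc_uM inhibitor concentrations at which to evaluate the curve.
#' @param ... unused.
#' @return predicted percent activity.
#' @export
predict.ic50_fit <- function(object, conc_uM, ...) {
  object$y0 + object$a * object$ic50 / (object$ic50 + conc_uM)
}

#' Cheng-Prusoff inhibition constant with propagated standard error
#'
#' Converts an observed IC50 into a competitive inhibition constant,
#' `Ki = IC50 / (1 + [S]/Km)`, and propagates the standard errors of IC50
#' and Km:
#' \deqn{\sigma_{Ki}^2 = \left(\frac{Km}{Km + [S]}\right)^2 \sigma_{IC50}^2
#'   + \left(\frac{[S] \cdot IC50}{(Km + [S])^2}\right)^2 \sigma_{Km}^2}
#'
#' @param ic50 observed IC50 (uM), > 0.
#' @param se_ic50 standard error of IC50 (uM), >= 0.
#' @param km Michaelis constant for the substrate (uM), > 0.
#' @param se_km standard error of Km (uM), >= 0.
#' @param s_conc substrate concentration used in the inhibition assay (uM),
#'   >= 0.
#' @return object of class `ki_result`: `ki`, `se_ki` (uM) plus the inputs
#'   used (`ic50_used`, `km_used`, `s_conc`).
#' @export
cheng_prusoff_ki <- function(ic50, se_ic50 = 0, km, se_km = 0, s_conc) {
  if (ic50 <= 0 || km <= 0) stop_input("ic50 and km must be > 0")
  if (s_conc < 0) stop_input("s_conc must be >= 0")
  if (se_ic50 < 0 || se_km < 0) stop_input("standard errors must be >= 0")
  ki <- ic50 / (1 + s_conc / km)
  se_ki <- sqrt((km / (km + s_conc))^2 * se_ic50^2 +
                  (s_conc * ic50 / (km + s_conc)^2)^2 * se_km^2)
  structure(list(ki = ki, se_ki = se_ki, s_conc = s_conc,
                 km_used = km, ic50_used = ic50),
            class = "ki_result")
}

#' Molar turnover from specific activity
#'
#' Converts a specific ATPase activity (nmol Pi/min/mg protein) into a
#' per-transporter turnover (min^-1): `rate = activity * MW * 1e-3` for a
#' molecular weight in kDa.
#'
#' @param activity specific activity in nmol Pi/min/mg, >= 0.
#' @param mw_kda molecular weight of the transporter in kDa, > 0.
#' @return turnover in min^-1.
#' @export
molar_turnover <- function(activity, mw_kda) {
  if (any(activity < 0)) stop_input("activity must be >= 0")
  if (mw_kda <= 0) stop_input("mw_kda must be > 0")
  activity * mw_kda * 1e-3
}

#' Molecular weight defaults (kDa)
#'
#' Transporter molecular weights implied by the ratio of published
#' specific-activity and turnover numbers (derived values, not measured
#' masses); user-overridable wherever they are consumed.
#'
#' @export
default_mw_kda <- c(tm287_288 = 132.7, bmrcd = 141.5, msbA = 136.3)

#' Cumulative turnover over an incubation
#'
#' ATP hydrolyzed per transporter during `minutes` of incubation at a
#' constant turnover rate: `rate * minutes`.
#'
#' @param rate turnover rate in min^-1, >= 0.
#' @param minutes incubation time in minutes, >= 0.
#' @return dimensionless count of hydrolysis events per transporter.
#' @export
cumulative_turnover <- function(rate, minutes) {
  if (any(rate < 0) || any(minutes < 0)) stop_input("inputs must be >= 0")
  rate * minutes
}

#' Activity as a percentage of a reference
#'
#' @param value measured value.
#' @param reference reference value, > 0.
#' @param digits significant digits for the reported percentage (default 3,
#'   matching typical table precision); use `NULL` for full precision.
#' @return `100 * value / reference`.
#' @export
percent_of_reference <- function(value, reference, digits = 3) {
  if (reference <= 0) stop_input("reference must be > 0")
  pct <- 100 * value / reference
  if (!is.null(digits)) pct <- signif(pct, digits)
  pct
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> vmax = %.4g +/- %.2g, Km = %.4g +/- %.2g uM\n",
              x$vmax, x$se_vmax, x$km, x$se_km))
  invisible(x)
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("<ic50_fit> IC50 = %.4g +/- %.2g uM, y0 = %.3g%%, a = %.3g%%\n",
              x$ic50, x$se_ic50, x$y0, x$a))
  invisible(x)
}

#' @export
print.ki_result <- function(x, ...) {
  cat(sprintf("<ki_result> Ki = %.4g +/- %.2g uM (IC50 = %.4g, Km = %.4g, [S] = %.4g uM)\n",
              x$ki, x$se_ki, x$ic50_used, x$km_used, x$s_conc))
  invisible(x)
}
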
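# Time-dependent ROC/AUC (cumulative cases / dynamic controls) and Brier
# prediction error, both with inverse-probability-of-censoring weighting:
# subjects censored before the horizon drop out and the remainder are
# reweighted by 1 / G(.), where G is the Kaplan-Meier estimate of the
# censoring distribution.

# KM of the censoring distribution; returns a survival_curve of G.
censoring_km <- function(times, events) {
  suppressWarnings(km_estimate(times, 1 - events))
}

# left limit G(t-): the step value just before t
curve_at_left <- function(curve, t) {
  idx <- findInterval(t, curve$time, left.open = TRUE)
  ifelse(idx == 0, 1, c(1, curve$surv)[idx + 1])
}

#' Time-dependent ROC curve with IPCW
#'
#' Cumulative/dynamic definition at a horizon tau: cases experienced the
#' event by tau, controls are event-free at tau.  Subjects censored before
#' tau contribute nothing; cases are weighted 1/G(T-) and controls 1/G(tau),
#' G being the censoring Kaplan-Meier.  The AUC is the weighted probability
#' that a random case outranks a random control (ties count 1/2) and equals
#' the trapezoidal area under the curve.
#'
#' @param marker per-patient risk values (higher = higher risk).
#' @param times,events follow-up and 0/1 event indicators.
#' @param horizon months.
#' @return object of class `td_roc` with `fpr`, `tpr`, `auc`, `n_cases`,
#'   `n_controls`, `horizon`.
#' @export
td_roc <- function(marker, times, events, horizon) {
  stopifnot(length(marker) == length(times), length(times) == length(events))
  G <- censoring_km(times, events)
  is_case <- times <= horizon & events == 1
  is_control <- times > horizon
  n_cases <- sum(is_case); n_controls <- sum(is_control)
  if (n_cases == 0 || n_controls == 0) {
    stop(sprintf("td_roc(): cannot form the ROC at %g months (%d cases, %d controls)",
                 horizon, n_cases, n_controls))
  }
  w <- numeric(length(times))
  w[is_case] <- 1 / curve_at_left(G, times[is_case])
  w[is_control] <- 1 / curve_at(G, horizon)
  if (any(!is.finite(w[is_case | is_control]))) {
    stop("td_roc(): censoring weights degenerate (G reaches 0 before the horizon)")
  }
  mc <- marker[is_case]; wc <- w[is_case]
  mk <- marker[is_control]; wk <- w[is_control]
  # curve over decreasing thresholds at the observed marker values
  thr <- sort(unique(marker), decreasing = TRUE)
  tpr <- vapply(thr, function(ct) sum(wc[mc >= ct]) / sum(wc), 0)
  fpr <- vapply(thr, function(ct) sum(wk[mk >= ct]) / sum(wk), 0)
  tpr <- c(0, tpr, 1); fpr <- c(0, fpr, 1)
  # weighted rank AUC
  cmp <- outer(mc, mk, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- drop(wc %*% cmp %*% wk) / (sum(wc) * sum(wk))
  out <- list(horizon = horizon, fpr = fpr, tpr = tpr, auc = auc,
              n_cases = n_cases, n_controls = n_controls,
              censoring_weight_model = "Kaplan-Meier of censoring, G(T-) for cases, G(tau) for controls")
  class(out) <- "td_roc"
  out
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf("<td_roc at %g months: AUC %.3f (%d cases / %d controls)>\n",
              x$horizon, x$auc, x$n_cases, x$n_controls))
  invisible(x)
}

#' IPCW Brier prediction error at a horizon
#'
#' Mean squared error between the event-free status at the horizon and the
#' predicted survival probability, reweighted for censoring; the null
#' reference uses the marginal Kaplan-Meier probability for everyone.
#'
#' @param predicted_survival per-patient predicted survival probability at
#'   the horizon, in [0, 1].
#' @param times,events follow-up and 0/1 event indicators.
#' @param horizon months.
#' @return list of class `prediction_error` with `horizon`, `brier_score`,
#'   `reference_brier` (marginal-KM null model).
#' @export
brier_prediction_error <- function(predicted_survival, times, events, horizon) {
  stopifnot(length(predicted_survival) == length(times))
  if (any(predicted_survival < 0 | predicted_survival > 1)) {
    stop("brier_prediction_error(): predictions must lie in [0, 1]")
  }
  G <- censoring_km(times, events)
  km <- suppressWarnings(km_estimate(times, events))
  brier_of <- function(pred) {
    is_case <- times <= horizon & events == 1
    is_control <- times > horizon
    if (!any(is_case) && !any(is_control)) {
      stop("brier_prediction_error(): no usable subjects at the horizon")
    }
    contrib <- numeric(length(times))
    contrib[is_case] <- (0 - pred[is_case])^2 / curve_at_left(G, times[is_case])
    contrib[is_control] <- (1 - pred[is_control])^2 / curve_at(G, horizon)
    if (any(!is.finite(contrib))) {
      stop("brier_prediction_error(): censoring weights degenerate at the horizon")
    }
    mean(contrib)
  }
  null_pred <- rep(curve_at(km, horizon), length(times))
  out <- list(horizon = horizon, brier_score = brier_of(predicted_survival),
              reference_brier = brier_of(null_pred))
  class(out) <- "prediction_error"
  out
}

#' @export
print.prediction_error <- function(x, ...) {
  cat(sprintf("<prediction_error at %g months: Brier %.4f (null %.4f)>\n",
              x$horizon, x$brier_score, x$reference_brier))
  invisible(x)
}
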
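# Native survival estimators: Kaplan-Meier, Nelson-Aalen, Mantel-Cox
# log-rank, Harrell's concordance.  Tied event and censoring times at the
# same instant follow the standard risk-set convention: events precede
# censorings (a subject censored at t is still at risk for the event at t).

risk_table <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) > 0)
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be finite and non-negative")
  }
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  ut <- sort(unique(times[events == 1]))
  n_risk <- vapply(ut, function(t) sum(times >= t), 0)
  n_event <- vapply(ut, function(t) sum(times == t & events == 1), 0)
  list(time = ut, n_risk = n_risk, n_event = n_event)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times non-negative follow-up times (months).
#' @param events 0 = censored, 1 = death.
#' @param conf_level confidence level for the pointwise log-log interval.
#' @return object of class `survival_curve` with per-event-time fields
#'   `time`, `n_risk`, `n_event`, `surv`, `greenwood_var` (variance of the
#'   survival estimate), `ci_low`, `ci_high`.
#' @export
km_estimate <- function(times, events, conf_level = 0.95) {
  rt <- risk_table(times, events)
  if (length(rt$time) == 0) {
    warning("km_estimate(): no events; survival curve is flat at 1")
    out <- list(time = numeric(0), n_risk = numeric(0), n_event = numeric(0),
                surv = numeric(0), greenwood_var = numeric(0),
                ci_low = numeric(0), ci_high = numeric(0), n = length(times))
    class(out) <- "survival_curve"
    return(out)
  }
  s <- cumprod(1 - rt$n_event / rt$n_risk)
  # Greenwood: var(S) = S^2 * sum d / (n (n - d))
  gw <- cumsum(rt$n_event / (rt$n_risk * pmax(rt$n_risk - rt$n_event, 1e-300)))
  v <- s^2 * gw
  z <- qnorm(1 - (1 - conf_level) / 2)
  # log-log transform CI; undefined at S = 0 or 1
  with_ci <- s > 0 & s < 1
  lo <- hi <- rep(NA_real_, length(s))
  se_ll <- sqrt(gw[with_ci]) / abs(log(s[with_ci]))
  lo[with_ci] <- s[with_ci]^exp(z * se_ll)
  hi[with_ci] <- s[with_ci]^exp(-z * se_ll)
  lo[s == 0] <- 0; hi[s == 0] <- 0
  out <- list(time = rt$time, n_risk = rt$n_risk, n_event = rt$n_event,
              surv = s, greenwood_var = v, ci_low = lo, ci_high = hi,
              n = length(times))
  class(out) <- "survival_curve"
  out
}

#' Nelson-Aalen cumulative hazard estimate
#'
#' H(t) = sum of d_i / n_i over event times <= t, with Aalen variance
#' sum d_i / n_i^2 and log-transformed confidence interval.
#'
#' @inheritParams km_estimate
#' @return object of class `cumhaz_curve` with `time`, `n_risk`, `n_event`,
#'   `cumhaz`, `variance`, `ci_low`, `ci_high`.
#' @export
na_cumhaz <- function(times, events, conf_level = 0.95) {
  rt <- risk_table(times, events)
  h <- cumsum(rt$n_event / rt$n_risk)
  v <- cumsum(rt$n_event / rt$n_risk^2)
  z <- qnorm(1 - (1 - conf_level) / 2)
  pos <- h > 0
  lo <- hi <- rep(NA_real_, length(h))
  lo[pos] <- h[pos] * exp(-z * sqrt(v[pos]) / h[pos])
  hi[pos] <- h[pos] * exp(z * sqrt(v[pos]) / h[pos])
  out <- list(time = rt$time, n_risk = rt$n_risk, n_event = rt$n_event,
              cumhaz = h, variance = v, ci_low = lo, ci_high = hi,
              n = length(times))
  class(out) <- "cumhaz_curve"
  out
}

#' Evaluate a step curve at arbitrary times
#'
#' Right-continuous step lookup: a `survival_curve` is 1 before the first
#' event time; a `cumhaz_curve` is 0.
#'
#' @param curve a `survival_curve` or `cumhaz_curve`.
#' @param t numeric times.
#' @return numeric vector of estimates at `t`.
#' @export
curve_at <- function(curve, t) {
  values <- if (inherits(curve, "survival_curve")) curve$surv else curve$cumhaz
  init <- if (inherits(curve, "survival_curve")) 1 else 0
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, init, c(init, values)[idx + 1])
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve: n=%d, %d event times, S(max)=%.3f>\n",
              x$n, length(x$time),
              if (length(x$surv)) x$surv[length(x$surv)] else 1))
  invisible(x)
}

#' @export
print.cumhaz_curve <- function(x, ...) {
  cat(sprintf("<cumhaz_curve: n=%d, %d event times, H(max)=%.3f>\n",
              x$n, length(x$time),
              if (length(x$cumhaz)) x$cumhaz[length(x$cumhaz)] else 0))
  invisible(x)
}

#' Export a step curve as a data.frame
#'
#' @param x a `survival_curve` or `cumhaz_curve`.
#' @param row.names,optional,... ignored (base generic signature).
#' @return data.frame with one row per event time.
#' @export
as.data.frame.survival_curve <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
             surv = x$surv, greenwood_var = x$greenwood_var,
             ci_low = x$ci_low, ci_high = x$ci_high)
}

#' @rdname as.data.frame.survival_curve
#' @export
as.data.frame.cumhaz_curve <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
             cumhaz = x$cumhaz, variance = x$variance,
             ci_low = x$ci_low, ci_high = x$ci_high)
}

#' Mantel-Cox log-rank test for two or more groups
#'
#' Chi-square statistic from observed-minus-expected event counts with the
#' hypergeometric covariance, df = number of groups - 1.
#'
#' @param times,events follow-up times and 0/1 event indicators.
#' @param group group labels (>= 2 non-empty groups).
#' @return list of class `logrank_result` with `chi_square`, `df`, `p_value`,
#'   `observed`, `expected` per group.
#' @export
log_rank <- function(times, events, group) {
  stopifnot(length(times) == length(events), length(times) == length(group))
  group <- as.character(group)
  gl <- sort(unique(group))
  k <- length(gl)
  if (k < 2) stop("log_rank(): need at least two groups")
  ut <- sort(unique(times[events == 1]))
  O <- E <- setNames(numeric(k), gl)
  V <- matrix(0, k - 1, k - 1)
  for (t in ut) {
    at_risk <- times >= t
    n <- sum(at_risk)
    d <- sum(times == t & events == 1)
    ng <- vapply(gl, function(g) sum(at_risk & group == g), 0)
    dg <- vapply(gl, function(g) sum(times == t & events == 1 & group == g), 0)
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      # hypergeometric covariance of the event counts in groups 1..k-1
      p <- ng / n
      f <- d * (n - d) / (n - 1)
      Vt <- f * (diag(p[-k], k - 1) - tcrossprod(p[-k]))
      V <- V + Vt
    }
  }
  omev <- (O - E)[-k]
  chi <- tryCatch(drop(t(omev) %*% solve(V, omev)), error = function(e) {
    drop(t(omev) %*% MASS_ginv(V) %*% omev)
  })
  chi <- max(chi, 0)
  out <- list(chi_square = chi, df = k - 1,
              p_value = pchisq(chi, df = k - 1, lower.tail = FALSE),
              observed = O, expected = E, groups = gl)
  class(out) <- "logrank_result"
  out
}

# Moore-Penrose pseudo-inverse (degenerate covariance fallback).
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank (Mantel-Cox): chi-square = %.4f on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Harrell's concordance index
#'
#' Fraction of usable pairs in which the subject with the higher risk score
#' fails first.  A pair (i, j) is usable when t_i < t_j and subject i had the
#' event, or t_i = t_j with exactly one event (events precede censorings).
#' Risk ties count 1/2.  Convention: higher risk score = shorter predicted
#' survival.
#'
#' @param risk numeric risk scores.
#' @param times,events follow-up and 0/1 event indicators.
#' @return concordance in [0, 1].
#' @export
concordance_index <- function(risk, times, events) {
  stopifnot(length(risk) == length(times), length(times) == length(events))
  n <- length(risk)
  conc <- 0
  usable <- 0
  ev <- which(events == 1)
  for (i in ev) {
    # pairs anchored at event i: partners with longer follow-up, or equal
    # follow-up without an event at that instant
    cmp <- (times > times[i]) | (times == times[i] & events == 0)
    m <- sum(cmp)
    if (m == 0) next
    usable <- usable + m
    conc <- conc + sum(risk[i] > risk[cmp]) + 0.5 * sum(risk[i] == risk[cmp])
  }
  if (usable == 0) stop("concordance_index(): no usable pairs")
  conc / usable
}
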
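# Independent brute-force oracles used to freeze expected values.  These
# deliberately share no code with the package implementations.

# Efron partial log-likelihood by direct summation over risk sets.
efron_loglik_brute <- function(beta, X, times, events) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    D <- which(times == t & events == 1)
    R <- which(times >= t)
    d <- length(D)
    sum_R <- sum(exp(eta[R]))
    sum_D <- sum(exp(eta[D]))
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_R - (l / d) * sum_D)
    }
  }
  ll
}

# Harrell's C by exhaustive enumeration of ordered pairs.
cindex_brute <- function(risk, times, events) {
  num <- den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    usable <- (events[i] == 1 && times[i] < times[j]) ||
      (events[i] == 1 && events[j] == 0 && times[i] == times[j])
    if (!usable) next
    den <- den + 1
    if (risk[i] > risk[j]) num <- num + 1
    else if (risk[i] == risk[j]) num <- num + 0.5
  }
  num / den
}

# IPCW cumulative/dynamic AUC by exhaustive weighted pair enumeration,
# with the censoring KM computed from scratch.
ipcw_auc_brute <- function(marker, times, events, horizon) {
  km_cens <- function(t) {           # G(t), KM of censoring
    s <- 1
    for (u in sort(unique(times[events == 0]))) {
      if (u > t) break
      n_risk <- sum(times > u | (times == u))
      d <- sum(times == u & events == 0)
      s <- s * (1 - d / n_risk)
    }
    s
  }
  km_cens_left <- function(t) {      # G(t-)
    s <- 1
    for (u in sort(unique(times[events == 0]))) {
      if (u >= t) break
      n_risk <- sum(times >= u)
      d <- sum(times == u & events == 0)
      s <- s * (1 - d / n_risk)
    }
    s
  }
  cases <- which(times <= horizon & events == 1)
  controls <- which(times > horizon)
  wc <- vapply(cases, function(i) 1 / km_cens_left(times[i]), 0)
  wk <- rep(1 / km_cens(horizon), length(controls))
  num <- den <- 0
  for (a in seq_along(cases)) for (b in seq_along(controls)) {
    w <- wc[a] * wk[b]
    den <- den + w
    mi <- marker[cases[a]]; mj <- marker[controls[b]]
    num <- num + w * ((mi > mj) + 0.5 * (mi == mj))
  }
  num / den
}

# IPCW Brier score by direct weighted summation.
brier_brute <- function(pred, times, events, horizon) {
  G <- function(t) {
    s <- 1
    for (u in sort(unique(times[events == 0]))) {
      if (u > t) break
      s <- s * (1 - sum(times == u & events == 0) / sum(times >= u | times == u))
    }
    s
  }
  G_left <- function(t) {
    s <- 1
    for (u in sort(unique(times[events == 0]))) {
      if (u >= t) break
      s <- s * (1 - sum(times == u & events == 0) / sum(times >= u))
    }
    s
  }
  total <- 0
  for (i in seq_along(times)) {
    if (times[i] <= horizon && events[i] == 1) {
      total <- total + pred[i]^2 / G_left(times[i])
    } else if (times[i] > horizon) {
      total <- total + (1 - pred[i])^2 / G(horizon)
    }
  }
  total / length(times)
}

# small complete-case synthetic cohort for model-level tests
make_complete_cohort <- function(n = 578, seed = 1, ...) {
  cfg <- generator_config(n = n, seed = seed, ...)
  suppressMessages(complete_case_filter(simulate_cohort(cfg)))
}
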
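# Cox proportional hazards by Newton-Raphson on the Efron partial
# likelihood.  Step-halving guards the ascent, a small ridge is added when
# the information matrix is singular, and runaway coefficients (monotone
# likelihood / complete separation) are capped with a warning.

#' Build a numeric model matrix from cohort columns
#'
#' Categorical columns are one-hot expanded against their first observed
#' level (favorable/neutral levels first when the column is a known clinical
#' category); numeric columns pass through.
#'
#' @param cohort a `cohort_table` (or data.frame).
#' @param covariates column names to include.
#' @return numeric matrix with informative column names.
#' @export
cox_model_matrix <- function(cohort, covariates) {
  cols <- lapply(covariates, function(v) {
    x <- cohort[[v]]
    if (is.null(x)) stop(sprintf("cox_model_matrix(): no column '%s'", v))
    if (is.numeric(x)) {
      m <- matrix(x, ncol = 1, dimnames = list(NULL, v))
      return(m)
    }
    x <- as.character(x)
    lev <- if (v %in% names(.clical_levels)) {
      intersect(.clical_levels[[v]], unique(x))
    } else sort(unique(x))
    if (length(lev) < 2) {
      warning(sprintf("cox_model_matrix(): '%s' is constant; dropped", v))
      return(NULL)
    }
    ref <- lev[1]
    do.call(cbind, setNames(lapply(lev[-1], function(l) as.numeric(x == l)),
                            paste0(v, "=", lev[-1], "_vs_", ref)))
  })
  out <- do.call(cbind, Filter(Negate(is.null), cols))
  if (is.null(out)) stop("cox_model_matrix(): no usable covariates")
  out
}

# Efron partial log-likelihood, gradient and Hessian at beta.
# X sorted together with times/events is handled internally.
efron_loglik <- function(beta, X, times, events, what = c("all", "loglik")) {
  what <- match.arg(what)
  n <- nrow(X); p <- ncol(X)
  ord <- order(times)
  X <- X[ord, , drop = FALSE]; times <- times[ord]; events <- events[ord]
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)                       # overflow guard; cancels in ratios
  r <- exp(eta)
  rX <- X * r
  # suffix sums: risk set at t = positions first(t)..n
  S_R  <- rev(cumsum(rev(r)))
  Sx_R <- apply(rX, 2, function(col) rev(cumsum(rev(col))))
  Sx_R <- matrix(Sx_R, nrow = n)
  ll <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  ut <- unique(times[events == 1])
  first_pos <- match(ut, times)               # times sorted ascending
  need_hess <- what == "all"
  if (need_hess) {
    # suffix sums of r * x x' (p x p per position), stored flattened
    rXX <- t(vapply(seq_len(n), function(i) tcrossprod(X[i, ]) * r[i],
                    numeric(p * p)))
    rXX <- matrix(rXX, nrow = n)
    Sxx_R <- apply(rXX, 2, function(col) rev(cumsum(rev(col))))
    Sxx_R <- matrix(Sxx_R, nrow = n)
  }
  for (j in seq_along(ut)) {
    t_j <- ut[j]
    i0 <- first_pos[j]
    D <- which(times == t_j & events == 1)
    d <- length(D)
    sR <- S_R[i0]; sxR <- Sx_R[i0, ]
    sD <- sum(r[D]); sxD <- colSums(rX[D, , drop = FALSE])
    ll <- ll + sum(eta[D])
    if (need_hess) {
      sxxR <- matrix(Sxx_R[i0, ], p, p)
      sxxD <- matrix(colSums(rXX[D, , drop = FALSE]), p, p)
    }
    for (l in seq_len(d) - 1) {
      f <- l / d
      phi <- sR - f * sD
      ll <- ll - log(phi)
      if (need_hess) {
        z <- (sxR - f * sxD) / phi
        grad <- grad - z
        info <- info + (sxxR - f * sxxD) / phi - tcrossprod(z)
      }
    }
    if (need_hess) grad <- grad + colSums(X[D, , drop = FALSE])
  }
  if (what == "loglik") return(ll)
  list(loglik = ll, grad = grad, info = info)
}

#' Fit a Cox proportional hazards model (Efron ties)
#'
#' Newton-Raphson maximization of the Efron partial likelihood with
#' step-halving, Wald confidence intervals and p-values.  Supports univariate
#' and multivariate fits; categorical inputs should be expanded first with
#' [cox_model_matrix()].
#'
#' @param X numeric covariate matrix (n x p).
#' @param times,events follow-up times and 0/1 event indicators.
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance on the coefficient max-change.
#' @param conf_level Wald CI level.
#' @return object of class `cox_fit` with `coef`, `se`, `hazard_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `loglik`, `loglik_null`, `iterations`,
#'   `converged`, `ties_method = "efron"`.
#' @export
cox_fit <- function(X, times, events, max_iter = 50, tol = 1e-9,
                    conf_level = 0.95) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(times), length(times) == length(events))
  if (sum(events) < 1) stop("cox_fit(): at least one event required")
  p <- ncol(X)
  beta <- numeric(p)
  ll0 <- efron_loglik(beta, X, times, events, what = "loglik")
  ll_old <- ll0
  converged <- FALSE
  iter <- 0
  separation <- FALSE
  for (iter in seq_len(max_iter)) {
    e <- efron_loglik(beta, X, times, events)
    step <- tryCatch(solve(e$info, e$grad), error = function(err) {
      solve(e$info + diag(1e-8, p), e$grad)
    })
    # step-halving ascent
    new_beta <- beta + step
    ll_new <- efron_loglik(new_beta, X, times, events, what = "loglik")
    halvings <- 0
    while (is.na(ll_new) || (ll_new < e$loglik - 1e-12)) {
      step <- step / 2
      halvings <- halvings + 1
      if (halvings > 30) break
      new_beta <- beta + step
      ll_new <- efron_loglik(new_beta, X, times, events, what = "loglik")
    }
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    ll_old <- ll_new
    if (any(abs(beta) > 15)) {
      separation <- TRUE
      beta <- pmin(pmax(beta, -15), 15)
      warning("cox_fit(): monotone likelihood suspected; coefficient capped at |15|")
      break
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  e <- efron_loglik(beta, X, times, events)
  se <- sqrt(diag(tryCatch(solve(e$info), error = function(err) {
    solve(e$info + diag(1e-8, p))
  })))
  z <- qnorm(1 - (1 - conf_level) / 2)
  fit <- list(coef = setNames(beta, colnames(X)),
              se = setNames(se, colnames(X)),
              hazard_ratio = setNames(exp(beta), colnames(X)),
              ci_low = setNames(exp(beta - z * se), colnames(X)),
              ci_high = setNames(exp(beta + z * se), colnames(X)),
              p_value = setNames(2 * pnorm(-abs(beta / se)), colnames(X)),
              loglik = e$loglik, loglik_null = ll0,
              score_residual = max(abs(e$grad)),
              iterations = iter, converged = converged && !separation,
              separation = separation, ties_method = "efron",
              n = nrow(X), n_events = sum(events))
  class(fit) <- "cox_fit"
  fit
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH (Efron ties): n=%d, events=%d, %s after %d iteration(s)\n",
              x$n, x$n_events,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(cox_forest_table(x), row.names = FALSE)
  invisible(x)
}

#' Forest-plot table of a Cox fit
#'
#' Hazard ratios with 95% CIs and Wald p-values, one row per covariate, in
#' the layout used for forest plots.
#'
#' @param fit a `cox_fit`.
#' @return data.frame with variable, hazard_ratio, ci_low, ci_high, p_value.
#' @export
cox_forest_table <- function(fit) {
  data.frame(variable = names(fit$coef),
             hazard_ratio = round(unname(fit$hazard_ratio), 3),
             ci_low = round(unname(fit$ci_low), 3),
             ci_high = round(unname(fit$ci_high), 3),
             p_value = signif(unname(fit$p_value), 3),
             stringsAsFactors = FALSE)
}

#' Proportional-hazards diagnostic via a time-interaction covariate
#'
#' Adds covariate x log(t) interactions to the partial likelihood (the
#' interaction is evaluated at each event time inside the risk sets, so no
#' data expansion is needed) and reports the Wald p-value of each
#' interaction term; a small p flags a time-dependent effect, i.e. a
#' proportional-hazards violation.
#'
#' @param X numeric covariate matrix.
#' @param times,events follow-up and 0/1 event indicators.
#' @param max_iter,tol Newton-Raphson controls.
#' @return data.frame with the interaction coefficients and Wald p-values.
#' @export
cox_ph_time_interaction <- function(X, times, events, max_iter = 50, tol = 1e-8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  beta <- numeric(2 * p)
  ll_fn <- function(b, what = "all") {
    efron_tt_loglik(b, X, times, events, what)
  }
  for (iter in seq_len(max_iter)) {
    e <- ll_fn(beta)
    step <- tryCatch(solve(e$info, e$grad), error = function(err) {
      solve(e$info + diag(1e-8, 2 * p), e$grad)
    })
    new_beta <- beta + step
    ll_new <- ll_fn(new_beta, "loglik")
    h <- 0
    while (is.na(ll_new) || ll_new < e$loglik - 1e-12) {
      step <- step / 2; h <- h + 1
      if (h > 30) break
      new_beta <- beta + step
      ll_new <- ll_fn(new_beta, "loglik")
    }
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (delta < tol) break
  }
  e <- ll_fn(beta)
  se <- sqrt(diag(solve(e$info + diag(1e-10, 2 * p))))
  ti <- seq_len(p) + p
  data.frame(variable = colnames(X),
             interaction_coef = beta[ti],
             interaction_p = 2 * pnorm(-abs(beta[ti] / se[ti])),
             stringsAsFactors = FALSE)
}

# Efron likelihood with time-interaction columns x * log(t); the effective
# covariate vector changes with the event time, so risk sets are rebuilt per
# event time (slower, diagnostic use only).
efron_tt_loglik <- function(beta, X, times, events, what = "all") {
  n <- nrow(X); p <- ncol(X)
  b1 <- beta[seq_len(p)]; b2 <- beta[seq_len(p) + p]
  ut <- sort(unique(times[events == 1]))
  ll <- 0; grad <- numeric(2 * p); info <- matrix(0, 2 * p, 2 * p)
  for (t_j in ut) {
    lt <- log(t_j)
    R <- which(times >= t_j)
    D <- which(times == t_j & events == 1)
    Z <- cbind(X[R, , drop = FALSE], X[R, , drop = FALSE] * lt)
    eta <- drop(Z %*% beta)
    mx <- max(eta)
    r <- exp(eta - mx)
    rZ <- Z * r
    inD <- match(D, R)
    sR <- sum(r); szR <- colSums(rZ)
    sD <- sum(r[inD]); szD <- colSums(rZ[inD, , drop = FALSE])
    d <- length(D)
    ll <- ll + sum(eta[inD])
    if (what == "all") {
      rZZ <- crossprod(Z, rZ)
      ZD <- Z[inD, , drop = FALSE]
      rZZD <- crossprod(ZD, rZ[inD, , drop = FALSE])
    }
    for (l in seq_len(d) - 1) {
      f <- l / d
      phi <- sR - f * sD
      ll <- ll - (log(phi) + mx)
      if (what == "all") {
        zbar <- (szR - f * szD) / phi
        grad <- grad - zbar
        info <- info + (rZZ - f * rZZD) / phi - tcrossprod(zbar)
      }
    }
    if (what == "all") grad <- grad + colSums(Z[inD, , drop = FALSE])
  }
  if (what == "loglik") return(ll)
  list(loglik = ll, grad = grad, info = info)
}
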
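# Survival random forest validation of the clinical score.  The forest
# itself (log-rank splits, Nelson-Aalen leaves, bootstrap aggregation) is
# compiled code; this file provides feature encoding, the train/validation
# split, OOB tuning over the published grid, horizon predictions and the
# probability-threshold risk grouping.

#' Stratified train/validation split
#'
#' Seeded split stratified by the event indicator, so the event fraction of
#' the two parts matches within one subject.
#'
#' @param cohort a `cohort_table`.
#' @param train_fraction fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with `train` and `validation` cohort tables.
#' @export
split_cohort <- function(cohort, train_fraction = 0.8, seed = 1) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("split_cohort(): train_fraction must be in (0, 1)")
  }
  ev <- cohort$os_event
  if (anyNA(ev)) stop("split_cohort(): os_event required for stratification")
  set.seed(seed)
  take <- logical(nrow(cohort))
  for (g in unique(ev)) {
    idx <- which(ev == g)
    n_train <- round(length(idx) * train_fraction)
    if (n_train == 0 || n_train == length(idx)) {
      stop("split_cohort(): cohort too small to populate both strata")
    }
    take[sample(idx, n_train)] <- TRUE
  }
  subset_cohort <- function(keep) {
    out <- cohort[keep, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- class(cohort)
    attr(out, "provenance") <- attr(cohort, "provenance")
    out
  }
  list(train = subset_cohort(take), validation = subset_cohort(!take))
}

#' Encode the seven forest features as an integer matrix
#'
#' Features: age group, BRAF, LDH category, CNS metastases, previous
#' treatment type (5-level by default, or dichotomized pre-target), NLR and
#' eosinophil categories.  Categories are coded as ordered integers
#' (unfavorable low) so the axis-parallel splits of the forest can separate
#' any category subset of these small factors.
#'
#' @param cohort a complete-case `cohort_table`.
#' @param prior_treatment_encoding "five_level" (default) or "pre_target".
#' @param age_cutoff ignored unless `age_years` must be re-binned (65
#'   default; 60 is the alternative convention for forest features).
#' @return integer matrix n x 7 with a `feature_levels` attribute.
#' @export
srf_features <- function(cohort,
                         prior_treatment_encoding = c("five_level", "pre_target"),
                         age_cutoff = NULL) {
  prior_treatment_encoding <- match.arg(prior_treatment_encoding)
  age <- cohort$age_group
  if (!is.null(age_cutoff)) {
    if (!all(is.finite(cohort$age_years))) {
      stop("srf_features(): age_years needed to re-bin with a custom cutoff")
    }
    age <- derive_age_group(cohort$age_years, age_cutoff)
  }
  codes <- list(
    age_group = c(younger = 0L, older = 1L),
    braf = c(mutated = 0L, wildtype = 1L),
    ldh_category = c(very_high = 0L, high = 1L, normal = 2L),
    cns_met = c(yes = 0L, no = 1L),
    prior_treatment = c(target = 0L, target_and_immunotherapy = 1L,
                        cytostatic = 2L, immunotherapy = 3L, naive = 4L),
    pre_target = c(yes = 0L, no = 1L),
    eosinophil_category = c(elevated = 0L, normal = 1L),
    nlr_category = c(abnormal = 0L, normal = 1L)
  )
  treat_col <- if (prior_treatment_encoding == "five_level") "prior_treatment" else "pre_target"
  vars <- c("age_group", "braf", "ldh_category", "cns_met", treat_col,
            "eosinophil_category", "nlr_category")
  X <- matrix(NA_integer_, nrow(cohort), length(vars),
              dimnames = list(NULL, vars))
  for (v in vars) {
    col <- if (v == "age_group") age else cohort[[v]]
    w <- codes[[v]][as.character(col)]
    if (nrow(cohort) > 0 && anyNA(w)) {
      bad <- which(is.na(w))[1]
      stop(sprintf("srf_features(): unseen/missing level '%s' in '%s' (record %s)",
                   col[bad], v, cohort$patient_id[bad]))
    }
    X[, v] <- as.integer(w)
  }
  attr(X, "feature_levels") <- codes[vars]
  X
}

#' Fit a survival random forest
#'
#' Bootstrap-aggregated survival trees with log-rank splitting and
#' Nelson-Aalen leaf cumulative hazards.  Out-of-bag ensemble mortality
#' (the sum of the OOB cumulative hazard over the event-time grid) gives
#' the OOB error as 1 - Harrell's concordance.
#'
#' @param cohort complete-case `cohort_table` with survival columns, or an
#'   integer feature matrix (then supply `times`/`events`).
#' @param ntree,mtry,nodesize forest parameters.  `nodesize` is the minimum
#'   number of bootstrap cases in a child node.
#' @param seed integer seed.
#' @param times,events used when `cohort` is a plain matrix.
#' @param prior_treatment_encoding passed to [srf_features()].
#' @return object of class `srf_model`: forest structure, parameters,
#'   `oob_mortality`, `oob_error` (1 - OOB concordance), the event-time
#'   grid, and the feature encoding.
#' @export
fit_srf <- function(cohort, ntree = 500, mtry = 2, nodesize = 6, seed = 1,
                    times = NULL, events = NULL,
                    prior_treatment_encoding = "five_level") {
  if (is.matrix(cohort)) {
    X <- cohort
    feature_levels <- attr(X, "feature_levels")
  } else {
    X <- srf_features(cohort, prior_treatment_encoding)
    feature_levels <- attr(X, "feature_levels")
    times <- cohort$os_months
    events <- cohort$os_event
  }
  stopifnot(length(times) == nrow(X), length(events) == nrow(X))
  if (sum(events) == 0) stop("fit_srf(): no events in training data")
  grid <- sort(unique(times[events == 1]))
  set.seed(seed)
  forest <- srf_fit_cpp(X, as.numeric(times), as.integer(events),
                        as.integer(ntree), as.integer(mtry),
                        as.integer(nodesize), grid)
  mort <- rowSums(forest$oob_chf)
  ok <- !is.na(mort)
  oob_error <- 1 - concordance_index(mort[ok], times[ok], events[ok])
  model <- list(forest = forest[c("roots", "svar", "sval", "left", "right",
                                  "loff", "llen", "ltime", "linc")],
                ntree = ntree, mtry = mtry, nodesize = nodesize, seed = seed,
                features = colnames(X), feature_levels = feature_levels,
                prior_treatment_encoding = prior_treatment_encoding,
                time_grid = grid, oob_chf = forest$oob_chf,
                oob_mortality = mort, oob_error = oob_error,
                n = nrow(X), n_events = sum(events))
  class(model) <- "srf_model"
  model
}

#' @export
print.srf_model <- function(x, ...) {
  cat(sprintf("<srf_model: ntree=%d mtry=%d nodesize=%d | n=%d events=%d | OOB error %.3f>\n",
              x$ntree, x$mtry, x$nodesize, x$n, x$n_events, x$oob_error))
  invisible(x)
}

#' Tune forest parameters by out-of-bag error
#'
#' For each tree count in the grid, every (mtry, nodesize) combination is
#' fitted and the OOB error (1 - OOB concordance) recorded; the smallest
#' error wins, with ties broken toward fewer trees, then smaller nodesize,
#' then smaller mtry.  The default grids follow the published tuning:
#' ntree in {50, 100, 200, 500, 1000}, mtry searched upward from 2.
#'
#' @param cohort complete-case `cohort_table` (>= 30 records, >= 10 events).
#' @param ntree_grid,mtry_grid,nodesize_grid search grids.
#' @param seed integer seed (same bootstrap stream per combination index).
#' @param prior_treatment_encoding passed to [srf_features()].
#' @return list of class `srf_tuning`: `best` (ntree, mtry, nodesize,
#'   oob_error) and `oob_table` (the full grid).
#' @export
tune_srf <- function(cohort, ntree_grid = c(50, 100, 200, 500, 1000),
                     mtry_grid = 2:4, nodesize_grid = c(3, 6, 10, 15),
                     seed = 1, prior_treatment_encoding = "five_level") {
  if (nrow(cohort) < 30 || sum(cohort$os_event) < 10) {
    stop("tune_srf(): need at least 30 records with at least 10 events")
  }
  X <- srf_features(cohort, prior_treatment_encoding)
  constant <- apply(X, 2, function(col) length(unique(col)) == 1)
  if (any(constant)) {
    warning("tune_srf(): constant feature(s) excluded from mtry cap: ",
            paste(colnames(X)[constant], collapse = ", "))
  }
  p_eff <- sum(!constant)
  mtry_grid <- mtry_grid[mtry_grid <= p_eff]
  if (!length(mtry_grid)) mtry_grid <- p_eff
  grid <- expand.grid(ntree = ntree_grid, mtry = mtry_grid,
                      nodesize = nodesize_grid)
  grid$oob_error <- NA_real_
  for (i in seq_len(nrow(grid))) {
    m <- fit_srf(X, ntree = grid$ntree[i], mtry = grid$mtry[i],
                 nodesize = grid$nodesize[i], seed = seed,
                 times = cohort$os_months, events = cohort$os_event)
    grid$oob_error[i] <- m$oob_error
  }
  ord <- order(grid$oob_error, grid$ntree, grid$nodesize, grid$mtry)
  best <- grid[ord[1], ]
  out <- list(best = best, oob_table = grid, seed = seed)
  class(out) <- "srf_tuning"
  out
}

#' @export
print.srf_tuning <- function(x, ...) {
  cat(sprintf("<srf_tuning: best ntree=%d mtry=%d nodesize=%d (OOB error %.4f)>\n",
              x$best$ntree, x$best$mtry, x$best$nodesize, x$best$oob_error))
  invisible(x)
}

#' Predict survival probabilities at fixed horizons
#'
#' Ensemble cumulative hazard (mean over trees of the terminal-node
#' Nelson-Aalen estimates) converted to survival by exp(-H); monotone
#' non-increasing in the horizon by construction.
#'
#' @param model an `srf_model`.
#' @param cohort a `cohort_table` (or pre-encoded feature matrix) with the
#'   model's features.
#' @param horizons months; default the published 12/24/36/60.
#' @return numeric matrix n x length(horizons), columns named "p<horizon>".
#' @export
predict_survival_prob <- function(model, cohort, horizons = c(12, 24, 36, 60)) {
  stopifnot(inherits(model, "srf_model"))
  if (any(horizons < 0)) stop("predict_survival_prob(): horizons must be >= 0")
  X <- if (is.matrix(cohort)) cohort else {
    srf_features(cohort, model$prior_treatment_encoding)
  }
  if (!identical(colnames(X), model$features)) {
    stop("predict_survival_prob(): feature mismatch with the fitted model")
  }
  ord <- order(horizons)
  chf <- srf_predict_cpp(model$forest, X, as.numeric(horizons[ord]))
  surv <- exp(-chf)
  out <- matrix(NA_real_, nrow(X), length(horizons),
                dimnames = list(NULL, paste0("p", horizons)))
  out[, ord] <- surv
  out
}

#' Out-of-bag survival probabilities of the training records
#'
#' Survival probabilities derived from the OOB ensemble cumulative hazard
#' (each record predicted only by trees whose bootstrap sample excluded it).
#' Use these, rather than [predict_survival_prob()] on the training data,
#' whenever the probabilities feed a downstream test on the same records:
#' in-sample ensemble predictions are optimistically biased.
#'
#' @param model an `srf_model`.
#' @param horizons months.
#' @return numeric matrix n x length(horizons).
#' @export
oob_survival_prob <- function(model, horizons = c(12, 24, 36, 60)) {
  stopifnot(inherits(model, "srf_model"))
  idx <- findInterval(horizons, model$time_grid)
  chf <- cbind(0, model$oob_chf)[, idx + 1, drop = FALSE]
  colnames(chf) <- paste0("p", horizons)
  exp(-chf)
}

#' Group patients by predicted survival probability
#'
#' `three_group` mode applies the published fixed thresholds to the 60-month
#' survival probability: below 0.2 high risk, at or above 0.41 low risk,
#' medium in between.  `five_signature` mode cuts the predicted-probability
#' distribution at the CLICAL signature proportions (cumulative 9.1%, 23.2%,
#' 45.3%, 93.6%, worst to best) so the forest signatures are size-matched to
#' the score signatures.
#'
#' @param probs_at_60 survival probabilities in [0, 1] at the 60-month
#'   horizon.
#' @param mode "three_group" or "five_signature".
#' @param thresholds for `three_group`, the (high, low) cut pair (default
#'   c(0.2, 0.41)); for `five_signature`, the cumulative proportions of
#'   signatures I..IV (default c(0.091, 0.232, 0.453, 0.936)).
#' @return list of class `risk_groups`: `group` (per patient), `mode`,
#'   `thresholds`.
#' @export
assign_risk_groups <- function(probs_at_60,
                               mode = c("three_group", "five_signature"),
                               thresholds = NULL) {
  mode <- match.arg(mode)
  p <- as.numeric(probs_at_60)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("assign_risk_groups(): probabilities must lie in [0, 1]")
  }
  if (mode == "three_group") {
    if (is.null(thresholds)) thresholds <- c(0.2, 0.41)
    if (length(thresholds) != 2 || thresholds[1] >= thresholds[2]) {
      stop("assign_risk_groups(): three_group needs increasing (high, low) thresholds")
    }
    group <- ifelse(p < thresholds[1], "high",
                    ifelse(p >= thresholds[2], "low", "medium"))
  } else {
    if (is.null(thresholds)) thresholds <- c(0.091, 0.232, 0.453, 0.936)
    if (length(thresholds) != 4 || any(diff(thresholds) <= 0)) {
      stop("assign_risk_groups(): five_signature needs 4 increasing cumulative proportions")
    }
    cuts <- quantile(p, probs = thresholds, type = 1)
    group <- signature_labels[1 + findInterval(p, cuts, left.open = TRUE)]
  }
  if (length(unique(group)) == 1 && length(p) > 1) {
    warning("assign_risk_groups(): all patients fall in a single group")
  }
  out <- list(group = group, mode = mode, thresholds = thresholds)
  class(out) <- "risk_groups"
  out
}
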
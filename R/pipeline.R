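# End-to-end driver: simulate (or read) a cohort, filter to complete cases,
# score, run the native survival statistics by signature and by ICI agent,
# fit Cox models, evaluate the Cox model on a held-out split with
# time-dependent AUCs, tune/fit/predict the survival random forest, group by
# predicted risk, and write all artifacts with a reproducibility manifest.

#' Pipeline configuration
#'
#' @param generator a `generator_config`, or NULL when reading a cohort.
#' @param cohort_csv input cohort CSV path (used when `generator` is NULL).
#' @param seed master seed; stage seeds derive from it.
#' @param horizons evaluation horizons in months.
#' @param srf_ntree_grid,srf_mtry_grid,srf_nodesize_grid forest tuning grids.
#' @param train_fraction held-out split fraction.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(), cohort_csv = NULL,
                            seed = 1, horizons = c(12, 24, 36, 60),
                            srf_ntree_grid = c(50, 100, 200, 500, 1000),
                            srf_mtry_grid = 2:4,
                            srf_nodesize_grid = c(3, 6, 10, 15),
                            train_fraction = 0.8) {
  cfg <- list(generator = generator, cohort_csv = cohort_csv, seed = seed,
              horizons = horizons, srf_ntree_grid = srf_ntree_grid,
              srf_mtry_grid = srf_mtry_grid,
              srf_nodesize_grid = srf_nodesize_grid,
              train_fraction = train_fraction)
  class(cfg) <- "pipeline_config"
  cfg
}

# stable polynomial hash of the JSON-serialized config (fingerprint only;
# kept below 2^31 so integer arithmetic stays exact)
config_hash <- function(cfg) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                      digits = 10, null = "null",
                                      force = TRUE))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 67108859
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate/read -> validate -> complete-case filter -> CLICAL
#' scoring -> KM/Nelson-Aalen/log-rank by signature and by ICI agent ->
#' univariate and multivariate Cox with forest table -> train/validation
#' split -> Cox time-dependent AUC at the horizons (the 60-month ROC is
#' allowed to fail when cases or controls run out, mirroring sparse
#' long-horizon follow-up) -> SRF tune/fit/predict -> risk grouping -> KM by
#' SRF signature.  Any stage failure aborts with the stage name; artifacts
#' written so far are kept.
#'
#' @param config a `pipeline_config`.
#' @param out_dir directory for artifacts (created if needed); NULL skips
#'   file output.
#' @return list of class `pipeline_result` (also the run manifest).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit_csv <- function(df, name) {
    if (!is.null(out_dir)) {
      write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }
  emit_json <- function(x, name) {
    if (!is.null(out_dir)) {
      jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                           digits = 10, force = TRUE)
    }
  }
  stage <- function(name, expr) {
    say("stage %s", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cohort <- stage("input", {
    if (!is.null(config$cohort_csv)) {
      read_cohort(config$cohort_csv)
    } else {
      simulate_cohort(config$generator)
    }
  })
  if (!is.null(out_dir) && is.null(config$cohort_csv)) {
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  }
  complete <- stage("complete_case_filter", {
    suppressMessages(complete_case_filter(cohort))
  })
  say("complete cases: %d of %d", nrow(complete), nrow(cohort))

  scores <- stage("clical_score", score_cohort(complete))
  emit_csv(scores$scores, "clical_scores.csv")
  emit_csv(scores$summary, "clical_summary.csv")

  surv_stats <- stage("survival_by_group", {
    out <- list()
    for (grp in c("signature", "ici_agent")) {
      g <- if (grp == "signature") scores$scores$signature else complete[[grp]]
      lr <- log_rank(complete$os_months, complete$os_event, g)
      out[[grp]] <- list(log_rank = lr, km = list(), na = list())
      for (lev in sort(unique(g))) {
        sel <- g == lev
        out[[grp]]$km[[lev]] <- suppressWarnings(
          km_estimate(complete$os_months[sel], complete$os_event[sel]))
        out[[grp]]$na[[lev]] <- na_cumhaz(complete$os_months[sel],
                                          complete$os_event[sel])
        emit_csv(as.data.frame(out[[grp]]$km[[lev]]),
                 sprintf("km_%s_%s.csv", grp, lev))
      }
      emit_json(list(chi_square = lr$chi_square, df = lr$df,
                     p_value = lr$p_value), sprintf("logrank_%s.json", grp))
    }
    out
  })

  cox <- stage("cox", {
    vars <- clical_variables()
    X <- cox_model_matrix(complete, vars)
    multi <- cox_fit(X, complete$os_months, complete$os_event)
    uni <- lapply(seq_len(ncol(X)), function(j) {
      cox_fit(X[, j, drop = FALSE], complete$os_months, complete$os_event)
    })
    uni_table <- do.call(rbind, lapply(uni, cox_forest_table))
    emit_csv(cox_forest_table(multi), "cox_multivariate_forest.csv")
    emit_csv(uni_table, "cox_univariate_forest.csv")
    list(multivariate = multi, univariate = uni_table)
  })

  split <- stage("split", {
    split_cohort(complete, config$train_fraction, seed = config$seed + 1)
  })

  cox_val <- stage("cox_validation", {
    vars <- clical_variables()
    # encode once on the full complete-case cohort so the validation rows
    # share the training design (tiny splits can lose category levels)
    Xall <- cox_model_matrix(complete, vars)
    tr <- complete$patient_id %in% split$train$patient_id
    fit <- cox_fit(Xall[tr, , drop = FALSE], complete$os_months[tr],
                   complete$os_event[tr])
    lp <- drop(Xall[!tr, , drop = FALSE] %*% fit$coef)
    split$validation <- complete[!tr, , drop = FALSE]
    aucs <- list()
    for (h in config$horizons) {
      aucs[[paste0("auc", h)]] <- tryCatch(
        td_roc(lp, split$validation$os_months, split$validation$os_event, h)$auc,
        error = function(e) {
          say("cox_validation: ROC at %g months not computable (%s)", h,
              conditionMessage(e))
          NA_real_
        })
    }
    emit_json(aucs, "cox_validation_auc.json")
    aucs
  })

  srf <- if (nrow(split$train) < 30 || sum(split$train$os_event) < 10) {
    say("srf: skipped (insufficient records/events in training split)")
    list(skipped = TRUE, reason = "insufficient records or events")
  } else stage("srf", {
    tuning <- tune_srf(split$train, ntree_grid = config$srf_ntree_grid,
                       mtry_grid = config$srf_mtry_grid,
                       nodesize_grid = config$srf_nodesize_grid,
                       seed = config$seed + 2)
    emit_csv(tuning$oob_table, "srf_oob_table.csv")
    # final model on the full complete-case cohort at the tuned parameters
    model <- fit_srf(complete, ntree = tuning$best$ntree,
                     mtry = tuning$best$mtry,
                     nodesize = tuning$best$nodesize, seed = config$seed + 3)
    probs <- predict_survival_prob(model, complete, config$horizons)
    p60 <- probs[, ncol(probs)]
    rg3 <- assign_risk_groups(p60, "three_group")
    rg5 <- assign_risk_groups(p60, "five_signature")
    pred <- data.frame(patient_id = complete$patient_id, probs,
                       risk_group = rg3$group, srf_signature = rg5$group,
                       stringsAsFactors = FALSE)
    emit_csv(pred, "srf_predictions.csv")
    emit_json(list(ntree = tuning$best$ntree, mtry = tuning$best$mtry,
                   nodesize = tuning$best$nodesize,
                   oob_error = model$oob_error), "srf_tuned_params.json")
    for (lev in sort(unique(rg5$group))) {
      sel <- rg5$group == lev
      emit_csv(as.data.frame(suppressWarnings(
        km_estimate(complete$os_months[sel], complete$os_event[sel]))),
        sprintf("km_srf_signature_%s.csv", lev))
    }
    lr5 <- tryCatch(log_rank(complete$os_months, complete$os_event, rg5$group),
                    error = function(e) NULL)
    list(tuning = tuning, model = model, predictions = pred,
         log_rank_five = lr5, skipped = FALSE)
  })

  manifest <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("clical")),
    r_version = R.version.string,
    n_input = nrow(cohort), n_complete = nrow(complete),
    plateau_factor_c = attr(cohort, "plateau_factor_c"),
    signatures = sort(unique(scores$scores$signature)),
    signature_counts = as.list(table(scores$scores$signature)),
    logrank_signature_p = surv_stats$signature$log_rank$p_value,
    cox_validation_auc = cox_val,
    srf_skipped = isTRUE(srf$skipped),
    srf_params = if (!isTRUE(srf$skipped)) {
      list(ntree = srf$tuning$best$ntree, mtry = srf$tuning$best$mtry,
           nodesize = srf$tuning$best$nodesize,
           oob_error = srf$model$oob_error)
    }
  )
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  emit_json(manifest, "manifest.json")
  if (!is.null(out_dir)) {
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  result <- list(manifest = manifest, cohort = cohort, complete = complete,
                 scores = scores, survival = surv_stats, cox = cox,
                 cox_validation = cox_val, srf = srf, log = log_lines)
  class(result) <- "pipeline_result"
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  str(x$manifest, give.attr = FALSE)
  invisible(x)
}
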
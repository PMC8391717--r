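strong_cohort <- function(seed = 2, n = 578) {
  # widened hazard separation: a cohort where the clinical features carry a
  # strong survival signal
  cfg <- generator_config(n = n, seed = seed,
    signature_hazard_32 = c(I = 6.8, II = 3.4, III = 1.7, IV = 0.55, V = 0.12),
    plateau_factor_c = 0.2)
  suppressMessages(complete_case_filter(simulate_cohort(cfg)))
}

test_that("split_cohort stratifies by event and is deterministic", {
  co <- make_complete_cohort(n = 700, seed = 10)
  co <- co[seq_len(500), ]
  sp <- split_cohort(co, 0.8, seed = 3)
  expect_equal(nrow(sp$train), 400)
  expect_equal(nrow(sp$validation), 100)
  expect_lt(abs(mean(sp$train$os_event) - mean(sp$validation$os_event)), 0.02)
  sp2 <- split_cohort(co, 0.8, seed = 3)
  expect_identical(sp$train$patient_id, sp2$train$patient_id)
  expect_error(split_cohort(co, 1), "train_fraction")
  expect_error(split_cohort(co[1:3, ], 0.5), "too small")
})

test_that("forest predictions are monotone, deterministic and order-invariant", {
  co <- strong_cohort()
  m <- fit_srf(co, ntree = 200, mtry = 2, nodesize = 6, seed = 7)
  p <- predict_survival_prob(m, co, horizons = c(12, 24, 36, 60))
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(t(p)) <= 1e-12))        # non-increasing across horizons
  # horizon 0 -> probability 1
  expect_equal(unname(predict_survival_prob(m, co[1:3, ], horizons = 0)[, 1]),
               rep(1, 3))
  # duplicate records predict identically
  dup <- co[c(1, 1), ]; dup$patient_id <- c("a", "b")
  class(dup) <- class(co)
  pd <- predict_survival_prob(m, dup)
  expect_equal(pd[1, ], pd[2, ])
  # record order does not change per-patient predictions
  perm <- sample(nrow(co))
  pp <- predict_survival_prob(m, co[perm, ])
  expect_equal(pp[order(perm), ], p, tolerance = 1e-12)
  # refit with the same seed is identical
  m2 <- fit_srf(co, ntree = 200, mtry = 2, nodesize = 6, seed = 7)
  expect_identical(m$oob_mortality, m2$oob_mortality)
})

test_that("degenerate single-node forest predicts the pooled hazard for everyone", {
  co <- strong_cohort(seed = 5, n = 300)
  m <- fit_srf(co, ntree = 300, mtry = 2, nodesize = nrow(co), seed = 6)
  p <- predict_survival_prob(m, co)
  expect_equal(max(apply(p, 2, function(col) diff(range(col)))), 0)
  pooled <- exp(-curve_at(na_cumhaz(co$os_months, co$os_event),
                          c(12, 24, 36, 60)))
  expect_equal(unname(p[1, ]), pooled, tolerance = 0.02)
})

test_that("OOB concordance reflects signal strength and leaks nothing", {
  co <- strong_cohort()
  m <- fit_srf(co, ntree = 300, mtry = 2, nodesize = 6, seed = 3)
  oob_c <- 1 - m$oob_error
  expect_gt(oob_c, 0.65)
  # in-sample concordance strictly higher than OOB (no in-bag leakage)
  p60 <- predict_survival_prob(m, co, horizons = 60)[, 1]
  in_c <- concordance_index(-p60, co$os_months, co$os_event)
  expect_gt(in_c, oob_c)
  # pure-noise features: OOB error near 0.5
  set.seed(4)
  n <- 400
  Xn <- matrix(sample(0:3, n * 7, TRUE), n, 7,
               dimnames = list(NULL, paste0("f", 1:7)))
  mn <- fit_srf(Xn, ntree = 300, mtry = 2, nodesize = 6, seed = 5,
                times = rexp(n, 0.1), events = rbinom(n, 1, 0.8))
  expect_equal(mn$oob_error, 0.5, tolerance = 0.07)
  expect_error(fit_srf(Xn, times = rexp(n), events = rep(0, n)), "no events")
})

test_that("feature encoding covers both treatment encodings and rejects unknowns", {
  co <- make_complete_cohort(n = 200, seed = 8)
  X5 <- srf_features(co)
  expect_equal(colnames(X5),
               c("age_group", "braf", "ldh_category", "cns_met",
                 "prior_treatment", "eosinophil_category", "nlr_category"))
  X2 <- srf_features(co, prior_treatment_encoding = "pre_target")
  expect_true("pre_target" %in% colnames(X2))
  expect_true(all(X5[, "prior_treatment"] %in% 0:4))
  bad <- co; bad$braf[1] <- "untested"
  expect_error(srf_features(bad), "untested")
  # model rejects mismatched features
  m <- fit_srf(co, ntree = 50, seed = 1)
  expect_error(predict_survival_prob(m, X2), "feature mismatch")
})

test_that("tuning searches the grid and beats a deliberately poor setting", {
  co <- make_complete_cohort(n = 578, seed = 20)
  tu <- tune_srf(co, ntree_grid = c(50, 200), mtry_grid = 2,
                 nodesize_grid = c(6, 15), seed = 2)
  expect_true(tu$best$ntree %in% c(50, 200))
  expect_equal(nrow(tu$oob_table), 4)
  expect_equal(tu$best$oob_error, min(tu$oob_table$oob_error))
  # ties broken toward fewer trees then smaller nodesize
  tied <- tu$oob_table
  tied$oob_error <- 0.4
  ord <- order(tied$oob_error, tied$ntree, tied$nodesize, tied$mtry)
  expect_equal(tied$ntree[ord[1]], 50)
  expect_equal(tied$nodesize[ord[1]], 6)
  expect_error(tune_srf(co[1:20, ]), "at least 30")
})

test_that("risk grouping applies the published thresholds and quantile cuts", {
  rg <- assign_risk_groups(c(0.19, 0.41, 0.3, 0.2, 0.05, 0.9), "three_group")
  expect_equal(rg$group, c("high", "low", "medium", "medium", "high", "low"))
  expect_warning(assign_risk_groups(rep(0.3, 5), "three_group"), "single group")
  expect_error(assign_risk_groups(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(assign_risk_groups(0.5, "three_group", thresholds = c(0.5, 0.2)),
               "increasing")
  # five-signature cuts are size-matched to the configured proportions
  set.seed(9)
  p <- runif(1000)
  rg5 <- assign_risk_groups(p, "five_signature")
  frac <- table(rg5$group)[c("I", "II", "III", "IV", "V")] / 1000
  expect_equal(unname(as.vector(frac)), c(0.091, 0.141, 0.221, 0.483, 0.064),
               tolerance = 0.02)
  # groups ordered by probability: I holds the lowest predicted survival
  expect_lt(max(p[rg5$group == "I"]), min(p[rg5$group == "V"]))
})

test_that("five-signature groups from a fitted forest have ordered survival", {
  co <- strong_cohort(seed = 31)
  m <- fit_srf(co, ntree = 300, mtry = 2, nodesize = 6, seed = 8)
  p60 <- predict_survival_prob(m, co, horizons = 60)[, 1]
  rg <- assign_risk_groups(p60, "five_signature")
  km32 <- vapply(c("I", "II", "III", "IV", "V"), function(g) {
    sel <- rg$group == g
    curve_at(suppressWarnings(km_estimate(co$os_months[sel],
                                          co$os_event[sel])), 32)
  }, 0)
  expect_true(all(diff(km32) > 0))   # survival improves from I to V
})

test_that("uninformative features give null log-rank behavior across seeds", {
  # features independent of survival: the five-signature log-rank should
  # reject at about the nominal level
  rejections <- 0
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    n <- 150
    Xn <- matrix(sample(0:2, n * 7, TRUE), n, 7,
                 dimnames = list(NULL, paste0("f", 1:7)))
    tt <- rexp(n, 0.08); ev <- rbinom(n, 1, 0.8)
    m <- fit_srf(Xn, ntree = 60, mtry = 2, nodesize = 10, seed = s,
                 times = tt, events = ev)
    # grouping must use OOB predictions: in-sample ensemble predictions are
    # correlated with each record's own outcome and inflate the chi-square
    p60 <- oob_survival_prob(m, horizons = 60)[, 1]
    rg <- suppressWarnings(assign_risk_groups(p60, "five_signature"))
    lr <- tryCatch(log_rank(tt, ev, rg$group), error = function(e) NULL)
    if (!is.null(lr) && lr$p_value < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / n_seeds, 0.15)
})
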
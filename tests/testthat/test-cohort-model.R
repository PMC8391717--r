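test_that("LDH categorization respects the ratio boundaries", {
  expect_equal(categorize_ldh(450, 500), "normal")   # ratio 0.9
  expect_equal(categorize_ldh(500, 500), "normal")   # boundary ratio 1
  expect_equal(categorize_ldh(1250, 500), "very_high")
  expect_equal(categorize_ldh(c(600, 1000, 1001), rep(500, 3)),
               c("high", "high", "very_high"))
  # alternative boundary convention
  expect_equal(categorize_ldh(500, 500, boundary = "upper"), "high")
  expect_error(categorize_ldh(-1, 500), "positive")
  expect_error(categorize_ldh(500, 0), "positive")
})

test_that("NLR ratio and category follow the [1, 4] normal range", {
  expect_equal(categorize_nlr(4000, 800),
               data.frame(nlr_value = 5, nlr_category = "abnormal"))
  expect_equal(categorize_nlr(2000, 1000)$nlr_category, "normal")
  expect_equal(categorize_nlr(800, 1000),
               data.frame(nlr_value = 0.8, nlr_category = "abnormal"))
  # closed interval boundaries are normal
  expect_equal(categorize_nlr(c(1000, 4000), c(1000, 1000))$nlr_category,
               c("normal", "normal"))
  expect_error(categorize_nlr(1000, 0), "positive")
  # ratio reconstruction property
  set.seed(42)
  neut <- runif(50, 500, 9000); lymph <- runif(50, 200, 4000)
  expect_equal(categorize_nlr(neut, lymph)$nlr_value * lymph, neut,
               tolerance = 1e-9)
})

test_that("age grouping uses the configurable cutoff", {
  expect_equal(derive_age_group(64), "younger")
  expect_equal(derive_age_group(65), "older")
  expect_equal(derive_age_group(65, cutoff = 61), "older")
  expect_equal(derive_age_group(60, cutoff = 61), "younger")
  expect_warning(val <- derive_age_group(15), "below 18")
  expect_equal(val, "younger")
})

test_that("complete_case_filter drops unknowns, is idempotent and order-preserving", {
  df <- data.frame(
    patient_id = c("a", "b", "c"),
    age_group = c("older", "younger", "older"),
    braf = c("mutated", "untested", "wildtype"),
    cns_met = "no", ldh_category = "normal",
    eosinophil_category = "normal", nlr_category = "normal",
    prior_treatment = c("target", "naive", "naive"),
    pre_target = c("yes", "no", "no"),
    os_months = c(5, 10, 15), os_event = c(1, 0, 1),
    stringsAsFactors = FALSE)
  cohort <- cohort_table(df)
  filtered <- suppressMessages(complete_case_filter(cohort))
  expect_equal(filtered$patient_id, c("a", "c"))
  expect_equal(attr(filtered, "n_removed"), 1)
  expect_equal(unname(attr(filtered, "removed_counts")["braf"]), 1)
  again <- suppressMessages(complete_case_filter(filtered))
  expect_equal(as.data.frame(again), as.data.frame(filtered),
               ignore_attr = TRUE)
  # no missing values -> identity
  full <- cohort_table(df[df$braf != "untested", ])
  expect_equal(suppressMessages(complete_case_filter(full))$patient_id,
               full$patient_id)
  # empty result warns rather than errors
  all_missing <- cohort_table(transform(df[2, ], braf = "untested"))
  expect_warning(suppressMessages(complete_case_filter(all_missing)),
                 "no complete cases")
})

test_that("cohort CSV round-trips and normalizes tokens", {
  cohort <- simulate_cohort(generator_config(n = 40, seed = 9))
  f <- tempfile(fileext = ".csv")
  write_cohort(cohort, f)
  back <- read_cohort(f)
  expect_equal(as.data.frame(back)[names(as.data.frame(cohort))],
               as.data.frame(cohort), tolerance = 1e-12, ignore_attr = TRUE)
  # write(read(f)) is byte-identical on canonical files
  f2 <- tempfile(fileext = ".csv")
  write_cohort(back, f2)
  expect_identical(readLines(f), readLines(f2))
  # token variants normalize
  raw <- read.csv(f, stringsAsFactors = FALSE)
  idx <- which(raw$pre_target == "no")[1:2]   # rows free of the BRAF constraint
  raw$ldh_category[idx[1]] <- "VERY-HIGH"
  raw$braf[idx[2]] <- "Wild Type"
  f3 <- tempfile(fileext = ".csv")
  write.csv(raw, f3, row.names = FALSE)
  reread <- read_cohort(f3)
  expect_equal(reread$ldh_category[idx[1]], "very_high")
  expect_equal(reread$braf[idx[2]], "wildtype")
  # unknown token errors with row and column
  raw$cns_met[3] <- "perhaps"
  write.csv(raw, f3, row.names = FALSE)
  expect_error(read_cohort(f3), "cns_met.*row 3|row 3.*cns_met")
  # mandatory columns enforced
  f4 <- tempfile(fileext = ".csv")
  write.csv(raw[, setdiff(names(raw), "os_event")], f4, row.names = FALSE)
  expect_error(read_cohort(f4), "os_event")
})

test_that("raw inputs are re-derived and mismatches warn", {
  df <- data.frame(patient_id = c("p1", "p2"), age_years = c(70, 40),
                   age_group = c("younger", "younger"),  # p1 wrong on purpose
                   ldh_ratio = c(2.5, 0.5),
                   neutrophils = c(4000, 2000), lymphocytes = c(800, 1000),
                   braf = "wildtype", cns_met = "no",
                   eosinophil_category = "normal",
                   prior_treatment = "naive",
                   os_months = c(3, 6), os_event = c(1, 0),
                   stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  expect_warning(cohort <- read_cohort(f), "age_group")
  expect_equal(cohort$age_group, c("older", "younger"))
  expect_equal(cohort$ldh_category, c("very_high", "normal"))
  expect_equal(cohort$nlr_category, c("abnormal", "normal"))
  expect_equal(cohort$nlr_value, c(5, 2))
  expect_equal(cohort$pre_target, c("no", "no"))
})

test_that("validation enforces the pre-target / BRAF structural invariant", {
  df <- data.frame(patient_id = "x", age_group = "older", braf = "wildtype",
                   cns_met = "no", ldh_category = "normal",
                   eosinophil_category = "normal", nlr_category = "normal",
                   prior_treatment = "target", pre_target = "yes",
                   os_months = 1, os_event = 1, stringsAsFactors = FALSE)
  expect_error(cohort_table(df), "pre_target_without_braf_mutation")
  report <- validate_cohort(cohort_table(df, validate = FALSE), report = TRUE)
  expect_true("pre_target_without_braf_mutation" %in% report$rule)
  df$braf <- "mutated"
  expect_s3_class(cohort_table(df), "cohort_table")
  expect_error(cohort_table(transform(df, os_months = -2)), "negative_os_months")
  expect_error(cohort_table(transform(df, os_event = 2)), "os_event_not_binary")
})
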
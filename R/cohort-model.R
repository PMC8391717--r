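#' @useDynLib clical, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats qnorm pnorm pchisq runif rbinom quantile setNames
#' @importFrom utils read.csv write.csv modifyList str
"_PACKAGE"

# Category vocabularies.  Tokens are the canonical lower-case forms used in
# cohort CSV files; "unknown"/"untested" mark missing clinical information.
.clical_levels <- list(
  sex                 = c("female", "male", "unknown"),
  age_group           = c("younger", "older", "unknown"),
  braf                = c("mutated", "wildtype", "untested"),
  cns_met             = c("yes", "no", "unknown"),
  ldh_category        = c("normal", "high", "very_high", "unknown"),
  eosinophil_category = c("normal", "elevated", "unknown"),
  nlr_category        = c("normal", "abnormal", "unknown"),
  prior_treatment     = c("naive", "immunotherapy", "target",
                          "target_and_immunotherapy", "cytostatic"),
  pre_target          = c("yes", "no"),
  ici_agent           = c("anti_ctla4", "nivolumab", "pembrolizumab"),
  response            = c("CR", "PR", "SD", "PD", "unknown")
)

.missing_tokens <- c(age_group = "unknown", braf = "untested",
                     cns_met = "unknown", ldh_category = "unknown",
                     eosinophil_category = "unknown", nlr_category = "unknown")

.cohort_columns <- c("patient_id", "sex", "age_years", "age_group", "braf",
                     "cns_met", "ldh_ratio", "ldh_category",
                     "eosinophil_category", "neutrophils", "lymphocytes",
                     "nlr_value", "nlr_category", "prior_treatment",
                     "pre_target", "ici_agent", "os_months", "os_event",
                     "response")

#' Names of the seven CLICAL scoring variables
#'
#' The score is built from seven baseline categorical variables: age group,
#' BRAF mutation status, prior targeted therapy (dichotomized), LDH category,
#' NLR category, eosinophil category and CNS metastases.
#'
#' @return Character vector of the seven column names.
#' @export
clical_variables <- function() {
  c("age_group", "braf", "pre_target", "ldh_category", "nlr_category",
    "eosinophil_category", "cns_met")
}

#' Categorize an LDH value against the local laboratory reference
#'
#' LDH is grouped by multiples of the upper limit of the local laboratory
#' reference (LLR) interval: ratio <= 1 is normal, 1 < ratio <= 2 is high,
#' ratio > 2 is very high.  The placement of the exact boundaries is a
#' convention (the source tables print both open and closed forms); the
#' closed-on-the-left reading used here is controlled by `boundary`.
#'
#' @param ldh_value numeric, measured LDH concentration(s); must be positive.
#' @param llr_upper numeric, upper limit of the local reference interval.
#' @param boundary "lower" (default; ratio exactly 1 is normal, exactly 2 is
#'   high) or "upper" (ratio exactly 1 is high, exactly 2 is very high).
#' @return character vector with values "normal", "high" or "very_high".
#' @export
categorize_ldh <- function(ldh_value, llr_upper, boundary = c("lower", "upper")) {
  boundary <- match.arg(boundary)
  if (any(!is.finite(ldh_value)) || any(!is.finite(llr_upper)) ||
      any(ldh_value <= 0) || any(llr_upper <= 0)) {
    stop("categorize_ldh(): LDH value and reference limit must be positive")
  }
  ratio <- ldh_value / llr_upper
  categorize_ldh_ratio(ratio, boundary)
}

categorize_ldh_ratio <- function(ratio, boundary = "lower") {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("categorize_ldh_ratio(): ratio must be positive")
  }
  if (boundary == "lower") {
    ifelse(ratio <= 1, "normal", ifelse(ratio <= 2, "high", "very_high"))
  } else {
    ifelse(ratio < 1, "normal", ifelse(ratio < 2, "high", "very_high"))
  }
}

#' Neutrophil-to-lymphocyte ratio and its clinical category
#'
#' NLR = absolute neutrophil count / absolute lymphocyte count.  The ratio is
#' normal on the closed interval [1, 4]; values below 1 (low) or above 4
#' (high) are both reported as "abnormal", matching the dichotomy used in the
#' scoring algorithm.
#'
#' @param neutrophils,lymphocytes positive absolute counts (same units).
#' @return data.frame with columns `nlr_value` and `nlr_category`.
#' @export
categorize_nlr <- function(neutrophils, lymphocytes) {
  if (any(!is.finite(neutrophils)) || any(!is.finite(lymphocytes)) ||
      any(neutrophils <= 0) || any(lymphocytes <= 0)) {
    stop("categorize_nlr(): counts must be positive")
  }
  value <- neutrophils / lymphocytes
  data.frame(nlr_value = value,
             nlr_category = ifelse(value >= 1 & value <= 4, "normal", "abnormal"),
             stringsAsFactors = FALSE)
}

#' Dichotomize age into younger/older groups
#'
#' @param age_years age in years (adult cohort; values below 18 warn but are
#'   still classified).
#' @param cutoff years; ages at or above the cutoff are "older".  Default 65,
#'   the dichotomy the published score counts were built on; 60 is the
#'   alternative used by some forest feature definitions.
#' @return character vector "younger"/"older".
#' @export
derive_age_group <- function(age_years, cutoff = 65) {
  if (any(!is.finite(age_years)) || any(age_years < 0)) {
    stop("derive_age_group(): age must be non-negative")
  }
  if (any(age_years < 18)) {
    warning("derive_age_group(): age below 18 observed; classified anyway")
  }
  ifelse(age_years >= cutoff, "older", "younger")
}

#' Construct a cohort table
#'
#' A cohort table is a plain data.frame (one row per patient) carrying a
#' `provenance` attribute.  Missing optional columns are filled with NA /
#' "unknown" tokens; category tokens are normalized and checked.
#'
#' @param df data.frame with at least `patient_id`; canonical columns are
#'   filled in when absent.
#' @param provenance free-text label (e.g. "synthetic seed=1").
#' @param validate check category tokens and structural invariants.
#' @return data.frame of class `cohort_table`.
#' @export
cohort_table <- function(df, provenance = "unspecified", validate = TRUE) {
  stopifnot(is.data.frame(df))
  if (!"patient_id" %in% names(df)) stop("cohort_table(): patient_id required")
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    stop("cohort_table(): duplicate patient_id values")
  }
  numeric_cols <- c("age_years", "ldh_ratio", "neutrophils", "lymphocytes",
                    "nlr_value", "os_months", "os_event")
  for (col in .cohort_columns) {
    if (!col %in% names(df)) {
      fill <- if (col %in% names(.clical_levels)) {
        miss <- intersect(c("unknown", "untested"), .clical_levels[[col]])
        if (length(miss)) miss[1] else NA_character_
      } else NA_real_
      df[[col]] <- rep(fill, nrow(df))
    }
  }
  for (col in numeric_cols) df[[col]] <- as.numeric(df[[col]])
  df <- df[, c(.cohort_columns, setdiff(names(df), .cohort_columns)), drop = FALSE]
  for (col in names(.clical_levels)) {
    df[[col]] <- normalize_tokens(df[[col]], col)
  }
  rownames(df) <- NULL
  class(df) <- c("cohort_table", "data.frame")
  attr(df, "provenance") <- provenance
  if (validate) validate_cohort(df)
  df
}

# Lower-case, map spaces/hyphens to underscores, check against vocabulary.
normalize_tokens <- function(x, column) {
  lv <- .clical_levels[[column]]
  x <- as.character(x)
  na <- is.na(x) | x == ""
  y <- gsub("[ -]+", "_", trimws(tolower(x)))
  if (column == "response") {
    y <- toupper(y)
    y[y == "UNKNOWN"] <- "unknown"
  }
  # common aliases
  alias <- c(elevated = "elevated", abnormal = "abnormal",
             wild_type = "wildtype", mutation = "mutated", mut = "mutated",
             anti_ctla_4 = "anti_ctla4", "naïve" = "naive")
  hit <- y %in% names(alias)
  y[hit] <- alias[y[hit]]
  if (column == "eosinophil_category") y[y == "abnormal"] <- "elevated"
  miss <- intersect(c("unknown", "untested"), lv)
  if (length(miss)) y[na] <- miss[1] else y[na] <- NA_character_
  bad <- which(!is.na(y) & !(y %in% lv))
  if (length(bad)) {
    stop(sprintf("unknown token '%s' in column '%s' (row %d)",
                 x[bad[1]], column, bad[1]))
  }
  y
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table: %d patients; provenance: %s>\n",
              nrow(x), attr(x, "provenance") %||% "unspecified"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate structural invariants of a cohort table
#'
#' Checks that pre_target is consistent with prior_treatment, that targeted
#' pre-treatment only occurs in BRAF-mutated patients, and that survival
#' columns are well formed.  Violations raise an error carrying a per-rule
#' report; use `report = TRUE` to obtain the report without erroring.
#'
#' @param cohort a `cohort_table`.
#' @param report return the violation report instead of erroring.
#' @return invisibly `TRUE`, or the report data.frame when `report = TRUE`.
#' @export
validate_cohort <- function(cohort, report = FALSE) {
  probs <- list()
  pt <- cohort$prior_treatment
  expected_pre <- ifelse(pt %in% c("target", "target_and_immunotherapy"), "yes", "no")
  known_pt <- !is.na(pt)
  bad <- known_pt & !is.na(cohort$pre_target) & cohort$pre_target != expected_pre
  if (any(bad)) {
    probs$pre_target_mismatch <- cohort$patient_id[bad]
  }
  bad2 <- !is.na(cohort$pre_target) & cohort$pre_target == "yes" &
    cohort$braf != "mutated"
  if (any(bad2)) probs$pre_target_without_braf_mutation <- cohort$patient_id[bad2]
  osm <- cohort$os_months
  bad3 <- !is.na(osm) & osm < 0
  if (any(bad3)) probs$negative_os_months <- cohort$patient_id[bad3]
  ev <- cohort$os_event
  bad4 <- !is.na(ev) & !(ev %in% c(0, 1))
  if (any(bad4)) probs$os_event_not_binary <- cohort$patient_id[bad4]
  if (report) {
    return(data.frame(
      rule = rep(names(probs), lengths(probs)),
      patient_id = unlist(probs, use.names = FALSE),
      stringsAsFactors = FALSE))
  }
  if (length(probs)) {
    msg <- paste(sprintf("%s: %d record(s) (e.g. %s)", names(probs),
                         lengths(probs), vapply(probs, `[`, "", 1)),
                 collapse = "; ")
    stop("cohort validation failed - ", msg)
  }
  invisible(TRUE)
}

#' Restrict a cohort to complete cases for a set of variables
#'
#' The scoring algorithm requires every scoring variable to be observed; this
#' drops records with an unknown/untested value in any required variable and
#' records how many were removed per variable (attribute `removed_counts`).
#'
#' @param cohort a `cohort_table`.
#' @param required_variables columns that must be observed; defaults to the
#'   seven CLICAL variables.
#' @return filtered `cohort_table` (order preserved) with attributes
#'   `removed_counts` (per-variable missing counts among removed records) and
#'   `n_removed`.
#' @export
complete_case_filter <- function(cohort, required_variables = clical_variables()) {
  stopifnot(all(required_variables %in% names(cohort)))
  miss <- sapply(required_variables, function(v) {
    tok <- .missing_tokens[v]
    if (is.na(tok)) tok <- "unknown"
    is.na(cohort[[v]]) | cohort[[v]] == tok
  })
  miss <- matrix(miss, nrow = nrow(cohort),
                 dimnames = list(NULL, required_variables))
  keep <- rowSums(miss) == 0
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(cohort)
  attr(out, "provenance") <- attr(cohort, "provenance")
  attr(out, "removed_counts") <- colSums(miss[!keep, , drop = FALSE])
  attr(out, "n_removed") <- sum(!keep)
  if (nrow(out) == 0 && nrow(cohort) > 0) {
    warning("complete_case_filter(): no complete cases remain")
  }
  message(sprintf("complete_case_filter: kept %d of %d records", nrow(out),
                  nrow(cohort)))
  out
}

#' Read a cohort CSV
#'
#' Reads the canonical cohort CSV schema.  Category tokens are
#' case-insensitive with spaces/hyphens normalized to underscores.  When raw
#' inputs are present (age_years, ldh_ratio, neutrophils/lymphocytes) the
#' derived category columns are recomputed; a disagreement with a supplied
#' category column is a warning, and absent category columns are filled in.
#'
#' @param path CSV file path.
#' @param age_cutoff years, for age-group derivation.
#' @param provenance provenance label; defaults to the file name.
#' @return a `cohort_table`.
#' @export
read_cohort <- function(path, age_cutoff = 65, provenance = basename(path)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df)) {
    stop("read_cohort(): missing mandatory column 'patient_id'")
  }
  for (col in c("os_months", "os_event")) {
    if (!col %in% names(df)) {
      stop(sprintf("read_cohort(): missing mandatory column '%s'", col))
    }
  }
  derive <- function(col, have_raw, value) {
    if (!all(have_raw)) return()
    recomputed <- value()
    if (col %in% names(df)) {
      old <- normalize_tokens(df[[col]], col)
      known <- !(old %in% c("unknown", "untested")) & !is.na(recomputed)
      if (any(known & old != recomputed)) {
        warning(sprintf("read_cohort(): %d %s value(s) disagree with raw inputs; recomputed",
                        sum(known & old != recomputed), col))
      }
    }
    df[[col]] <<- recomputed
  }
  if ("age_years" %in% names(df)) {
    derive("age_group", is.finite(df$age_years),
           function() derive_age_group(df$age_years, age_cutoff))
  }
  if ("ldh_ratio" %in% names(df)) {
    ok <- is.finite(df$ldh_ratio) & df$ldh_ratio > 0
    if (any(ok)) {
      rec <- rep(NA_character_, nrow(df))
      rec[ok] <- categorize_ldh_ratio(df$ldh_ratio[ok])
      if ("ldh_category" %in% names(df)) {
        old <- normalize_tokens(df$ldh_category, "ldh_category")
        known <- ok & old != "unknown"
        if (any(known & old != rec)) {
          warning(sprintf("read_cohort(): %d ldh_category value(s) disagree with ldh_ratio; recomputed",
                          sum(known & old != rec)))
        }
        rec[!ok] <- old[!ok]
      } else rec[!ok] <- "unknown"
      df$ldh_category <- rec
    }
  }
  if (all(c("neutrophils", "lymphocytes") %in% names(df))) {
    ok <- is.finite(df$neutrophils) & is.finite(df$lymphocytes) &
      df$neutrophils > 0 & df$lymphocytes > 0
    if (any(ok)) {
      nl <- categorize_nlr(df$neutrophils[ok], df$lymphocytes[ok])
      val <- rep(NA_real_, nrow(df)); cat_ <- rep(NA_character_, nrow(df))
      val[ok] <- nl$nlr_value; cat_[ok] <- nl$nlr_category
      if ("nlr_category" %in% names(df)) {
        old <- normalize_tokens(df$nlr_category, "nlr_category")
        known <- ok & old != "unknown"
        if (any(known & old != cat_)) {
          warning(sprintf("read_cohort(): %d nlr_category value(s) disagree with counts; recomputed",
                          sum(known & old != cat_)))
        }
        cat_[!ok] <- old[!ok]
      } else cat_[!ok] <- "unknown"
      df$nlr_value <- ifelse(ok, val, df$nlr_value %||% NA_real_)
      df$nlr_category <- cat_
    }
  }
  if ("prior_treatment" %in% names(df)) {
    pt <- normalize_tokens(df$prior_treatment, "prior_treatment")
    df$pre_target <- ifelse(pt %in% c("target", "target_and_immunotherapy"),
                            "yes", "no")
  }
  cohort_table(df, provenance = provenance)
}

#' Write a cohort CSV
#'
#' Writes the canonical column set; numeric columns are rendered to 6
#' significant digits so that write -> read round-trips exactly.
#'
#' @param cohort a `cohort_table`.
#' @param path output CSV path.
#' @return invisibly `path`.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)[, .cohort_columns, drop = FALSE]
  for (col in c("age_years", "ldh_ratio", "neutrophils", "lymphocytes",
                "nlr_value", "os_months")) {
    out[[col]] <- signif(out[[col]], 6)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
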
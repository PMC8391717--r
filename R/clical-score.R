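# CLICAL: each of seven baseline variables contributes an integer weight
# (1 = unfavorable, 2 = favorable, 3 = favorable level of the trichotomous
# LDH); the score is the weight sum divided by 7.  All arithmetic is exact on
# the integer weight sum; the rational score is rendered to 3 decimals only
# at I/O so 11/7 prints as 1.571.

#' Default CLICAL weight scheme
#'
#' Seven variables, weight 1 always marking the unfavorable category:
#' age (younger 1 / older 2), BRAF (mutated 1 / wildtype 2), prior targeted
#' therapy (yes 1 / no 2), LDH (very high 1 / high 2 / normal 3), NLR
#' (abnormal 1 / normal 2), eosinophils (elevated 1 / normal 2) and CNS
#' metastases (yes 1 / no 2).  CNS metastases is the seventh variable: the
#' published score levels are multiples of 1/7 with maximum 15/7, which forces
#' seven variables, exactly one of them trichotomous; CNS involvement is the
#' remaining baseline clinical variable and is also a forest feature.  The age
#' direction (younger = unfavorable) follows the published weight list and is
#' configurable here.
#'
#' @return object of class `weight_scheme`: a named list mapping each
#'   variable to a named integer vector of category weights.
#' @export
default_weight_scheme <- function() {
  ws <- list(
    age_group           = c(younger = 1L, older = 2L),
    braf                = c(mutated = 1L, wildtype = 2L),
    pre_target          = c(yes = 1L, no = 2L),
    ldh_category        = c(very_high = 1L, high = 2L, normal = 3L),
    nlr_category        = c(abnormal = 1L, normal = 2L),
    eosinophil_category = c(elevated = 1L, normal = 2L),
    cns_met             = c(yes = 1L, no = 2L)
  )
  class(ws) <- "weight_scheme"
  ws
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat(sprintf("<weight_scheme: %d variables>\n", length(x)))
  for (v in names(x)) {
    cat(sprintf("  %-20s %s\n", v,
                paste(sprintf("%s=%d", names(x[[v]]), x[[v]]), collapse = " ")))
  }
  invisible(x)
}

validate_weight_scheme <- function(scheme) {
  stopifnot(is.list(scheme), length(scheme) >= 1)
  for (v in names(scheme)) {
    w <- scheme[[v]]
    if (!all(w %in% 1:3)) stop("weights must be integers in {1,2,3}")
    if (is.null(names(w)) || anyDuplicated(names(w))) {
      stop("each variable needs uniquely named category weights")
    }
  }
  invisible(TRUE)
}

#' Serialize / deserialize a weight scheme
#'
#' @param scheme a `weight_scheme`.
#' @param path JSON file path.
#' @return `write_weight_scheme` returns `path` invisibly;
#'   `read_weight_scheme` returns a `weight_scheme`.
#' @export
write_weight_scheme <- function(scheme, path) {
  jsonlite::write_json(lapply(scheme, as.list), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_weight_scheme
#' @export
read_weight_scheme <- function(path) {
  raw <- jsonlite::read_json(path)
  ws <- lapply(raw, function(v) {
    w <- as.integer(unlist(v))
    names(w) <- names(v)
    w
  })
  class(ws) <- "weight_scheme"
  validate_weight_scheme(ws)
  ws
}

#' Default score-level to signature map
#'
#' Adjacent score levels with similar survival are merged into five ordered
#' signatures (I worst ... V best).  On the weight-sum scale (denominator 7):
#' sums 7-9 -> I, 10 -> II, 11 -> III, 12-13 -> IV, 14-15 -> V.  The minimum
#' sum 7 (score 1.000, all seven unfavorable) was not observed in the source
#' cohort and is assigned to Signature I, which it is dominated by.
#'
#' @return object of class `signature_map`: integer vector indexed by weight
#'   sum giving the signature number 1..5.
#' @export
default_signature_map <- function() {
  m <- c(`7` = 1L, `8` = 1L, `9` = 1L, `10` = 2L, `11` = 3L, `12` = 4L,
         `13` = 4L, `14` = 5L, `15` = 5L)
  class(m) <- "signature_map"
  m
}

signature_labels <- c("I", "II", "III", "IV", "V")

#' Map a CLICAL score to its signature
#'
#' @param score numeric score(s), multiples of 1/7 in [1, 15/7] (a rounded
#'   3-decimal rendering is accepted), or integer weight sums in 7..15.
#' @param map a `signature_map`.
#' @return character vector of signature labels "I".."V".
#' @export
assign_signature <- function(score, map = default_signature_map()) {
  if (all(score >= 7 & score == round(score))) {
    ws <- as.integer(score)
    if (any(ws < 7 | ws > 15)) {
      stop("assign_signature(): score outside the achievable range [1, 15/7]")
    }
  } else {
    ws <- as.integer(round(score * 7))
    if (any(ws < 7 | ws > 15)) {
      stop("assign_signature(): score outside the achievable range [1, 15/7]")
    }
    if (any(abs(score - ws / 7) > 5e-4)) {
      stop("assign_signature(): score is not a multiple of 1/7")
    }
  }
  signature_labels[unname(map[as.character(ws)])]
}

#' Compute the CLICAL score of one patient record
#'
#' @param record one-row data.frame (or list) with the scheme's variables.
#' @param scheme a `weight_scheme`.
#' @param map a `signature_map`.
#' @return list of class `clical_result` with `weight_sum`, `score`
#'   (weight_sum / n_variables, exact), `score_label` (3-decimal rendering)
#'   and `signature`.
#' @export
compute_score <- function(record, scheme = default_weight_scheme(),
                          map = default_signature_map()) {
  validate_weight_scheme(scheme)
  n <- length(scheme)
  total <- 0L
  for (v in names(scheme)) {
    val <- as.character(record[[v]])
    if (length(val) != 1 || is.na(val) || !(val %in% names(scheme[[v]]))) {
      stop(sprintf("incomplete record: variable '%s' has unscorable value '%s'",
                   v, if (length(val)) val else "<absent>"))
    }
    total <- total + scheme[[v]][[val]]
  }
  res <- list(weight_sum = total, score = total / n,
              score_label = format_score(total / n),
              signature = assign_signature(total, map))
  class(res) <- "clical_result"
  res
}

format_score <- function(score) sprintf("%.3f", round(score, 3))

#' @export
print.clical_result <- function(x, ...) {
  cat(sprintf("CLICAL score %s (weight sum %d) -> Signature %s\n",
              x$score_label, x$weight_sum, x$signature))
  invisible(x)
}

#' Score a whole cohort
#'
#' Applies the weight scheme to every record of a complete-case cohort and
#' tabulates the distinct score levels and signature totals in the layout of
#' the published score table.
#'
#' @param cohort a `cohort_table`, already passed through
#'   [complete_case_filter()] (incomplete records raise an error naming the
#'   offending patient).
#' @param scheme a `weight_scheme`.
#' @param map a `signature_map`.
#' @return list of class `clical_scores`: `scores` (per-patient data.frame
#'   with patient_id, weight_sum, score, signature) and `summary` (per score
#'   level: n, signature, signature_n, signature_pct).
#' @export
score_cohort <- function(cohort, scheme = default_weight_scheme(),
                         map = default_signature_map()) {
  validate_weight_scheme(scheme)
  n_var <- length(scheme)
  n <- nrow(cohort)
  ws <- rep(0L, n)
  for (v in names(scheme)) {
    w <- scheme[[v]][as.character(cohort[[v]])]
    if (n > 0 && anyNA(w)) {
      bad <- which(is.na(w))[1]
      stop(sprintf("incomplete record '%s': variable '%s' has unscorable value '%s'; run complete_case_filter() first",
                   cohort$patient_id[bad], v, cohort[[v]][bad]))
    }
    ws <- ws + as.integer(w)
  }
  scores <- data.frame(patient_id = cohort$patient_id, weight_sum = ws,
                       score = ws / n_var,
                       score_label = format_score(ws / n_var),
                       signature = if (n) assign_signature(ws, map) else character(0),
                       stringsAsFactors = FALSE)
  out <- list(scores = scores, summary = summarize_score_levels(scores))
  class(out) <- "clical_scores"
  out
}

summarize_score_levels <- function(scores) {
  if (nrow(scores) == 0) {
    return(data.frame(score_label = character(0), n = integer(0),
                      signature = character(0), signature_n = integer(0),
                      signature_pct = numeric(0), stringsAsFactors = FALSE))
  }
  lev <- sort(unique(scores$weight_sum))
  n_at <- vapply(lev, function(l) sum(scores$weight_sum == l), 0L)
  sig <- assign_signature(lev)
  sig_tot <- vapply(sig, function(s) sum(scores$signature == s), 0L)
  data.frame(score_label = format_score(lev / 7), n = n_at, signature = sig,
             signature_n = unname(sig_tot),
             signature_pct = round(100 * unname(sig_tot) / nrow(scores), 1),
             stringsAsFactors = FALSE)
}

#' @export
print.clical_scores <- function(x, ...) {
  cat(sprintf("<clical_scores: %d patients, %d score levels>\n",
              nrow(x$scores), nrow(x$summary)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Enumerate all achievable CLICAL profiles
#'
#' Expands every combination of scorable categories under a weight scheme
#' (192 profiles for the default 2^6 x 3 scheme) with their weight sums,
#' scores and signatures.  Used for exhaustive property checks.
#'
#' @param scheme a `weight_scheme`.
#' @param map a `signature_map`.
#' @return data.frame with one row per profile.
#' @export
enumerate_profiles <- function(scheme = default_weight_scheme(),
                               map = default_signature_map()) {
  grid <- expand.grid(lapply(scheme, names), stringsAsFactors = FALSE)
  ws <- rep(0L, nrow(grid))
  for (v in names(scheme)) ws <- ws + as.integer(scheme[[v]][grid[[v]]])
  grid$weight_sum <- ws
  grid$score <- ws / length(scheme)
  grid$signature <- assign_signature(ws, map)
  grid
}
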
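# Segmentation and diagnostic evaluation: Jaccard overlap of binary masks,
# sensitivity/specificity/accuracy from 2x2 confusion counts, and McNemar's
# paired chi-square test for comparing two modalities on the same cases.

#' Jaccard index of two binary masks
#'
#' Intersection over union of the foreground pixel sets:
#' `|X1 n X2| / |X1 u X2|`. When both masks are empty the index is defined
#' as 1 (perfect agreement on absence).
#'
#' @param predicted,reference 0/1 matrices of identical shape.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2, 2)
#' jaccard_index(a, a)
jaccard_index <- function(predicted, reference) {
  check_binary_mask(predicted, "predicted")
  check_binary_mask(reference, "reference")
  if (!identical(dim(predicted), dim(reference))) {
    abort_contract("`predicted` and `reference` must share the same shape")
  }
  inter <- sum(predicted == 1 & reference == 1)
  union <- sum(predicted == 1 | reference == 1)
  if (union == 0) 1 else inter / union
}

#' 2x2 diagnostic confusion table
#'
#' @param tp,fp,fn,tn Nonnegative case counts of true/false positives and
#'   negatives against the gold standard.
#' @return An object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    abort_param("confusion counts must be nonnegative integers")
  }
  if (sum(counts) == 0) abort_param("confusion table must contain at least one case")
  structure(as.list(counts), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table: tp=%d fp=%d fn=%d tn=%d>\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Sensitivity, specificity and accuracy
#'
#' Computes sensitivity `tp / (tp + fn)`, specificity `tn / (tn + fp)` and
#' accuracy `(tp + tn) / total`. A metric whose denominator is zero is
#' reported as `NA` and named in the `undefined` field rather than silently
#' set to 0 (for example, specificity in a cohort with no gold-negative
#' cases).
#'
#' @param table A [confusion_table()].
#' @return An object of class `metric_report`: list with `sensitivity`,
#'   `specificity`, `accuracy` (proportions in `[0, 1]` or `NA`) and
#'   `undefined` (character vector of metrics with zero denominators).
#' @export
#' @examples
#' diagnostic_metrics(confusion_table(tp = 81, fp = 0, fn = 8, tn = 0))
diagnostic_metrics <- function(table) {
  if (!inherits(table, "confusion_table")) {
    abort_contract("`table` must be a confusion_table()")
  }
  safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_ratio(table$tp, table$tp + table$fn)
  spec <- safe_ratio(table$tn, table$tn + table$fp)
  total <- table$tp + table$fp + table$fn + table$tn
  acc <- safe_ratio(table$tp + table$tn, total)
  undefined <- c("sensitivity", "specificity", "accuracy")[
    c(is.na(sens), is.na(spec), is.na(acc))
  ]
  structure(list(sensitivity = sens, specificity = spec, accuracy = acc,
                 undefined = undefined),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat(sprintf("<metric_report: sens %s, spec %s, acc %s>\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$accuracy)))
  invisible(x)
}

#' @export
tidy.metric_report <- function(x, ...) {
  tibble(metric = c("sensitivity", "specificity", "accuracy"),
         estimate = c(x$sensitivity, x$specificity, x$accuracy),
         undefined = metric %in% x$undefined)
}

#' Paired per-case calls for two modalities
#'
#' Tabulates per-case correctness of two modalities into the concordance /
#' discordance counts of the paired 2x2 table: `a` (both correct), `b` (A
#' correct, B wrong), `c` (A wrong, B correct), `d` (both wrong).
#'
#' @param correct_a,correct_b Logical vectors of per-case correctness, one
#'   entry per case.
#' @return An object of class `paired_calls` with fields `a`, `b`, `c`, `d`
#'   and `n`.
#' @export
paired_calls <- function(correct_a, correct_b) {
  if (length(correct_a) != length(correct_b) || length(correct_a) == 0L) {
    abort_contract("`correct_a` and `correct_b` must be equal-length, nonempty")
  }
  correct_a <- as.logical(correct_a)
  correct_b <- as.logical(correct_b)
  if (anyNA(correct_a) || anyNA(correct_b)) {
    abort_contract("paired calls must not contain NA")
  }
  structure(list(a = sum(correct_a & correct_b),
                 b = sum(correct_a & !correct_b),
                 c = sum(!correct_a & correct_b),
                 d = sum(!correct_a & !correct_b),
                 n = length(correct_a)),
            class = "paired_calls")
}

#' McNemar's paired chi-square test
#'
#' Tests whether two modalities applied to the same cases differ, using only
#' the discordant-pair counts `b` and `c`. With the continuity correction the
#' statistic is `(max(|b - c| - 1, 0))^2 / (b + c)`; without it,
#' `(b - c)^2 / (b + c)`. The p-value comes from the chi-square distribution
#' with one degree of freedom. When there are no discordant pairs the
#' statistic is 0 and the p-value 1.
#'
#' @param calls A [paired_calls()] object, or a list with fields `b` and `c`.
#' @param continuity_correction Apply the continuity correction
#'   (default `TRUE`).
#' @param alpha Significance level (default 0.05).
#' @return List with `statistic`, `p_value`, `b`, `c`, `significant`
#'   (`p_value < alpha`), `continuity_correction` and `alpha`.
#' @export
#' @examples
#' paired_chi_square(list(b = 5, c = 1))$statistic            # 1.5
#' paired_chi_square(list(b = 5, c = 1), FALSE)$statistic     # 16/6
paired_chi_square <- function(calls, continuity_correction = TRUE,
                              alpha = 0.05) {
  b <- calls$b
  c_ <- calls$c
  if (!is_scalar_number(b) || !is_scalar_number(c_) || b < 0 || c_ < 0 ||
      b != floor(b) || c_ != floor(c_)) {
    abort_param("discordance counts `b` and `c` must be nonnegative integers")
  }
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    abort_param("`alpha` must lie in (0, 1)")
  }
  if (b + c_ == 0) {
    stat <- 0
    p <- 1
  } else {
    num <- if (continuity_correction) max(abs(b - c_) - 1, 0) else b - c_
    stat <- num^2 / (b + c_)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(statistic = stat, p_value = p, b = b, c = c_,
       significant = p < alpha,
       continuity_correction = continuity_correction, alpha = alpha)
}

confusion_from_calls <- function(gold, call) {
  confusion_table(tp = sum(gold & call), fp = sum(!gold & call),
                  fn = sum(gold & !call), tn = sum(!gold & !call))
}

#' Cohort-level diagnostic comparison of two modalities
#'
#' For a cohort of cases with gold-standard labels and per-case positive
#' calls by two modalities, computes per-modality confusion tables and
#' metrics, overall and stratified by grade, plus McNemar's paired test per
#' stratum.
#'
#' @param calls Data frame with columns `case_id`, `gold` (logical),
#'   `call_a`, `call_b` (logical positive calls) and `grade`, as produced by
#'   [simulate_reader_calls()].
#' @param alpha Significance level for the paired tests (default 0.05).
#' @param continuity_correction Passed to [paired_chi_square()].
#' @return An object of class `cohort_report`: list with `metrics` (tibble:
#'   stratum, modality, n, tp/fp/fn/tn, sensitivity, specificity, accuracy)
#'   and `tests` (tibble: stratum, b, c, statistic, p_value, significant).
#' @export
cohort_report <- function(calls, alpha = 0.05, continuity_correction = TRUE) {
  required <- c("case_id", "gold", "call_a", "call_b", "grade")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols) > 0L) {
    abort_contract(sprintf("`calls` is missing column(s): %s",
                           paste(missing_cols, collapse = ", ")))
  }
  bad <- calls$case_id[is.na(calls$gold) | is.na(calls$call_a) |
                         is.na(calls$call_b) | is.na(calls$grade)]
  if (length(bad) > 0L) {
    abort_contract(sprintf("missing labels for case(s): %s",
                           paste(bad, collapse = ", ")))
  }
  strata <- c("overall", sort(unique(calls$grade)))
  subset_for <- function(stratum) {
    if (stratum == "overall") calls else calls[calls$grade == stratum, ]
  }
  metrics <- purrr::map_dfr(strata, function(stratum) {
    d <- subset_for(stratum)
    purrr::map_dfr(c(a = "call_a", b = "call_b"), function(col) {
      ct <- confusion_from_calls(d$gold, d[[col]])
      mr <- diagnostic_metrics(ct)
      tibble(n = nrow(d), tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn,
             sensitivity = mr$sensitivity, specificity = mr$specificity,
             accuracy = mr$accuracy)
    }, .id = "modality") |>
      dplyr::mutate(stratum = stratum, .before = 1)
  })
  tests <- purrr::map_dfr(strata, function(stratum) {
    d <- subset_for(stratum)
    pc <- paired_calls(d$call_a == d$gold, d$call_b == d$gold)
    ts <- paired_chi_square(pc, continuity_correction, alpha)
    tibble(stratum = stratum, n = pc$n, b = ts$b, c = ts$c,
           statistic = ts$statistic, p_value = ts$p_value,
           significant = ts$significant)
  })
  structure(list(metrics = metrics, tests = tests, alpha = alpha),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\nMetrics:\n")
  print(x$metrics)
  cat("Paired tests:\n")
  print(x$tests)
  invisible(x)
}

#' Serialize a cohort report to JSON
#'
#' @param report A `cohort_report`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cohort_report <- function(report, path) {
  jsonlite::write_json(
    list(alpha = report$alpha,
         metrics = report$metrics, tests = report$tests),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
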
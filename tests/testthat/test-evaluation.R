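test_that("Jaccard index covers the standard cases", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(jaccard_index(a, a), 1)
  b <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(jaccard_index(a, b), 0)
  # |X1| = 6, |X2| = 4, overlap 2 -> 2 / 8
  x1 <- matrix(0, 4, 4); x1[1:3, 1:2] <- 1
  x2 <- matrix(0, 4, 4); x2[3:4, 1:2] <- 1
  expect_equal(sum(x1), 6); expect_equal(sum(x2), 4)
  expect_equal(jaccard_index(x1, x2), 0.25)
  expect_equal(jaccard_index(x2, x1), 0.25)
  empty <- matrix(0, 4, 4)
  expect_equal(jaccard_index(empty, empty), 1)
  expect_error(jaccard_index(a, matrix(0, 3, 3)),
               class = "ipsoseg_error_contract")
})

test_that("adding disjoint pixels to one mask never raises the Jaccard", {
  base <- matrix(0, 6, 6); base[2:4, 2:4] <- 1
  grown <- base
  j_prev <- jaccard_index(grown, base)
  for (px in list(c(1, 6), c(6, 1), c(6, 6), c(1, 1))) {
    grown[px[1], px[2]] <- 1
    j_now <- jaccard_index(grown, base)
    expect_lte(j_now, j_prev)
    j_prev <- j_now
  }
})

test_that("diagnostic metrics compute ratios and flag undefined ones", {
  # all-positive cohort: 81 of 89 confirmed, no negatives at all
  m <- diagnostic_metrics(confusion_table(tp = 81, fp = 0, fn = 8, tn = 0))
  expect_equal(m$sensitivity, 81 / 89, tolerance = 1e-12)
  expect_true(is.na(m$specificity))
  expect_identical(m$undefined, "specificity")
  sym <- diagnostic_metrics(confusion_table(tp = 5, fp = 5, fn = 5, tn = 5))
  expect_equal(sym$sensitivity, 0.5)
  expect_equal(sym$specificity, 0.5)
  perfect <- diagnostic_metrics(confusion_table(tp = 10, fp = 0, fn = 0, tn = 7))
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$accuracy),
               c(1, 1, 1))
  td <- tidy(m)
  expect_equal(td$undefined, c(FALSE, TRUE, FALSE))
})

test_that("McNemar statistic matches hand arithmetic and clamps", {
  expect_equal(paired_chi_square(list(b = 5, c = 1))$statistic, 1.5)
  expect_equal(paired_chi_square(list(b = 5, c = 1), FALSE)$statistic, 16 / 6,
               tolerance = 1e-12)
  bal <- paired_chi_square(list(b = 3, c = 3))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p_value, 1)
  none <- paired_chi_square(list(b = 0, c = 0))
  expect_equal(none$statistic, 0)
  expect_equal(none$p_value, 1)
  expect_false(none$significant)
})

test_that("McNemar agrees with stats::mcnemar.test", {
  for (bc in list(c(5, 1), c(12, 4), c(20, 20), c(2, 9))) {
    tab <- matrix(c(10, bc[1], bc[2], 10), 2, 2)
    for (correct in c(TRUE, FALSE)) {
      if (correct && abs(bc[1] - bc[2]) < 1) next  # base R does not clamp
      ref <- stats::mcnemar.test(tab, correct = correct)
      mine <- paired_chi_square(list(b = bc[1], c = bc[2]), correct)
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
    }
  }
})

test_that("McNemar with correction is conservative under the null", {
  rejections <- vapply(1:2000, function(r) {
    withr::with_seed(10000 + r, {
      discordant <- stats::rbinom(1, 100, 0.2)
      b <- stats::rbinom(1, discordant, 0.5)
      paired_chi_square(list(b = b, c = discordant - b))$significant
    })
  }, logical(1))
  rate <- mean(rejections)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.07)
})

test_that("cohort report covers the trivial and stratified cases", {
  calls <- tibble::tibble(
    case_id = sprintf("c%02d", 1:12),
    gold = rep(TRUE, 12),
    call_a = rep(TRUE, 12),
    call_b = rep(TRUE, 12),
    grade = rep(c("adhesive", "implantable", "penetrated"), each = 4)
  )
  rep_ <- cohort_report(calls)
  expect_equal(nrow(rep_$tests), 4)  # overall + 3 grades
  expect_true(all(rep_$metrics$sensitivity == 1))
  expect_true(all(rep_$tests$statistic == 0))
  expect_setequal(unique(rep_$metrics$stratum),
                  c("overall", "adhesive", "implantable", "penetrated"))
  expect_error(cohort_report(calls[, -2]), class = "ipsoseg_error_contract")
  bad <- calls; bad$call_a[3] <- NA
  expect_error(cohort_report(bad), class = "ipsoseg_error_contract")
})

test_that("cohort metrics recover generating sensitivities from simulation", {
  calls <- simulate_reader_calls(2000, 0.90, 0.85, 0.85, 0.80,
                                 correlation = 0.3, seed = 12)
  rep_ <- cohort_report(calls)
  overall <- rep_$metrics[rep_$metrics$stratum == "overall", ]
  expect_lte(abs(overall$sensitivity[overall$modality == "a"] - 0.90), 0.03)
  expect_lte(abs(overall$sensitivity[overall$modality == "b"] - 0.85), 0.03)
  # all-positive cohort: specificity has no denominator
  expect_true(all(is.na(overall$specificity)))
})
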
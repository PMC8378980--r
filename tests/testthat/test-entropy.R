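test_that("histogram counts pixels and conserves mass", {
  img <- matrix(0, 3, 3)
  h <- compute_histogram(img)
  expect_equal(h$counts[1], 9)
  expect_equal(sum(h$counts), 9)
  img2 <- matrix(c(0, 0, 255, 255), 2, 2)
  h2 <- compute_histogram(img2)
  expect_equal(h2$counts[c(1, 256)], c(2, 2))
  expect_equal(sum(h2$counts), length(img2))
  expect_error(compute_histogram(matrix(300, 2, 2)),
               class = "ipsoseg_error_domain")
  expect_error(compute_histogram(matrix(1.5, 2, 2)),
               class = "ipsoseg_error_domain")
})

test_that("Kapur objective matches closed forms and conventions", {
  uni <- gray_histogram(rep(1, 256))
  expect_equal(kapur_objective(uni, 127), 2 * log(128), tolerance = 1e-12)
  # all mass on one level: any split leaves an empty class
  spike <- gray_histogram(c(rep(0, 50), 9, rep(0, 205)))
  expect_identical(kapur_objective(spike, 100), -Inf)
  # two point-mass classes have zero entropy each
  two <- rep(0, 256); two[51] <- 5; two[201] <- 5
  expect_equal(kapur_objective(gray_histogram(two), 100), 0)
  expect_error(kapur_objective(uni, c(10, 10)),
               class = "ipsoseg_error_contract")
  expect_error(kapur_objective(uni, 255), class = "ipsoseg_error_contract")
})

test_that("Kapur objective agrees with an independent direct evaluation", {
  for (seed in 1:20) {
    h <- random_histogram(seed)
    t1 <- withr::with_seed(seed, sort(sample(0:254, 1 + seed %% 3)))
    expect_equal(kapur_objective(h, t1), kapur_direct(h$counts, t1),
                 tolerance = 1e-10)
  }
})

test_that("Kapur objective is invariant to uniform count scaling", {
  h <- random_histogram(7)
  h3 <- gray_histogram(h$counts * 3)
  for (t in c(10, 127, 200)) {
    expect_equal(kapur_objective(h, t), kapur_objective(h3, t),
                 tolerance = 1e-12)
  }
})

test_that("exhaustive search maximizes and breaks ties lexicographically", {
  uni <- gray_histogram(rep(1, 256))
  ex <- exhaustive_threshold_search(uni, 1)
  expect_identical(ex$thresholds, 127L)
  expect_equal(ex$score, 2 * log(128), tolerance = 1e-12)
  # 4-bin uniform: t = 1 splits 2/2, score 2 ln 2
  four <- exhaustive_threshold_search(gray_histogram(c(1, 1, 1, 1)), 1)
  expect_identical(four$thresholds, 1L)
  expect_equal(four$score, 2 * log(2), tolerance = 1e-12)
  # mass only at 50 and 200: every t in [50, 199] ties; smallest wins
  two <- rep(0, 256); two[51] <- 4; two[201] <- 6
  tie <- exhaustive_threshold_search(gray_histogram(two), 1)
  expect_identical(tie$thresholds, 50L)
  expect_error(exhaustive_threshold_search(uni, 5),
               class = "ipsoseg_error_capacity")
})

test_that("exhaustive search equals direct enumeration on small histograms", {
  for (seed in c(3, 14, 27)) {
    counts <- withr::with_seed(seed, sample(0:9, 16, replace = TRUE))
    counts[1] <- counts[1] + 1  # guarantee nonzero mass
    scores <- vapply(0:14, function(t) kapur_direct(counts, t), numeric(1))
    ex <- exhaustive_threshold_search(gray_histogram(counts), 1)
    expect_equal(ex$score, max(scores), tolerance = 1e-12)
    expect_identical(ex$thresholds, as.integer(which.max(scores) - 1L))
  }
})

test_that("exhaustive multilevel search agrees with direct enumeration", {
  counts <- withr::with_seed(5, sample(0:9, 12, replace = TRUE))
  counts[c(1, 12)] <- counts[c(1, 12)] + 1
  h <- gray_histogram(counts)
  cand <- utils::combn(0:10, 2)
  scores <- apply(cand, 2, function(t) kapur_direct(counts, t))
  ex <- exhaustive_threshold_search(h, 2)
  expect_equal(ex$score, max(scores), tolerance = 1e-12)
  expect_identical(ex$thresholds, as.integer(cand[, which.max(scores)]))
})

test_that("PSO threshold search is self-consistent and matches the oracle", {
  uni <- gray_histogram(rep(1, 256))
  ps <- pso_threshold_search(uni, 1, pso_config(seed = 7))
  expect_identical(ps$thresholds, 127L)
  expect_equal(ps$score, 2 * log(128), tolerance = 1e-9)
  for (seed in c(2, 13, 31)) {
    h <- random_histogram(seed)
    res <- pso_threshold_search(h, 1, pso_config(seed = seed))
    expect_equal(res$score, kapur_objective(h, res$thresholds),
                 tolerance = 1e-12)
    ex <- exhaustive_threshold_search(h, 1)
    expect_equal(res$score, ex$score, tolerance = 1e-9)
  }
})

test_that("PSO threshold search returns strictly increasing in-range thresholds for k = 2", {
  for (seed in c(4, 9)) {
    h <- random_histogram(seed + 100)
    res <- pso_threshold_search(h, 2, pso_config(seed = seed))
    expect_length(res$thresholds, 2)
    expect_true(all(diff(res$thresholds) > 0))
    expect_true(all(res$thresholds >= 0 & res$thresholds <= 254))
    expect_equal(res$score, kapur_objective(h, res$thresholds),
                 tolerance = 1e-12)
  }
})
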
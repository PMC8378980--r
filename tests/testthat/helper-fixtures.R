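# Fixtures are generated in code; nothing is read from disk.

# Random 256-bin histogram with counts uniform on {0, ..., 100}.
random_histogram <- function(seed) {
  counts <- withr::with_seed(seed, sample(0:100, 256, replace = TRUE))
  gray_histogram(counts)
}

# Independent direct evaluation of the Kapur entropy sum: normalizes each
# class explicitly and sums -q log q, with no shared code with the package's
# cumulant-based implementation.
kapur_direct <- function(counts, thresholds) {
  n_bins <- length(counts)
  edges <- c(0, thresholds + 1, n_bins)
  total <- sum(counts)
  score <- 0
  for (j in seq_len(length(edges) - 1)) {
    cls <- counts[(edges[j] + 1):edges[j + 1]]
    omega <- sum(cls) / total
    if (omega == 0) return(-Inf)
    q <- (cls / total) / omega
    q <- q[q > 0]
    score <- score - sum(q * log(q))
  }
  score
}

# Two-tissue image: dark background with a bright centered square of about
# the same total area, both with Gaussian intensity noise, clipped to the
# 8-bit range.
two_gaussian_image <- function(seed, size = 96L, target_half = 34L,
                               bg_mean = 60, fg_mean = 180, sigma = 10) {
  withr::with_seed(seed, {
    img <- matrix(rnorm(size * size, bg_mean, sigma), size, size)
    lo <- size %/% 2 - target_half + 1L
    hi <- size %/% 2 + target_half
    truth <- matrix(0, size, size)
    truth[lo:hi, lo:hi] <- 1
    img[truth == 1] <- rnorm(sum(truth), fg_mean, sigma)
    img <- matrix(pmin(pmax(round_half_away(img), 0), 255), size, size)
    list(image = img, truth = truth)
  })
}

quadratic_objective <- function(x) -(x - 128)^2
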
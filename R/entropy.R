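# Kapur maximum-entropy thresholding over gray-level histograms: the
# objective, an exhaustive-search oracle, and the PSO-driven search.

#' Gray-level histogram of an image
#'
#' @param image Numeric matrix with integer values in `[0, n_bins - 1]`.
#' @param n_bins Number of gray levels (default 256 for 8-bit images).
#' @return An object of class `gray_histogram`: list with `counts` (length
#'   `n_bins`), `n_bins` and `total`.
#' @export
#' @examples
#' img <- matrix(c(0, 0, 255, 255), 2, 2)
#' h <- compute_histogram(img)
#' h$counts[c(1, 256)]
compute_histogram <- function(image, n_bins = 256L) {
  if (!is.matrix(image) || length(image) < 1L) {
    abort_contract("`image` must be a nonempty matrix")
  }
  v <- as.vector(image)
  bad <- which(is.na(v) | v < 0 | v > n_bins - 1 | v != floor(v))
  if (length(bad) > 0L) {
    abort_domain(sprintf(
      "pixel value %s outside the integer range [0, %d]",
      format(v[bad[1]]), n_bins - 1L
    ))
  }
  counts <- tabulate(as.integer(v) + 1L, nbins = n_bins)
  gray_histogram(counts)
}

#' Construct a gray-level histogram from counts
#'
#' @param counts Nonnegative integer vector of per-level counts; its length
#'   sets the number of bins.
#' @return An object of class `gray_histogram`.
#' @export
gray_histogram <- function(counts) {
  if (!is.numeric(counts) || length(counts) < 2L || anyNA(counts) ||
      any(counts < 0) || any(counts != floor(counts))) {
    abort_param("`counts` must be nonnegative integers (length >= 2)")
  }
  total <- sum(counts)
  if (total <= 0) abort_param("histogram must contain at least one pixel")
  structure(list(counts = as.numeric(counts), n_bins = length(counts),
                 total = total),
            class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  cat(sprintf("<gray_histogram: %d bins, %g pixels, support %d levels>\n",
              x$n_bins, x$total, sum(x$counts > 0)))
  invisible(x)
}

#' @export
tidy.gray_histogram <- function(x, ...) {
  tibble(level = seq_len(x$n_bins) - 1L, count = x$counts)
}

#' @export
autoplot.gray_histogram <- function(object, thresholds = NULL, ...) {
  p <- ggplot(tidy(object), aes(x = .data$level, y = .data$count)) +
    geom_col(width = 1) +
    labs(x = "gray level", y = "count")
  if (!is.null(thresholds)) {
    p <- p + geom_vline(xintercept = thresholds, linetype = "dashed")
  }
  p
}

check_thresholds <- function(thresholds, n_bins) {
  if (!is.numeric(thresholds) || length(thresholds) < 1L ||
      any(thresholds != floor(thresholds)) ||
      any(thresholds < 0) || any(thresholds > n_bins - 2) ||
      is.unsorted(thresholds, strictly = TRUE)) {
    abort_contract(sprintf(
      "thresholds must be strictly increasing integers in [0, %d]", n_bins - 2L
    ))
  }
  as.integer(thresholds)
}

# Cumulative probability mass and cumulative -p log p, for O(1) class scores.
hist_cumulants <- function(hist) {
  p <- hist$counts / hist$total
  plogp <- ifelse(p > 0, p * log(p), 0)
  list(cum_p = cumsum(p), cum_h = cumsum(-plogp))
}

# Entropy sum over classes delimited by `thresholds` given precomputed
# cumulants. Class j holds levels (t_{j-1}, t_j] with t_0 = -1 and
# t_{k+1} = n_bins - 1; a class with zero mass makes the score -Inf.
kapur_from_cumulants <- function(cum, thresholds, n_bins) {
  upper <- c(thresholds + 1L, n_bins)         # 1-based inclusive upper index
  lower <- c(1L, thresholds + 2L)             # 1-based inclusive lower index
  omega <- cum$cum_p[upper] - c(0, cum$cum_p)[lower]
  if (any(omega <= 0)) return(-Inf)
  h <- cum$cum_h[upper] - c(0, cum$cum_h)[lower]
  sum(h / omega + log(omega))
}

#' Kapur's maximum-entropy objective
#'
#' Splits the gray levels into `k + 1` classes at the thresholds (a threshold
#' is the last level of its lower class) and returns the sum over classes of
#' the Shannon entropy of the within-class gray-level distribution, in nats.
#' A class with zero probability mass makes the candidate infeasible and the
#' score `-Inf`; `0 * log 0` contributes 0.
#'
#' @param hist A `gray_histogram`.
#' @param thresholds Strictly increasing integer vector in
#'   `[0, n_bins - 2]`.
#' @return The entropy sum in nats, or `-Inf` for an infeasible split.
#' @export
#' @examples
#' h <- gray_histogram(rep(1, 256))
#' kapur_objective(h, 127)  # 2 * log(128)
kapur_objective <- function(hist, thresholds) {
  thresholds <- check_thresholds(thresholds, hist$n_bins)
  kapur_from_cumulants(hist_cumulants(hist), thresholds, hist$n_bins)
}

#' Exhaustive maximum-entropy threshold search
#'
#' Enumerates every feasible set of `k` thresholds and returns the one
#' maximizing [kapur_objective()], breaking ties by the lexicographically
#' smallest threshold vector. Serves as the brute-force oracle against which
#' the PSO search is validated.
#'
#' @param hist A `gray_histogram`.
#' @param k Number of thresholds (>= 1). The number of candidate combinations
#'   `choose(n_bins - 1, k)` must not exceed 1e7.
#' @return List with `thresholds` (integer vector), `score`.
#' @export
#' @examples
#' exhaustive_threshold_search(gray_histogram(rep(1, 256)), k = 1)
exhaustive_threshold_search <- function(hist, k = 1L) {
  if (!is_scalar_number(k) || k < 1 || k != floor(k)) {
    abort_param("`k` must be a positive integer")
  }
  n_bins <- hist$n_bins
  n_candidates <- choose(n_bins - 1, k)
  if (n_candidates > 1e7) {
    abort_capacity(sprintf(
      "exhaustive search over %.3g combinations exceeds the 1e7 guard",
      n_candidates
    ))
  }
  cum <- hist_cumulants(hist)
  if (k == 1L) {
    t_all <- 0:(n_bins - 2L)
    upper <- t_all + 1L
    omega1 <- cum$cum_p[upper]
    omega2 <- cum$cum_p[n_bins] - omega1
    h1 <- cum$cum_h[upper]
    h2 <- cum$cum_h[n_bins] - h1
    scores <- ifelse(omega1 > 0 & omega2 > 0,
                     h1 / omega1 + log(pmax(omega1, .Machine$double.xmin)) +
                       h2 / omega2 + log(pmax(omega2, .Machine$double.xmin)),
                     -Inf)
    best <- which.max(scores)
    return(list(thresholds = t_all[best], score = scores[best]))
  }
  cand <- combn(0:(n_bins - 2L), k)          # columns in lexicographic order
  scores <- apply(cand, 2, function(t) kapur_from_cumulants(cum, t, n_bins))
  best <- which.max(scores)                  # first occurrence = smallest
  list(thresholds = as.integer(cand[, best]), score = scores[best])
}

#' Decode a continuous PSO position into a threshold set
#'
#' Rounds (half away from zero) each coordinate to an integer and sorts
#' ascending. Positions that collapse to duplicate thresholds are infeasible.
#'
#' @param position Numeric vector in `[0, n_bins - 2]^k`.
#' @return Integer vector of sorted thresholds, or `NULL` if duplicated.
#' @keywords internal
decode_thresholds <- function(position) {
  t <- sort(as.integer(round_half_away(position)))
  if (anyDuplicated(t)) NULL else t
}

#' Maximum-entropy threshold search via the improved PSO
#'
#' Runs [pso_optimize()] over the continuous box `[0, n_bins - 2]^k`.
#' Candidate positions are decoded by rounding to the nearest integer and
#' sorting ascending before evaluating [kapur_objective()]; decodings with
#' duplicate thresholds score `-Inf`.
#'
#' @param hist A `gray_histogram`.
#' @param k Number of thresholds (default 1).
#' @param config A [pso_config()]; its seed makes the search deterministic.
#' @param standard If `TRUE` use the fixed-factor baseline
#'   [pso_optimize_standard()] instead of the improved optimizer.
#' @return List with `thresholds`, `score` (equal to re-evaluating
#'   [kapur_objective()] at the returned thresholds) and `result`, the full
#'   `pso_result` trace.
#' @export
#' @examples
#' h <- gray_histogram(rep(1, 256))
#' pso_threshold_search(h, k = 1, config = pso_config(seed = 7))$thresholds
pso_threshold_search <- function(hist, k = 1L, config = pso_config(),
                                 standard = FALSE) {
  if (!is_scalar_number(k) || k < 1 || k != floor(k)) {
    abort_param("`k` must be a positive integer")
  }
  n_bins <- hist$n_bins
  cum <- hist_cumulants(hist)
  objective <- function(x) {
    t <- decode_thresholds(x)
    if (is.null(t)) return(-Inf)
    kapur_from_cumulants(cum, t, n_bins)
  }
  bounds <- search_bounds(rep(0, k), rep(n_bins - 2, k))
  optimizer <- if (standard) pso_optimize_standard else pso_optimize
  res <- optimizer(objective, bounds, config)
  thresholds <- decode_thresholds(res$best_position)
  if (is.null(thresholds) || !is.finite(res$best_fitness)) {
    abort_degenerate(
      "the entropy search found no feasible threshold set: every candidate left an empty gray-level class"
    )
  }
  list(thresholds = thresholds, score = res$best_fitness, result = res)
}
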
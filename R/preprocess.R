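# Preprocessing chain for 8-bit gray-scale rasters: linear contrast stretch,
# Gaussian smoothing, binarization, connected-component labeling and area
# filtering. Images are plain numeric matrices (rows = image rows, origin
# top-left) with integer values in [0, 255]; masks are 0/1 matrices.

#' Linear gray-scale stretch
#'
#' Maps the input window `[in_low, in_high]` linearly onto `[0, 255]`,
#' clipping values outside the window first:
#' `round(255 * (clip(p, in_low, in_high) - in_low) / (in_high - in_low))`
#' with half-away-from-zero rounding. If `in_low`/`in_high` are omitted they
#' are taken from the image's own intensity quantiles (`percentiles`,
#' default 1st and 99th), which enhances contrast without per-image tuning.
#'
#' @param image Numeric matrix with values in `[0, 255]`.
#' @param in_low,in_high Integer window limits, `0 <= in_low < in_high <= 255`,
#'   or `NULL` to derive them from `percentiles`.
#' @param percentiles Length-2 vector of probabilities used when the window is
#'   derived from the image.
#' @return The stretched image, same shape, integer values in `[0, 255]`.
#' @export
#' @examples
#' img <- matrix(c(10, 50, 90), 1, 3)
#' linear_stretch(img, in_low = 10, in_high = 90)
linear_stretch <- function(image, in_low = NULL, in_high = NULL,
                           percentiles = c(0.01, 0.99)) {
  check_gray_image(image)
  if (is.null(in_low) || is.null(in_high)) {
    q <- quantile(as.vector(image), probs = percentiles, names = FALSE, type = 1)
    in_low <- in_low %||% q[1]
    in_high <- in_high %||% q[2]
    if (in_low >= in_high) {
      abort_degenerate(sprintf(
        "intensity window collapsed: quantiles give [%g, %g]; the image has too little contrast to stretch",
        in_low, in_high
      ))
    }
  }
  if (!is_scalar_number(in_low) || !is_scalar_number(in_high) ||
      in_low < 0 || in_high > 255 || in_low >= in_high) {
    abort_param("stretch window must satisfy 0 <= in_low < in_high <= 255")
  }
  out <- round_half_away(255 * (clamp(image, in_low, in_high) - in_low) /
                           (in_high - in_low))
  matrix(out, nrow(image), ncol(image))
}

#' Binarize an image at a threshold
#'
#' A pixel becomes foreground (1) iff its value is strictly greater than the
#' threshold, matching the class convention of [kapur_objective()] where a
#' threshold is the last level of the lower class.
#'
#' @param image Numeric matrix with values in `[0, 255]`.
#' @param threshold Integer in `[0, 255]`.
#' @return A 0/1 matrix of the same shape.
#' @export
binarize <- function(image, threshold) {
  check_gray_image(image)
  if (!is_scalar_number(threshold) || threshold < 0 || threshold > 255) {
    abort_param("`threshold` must lie in [0, 255]")
  }
  (image > threshold) + 0
}

#' Label connected foreground components
#'
#' Labels maximal connected sets of foreground pixels 1..L in the order their
#' first pixel is met by a row-major scan (top-left origin), under 4- or
#' 8-adjacency, and tabulates region areas. Implemented as a seeded
#' breadth-first flood fill with vectorized frontier expansion.
#'
#' @param mask A 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return An object of class `region_labeling`: list with `labels` (integer
#'   matrix, 0 = background) and `region_areas` (named integer vector,
#'   names = labels).
#' @export
#' @examples
#' m <- matrix(0, 5, 5); m[1:2, 1:2] <- 1; m[5, 5] <- 1
#' label_connected(m)$region_areas
label_connected <- function(mask, connectivity = 8L) {
  check_binary_mask(mask)
  if (!connectivity %in% c(4L, 8L)) {
    abort_param("`connectivity` must be 4 or 8")
  }
  h <- nrow(mask); w <- ncol(mask)
  offsets <- if (connectivity == 4L) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else {
    cbind(dr = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
          dc = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  }
  labels <- matrix(0L, h, w)
  fg <- which(mask == 1)
  if (length(fg) == 0L) {
    return(structure(list(labels = labels,
                          region_areas = integer(0)),
                     class = "region_labeling"))
  }
  # row-major visiting order for deterministic label numbering
  r <- (fg - 1L) %% h + 1L
  c_ <- (fg - 1L) %/% h + 1L
  seeds <- fg[order(r, c_)]
  next_label <- 0L
  areas <- integer(0)
  for (seed in seeds) {
    if (labels[seed] != 0L) next
    next_label <- next_label + 1L
    labels[seed] <- next_label
    frontier <- seed
    area <- 1L
    while (length(frontier) > 0L) {
      fr <- (frontier - 1L) %% h + 1L
      fc <- (frontier - 1L) %/% h + 1L
      nr <- rep(fr, times = nrow(offsets)) +
        rep(offsets[, "dr"], each = length(frontier))
      nc <- rep(fc, times = nrow(offsets)) +
        rep(offsets[, "dc"], each = length(frontier))
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      idx <- unique((nc[ok] - 1L) * h + nr[ok])
      idx <- idx[mask[idx] == 1 & labels[idx] == 0L]
      labels[idx] <- next_label
      area <- area + length(idx)
      frontier <- idx
    }
    areas[next_label] <- area
  }
  names(areas) <- seq_len(next_label)
  structure(list(labels = labels, region_areas = areas),
            class = "region_labeling")
}

#' @export
print.region_labeling <- function(x, ...) {
  cat(sprintf("<region_labeling: %d region(s), areas [%s]>\n",
              length(x$region_areas),
              paste(x$region_areas, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.region_labeling <- function(x, ...) {
  tibble(label = as.integer(names(x$region_areas)),
         area = as.integer(x$region_areas))
}

#' Keep regions within an area window
#'
#' Removes labeled regions whose pixel count falls outside
#' `[min_area, max_area]`; removed regions become background.
#'
#' @param labeling A `region_labeling` from [label_connected()].
#' @param min_area Smallest area kept (>= 1).
#' @param max_area Largest area kept (default `Inf`, unbounded).
#' @return A 0/1 matrix retaining only the surviving regions.
#' @export
area_filter <- function(labeling, min_area = 1L, max_area = Inf) {
  if (!inherits(labeling, "region_labeling")) {
    abort_contract("`labeling` must come from label_connected()")
  }
  if (!is_scalar_number(min_area) || min_area < 1) {
    abort_param("`min_area` must be >= 1")
  }
  if (min_area > max_area) {
    abort_param("`min_area` must not exceed `max_area`")
  }
  keep <- as.integer(names(labeling$region_areas))[
    labeling$region_areas >= min_area & labeling$region_areas <= max_area
  ]
  (labeling$labels %in% keep) + 0 -> out
  matrix(out, nrow(labeling$labels), ncol(labeling$labels))
}

gaussian_kernel_1d <- function(sigma) {
  radius <- ceiling(4 * sigma)
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Mirror indices beyond [1, n] back inside (half-sample symmetric reflection:
# the edge pixel is repeated).
reflect_index <- function(i, n) {
  period <- 2L * n
  j <- ((i - 1L) %% period + period) %% period
  ifelse(j < n, j + 1L, period - j)
}

#' Gaussian smoothing
#'
#' Convolves the image with a normalized 2-D Gaussian kernel, truncated at
#' four standard deviations, with mirror-reflected boundaries, then rounds
#' half-away-from-zero back to integers in `[0, 255]`. The kernel is applied
#' separably (two 1-D passes), which is exact for a Gaussian.
#'
#' @param image Numeric matrix with values in `[0, 255]`.
#' @param sigma Positive standard deviation in pixels.
#' @return The smoothed image, same shape, integer values in `[0, 255]`.
#' @export
gaussian_smooth <- function(image, sigma) {
  check_gray_image(image)
  if (!is_scalar_number(sigma) || sigma <= 0) {
    abort_param("`sigma` must be a positive number")
  }
  k <- gaussian_kernel_1d(sigma)
  radius <- (length(k) - 1L) %/% 2L
  convolve_1d <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    idx <- reflect_index(outer(seq_len(n), (-radius):radius, `+`), n)
    acc <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      sel <- idx[, j]
      acc <- acc + k[j] * (if (along_rows) m[sel, , drop = FALSE]
                           else m[, sel, drop = FALSE])
    }
    acc
  }
  out <- convolve_1d(convolve_1d(image, TRUE), FALSE)
  matrix(clamp(round_half_away(out), 0, 255), nrow(image), ncol(image))
}
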
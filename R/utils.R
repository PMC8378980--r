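# Shared numeric conventions and validation helpers.

#' Round half away from zero
#'
#' Deterministic rounding used everywhere an integer raster is produced.
#' Unlike [base::round()] (banker's rounding), ties move away from zero, so
#' `0.5 -> 1` and `-0.5 -> -1`.
#'
#' @param x Numeric vector or matrix.
#' @return Numeric object of the same shape with integral values.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 2.4))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

abort_param <- function(msg) abort(msg, class = "ipsoseg_error_parameter")
abort_contract <- function(msg) abort(msg, class = "ipsoseg_error_contract")
abort_domain <- function(msg) abort(msg, class = "ipsoseg_error_domain")
abort_io <- function(msg) abort(msg, class = "ipsoseg_error_io")
abort_degenerate <- function(msg) abort(msg, class = "ipsoseg_error_degenerate")
abort_capacity <- function(msg) abort(msg, class = "ipsoseg_error_capacity")
abort_eval <- function(msg) abort(msg, class = "ipsoseg_error_evaluation")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_gray_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image) || length(image) < 1L) {
    abort_contract(sprintf("`%s` must be a nonempty numeric matrix", arg))
  }
  if (anyNA(image) || any(image < 0 | image > 255)) {
    abort_domain(sprintf("`%s` must contain values in [0, 255] with no NA", arg))
  }
  invisible(image)
}

check_binary_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.numeric(mask) || length(mask) < 1L) {
    abort_contract(sprintf("`%s` must be a nonempty numeric matrix", arg))
  }
  if (anyNA(mask) || !all(mask %in% c(0, 1))) {
    abort_contract(sprintf("`%s` must contain only 0/1 values", arg))
  }
  invisible(mask)
}

# Derive a reproducible child seed from a base seed and a stream index,
# staying inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 7919) %% 2147483647)
}
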
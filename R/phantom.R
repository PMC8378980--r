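# Synthetic uterine MRI phantoms with known ground truth: an elliptical
# uterus with a myometrial band and a crescent-shaped placental region whose
# protrusion into the band encodes the clinical invasion grade, degraded by a
# smooth multiplicative bias field and additive Gaussian noise. Also
# simulates paired reader calls for the diagnostic-statistics module.

GRADE_LEVELS <- c("adhesive", "implantable", "penetrated")

#' Grade from invasion depth
#'
#' Maps the fraction of the myometrial band thickness penetrated by the
#' placenta onto the three clinical grades: `adhesive` below 0.2,
#' `implantable` in `[0.2, 0.8)`, `penetrated` at 0.8 and above.
#'
#' @param invasion_depth_fraction Number in `[0, 1]`.
#' @return One of `"adhesive"`, `"implantable"`, `"penetrated"`.
#' @export
invasion_grade <- function(invasion_depth_fraction) {
  if (!is.numeric(invasion_depth_fraction) ||
      any(invasion_depth_fraction < 0 | invasion_depth_fraction > 1)) {
    abort_param("`invasion_depth_fraction` must lie in [0, 1]")
  }
  cut(invasion_depth_fraction, breaks = c(-Inf, 0.2, 0.8, Inf),
      labels = GRADE_LEVELS, right = FALSE) |> as.character()
}

#' Phantom generation parameters
#'
#' @param width,height Raster size in pixels (default 256 x 256).
#' @param background_mean,myometrium_mean,placenta_mean Tissue intensities in
#'   `[0, 255]`, strictly increasing (defaults 40, 110, 180): the dark
#'   surroundings and uterine cavity, the myometrial band, and the bright
#'   placental region.
#' @param noise_sigma Standard deviation of additive Gaussian noise on the
#'   8-bit scale (default 0).
#' @param bias_amplitude Peak relative amplitude of the smooth multiplicative
#'   bias field, in `[0, 1)` (default 0).
#' @param invasion_depth_fraction Fraction of the myometrial band thickness
#'   penetrated by the placenta, in `[0, 1]`; encodes the grade via
#'   [invasion_grade()].
#' @param band_fraction Thickness of the myometrial band as a fraction of the
#'   uterus semi-axes (default 0.18).
#' @param axis_fraction Uterus semi-axes as fractions of the image half-size
#'   (length-2, default `c(0.72, 0.62)`).
#' @param placenta_angle Center of the placental crescent's angular sector,
#'   radians (default `pi / 2`, anterior wall).
#' @param placenta_halfwidth Angular half-width of the crescent, radians
#'   (default `pi / 3`).
#' @param placenta_thickness Radial thickness of the crescent inside the
#'   cavity, in normalized elliptical-radius units (default 0.22).
#' @param center_offset Length-2 pixel offset of the uterus center from the
#'   image center (default `c(0, 0)`).
#' @param seed Integer seed controlling noise and bias realization.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(width = 256L, height = 256L,
                           background_mean = 40, myometrium_mean = 110,
                           placenta_mean = 180,
                           noise_sigma = 0, bias_amplitude = 0,
                           invasion_depth_fraction = 0.5,
                           band_fraction = 0.18,
                           axis_fraction = c(0.72, 0.62),
                           placenta_angle = pi / 2,
                           placenta_halfwidth = pi / 3,
                           placenta_thickness = 0.22,
                           center_offset = c(0, 0),
                           seed = 1L) {
  if (!is_scalar_number(width) || !is_scalar_number(height) ||
      width < 32 || height < 32) {
    abort_param("phantom geometry must be at least 32 x 32 pixels to render all structures")
  }
  means <- c(background_mean, myometrium_mean, placenta_mean)
  if (any(!is.finite(means)) || any(means < 0 | means > 255) ||
      is.unsorted(means, strictly = TRUE)) {
    abort_param("tissue means must be strictly increasing within [0, 255]")
  }
  if (!is_scalar_number(noise_sigma) || noise_sigma < 0) {
    abort_param("`noise_sigma` must be nonnegative")
  }
  if (!is_scalar_number(bias_amplitude) || bias_amplitude < 0 ||
      bias_amplitude >= 1) {
    abort_param("`bias_amplitude` must lie in [0, 1)")
  }
  if (!is_scalar_number(invasion_depth_fraction) ||
      invasion_depth_fraction < 0 || invasion_depth_fraction > 1) {
    abort_param("`invasion_depth_fraction` must lie in [0, 1]")
  }
  if (band_fraction <= 0 || band_fraction >= 0.5) {
    abort_param("`band_fraction` must lie in (0, 0.5)")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         background_mean = background_mean,
         myometrium_mean = myometrium_mean, placenta_mean = placenta_mean,
         noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
         invasion_depth_fraction = invasion_depth_fraction,
         band_fraction = band_fraction, axis_fraction = axis_fraction,
         placenta_angle = placenta_angle,
         placenta_halfwidth = placenta_halfwidth,
         placenta_thickness = placenta_thickness,
         center_offset = center_offset, seed = as.integer(seed)),
    class = "phantom_params"
  )
}

# Second-order polynomial bias surface scaled to peak amplitude 1 over the
# image; coefficients are drawn once per phantom (seeded).
bias_surface <- function(width, height) {
  xn <- matrix(rep(seq(-1, 1, length.out = width), each = height),
               height, width)
  yn <- matrix(rep(seq(-1, 1, length.out = height), times = width),
               height, width)
  coef <- runif(5, -1, 1)
  f <- coef[1] * xn + coef[2] * yn + coef[3] * xn * yn +
    coef[4] * (xn^2 - 0.5) + coef[5] * (yn^2 - 0.5)
  m <- max(abs(f))
  if (m == 0) f else f / m
}

#' Render one synthetic uterine phantom
#'
#' Draws an elliptical uterus whose wall is a myometrial band of relative
#' thickness `band_fraction`, with a crescent-shaped placental region hugging
#' the inner wall and protruding into the band by
#' `invasion_depth_fraction` of its thickness. The noiseless tissue raster
#' takes exactly the three configured mean intensities; a smooth
#' multiplicative second-order polynomial bias field and additive Gaussian
#' noise are then applied and the result is clipped to `[0, 255]`. The truth
#' mask is the noiseless placental region. Fully determined by the seed.
#'
#' @param params A [phantom_params()].
#' @return An object of class `phantom_case`: list with `image` (integer
#'   matrix), `truth_mask` (0/1 matrix), `grade`, `case_id` and `params`.
#' @export
#' @examples
#' ph <- make_phantom(phantom_params(noise_sigma = 5, seed = 3))
#' ph$grade
make_phantom <- function(params) {
  if (!inherits(params, "phantom_params")) params <- do.call(phantom_params, params)
  withr::with_seed(params$seed, {
    w <- params$width; h <- params$height
    cx <- (w + 1) / 2 + params$center_offset[1]
    cy <- (h + 1) / 2 + params$center_offset[2]
    a <- params$axis_fraction[1] * w / 2
    b <- params$axis_fraction[2] * h / 2
    x <- matrix(rep(seq_len(w), each = h), h, w)
    y <- matrix(rep(seq_len(h), times = w), h, w)
    # normalized elliptical radius: 1 on the outer uterine boundary
    s <- sqrt(((x - cx) / a)^2 + ((y - cy) / b)^2)
    s_in <- 1 - params$band_fraction
    theta <- atan2(-(y - cy), x - cx)   # y axis points down in rasters
    dtheta <- abs(((theta - params$placenta_angle + pi) %% (2 * pi)) - pi)
    s_pl_low <- s_in - params$placenta_thickness
    s_pl_high <- s_in + params$invasion_depth_fraction * params$band_fraction
    placenta <- dtheta <= params$placenta_halfwidth &
      s >= s_pl_low & s <= s_pl_high
    if (!any(placenta)) {
      abort_param("phantom geometry too small: the placental region rendered empty")
    }
    band <- s >= s_in & s <= 1
    img <- matrix(params$background_mean, h, w)
    img[band] <- params$myometrium_mean
    img[placenta] <- params$placenta_mean
    if (params$bias_amplitude > 0) {
      img <- img * (1 + params$bias_amplitude * bias_surface(w, h))
    }
    if (params$noise_sigma > 0) {
      img <- img + rnorm(h * w, sd = params$noise_sigma)
    }
    img <- matrix(clamp(round_half_away(img), 0, 255), h, w)
    structure(
      list(image = img, truth_mask = placenta + 0,
           grade = invasion_grade(params$invasion_depth_fraction),
           case_id = sprintf("phantom_seed%d", params$seed),
           params = params),
      class = "phantom_case"
    )
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case %s: %dx%d, grade %s, truth area %d px>\n",
              x$case_id, x$params$width, x$params$height, x$grade,
              sum(x$truth_mask)))
  invisible(x)
}

# Invasion-depth ranges used when drawing a case of a given grade.
grade_depth_range <- function(grade) {
  switch(grade,
         adhesive = c(0.03, 0.17),
         implantable = c(0.25, 0.75),
         penetrated = c(0.82, 0.98),
         abort_param(sprintf("unknown grade '%s'", grade)))
}

#' Generate a cohort of phantoms
#'
#' Draws `n` phantoms with grades sampled from `grade_mix` and per-case
#' jittered geometry (uterus axes, center, crescent position and width, and
#' an invasion depth uniform within the grade's range). Deterministic given
#' the seed.
#'
#' @param n Number of cases (>= 1).
#' @param grade_mix Length-3 proportions over
#'   (adhesive, implantable, penetrated); must sum to 1.
#' @param params Template [phantom_params()] supplying size, tissue means,
#'   noise and bias settings.
#' @param seed Integer seed for the cohort draw.
#' @return A list of `phantom_case` objects (class `phantom_cohort`).
#' @export
#' @examples
#' cohort <- make_cohort(4, c(0.4, 0.4, 0.2), seed = 11)
#' purrr::map_chr(cohort, "grade")
make_cohort <- function(n, grade_mix = c(0.4, 0.4, 0.2),
                        params = phantom_params(), seed = 1L) {
  if (!is_scalar_number(n) || n < 1 || n != floor(n)) {
    abort_param("`n` must be a positive integer")
  }
  if (length(grade_mix) != 3L || any(grade_mix < 0) ||
      abs(sum(grade_mix) - 1) > 1e-9) {
    abort_param("`grade_mix` must be 3 nonnegative proportions summing to 1")
  }
  if (!inherits(params, "phantom_params")) params <- do.call(phantom_params, params)
  cases <- withr::with_seed(seed, {
    grades <- sample(GRADE_LEVELS, n, replace = TRUE, prob = grade_mix)
    lapply(seq_len(n), function(i) {
      rng <- grade_depth_range(grades[i])
      jittered <- modifyList(unclass(params), list(
        invasion_depth_fraction = runif(1, rng[1], rng[2]),
        axis_fraction = params$axis_fraction * runif(2, 0.92, 1.05),
        center_offset = params$center_offset +
          runif(2, -0.04, 0.04) * c(params$width, params$height),
        placenta_angle = runif(1, 0, 2 * pi),
        placenta_halfwidth = params$placenta_halfwidth * runif(1, 0.85, 1.15),
        seed = derive_seed(seed, i)
      ))
      case <- make_phantom(do.call(phantom_params, jittered))
      case$case_id <- sprintf("case%03d", i)
      case
    })
  })
  structure(cases, class = c("phantom_cohort", "list"))
}

#' Simulate paired diagnostic calls for two modalities
#'
#' Generates per-case correct/incorrect calls for two imaging modalities with
#' the stated marginal sensitivities (on gold-positive cases) and
#' specificities (on gold-negative controls), with within-case dependence
#' induced by a Gaussian copula of correlation `correlation`. With
#' `correlation = 1` and equal marginals, the two modalities always agree.
#'
#' @param n Number of cases, or a `phantom_cohort` whose length and grades
#'   are used.
#' @param sens_a,sens_b Marginal sensitivities in `[0, 1]`.
#' @param spec_a,spec_b Marginal specificities in `[0, 1]`.
#' @param correlation Latent Gaussian correlation in `[0, 1]`.
#' @param control_fraction Fraction of gold-negative controls in `[0, 1)`
#'   (default 0: every case is disease-positive, mirroring a
#'   pathology-confirmed cohort).
#' @param seed Integer seed.
#' @return A tibble with columns `case_id`, `grade` (`"none"` for controls),
#'   `gold` (logical), `call_a`, `call_b` (logical positive calls), and
#'   `correct_a`, `correct_b`.
#' @export
simulate_reader_calls <- function(n, sens_a, spec_a, sens_b, spec_b,
                                  correlation = 0, control_fraction = 0,
                                  seed = 1L) {
  grades <- NULL
  if (inherits(n, "phantom_cohort")) {
    grades <- purrr::map_chr(n, "grade")
    n <- length(n)
  }
  rates <- c(sens_a, spec_a, sens_b, spec_b)
  if (any(!is.finite(rates)) || any(rates < 0 | rates > 1)) {
    abort_param("sensitivities and specificities must lie in [0, 1]")
  }
  if (!is_scalar_number(correlation) || correlation < 0 || correlation > 1) {
    abort_param("`correlation` must lie in [0, 1] (the feasible range of the Gaussian copula used here)")
  }
  if (!is_scalar_number(control_fraction) || control_fraction < 0 ||
      control_fraction >= 1) {
    abort_param("`control_fraction` must lie in [0, 1)")
  }
  withr::with_seed(seed, {
    gold <- runif(n) >= control_fraction
    z1 <- rnorm(n)
    z2 <- correlation * z1 + sqrt(1 - correlation^2) * rnorm(n)
    p_a <- ifelse(gold, sens_a, spec_a)
    p_b <- ifelse(gold, sens_b, spec_b)
    correct_a <- z1 <= qnorm(p_a)
    correct_b <- z2 <= qnorm(p_b)
    tibble(
      case_id = sprintf("case%04d", seq_len(n)),
      grade = if (is.null(grades)) ifelse(gold, "implantable", "none")
              else ifelse(gold, grades, "none"),
      gold = gold,
      call_a = ifelse(gold, correct_a, !correct_a),
      call_b = ifelse(gold, correct_b, !correct_b),
      correct_a = correct_a,
      correct_b = correct_b
    )
  })
}
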
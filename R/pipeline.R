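# End-to-end segmentation of one gray-scale image and the cross-validation
# harness over a dataset of (image, reference-mask) pairs.

#' Segmentation pipeline configuration
#'
#' Assembles the stage toggles and parameters of the full pipeline:
#' linear stretch -> Gaussian smoothing -> maximum-entropy threshold search
#' (improved PSO) -> binarization -> connected components -> area filter.
#' Each preprocessing stage can be switched off independently.
#'
#' @param stretch Apply the linear contrast stretch (default `TRUE`).
#' @param stretch_percentiles Quantile window for the stretch when explicit
#'   limits are not given (default 1st and 99th percentile).
#' @param stretch_low,stretch_high Optional explicit window limits,
#'   overriding the percentiles.
#' @param smooth Apply Gaussian smoothing before thresholding (default
#'   `FALSE`: on images whose histogram has well-separated modes, smoothing
#'   manufactures thinly-populated transition gray levels that Kapur's
#'   objective then isolates as their own near-uniform class, pulling the
#'   threshold away from the modes; speckle suppression is left to the area
#'   filter instead).
#' @param smooth_sigma Smoothing standard deviation in pixels (default 1).
#' @param entropy_k Number of thresholds for the entropy search (default 1;
#'   use 2 for images with a distinct intermediate tissue between background
#'   and target, such as the myometrial band of the uterine phantoms).
#' @param connectivity Component connectivity, 4 or 8 (default 8).
#' @param min_area,max_area Area window of the component filter (defaults 32
#'   and `Inf`); set `min_area = 1` to disable.
#' @param pso A [pso_config()] for the threshold search.
#' @param seed Integer seed for the whole pipeline; overrides `pso$seed` so
#'   one seed fixes the entire run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(stretch = TRUE,
                            stretch_percentiles = c(0.01, 0.99),
                            stretch_low = NULL, stretch_high = NULL,
                            smooth = FALSE, smooth_sigma = 1,
                            entropy_k = 1L,
                            connectivity = 8L,
                            min_area = 32L, max_area = Inf,
                            pso = pso_config(), seed = 1L) {
  if (!is_scalar_number(entropy_k) || entropy_k < 1 ||
      entropy_k != floor(entropy_k)) {
    abort_param("`entropy_k` must be a positive integer")
  }
  if (smooth && (!is_scalar_number(smooth_sigma) || smooth_sigma <= 0)) {
    abort_param("`smooth_sigma` must be positive when smoothing is enabled")
  }
  if (!is_scalar_number(min_area) || min_area < 1 || min_area > max_area) {
    abort_param("area window must satisfy 1 <= min_area <= max_area")
  }
  if (length(stretch_percentiles) != 2L ||
      any(stretch_percentiles < 0 | stretch_percentiles > 1) ||
      stretch_percentiles[1] >= stretch_percentiles[2]) {
    abort_param("`stretch_percentiles` must be two increasing probabilities")
  }
  pso$seed <- as.integer(seed)
  structure(
    list(stretch = isTRUE(stretch),
         stretch_percentiles = as.numeric(stretch_percentiles),
         stretch_low = stretch_low, stretch_high = stretch_high,
         smooth = isTRUE(smooth), smooth_sigma = smooth_sigma,
         entropy_k = as.integer(entropy_k),
         connectivity = as.integer(connectivity),
         min_area = min_area, max_area = max_area,
         pso = pso, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Segment one gray-scale image
#'
#' Runs the configured pipeline on an 8-bit gray-scale image: optional
#' contrast stretch and Gaussian smoothing, maximum-entropy threshold search
#' with the improved PSO, binarization at the largest found threshold (the
#' brightest class is taken as the target), connected-component labeling and
#' area filtering. Deterministic given the image and the config seed.
#'
#' @param image Numeric matrix with integer values in `[0, 255]`.
#' @param config A [pipeline_config()].
#' @return An object of class `segmentation_result`: list with `mask` (0/1
#'   matrix), `thresholds`, `objective_value` (the Kapur score of the found
#'   thresholds), `optimizer_trace` (a `pso_result`), and `stage_log`, an
#'   ordered record of the applied stages and their parameters.
#' @export
#' @examples
#' ph <- make_phantom(phantom_params(seed = 2))
#' res <- segment_image(ph$image, pipeline_config(entropy_k = 2, seed = 5))
#' jaccard_index(res$mask, ph$truth_mask)
segment_image <- function(image, config = pipeline_config()) {
  check_gray_image(image)
  if (!inherits(config, "pipeline_config")) {
    abort_contract("`config` must be a pipeline_config()")
  }
  if (length(unique(as.vector(image))) == 1L) {
    abort_degenerate(
      "constant image: every gray-level split leaves an empty class, so the maximum-entropy objective is infeasible"
    )
  }
  stage_log <- list()
  log_stage <- function(name, params) {
    stage_log[[length(stage_log) + 1L]] <<- c(list(stage = name), params)
  }
  work <- image
  if (config$stretch) {
    work <- linear_stretch(work, config$stretch_low, config$stretch_high,
                           percentiles = config$stretch_percentiles)
    log_stage("linear_stretch",
              list(percentiles = config$stretch_percentiles,
                   in_low = config$stretch_low, in_high = config$stretch_high))
  }
  if (config$smooth) {
    work <- gaussian_smooth(work, config$smooth_sigma)
    log_stage("gaussian_smooth", list(sigma = config$smooth_sigma))
  }
  hist <- compute_histogram(work)
  search <- pso_threshold_search(hist, k = config$entropy_k, config = config$pso)
  log_stage("entropy_threshold",
            list(k = config$entropy_k, thresholds = search$thresholds,
                 score = search$score))
  target_threshold <- max(search$thresholds)
  mask <- binarize(work, target_threshold)
  log_stage("binarize", list(threshold = target_threshold))
  labeling <- label_connected(mask, config$connectivity)
  mask <- area_filter(labeling, config$min_area, config$max_area)
  log_stage("area_filter",
            list(connectivity = config$connectivity,
                 min_area = config$min_area, max_area = config$max_area,
                 regions_before = length(labeling$region_areas),
                 regions_after = length(unique(labeling$labels[mask == 1]))))
  structure(
    list(mask = mask, thresholds = search$thresholds,
         objective_value = search$score, optimizer_trace = search$result,
         stage_log = stage_log, config = config),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result: thresholds [%s], Kapur score %.4f, %d foreground px>\n",
    paste(x$thresholds, collapse = ", "), x$objective_value, sum(x$mask)
  ))
  invisible(x)
}

#' @export
glance.segmentation_result <- function(x, ...) {
  tibble(k = length(x$thresholds),
         threshold = max(x$thresholds),
         objective_value = x$objective_value,
         foreground_px = sum(x$mask),
         iterations_run = x$optimizer_trace$iterations_run)
}

# Normalize a case to (image, mask, case_id, grade); accepts phantom_case
# objects and plain lists with either `truth_mask` or `reference_mask`.
as_labeled_case <- function(case, i) {
  mask <- case$truth_mask %||% case$reference_mask
  if (is.null(case$image) || is.null(mask)) {
    abort_contract(sprintf("case %d lacks an image or a reference mask", i))
  }
  if (!identical(dim(case$image), dim(mask))) {
    abort_contract(sprintf("case %d: image and mask shapes differ", i))
  }
  list(image = case$image, mask = mask,
       case_id = case$case_id %||% sprintf("case%03d", i),
       grade = case$grade %||% "none")
}

default_tuning_grid <- function() {
  tidyr::expand_grid(
    stretch_percentiles = list(c(0.01, 0.99), c(0.02, 0.98)),
    min_area = c(32, 128)
  )
}

apply_tuning <- function(config, row) {
  config$stretch_percentiles <- row$stretch_percentiles[[1]]
  config$min_area <- row$min_area
  config
}

mean_case_jaccard <- function(cases, config) {
  mean(vapply(cases, function(cs) {
    jaccard_index(segment_image(cs$image, config)$mask, cs$mask)
  }, numeric(1)))
}

#' Cross-validate the segmentation pipeline
#'
#' Repeated k-fold cross-validation over labeled cases. Cases are shuffled
#' into folds of near-equal size (seeded); on each training split the cheap
#' preprocessing tunables (stretch percentiles and minimum region area) are
#' selected from a small grid by maximizing mean Jaccard, then the selected
#' configuration is applied to the held-out fold and per-case Jaccard is
#' recorded. PSO hyperparameters stay fixed throughout.
#'
#' @param cases List of cases: `phantom_case` objects or lists with `image`,
#'   `truth_mask`/`reference_mask`, optional `case_id` and `grade`.
#' @param folds Number of folds (default 2, i.e. a 50/50 split).
#' @param repeats Number of repeated shufflings (default 5).
#' @param config Base [pipeline_config()].
#' @param tuning_grid Data frame of tunable settings (columns
#'   `stretch_percentiles`, a list column, and `min_area`); `NULL` uses a
#'   built-in 2 x 2 grid.
#' @return An object of class `cv_report`: `per_case` tibble (repeat, fold,
#'   case_id, grade, jaccard), `fold_summary`, `grade_summary`,
#'   `overall_mean_jaccard`, `assignments`, plus the config and seed.
#' @export
run_cross_validation <- function(cases, folds = 2L, repeats = 5L,
                                 config = pipeline_config(),
                                 tuning_grid = NULL) {
  n <- length(cases)
  if (!is_scalar_number(folds) || folds < 2) {
    abort_param("`folds` must be at least 2")
  }
  if (folds > n) abort_param("`folds` must not exceed the number of cases")
  if (!is_scalar_number(repeats) || repeats < 1) {
    abort_param("`repeats` must be at least 1")
  }
  cases <- purrr::imap(cases, as_labeled_case)
  tuning_grid <- tuning_grid %||% default_tuning_grid()
  per_case <- list()
  assignments <- list()
  for (r in seq_len(repeats)) {
    fold_of <- withr::with_seed(derive_seed(config$seed, r), {
      fold_of <- integer(n)
      fold_of[sample.int(n)] <- rep_len(seq_len(folds), n)
      fold_of
    })
    assignments[[r]] <- tibble(
      rep = r, case_id = purrr::map_chr(cases, "case_id"), fold = fold_of
    )
    for (f in seq_len(folds)) {
      train <- cases[fold_of != f]
      test <- cases[fold_of == f]
      grid_scores <- vapply(seq_len(nrow(tuning_grid)), function(g) {
        mean_case_jaccard(train, apply_tuning(config, tuning_grid[g, ]))
      }, numeric(1))
      chosen <- which.max(grid_scores)
      tuned <- apply_tuning(config, tuning_grid[chosen, ])
      per_case[[length(per_case) + 1L]] <- purrr::map_dfr(test, function(cs) {
        seg <- segment_image(cs$image, tuned)
        tibble(rep = r, fold = f, case_id = cs$case_id, grade = cs$grade,
               jaccard = jaccard_index(seg$mask, cs$mask),
               grid_choice = chosen)
      })
    }
  }
  per_case <- dplyr::bind_rows(per_case)
  fold_summary <- per_case |>
    dplyr::group_by(.data$rep, .data$fold) |>
    dplyr::summarise(mean_jaccard = mean(.data$jaccard),
                     median_jaccard = median(.data$jaccard),
                     n = dplyr::n(), .groups = "drop")
  grade_summary <- per_case |>
    dplyr::group_by(.data$grade) |>
    dplyr::summarise(mean_jaccard = mean(.data$jaccard),
                     median_jaccard = median(.data$jaccard),
                     n = dplyr::n(), .groups = "drop")
  structure(
    list(per_case = per_case, fold_summary = fold_summary,
         grade_summary = grade_summary,
         overall_mean_jaccard = mean(per_case$jaccard),
         assignments = dplyr::bind_rows(assignments),
         folds = as.integer(folds), repeats = as.integer(repeats),
         config = config, seed = config$seed),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %d-fold x %d repeat(s), overall mean Jaccard %.4f>\n",
              x$folds, x$repeats, x$overall_mean_jaccard))
  print(x$fold_summary)
  invisible(x)
}

#' @export
tidy.cv_report <- function(x, ...) x$per_case

#' @export
glance.cv_report <- function(x, ...) {
  tibble(folds = x$folds, repeats = x$repeats,
         n_cases = length(unique(x$per_case$case_id)),
         overall_mean_jaccard = x$overall_mean_jaccard,
         overall_median_jaccard = median(x$per_case$jaccard))
}

#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot(object$per_case,
         aes(x = factor(.data$fold), y = .data$jaccard)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6) +
    labs(x = "fold", y = "Jaccard index")
}
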
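# File I/O: PNG/NIfTI image reading, PNG mask writing, YAML pipeline
# configuration, JSON run manifests, and case-directory loading.

#' Read a single-channel gray-scale image
#'
#' Reads one 2-D slice as an 8-bit gray-scale matrix. 8-bit PNG values are
#' taken as-is; 16-bit PNG and NIfTI sources are min-max rescaled onto
#' `[0, 255]` with the same half-away-from-zero rounding as
#' [linear_stretch()]. Multi-slice NIfTI volumes require `slice_index`.
#' DICOM input is not supported by this package; convert the series to NIfTI
#' or PNG first.
#'
#' @param path Input file path.
#' @param format `"auto"` (from the file extension), `"png"` or `"nifti"`.
#' @param slice_index 1-based slice to extract from a volume.
#' @return Numeric matrix with integer values in `[0, 255]`.
#' @export
read_gray_image <- function(path, format = c("auto", "png", "nifti"),
                            slice_index = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     png = "png", nii = "nifti", gz = "nifti",
                     dcm = abort_io("DICOM input is not supported; convert the series to NIfTI or PNG"),
                     abort_io(sprintf("cannot infer the format of '%s'; pass `format`", path)))
  }
  if (format == "png") {
    raw <- png::readPNG(path, info = TRUE)
    info <- attr(raw, "info")
    if (length(dim(raw)) == 3L) {
      ch <- dim(raw)[3]
      same <- all(vapply(seq_len(ch)[-1],
                         function(j) identical(raw[, , 1], raw[, , j]),
                         logical(1)))
      if (!same) {
        abort_io("unsupported photometric interpretation: PNG has distinct color channels; a single-channel gray-scale image is required")
      }
      raw <- raw[, , 1]
    }
    depth <- info$bit.depth %||% 8L
    if (depth <= 8L) {
      return(matrix(round_half_away(raw * 255), nrow(raw), ncol(raw)))
    }
    return(rescale_to_8bit(round_half_away(raw * (2^depth - 1))))
  }
  vol <- RNifti::readNifti(path)
  arr <- as.array(vol)
  if (length(dim(arr)) > 2L) {
    extra <- dim(arr)[-(1:2)]
    if (prod(extra) > 1L && is.null(slice_index)) {
      abort_io(sprintf(
        "volume has %d slices; pass `slice_index` to pick one", prod(extra)
      ))
    }
    slice_index <- slice_index %||% 1L
    if (slice_index < 1L || slice_index > prod(extra)) {
      abort_io(sprintf("`slice_index` %d outside [1, %d]",
                       slice_index, prod(extra)))
    }
    arr <- matrix(arr[slice_indices(dim(arr), slice_index)],
                  dim(arr)[1], dim(arr)[2])
  }
  rescale_to_8bit(arr)
}

slice_indices <- function(dims, k) {
  # linear indices of the k-th 2-D slice of an n-D array
  plane <- prod(dims[1:2])
  (k - 1L) * plane + seq_len(plane)
}

rescale_to_8bit <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi == lo) return(matrix(0, nrow(m), ncol(m)))
  matrix(round_half_away(255 * (m - lo) / (hi - lo)), nrow(m), ncol(m))
}

#' Write a gray-scale image or binary mask as 8-bit PNG
#'
#' Masks are stored with foreground 255 and background 0; reading the file
#' back with [read_gray_image()] and dividing by 255 reproduces the mask
#' exactly.
#'
#' @param mask A 0/1 matrix.
#' @param image A numeric matrix with integer values in `[0, 255]`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  check_binary_mask(mask)
  write_gray_image(mask * 255, path)
}

#' @rdname write_mask
#' @export
write_gray_image <- function(image, path) {
  check_gray_image(image)
  ok <- tryCatch({
    png::writePNG(image / 255, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_io(sprintf("cannot write PNG to '%s'", path))
  invisible(path)
}

config_schema <- function() {
  list(
    stretch = "logical", stretch_percentiles = "numeric",
    stretch_low = "numeric", stretch_high = "numeric",
    smooth = "logical", smooth_sigma = "numeric",
    entropy_k = "numeric", connectivity = "numeric",
    min_area = "numeric", max_area = "numeric",
    seed = "numeric", pso = "list"
  )
}

pso_schema <- function() {
  list(swarm_size = "numeric", n_max = "numeric", p_max = "numeric",
       p_min = "numeric", inertia_weight = "numeric", c1 = "numeric",
       c2 = "numeric", v_max = "numeric", seed = "numeric",
       stall_tolerance = "numeric", stall_window = "numeric")
}

check_schema <- function(values, schema, where) {
  unknown <- setdiff(names(values), names(schema))
  if (length(unknown) > 0L) {
    abort_param(sprintf("unknown config key%s %s in %s",
                        if (length(unknown) > 1) "s" else "",
                        paste(sprintf("'%s'", unknown), collapse = ", "), where))
  }
  for (key in names(values)) {
    expected <- schema[[key]]
    v <- values[[key]]
    ok <- switch(expected,
                 logical = is.logical(v),
                 numeric = is.numeric(v),
                 list = is.list(v))
    if (!ok) {
      abort_param(sprintf("config key '%s' in %s must be %s",
                          key, where, expected))
    }
  }
  invisible(values)
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file with optional top-level keys matching the arguments of
#' [pipeline_config()] plus a nested `pso` block matching [pso_config()].
#' Missing keys take the package defaults; unknown keys are rejected with the
#' offending name. An empty file yields the all-defaults configuration.
#'
#' @param path YAML file path.
#' @return A validated [pipeline_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  values <- yaml::read_yaml(path)
  if (is.null(values)) values <- list()
  if (!is.list(values)) abort_param("config file must contain a YAML mapping")
  check_schema(values, config_schema(), "the top level")
  pso_values <- values$pso %||% list()
  check_schema(pso_values, pso_schema(), "the `pso` block")
  values$pso <- do.call(pso_config, pso_values)
  do.call(pipeline_config, values)
}

#' Serialize a pipeline configuration to YAML
#'
#' @param config A [pipeline_config()].
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
dump_config <- function(config, path) {
  if (!inherits(config, "pipeline_config")) {
    abort_contract("`config` must be a pipeline_config()")
  }
  out <- unclass(config)
  out$pso <- unclass(out$pso)
  out$pso$v_max <- out$pso$v_max %||% NULL
  out <- out[!vapply(out, is.null, logical(1))]
  out$pso <- out$pso[!vapply(out$pso, is.null, logical(1))]
  if (is.infinite(out$max_area)) out$max_area <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records tool version, configuration snapshot, input paths with MD5
#' hashes, seed and timestamps for a reproducible run.
#'
#' @param path Output JSON path.
#' @param config A [pipeline_config()] (or any serializable list).
#' @param inputs Character vector of input file paths.
#' @param seed Integer seed of the run.
#' @param stages Optional stage log (e.g. from a `segmentation_result`).
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, config, inputs = character(), seed = NA,
                           stages = NULL) {
  manifest <- list(
    tool = "ipsoseg",
    version = as.character(utils::packageVersion("ipsoseg")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass_deep(config),
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    stages = stages
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Load a case directory of paired images and masks
#'
#' Reads the case layout written by [write_cohort()]: `<id>_img.png` paired
#' with `<id>_mask.png` and an optional `<id>.json` holding `grade`
#' metadata.
#'
#' @param dir Directory path.
#' @return A list of labeled cases (image, reference_mask, case_id, grade).
#' @export
load_cases <- function(dir) {
  if (!dir.exists(dir)) abort_io(sprintf("directory not found: %s", dir))
  img_files <- sort(list.files(dir, pattern = "_img\\.png$", full.names = TRUE))
  if (length(img_files) == 0L) {
    abort_io(sprintf("no '*_img.png' files found in %s", dir))
  }
  lapply(img_files, function(f) {
    id <- sub("_img\\.png$", "", basename(f))
    mask_file <- file.path(dir, paste0(id, "_mask.png"))
    if (!file.exists(mask_file)) {
      abort_io(sprintf("case '%s' has no mask file '%s'", id, mask_file))
    }
    meta_file <- file.path(dir, paste0(id, ".json"))
    grade <- if (file.exists(meta_file)) {
      jsonlite::read_json(meta_file)$grade %||% "none"
    } else "none"
    list(image = read_gray_image(f),
         reference_mask = read_gray_image(mask_file) / 255,
         case_id = id, grade = grade)
  })
}

#' Write a phantom cohort as a case directory
#'
#' @param cohort A `phantom_cohort` from [make_cohort()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (case in cohort) {
    write_gray_image(case$image, file.path(dir, paste0(case$case_id, "_img.png")))
    write_mask(case$truth_mask, file.path(dir, paste0(case$case_id, "_mask.png")))
    jsonlite::write_json(
      list(grade = case$grade,
           invasion_depth_fraction = case$params$invasion_depth_fraction,
           seed = case$params$seed),
      file.path(dir, paste0(case$case_id, ".json")),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
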
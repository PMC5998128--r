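# End-to-end pipeline: segmentation -> morphology -> classification ->
# enumeration, with optional on-disk artifacts and a run manifest.

#' Analyze one micrograph
#'
#' Runs the per-image chain: threshold learning, binarization, component
#' labelling, feature extraction and component classification.
#'
#' @param image A [mono_image].
#' @param config A [run_config].
#' @param classifier `"rule"` or a [train_svm] model.
#' @param decision Optional pre-learned [binary_decision] (used for a
#'   batch-global threshold); by default the threshold is learned on this
#'   image.
#' @return List with `decision`, `field`, `features` and `classes`.
#' @export
analyze_image <- function(image, config, classifier = "rule",
                          decision = NULL) {
  stopifnot(inherits(image, "mono_image"), inherits(config, "run_config"))
  if (is.null(decision)) decision <- learn_threshold(image)
  lf <- binarize(image, decision)
  field <- connected_components(lf$mask, config$connectivity,
                                config$min_component_area_px)
  features <- suppressWarnings(featurize(field, config$um_per_pixel))
  classes <- if (identical(classifier, "rule")) {
    classify_rule(features, config$rule_thresholds)
  } else {
    stopifnot(inherits(classifier, "cell_svm"))
    if (nrow(features) == 0L)
      factor(character(0), levels = class_labels())
    else
      factor(as.character(predict(classifier, features[, c(
        "area_px", "eccentricity", "compactness", "convex_area_px",
        "solidity", "extent", "perimeter_px")])), levels = class_labels())
  }
  list(decision = decision, field = field, features = features,
       classes = classes)
}

#' Run the full enumeration pipeline
#'
#' Chains segmentation, morphology, classification and enumeration over a
#' batch of micrographs and, when `out_dir` is given, writes per-image
#' artifacts (mask PNG, label TIFF, feature and class CSV), the report
#' (JSON + component CSV) and a run manifest recording the configuration,
#' input checksums, package version and seed. By default the threshold is
#' learned per image (each acquisition gets its own decision boundary); set
#' `global_theta = TRUE` to learn a single threshold on the first image and
#' apply it to the whole batch.
#'
#' @param inputs Character vector of image paths, or a list of
#'   [mono_image]s.
#' @param config A [run_config].
#' @param mode `"two_species"` or `"three_species"` (see
#'   [enumerate_images]).
#' @param calibration A [calibration_model] for the filamentous class (or
#'   named list of models).
#' @param svm_model Required in three-species mode.
#' @param out_dir Optional output directory for artifacts.
#' @param global_theta Learn one threshold for the whole batch.
#' @return An [enumeration_report]; per-image results are attached as
#'   attribute `"per_image"`, the manifest as attribute `"manifest"`.
#' @export
run_pipeline <- function(inputs, config,
                         mode = c("two_species", "three_species"),
                         calibration = NULL, svm_model = NULL,
                         out_dir = NULL, global_theta = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "run_config"))
  if (length(inputs) == 0L) stop("no inputs", call. = FALSE)
  from_paths <- is.character(inputs)
  images <- if (from_paths) {
    lapply(inputs, read_image, um_per_pixel = config$um_per_pixel)
  } else {
    if (inherits(inputs, "mono_image")) inputs <- list(inputs)
    lapply(inputs, function(x) {
      stopifnot(inherits(x, "mono_image")); x
    })
  }
  classifier <- if (mode == "two_species") "rule" else {
    if (is.null(svm_model))
      stop("three-species mode requires an svm_model", call. = FALSE)
    svm_model
  }

  shared_decision <- if (global_theta) learn_threshold(images[[1L]]) else NULL
  per_image <- vector("list", length(images))
  for (i in seq_along(images)) {
    res <- tryCatch(
      analyze_image(images[[i]], config, classifier, shared_decision),
      error = function(e)
        stop("pipeline stage failed on input ",
             if (from_paths) inputs[i] else i, ": ", conditionMessage(e),
             call. = FALSE))
    per_image[[i]] <- res
  }

  report <- enumerate_images(images, config, calibration = calibration,
                             mode = mode, svm_model = svm_model)

  manifest <- list(
    package_version = as.character(utils::packageVersion("cyanocount")),
    config = unclass(config)[setdiff(names(unclass(config)),
                                     "rule_thresholds")],
    rule_thresholds = unclass(config$rule_thresholds),
    mode = mode,
    inputs = if (from_paths)
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)))
    else
      data.frame(path = vapply(images, function(x) x$source_id, ""),
                 md5 = NA_character_),
    seed = config$rng_seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    theta = vapply(per_image, function(x) x$decision$theta, 0))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(images)) {
      stem <- file.path(out_dir, sprintf("image_%03d", i))
      write_mask_png(per_image[[i]]$field$mask, paste0(stem, "_mask.png"))
      write_labels_tiff(per_image[[i]]$field$labels,
                        paste0(stem, "_labels.tif"))
      utils::write.csv(cbind(per_image[[i]]$features,
                             class = as.character(per_image[[i]]$classes)),
                       paste0(stem, "_features.csv"), row.names = FALSE)
    }
    write_report(report, file.path(out_dir, "report.json"), "json")
    write_report(report, file.path(out_dir, "components.csv"), "csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  attr(report, "per_image") <- per_image
  attr(report, "manifest") <- manifest
  report
}
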
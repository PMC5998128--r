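# Two-phase enumeration: Phase 1 calibrates the projected area of a single
# cell from images of well-isolated cells; Phase 2 counts unicellular
# components directly and converts filamentous class area into cell numbers
# by dividing by the calibrated unit-cell area, then scales per-image counts
# to cells/ml through the counting-chamber geometry.

#' Unit-cell projected-area calibration
#'
#' @param species Class id the calibration belongs to (e.g. `"C_A"`).
#' @param unit_cell_area_um2 Mean projected area of one cell, um^2.
#' @param unit_cell_area_sd_um2 Standard deviation across cells, um^2.
#' @param n_cells Number of single cells the calibration is based on.
#'   Fewer than 10 triggers a low-n warning.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(species, unit_cell_area_um2,
                              unit_cell_area_sd_um2, n_cells) {
  stopifnot(unit_cell_area_um2 > 0, unit_cell_area_sd_um2 >= 0,
            n_cells >= 1)
  if (n_cells < 10)
    warning("calibration based on only ", n_cells,
            " cells; at least 10 recommended", call. = FALSE)
  structure(list(species = as.character(species),
                 unit_cell_area_um2 = unit_cell_area_um2,
                 unit_cell_area_sd_um2 = unit_cell_area_sd_um2,
                 n_cells = as.integer(n_cells)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s: %.3g +/- %.3g um^2 (n = %d)\n",
              x$species, x$unit_cell_area_um2, x$unit_cell_area_sd_um2,
              x$n_cells))
  invisible(x)
}

#' Phase-1 calibration of the projected area per unit cell
#'
#' Segments each image of a sonicated, filtered single-cell preparation and
#' takes the mean and SD of the retained component areas (um^2). Components
#' smaller than the configured minimum area are removed during
#' segmentation; components more elongated than `max_eccentricity` are
#' excluded as residual filament fragments or touching pairs (the
#' preparation protocol is expected to leave only well-isolated single
#' cells, so by default only clearly elongated outliers are dropped).
#'
#' @param images List of [mono_image]s of isolated single cells of one
#'   species (pure culture).
#' @param species Class id recorded in the model (e.g. `"C_M"`).
#' @param config A [run_config].
#' @param max_eccentricity Retain components with eccentricity at or below
#'   this bound (default `config$rule_thresholds$omega`).
#' @return A [calibration_model].
#' @export
calibrate_unit_area <- function(images, species, config,
                                max_eccentricity = NULL) {
  if (inherits(images, "mono_image")) images <- list(images)
  stopifnot(length(images) >= 1L, inherits(config, "run_config"))
  if (is.null(max_eccentricity))
    max_eccentricity <- config$rule_thresholds$omega
  areas <- numeric(0)
  n_excluded <- 0L
  for (img in images) {
    seg <- segment_image(img, config)
    if (seg$field$n_components == 0L) next
    feats <- suppressWarnings(featurize(seg$field, config$um_per_pixel))
    keep <- feats$eccentricity <= max_eccentricity
    n_excluded <- n_excluded + sum(!keep)
    areas <- c(areas, feats$area_um2[keep])
  }
  if (length(areas) == 0L)
    stop("calibration failed: no retained single-cell components",
         call. = FALSE)
  if (n_excluded > 0L)
    message(n_excluded, " component(s) excluded from calibration (eccentricity > ",
            format(max_eccentricity), ")")
  calibration_model(
    species = species,
    unit_cell_area_um2 = mean(areas),
    unit_cell_area_sd_um2 = if (length(areas) > 1L) stats::sd(areas) else 0,
    n_cells = length(areas))
}

#' Count unicellular components of a class
#'
#' For unicellular taxa every foreground component is one cell, so the
#' class is enumerated by counting its components.
#'
#' @param class_labels Factor/character vector of component labels (one per
#'   component, as returned by [classify_rule] or an SVM prediction).
#' @param target Class to count (default `"C_M"`).
#' @return Integer count.
#' @export
enumerate_unicellular <- function(class_labels, target = "C_M") {
  sum(class_labels == target)
}

#' Estimate filamentous cell numbers by area division
#'
#' Filaments are segmented as single components, so cells cannot be counted
#' directly; instead the total class area is divided by the Phase-1
#' calibrated area of one cell. The estimate is a real number (fractional
#' cells are meaningful for an area quotient). Its standard deviation is
#' propagated from the calibration uncertainty by the delta method:
#' `sd = total_area * se(unit_area) / unit_area^2`, with
#' `se = sd_cal / sqrt(n_cal)`.
#'
#' @param features Feature table ([featurize]) with an `area_um2` column.
#' @param class_labels Component class labels aligned with `features` rows.
#' @param target Filamentous class (default `"C_A"`).
#' @param calibration A [calibration_model] for `target`.
#' @return List with `estimated_cells`, `sd` and `total_area_um2`.
#' @export
enumerate_filamentous <- function(features, class_labels, target = "C_A",
                                  calibration) {
  if (missing(calibration) || !inherits(calibration, "calibration_model"))
    stop("a calibration_model for the target species is required",
         call. = FALSE)
  total_area <- sum(features$area_um2[class_labels == target])
  u <- calibration$unit_cell_area_um2
  se_u <- calibration$unit_cell_area_sd_um2 / sqrt(calibration$n_cells)
  list(estimated_cells = total_area / u,
       sd = total_area * se_u / u^2,
       total_area_um2 = total_area)
}

#' Convert per-image cell counts to a concentration
#'
#' The imaged volume per field is `grid_area_um2 * chamber_depth_um`
#' (1 um^3 = 1e-12 ml). Cells/ml is the mean number of cells per image
#' divided by that volume, scaled by the sample dilution factor.
#'
#' @param estimated_cells Total estimated cells over all images.
#' @param n_images Number of images the total came from.
#' @param config A [run_config] carrying the chamber geometry and dilution.
#' @return Cells per millilitre.
#' @export
to_concentration <- function(estimated_cells, n_images, config) {
  stopifnot(inherits(config, "run_config"), n_images >= 1)
  vol_ml <- config$grid_area_um2 * config$chamber_depth_um * 1e-12
  if (vol_ml <= 0) stop("imaged volume must be positive", call. = FALSE)
  (estimated_cells / n_images) / vol_ml * config$dilution_factor
}

#' Normalized mixture proportions
#'
#' Normalizes per-class estimated cell numbers to fractions summing to 1.
#' The `C_N` (neither) class is excluded. With all-zero counts the
#' proportions are undefined and returned as `NA` with a warning.
#'
#' @param counts Named numeric vector of estimated cells per class, or an
#'   [enumeration_report].
#' @return Named numeric vector of fractions.
#' @export
mixture_proportions <- function(counts) {
  if (inherits(counts, "enumeration_report"))
    counts <- stats::setNames(counts$per_class$estimated_cells,
                              counts$per_class$class)
  counts <- counts[names(counts) != "C_N"]
  if (length(counts) == 0L)
    stop("no counted classes", call. = FALSE)
  total <- sum(counts)
  if (total == 0) {
    warning("all counts zero: proportions undefined", call. = FALSE)
    return(stats::setNames(rep(NA_real_, length(counts)), names(counts)))
  }
  counts / total
}

#' Per-run enumeration report
#'
#' @param per_class `data.frame` with columns `class`, `object_count`,
#'   `total_area_um2`, `estimated_cells`, `cells_per_ml`, `sd`.
#' @param image_ids Character vector of the images enumerated.
#' @param chamber_volume_ul Imaged chamber volume per field in microlitres.
#' @param proportions Named numeric vector of mixture fractions.
#' @param components Optional per-component table (image id, label, class,
#'   features, centroid).
#' @return An object of class `enumeration_report`.
#' @export
enumeration_report <- function(per_class, image_ids, chamber_volume_ul,
                               proportions, components = NULL) {
  stopifnot(is.data.frame(per_class))
  if (any(per_class$estimated_cells < 0))
    stop("estimated cells must be non-negative", call. = FALSE)
  ok <- !is.na(proportions)
  if (any(ok) && abs(sum(proportions[ok]) - 1) > 1e-9)
    stop("proportions must sum to 1 over counted classes", call. = FALSE)
  structure(list(per_class = per_class,
                 image_ids = as.character(image_ids),
                 chamber_volume_ul = chamber_volume_ul,
                 proportions = proportions,
                 components = components),
            class = "enumeration_report")
}

#' @export
print.enumeration_report <- function(x, ...) {
  cat(sprintf("<enumeration_report> %d image(s)\n", length(x$image_ids)))
  df <- x$per_class
  df$estimated_cells <- round(df$estimated_cells)   # display rounding only
  print(df, row.names = FALSE)
  invisible(x)
}

#' Phase-2 enumeration of a set of micrographs
#'
#' Runs segmentation, feature extraction and classification on every image
#' and aggregates per-class counts, areas, estimated cell numbers and
#' concentrations into an [enumeration_report]. The unicellular classes
#' (`C_M`, and `C_K` in three-species mode) are enumerated by object
#' counting; the filamentous class `C_A` by total-area division with its
#' calibration. The per-class `sd` column is the standard deviation of the
#' per-image estimates (when more than one image is given), matching how
#' replicate fields are reported in practice.
#'
#' @param images List of [mono_image]s.
#' @param config A [run_config].
#' @param calibration A [calibration_model] for `C_A`, or a named list of
#'   calibrations; required when filaments are to be enumerated.
#' @param mode `"two_species"` (rule cascade, classes `C_A`/`C_M`) or
#'   `"three_species"` (SVM over the seven features, classes
#'   `C_A`/`C_M`/`C_K`).
#' @param svm_model A [train_svm] model, required in three-species mode.
#' @return An [enumeration_report].
#' @export
enumerate_images <- function(images, config, calibration = NULL,
                             mode = c("two_species", "three_species"),
                             svm_model = NULL) {
  mode <- match.arg(mode)
  if (inherits(images, "mono_image")) images <- list(images)
  if (length(images) == 0L) stop("no inputs", call. = FALSE)
  stopifnot(inherits(config, "run_config"))
  if (mode == "three_species" && is.null(svm_model))
    stop("three-species mode requires an svm_model", call. = FALSE)
  cal_a <- if (inherits(calibration, "calibration_model")) calibration
           else calibration[["C_A"]]

  classes <- if (mode == "two_species") c("C_A", "C_M") else
    c("C_A", "C_M", "C_K")
  per_image <- matrix(0, nrow = length(images), ncol = length(classes),
                      dimnames = list(NULL, classes))
  area_tot <- stats::setNames(numeric(length(classes)), classes)
  count_tot <- stats::setNames(integer(length(classes)), classes)
  comp_rows <- list()
  ids <- character(length(images))

  for (i in seq_along(images)) {
    img <- images[[i]]
    stopifnot(inherits(img, "mono_image"))
    ids[i] <- if (nzchar(img$source_id)) img$source_id else paste0("image_", i)
    seg <- segment_image(img, config)
    feats <- suppressWarnings(featurize(seg$field, config$um_per_pixel))
    if (nrow(feats) == 0L) next
    lab <- if (mode == "two_species") {
      classify_rule(feats, config$rule_thresholds)
    } else {
      f7 <- feats[, c("area_px", "eccentricity", "compactness",
                      "convex_area_px", "solidity", "extent",
                      "perimeter_px")]
      factor(as.character(predict(svm_model, f7)), levels = class_labels())
    }
    comp_rows[[i]] <- cbind(image_id = ids[i], feats[, "label", drop = FALSE],
                            class = as.character(lab),
                            feats[, setdiff(names(feats), "label")])
    for (cl in classes) {
      area_tot[cl] <- area_tot[cl] + sum(feats$area_um2[lab == cl])
      n_cl <- enumerate_unicellular(lab, cl)
      count_tot[cl] <- count_tot[cl] + n_cl
      per_image[i, cl] <- if (cl == "C_A" && !is.null(cal_a))
        sum(feats$area_um2[lab == cl]) / cal_a$unit_cell_area_um2 else n_cl
    }
  }

  est <- stats::setNames(numeric(length(classes)), classes)
  sd_est <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    if (cl == "C_A") {
      if (is.null(cal_a))
        stop("filament enumeration requires a C_A calibration_model",
             call. = FALSE)
      est[cl] <- area_tot[cl] / cal_a$unit_cell_area_um2
    } else {
      est[cl] <- count_tot[cl]
    }
    sd_est[cl] <- if (length(images) > 1L) stats::sd(per_image[, cl]) else 0
  }
  conc <- vapply(classes, function(cl)
    to_concentration(est[cl], length(images), config), 0)

  per_class <- data.frame(
    class = classes,
    object_count = as.integer(count_tot),
    total_area_um2 = as.numeric(area_tot),
    estimated_cells = as.numeric(est),
    cells_per_ml = as.numeric(conc),
    sd = as.numeric(sd_est))
  props <- suppressWarnings(
    mixture_proportions(stats::setNames(per_class$estimated_cells, classes)))
  components <- if (length(comp_rows)) do.call(rbind, comp_rows) else NULL
  if (!is.null(components)) rownames(components) <- NULL
  enumeration_report(
    per_class = per_class,
    image_ids = ids,
    chamber_volume_ul = config$grid_area_um2 * config$chamber_depth_um * 1e-9,
    proportions = props,
    components = components)
}
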
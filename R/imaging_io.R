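#' Single-channel intensity image
#'
#' Canonical container for a monochrome fluorescence micrograph: an integer
#' intensity raster together with its bit depth and the spatial calibration
#' (micrometres per pixel) needed to express areas in physical units.
#'
#' @param pixels Numeric matrix of non-negative integer intensities
#'   (rows x cols). Values must lie in `[0, 2^bit_depth - 1]`.
#' @param bit_depth Integer, one of 8, 12 or 16.
#' @param um_per_pixel Positive spatial calibration in micrometres per pixel.
#' @param source_id Free-text identifier of the acquisition (file name,
#'   synthetic seed, ...).
#'
#' @return An object of class `mono_image` with fields `pixels`, `bit_depth`,
#'   `um_per_pixel` and `source_id`.
#' @export
mono_image <- function(pixels, bit_depth, um_per_pixel, source_id = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("image must be at least 2 x 2 pixels", call. = FALSE)
  if (!bit_depth %in% c(8L, 12L, 16L))
    stop("`bit_depth` must be 8, 12 or 16", call. = FALSE)
  if (!is.numeric(um_per_pixel) || length(um_per_pixel) != 1L ||
      !is.finite(um_per_pixel) || um_per_pixel <= 0)
    stop("`um_per_pixel` must be a positive number", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 2^bit_depth - 1)
    stop("intensities must lie in [0, 2^bit_depth - 1]", call. = FALSE)
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         um_per_pixel = as.numeric(um_per_pixel),
         source_id = as.character(source_id)),
    class = "mono_image")
}

#' @export
print.mono_image <- function(x, ...) {
  cat(sprintf("<mono_image> %d x %d px, %d-bit, %.4g um/px%s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$um_per_pixel,
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

# ITU-R BT.709 luminance weights used for the RGB -> mono convenience path.
.luma_weights <- c(0.2126, 0.7152, 0.0722)

#' Read a micrograph into the canonical mono representation
#'
#' Reads an 8/12/16-bit TIFF or PNG. Three-channel inputs are reduced to a
#' single channel by ITU-R luminance weighting; native mono images pass
#' through unchanged (no rescaling). 12-bit data shipped in 16-bit TIFF
#' containers is detected by maximum-value inspection unless `bit_depth` is
#' given explicitly.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param um_per_pixel Spatial calibration to attach (micrometres per pixel).
#' @param bit_depth Optional explicit bit depth overriding container
#'   inspection (use `bit_depth = 16` to suppress 12-bit detection).
#'
#' @return A [mono_image].
#' @export
read_image <- function(path, um_per_pixel, bit_depth = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                    error = function(e) stop("unreadable TIFF: ", path,
                                             call. = FALSE))
    container_bits <- attr(raw, "bits.per.sample")
    if (is.null(container_bits)) container_bits <- 8L
    px <- raw
  } else if (ext == "png") {
    raw <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) stop("unreadable PNG: ", path,
                                             call. = FALSE))
    info <- attr(raw, "info")
    container_bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    px <- raw * (2^container_bits - 1)
  } else {
    stop("unsupported image format: .", ext, " (TIFF or PNG expected)",
         call. = FALSE)
  }
  if (!container_bits %in% c(8L, 16L))
    stop("unsupported container bit depth: ", container_bits, call. = FALSE)
  if (length(dim(px)) == 3L) {
    nch <- dim(px)[3]
    if (!nch %in% c(1L, 3L, 4L))
      stop("unsupported channel count: ", nch, call. = FALSE)
    px <- if (nch == 1L) px[, , 1L] else
      px[, , 1L] * .luma_weights[1] + px[, , 2L] * .luma_weights[2] +
      px[, , 3L] * .luma_weights[3]
  }
  px <- round(px)
  bd <- if (!is.null(bit_depth)) as.integer(bit_depth) else
    if (container_bits == 16L && max(px) <= 4095) 12L else
      as.integer(container_bits)
  if (!bd %in% c(8L, 12L, 16L))
    stop("unsupported bit depth: ", bd, call. = FALSE)
  mono_image(px, bd, um_per_pixel, source_id = basename(path))
}

#' Write a binary mask as an 8-bit PNG
#' @param mask Logical matrix (foreground = `TRUE`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' Write a label raster as a 16-bit TIFF
#' @param labels Integer matrix of component labels (0 = background).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_labels_tiff <- function(labels, path) {
  if (max(labels) > 65535) stop("more than 65535 labels", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles the spatial calibration, counting-chamber geometry, component
#' filtering parameters and rule-classifier thresholds used across the
#' pipeline. The chamber defaults describe a standard hemocytometer: a
#' 1 mm^2 counting grid at 0.1 mm depth (0.1 uL imaged per grid).
#'
#' @param um_per_pixel Micrometres per pixel. Required: the optics determine
#'   it and no safe default exists.
#' @param chamber_depth_um Chamber depth in micrometres (default 100).
#' @param grid_area_um2 Imaged grid area in square micrometres
#'   (default 1e6 = 1 mm^2).
#' @param dilution_factor Sample dilution factor, >= 1.
#' @param rule_thresholds A [rule_thresholds] object.
#' @param min_component_area_px Components smaller than this many pixels are
#'   discarded as noise (default 4).
#' @param connectivity Pixel adjacency for component labelling, 4 or 8.
#' @param rng_seed Integer seed recorded for reproducibility.
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(um_per_pixel,
                       chamber_depth_um = 100,
                       grid_area_um2 = 1e6,
                       dilution_factor = 1,
                       rule_thresholds = cyanocount::rule_thresholds(),
                       min_component_area_px = 4L,
                       connectivity = 8L,
                       rng_seed = 1L) {
  stopifnot(is.numeric(um_per_pixel), um_per_pixel > 0,
            chamber_depth_um > 0, grid_area_um2 > 0)
  if (dilution_factor < 1)
    stop("`dilution_factor` must be >= 1", call. = FALSE)
  if (!connectivity %in% c(4L, 8L))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  if (min_component_area_px < 0)
    stop("`min_component_area_px` must be non-negative", call. = FALSE)
  stopifnot(inherits(rule_thresholds, "rule_thresholds"))
  structure(
    list(um_per_pixel = um_per_pixel,
         chamber_depth_um = chamber_depth_um,
         grid_area_um2 = grid_area_um2,
         dilution_factor = dilution_factor,
         rule_thresholds = rule_thresholds,
         min_component_area_px = as.integer(min_component_area_px),
         connectivity = as.integer(connectivity),
         rng_seed = as.integer(rng_seed)),
    class = "run_config")
}

# keys accepted in the flat key = value configuration file
.config_keys <- c("um_per_pixel", "chamber_depth_um", "grid_area_um2",
                  "dilution_factor", "min_component_area_px", "connectivity",
                  "rng_seed", "omega", "tau", "psi_al", "psi_au", "psi_ml",
                  "psi_mu")

#' Read a run configuration from a flat key = value text file
#'
#' Blank lines and `#` comments are ignored. Rule-classifier boundaries are
#' set through the keys `omega`, `tau`, `psi_al`, `psi_au`, `psi_ml`,
#' `psi_mu`. Unknown keys are rejected.
#'
#' @param path Path to the configuration file.
#' @return A [run_config].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line: ", lines[bad][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  unknown <- setdiff(keys, .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(keys))
    stop("duplicated config key(s)", call. = FALSE)
  v <- function(k, default) if (k %in% keys) vals[keys == k] else default
  if (!"um_per_pixel" %in% keys)
    stop("config must set um_per_pixel", call. = FALSE)
  rt <- rule_thresholds(
    omega = v("omega", 0.70), tau = v("tau", 0.80),
    psi_al = v("psi_al", 0), psi_au = v("psi_au", Inf),
    psi_ml = v("psi_ml", 0), psi_mu = v("psi_mu", Inf))
  run_config(
    um_per_pixel = v("um_per_pixel", NA),
    chamber_depth_um = v("chamber_depth_um", 100),
    grid_area_um2 = v("grid_area_um2", 1e6),
    dilution_factor = v("dilution_factor", 1),
    rule_thresholds = rt,
    min_component_area_px = v("min_component_area_px", 4),
    connectivity = v("connectivity", 8),
    rng_seed = v("rng_seed", 1))
}

#' Write an enumeration report to CSV or JSON
#'
#' The JSON form stores the full report (per-class summary, image ids,
#' chamber volume, mixture proportions and, when present, the per-component
#' table) at full numeric precision; [read_report] restores it. The CSV form
#' writes one row per classified component (id, class, the seven features,
#' centroid); with no components an empty table with headers is written.
#'
#' @param report An [enumeration_report].
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "enumeration_report"))
  if (format == "json") {
    payload <- unclass(report)
    payload$proportions <- as.list(payload$proportions)  # keep names in JSON
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", dataframe = "columns")
  } else {
    comp <- report$components
    if (is.null(comp)) comp <- .empty_component_table()
    utils::write.csv(comp, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a report written by [write_report]
#'
#' @param path Path to a `.json` or `.csv` report file.
#' @return For JSON, an [enumeration_report]; for CSV, the per-component
#'   `data.frame`.
#' @export
read_report <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    comp <- x$components
    if (!is.null(comp) && !is.data.frame(comp)) comp <- as.data.frame(comp)
    enumeration_report(
      per_class = as.data.frame(x$per_class),
      image_ids = as.character(x$image_ids),
      chamber_volume_ul = x$chamber_volume_ul,
      proportions = unlist(x$proportions),
      components = comp)
  } else if (ext == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else stop("unsupported report format: .", ext, call. = FALSE)
}

.empty_component_table <- function() {
  data.frame(image_id = character(), label = integer(), class = character(),
             area_px = numeric(), area_um2 = numeric(),
             perimeter_px = numeric(), eccentricity = numeric(),
             compactness = numeric(), convex_area_px = numeric(),
             solidity = numeric(), extent = numeric(),
             centroid_row = numeric(), centroid_col = numeric())
}
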
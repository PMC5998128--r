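# Ground-truthed synthetic fluorescence micrographs.
#
# Scenes emulate the bright-object imaging model of autofluorescence
# microscopy: quasi-circular unicells (Microcystis-like), filaments
# rendered as chains of overlapping elliptical cells (Anabaena-like),
# needle/spindle shapes (Ankistrodesmus-like) and optional irregular
# debris on a dark noisy background, with an optional illumination
# gradient. Every rendered object is recorded in a ground-truth structure
# so each pipeline stage can be validated against known truth.

#' Scene specification for the synthetic micrograph generator
#'
#' Defaults describe the acquisition the pipeline targets: a 1600 x 1200
#' 12-bit mono camera behind a 10X objective (0.645 um/px for a 6.45 um
#' sensor pixel). Cell geometry defaults reproduce unit-cell projected
#' areas of ~24.6 um^2 (discs) and ~26.8 um^2 (filament cells).
#'
#' @param image_size `c(rows, cols)` of the raster.
#' @param bit_depth Intensity bit depth (8, 12 or 16).
#' @param um_per_pixel Spatial calibration, um per pixel.
#' @param counts Named integer vector of object counts per class
#'   (`C_M` discs, `C_A` filaments, `C_K` spindles).
#' @param disc_radius_um `c(mean, sd)` of the disc radius in um.
#' @param filament List: `cells_mean`, `cells_sd` (cells per filament),
#'   `cell_length_um`, `width_um`, `curvature` (SD of the per-cell heading
#'   change, radians) and `overlap_frac` (fraction of the cell length by
#'   which neighbouring cells overlap so the chain is one connected
#'   component).
#' @param spindle List: `length_um_mean`, `length_um_sd`, `width_um`.
#' @param intensity List: `cell_mean`, `cell_sd` (across-object brightness
#'   SD), `background_mean`, `background_sd` (per-pixel noise SD), on the
#'   native intensity scale.
#' @param illumination_gradient Amplitude of a multiplicative left-to-right
#'   linear ramp (0 disables; 0.2 means +/-10% across the field).
#' @param debris List: `count`, `size_um` (range of the nominal radius),
#'   `intensity` (uniform range of the debris brightness). Debris objects
#'   are recorded in the ground truth but never enter class totals.
#' @param max_overlap Maximum tolerated fraction of an object's pixels
#'   already occupied by earlier objects; 0 (default) additionally enforces
#'   a `margin_px` empty margin so objects stay separate components.
#' @param margin_px Separation margin in pixels used when `max_overlap` is 0.
#' @param seed Integer seed; identical specs render bit-identical scenes.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(1200, 1600),
                       bit_depth = 12L,
                       um_per_pixel = 0.645,
                       counts = c(C_M = 30L, C_A = 10L, C_K = 0L),
                       disc_radius_um = c(mean = 2.80, sd = 0.19),
                       filament = list(cells_mean = 12, cells_sd = 4,
                                       cell_length_um = 6.83, width_um = 5.0,
                                       curvature = 0.15, overlap_frac = 0.1),
                       spindle = list(length_um_mean = 40, length_um_sd = 10,
                                      width_um = 2.5),
                       intensity = list(cell_mean = 1800, cell_sd = 150,
                                        background_mean = 150,
                                        background_sd = 40),
                       illumination_gradient = 0,
                       debris = list(count = 0L, size_um = c(2, 10),
                                     intensity = c(300, 900)),
                       max_overlap = 0,
                       margin_px = 2L,
                       seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 16),
            bit_depth %in% c(8L, 12L, 16L), um_per_pixel > 0,
            all(counts >= 0L), disc_radius_um[["mean"]] > 0,
            disc_radius_um[["sd"]] >= 0,
            filament$cell_length_um > 0, filament$width_um > 0,
            filament$overlap_frac >= 0, filament$overlap_frac < 1,
            spindle$length_um_mean > 0, spindle$width_um > 0,
            max_overlap >= 0, max_overlap <= 1, margin_px >= 0)
  maxv <- 2^bit_depth - 1
  if (intensity$cell_mean > maxv || intensity$background_mean > maxv ||
      intensity$cell_mean <= intensity$background_mean)
    stop("intensity means must satisfy background < cell <= 2^bit_depth - 1",
         call. = FALSE)
  known <- c("C_M", "C_A", "C_K")
  if (!all(names(counts) %in% known))
    stop("counts names must be among ", paste(known, collapse = ", "),
         call. = FALSE)
  cnt <- stats::setNames(integer(3), known)
  cnt[names(counts)] <- as.integer(counts)
  structure(list(image_size = as.integer(image_size),
                 bit_depth = as.integer(bit_depth),
                 um_per_pixel = um_per_pixel, counts = cnt,
                 disc_radius_um = disc_radius_um, filament = filament,
                 spindle = spindle, intensity = intensity,
                 illumination_gradient = illumination_gradient,
                 debris = debris, max_overlap = max_overlap,
                 margin_px = as.integer(margin_px),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Ground truth of a synthetic scene
#'
#' @param mask Integer label raster; label i marks pixels owned by the
#'   i-th entry of `per_object` (overlap pixels stay with the earlier
#'   object).
#' @param per_object `data.frame`: `id`, `class`, `true_area_um2` (full
#'   rendered area of the object), `true_cell_count`.
#' @param totals Named vector of true cell counts per class (debris
#'   excluded).
#' @param overlap_px Number of pixels shared between objects.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(mask, per_object, totals, overlap_px = 0L) {
  cls <- per_object$class[per_object$class != "debris"]
  cnt <- per_object$true_cell_count[per_object$class != "debris"]
  agg <- tapply(cnt, factor(cls, levels = names(totals)), sum, default = 0L)
  if (!isTRUE(all.equal(as.numeric(agg), as.numeric(totals),
                        check.attributes = FALSE)))
    stop("totals must equal the sum of per-object cell counts", call. = FALSE)
  structure(list(mask = mask, per_object = per_object, totals = totals,
                 overlap_px = as.integer(overlap_px)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", nrow(x$per_object), "object(s); cells:",
      paste(names(x$totals), x$totals, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# ---- shape rasterizers ----------------------------------------------------

#' Rasterized disc, ellipse and line fixtures
#'
#' Small standalone rasterizers used for analytic shape checks: a disc of
#' radius `radius_px` centred on a pixel centre, a rotated ellipse with
#' semi-axes `a_px >= b_px`, and a 1-pixel-wide (or wider) straight line.
#'
#' @param radius_px Disc radius in pixels.
#' @param pad Background border width around the shape.
#' @return Logical matrix with `TRUE` on the shape.
#' @export
shape_disc <- function(radius_px, pad = 3L) {
  n <- 2L * (ceiling(radius_px) + pad) + 1L
  ctr <- ceiling(radius_px) + pad + 1L
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  (rr - ctr)^2 + (cc - ctr)^2 <= radius_px^2
}

#' @rdname shape_disc
#' @param a_px,b_px Ellipse semi-axes in pixels.
#' @param theta_rad Rotation of the major axis, radians.
#' @export
shape_ellipse <- function(a_px, b_px, theta_rad = 0, pad = 3L) {
  n <- 2L * (ceiling(a_px) + pad) + 1L
  ctr <- ceiling(a_px) + pad + 1L
  rr <- matrix(seq_len(n), n, n) - ctr
  cc <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr
  u <- cc * cos(theta_rad) + rr * sin(theta_rad)
  v <- -cc * sin(theta_rad) + rr * cos(theta_rad)
  (u / a_px)^2 + (v / b_px)^2 <= 1
}

#' @rdname shape_disc
#' @param length_px,width_px Line length and width in pixels.
#' @export
shape_line <- function(length_px, width_px = 1L, pad = 2L) {
  m <- matrix(FALSE, width_px + 2L * pad, length_px + 2L * pad)
  m[pad + seq_len(width_px), pad + seq_len(length_px)] <- TRUE
  m
}

# ---- internal rendering helpers -------------------------------------------

# pixel indices (column-major, in an nr x nc raster) of an ellipse
.ellipse_pixels <- function(cr, cc, a, b, theta, nr, nc) {
  r0 <- max(1L, floor(cr - a)); r1 <- min(nr, ceiling(cr + a))
  c0 <- max(1L, floor(cc - a)); c1 <- min(nc, ceiling(cc + a))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  rr <- matrix(rows, length(rows), length(cols)) - cr
  ccm <- matrix(cols, length(rows), length(cols), byrow = TRUE) - cc
  u <- ccm * cos(theta) + rr * sin(theta)
  v <- -ccm * sin(theta) + rr * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  w <- which(inside, arr.ind = TRUE)
  (cols[w[, 2L]] - 1L) * nr + rows[w[, 1L]]
}

# star-shaped irregular polygon (debris); returns pixel indices
.debris_pixels <- function(cr, cc, radius, nr, nc) {
  nv <- sample(5:9, 1L)
  ang <- sort(stats::runif(nv, 0, 2 * pi))
  rad <- radius * stats::runif(nv, 0.4, 1)
  vx <- cc + rad * cos(ang); vy <- cr + rad * sin(ang)
  r0 <- max(1L, floor(min(vy))); r1 <- min(nr, ceiling(max(vy)))
  c0 <- max(1L, floor(min(vx))); c1 <- min(nc, ceiling(max(vx)))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  py <- matrix(rows, length(rows), length(cols))
  px <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  inside <- matrix(FALSE, length(rows), length(cols))
  j <- nv
  for (i in seq_len(nv)) {        # even-odd ray casting
    crossing <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crossing)
    j <- i
  }
  w <- which(inside, arr.ind = TRUE)
  (cols[w[, 2L]] - 1L) * nr + rows[w[, 1L]]
}

# Chebyshev dilation of a pixel-index set by `margin` (clipped to raster)
.dilate_px <- function(px, margin, nr, nc) {
  if (margin == 0L || length(px) == 0L) return(px)
  rows <- ((px - 1L) %% nr) + 1L
  cols <- ((px - 1L) %/% nr) + 1L
  offs <- expand.grid(dr = -margin:margin, dc = -margin:margin)
  out <- unlist(lapply(seq_len(nrow(offs)), function(k) {
    r <- rows + offs$dr[k]; c <- cols + offs$dc[k]
    ok <- r >= 1L & r <= nr & c >= 1L & c <= nc
    (c[ok] - 1L) * nr + r[ok]
  }))
  unique(out)
}

# one filament: chain of overlapping ellipses; returns list(px, n_cells) or
# NULL when it leaves the raster
.filament_pixels <- function(spec, nr, nc) {
  fil <- spec$filament
  upp <- spec$um_per_pixel
  n_cells <- max(1L, round(stats::rnorm(1, fil$cells_mean, fil$cells_sd)))
  len <- fil$cell_length_um / upp
  wid <- fil$width_um / upp
  step <- len * (1 - fil$overlap_frac)
  if (nr - len <= 1 + len || nc - len <= 1 + len) return(NULL)
  cr <- stats::runif(1, 1 + len, nr - len)
  cc <- stats::runif(1, 1 + len, nc - len)
  heading <- stats::runif(1, 0, 2 * pi)
  px <- integer(0)
  for (j in seq_len(n_cells)) {
    if (cr < 1 + len / 2 || cr > nr - len / 2 ||
        cc < 1 + len / 2 || cc > nc - len / 2) return(NULL)
    px <- c(px, .ellipse_pixels(cr, cc, len / 2, wid / 2, heading, nr, nc))
    heading <- heading + stats::rnorm(1, 0, fil$curvature)
    cr <- cr + step * sin(heading)
    cc <- cc + step * cos(heading)
  }
  list(px = unique(px), n_cells = n_cells)
}

# ---- scene generation -----------------------------------------------------

#' Render a synthetic micrograph with ground truth
#'
#' Objects are placed by rejection sampling (largest classes first) under
#' the overlap policy of the spec, rendered onto a noisy background,
#' optionally shaded by an illumination gradient, and clipped to the bit
#' depth. Identical specs (including the seed) produce bit-identical
#' scenes.
#'
#' @param spec A [scene_spec].
#' @return List with `image` (a [mono_image]) and `truth`
#'   (a [ground_truth]).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  upp <- spec$um_per_pixel
  withr::with_seed(spec$seed, {
    occ <- matrix(FALSE, nr, nc)
    labels <- matrix(0L, nr, nc)
    objects <- list()
    overlap_px <- 0L
    place <- function(class_name, gen_fun) {
      for (attempt in seq_len(400L)) {
        obj <- gen_fun()
        if (is.null(obj) || length(obj$px) == 0L) next
        if (spec$max_overlap == 0) {
          guard <- .dilate_px(obj$px, spec$margin_px, nr, nc)
          if (any(occ[guard])) next
          shared <- 0L
        } else {
          shared <- sum(occ[obj$px])
          if (shared / length(obj$px) > spec$max_overlap) next
        }
        id <- length(objects) + 1L
        own <- obj$px[!occ[obj$px]]
        labels[own] <<- id
        occ[obj$px] <<- TRUE
        overlap_px <<- overlap_px + shared
        objects[[id]] <<- data.frame(
          id = id, class = class_name,
          true_area_um2 = length(obj$px) * upp^2,
          true_cell_count = obj$n_cells)
        return(invisible(TRUE))
      }
      stop("could not place a ", class_name,
           " object: scene too dense", call. = FALSE)
    }

    for (i in seq_len(spec$counts[["C_A"]]))
      place("C_A", function() .filament_pixels(spec, nr, nc))
    for (i in seq_len(spec$counts[["C_K"]])) {
      place("C_K", function() {
        len <- max(spec$spindle$width_um,
                   stats::rnorm(1, spec$spindle$length_um_mean,
                                spec$spindle$length_um_sd)) / upp
        wid <- spec$spindle$width_um / upp
        th <- stats::runif(1, 0, pi)
        if (nr - len / 2 <= 1 + len / 2 || nc - len / 2 <= 1 + len / 2)
          return(NULL)
        cr <- stats::runif(1, 1 + len / 2, nr - len / 2)
        cc <- stats::runif(1, 1 + len / 2, nc - len / 2)
        list(px = .ellipse_pixels(cr, cc, len / 2, wid / 2, th, nr, nc),
             n_cells = 1L)
      })
    }
    for (i in seq_len(spec$counts[["C_M"]])) {
      place("C_M", function() {
        r <- max(0.5, stats::rnorm(1, spec$disc_radius_um[["mean"]],
                                   spec$disc_radius_um[["sd"]])) / upp
        if (nr - r <= 1 + r || nc - r <= 1 + r) return(NULL)
        cr <- stats::runif(1, 1 + r, nr - r)
        cc <- stats::runif(1, 1 + r, nc - r)
        list(px = .ellipse_pixels(cr, cc, r, r, 0, nr, nc), n_cells = 1L)
      })
    }
    n_cells_objects <- length(objects)
    for (i in seq_len(spec$debris$count)) {
      place("debris", function() {
        rad <- stats::runif(1, spec$debris$size_um[1],
                            spec$debris$size_um[2]) / upp
        if (nr - rad <= 1 + rad || nc - rad <= 1 + rad) return(NULL)
        cr <- stats::runif(1, 1 + rad, nr - rad)
        cc <- stats::runif(1, 1 + rad, nc - rad)
        list(px = .debris_pixels(cr, cc, rad, nr, nc), n_cells = 0L)
      })
    }

    img <- matrix(stats::rnorm(nr * nc, spec$intensity$background_mean,
                               spec$intensity$background_sd), nr, nc)
    for (id in seq_along(objects)) {
      px <- which(labels == id)
      if (objects[[id]]$class == "debris") {
        lev <- stats::runif(1, spec$debris$intensity[1],
                            spec$debris$intensity[2])
      } else {
        lev <- stats::rnorm(1, spec$intensity$cell_mean,
                            spec$intensity$cell_sd)
      }
      img[px] <- lev + stats::rnorm(length(px), 0,
                                    spec$intensity$background_sd)
    }
    if (spec$illumination_gradient != 0) {
      ramp <- 1 + spec$illumination_gradient *
        (seq_len(nc) / nc - 0.5)
      img <- sweep(img, 2L, ramp, `*`)
    }
    img <- round(pmin(pmax(img, 0), 2^spec$bit_depth - 1))

    per_object <- if (length(objects)) do.call(rbind, objects) else
      data.frame(id = integer(0), class = character(0),
                 true_area_um2 = numeric(0), true_cell_count = integer(0))
    cls <- per_object$class
    totals <- stats::setNames(vapply(c("C_M", "C_A", "C_K"), function(k)
      sum(per_object$true_cell_count[cls == k]), 0), c("C_M", "C_A", "C_K"))
    list(image = mono_image(img, spec$bit_depth, upp,
                            source_id = paste0("synthetic_seed_", spec$seed)),
         truth = ground_truth(labels, per_object, totals, overlap_px))
  })
}

# ---- feature-table generator ----------------------------------------------

#' Representative per-taxon feature statistics
#'
#' Means and standard deviations of the seven morphological descriptors
#' measured on laboratory cultures of the three taxa (single segmented
#' cells; areas/perimeters on the acquisition's pixel scale). Used as the
#' default parameterization of [generate_feature_table].
#'
#' @return Named list (`C_M`, `C_A`, `C_K`), each with numeric vectors
#'   `mean` and `sd` over the features `area_px`, `eccentricity`,
#'   `compactness`, `convex_area_px`, `solidity`, `extent`,
#'   `perimeter_px`.
#' @export
default_feature_stats <- function() {
  f <- c("area_px", "eccentricity", "compactness", "convex_area_px",
         "solidity", "extent", "perimeter_px")
  list(
    C_M = list(mean = stats::setNames(
                 c(11.41, 0.59, 1.82, 11.63, 0.99, 0.81, 8.94), f),
               sd = stats::setNames(
                 c(5.05, 0.22, 0.34, 5.32, 0.03, 0.11, 2.65), f)),
    C_A = list(mean = stats::setNames(
                 c(150.04, 0.90, 0.61, 342.84, 0.70, 0.43, 75.12), f),
               sd = stats::setNames(
                 c(157.53, 0.14, 0.51, 711.74, 0.22, 0.23, 69.45), f)),
    C_K = list(mean = stats::setNames(
                 c(47.46, 0.98, 0.44, 63.29, 0.81, 0.30, 40.93), f),
               sd = stats::setNames(
                 c(31.84, 0.03, 0.30, 58.24, 0.10, 0.18, 20.75), f)))
}

#' Labelled synthetic feature table
#'
#' Draws independent Gaussian features per class from the given means/SDs,
#' truncating each feature to its valid range (eccentricity, solidity and
#' extent to `(0, 1]`; areas and perimeter to positive values).
#'
#' @param class_stats Per-class feature statistics in the format of
#'   [default_feature_stats].
#' @param n_per_class Rows drawn per class (default 272, giving 816 rows
#'   for three classes).
#' @param seed Integer seed.
#' @return `data.frame` with a `class` factor plus the seven feature
#'   columns.
#' @export
generate_feature_table <- function(class_stats = default_feature_stats(),
                                   n_per_class = 272L, seed = 1L) {
  feats <- names(class_stats[[1]]$mean)
  lo <- stats::setNames(rep(1e-3, length(feats)), feats)
  hi <- stats::setNames(rep(Inf, length(feats)), feats)
  hi[c("eccentricity", "solidity", "extent")] <- 1
  lo["eccentricity"] <- 0
  withr::with_seed(seed, {
    rows <- lapply(names(class_stats), function(cl) {
      s <- class_stats[[cl]]
      stopifnot(all(s$sd >= 0))
      m <- vapply(feats, function(f)
        pmin(pmax(stats::rnorm(n_per_class, s$mean[[f]], s$sd[[f]]),
                  lo[[f]]), hi[[f]]),
        numeric(n_per_class))
      cbind(data.frame(class = cl), as.data.frame(m))
    })
    out <- do.call(rbind, rows)
    out$class <- factor(out$class, levels = names(class_stats))
    rownames(out) <- NULL
    out
  })
}

# ---- dilution series ------------------------------------------------------

#' Synthetic serial-dilution series
#'
#' Generates scenes whose expected object counts are the base spec's counts
#' divided by each dilution factor, with the realized counts drawn from a
#' Poisson law (as for discrete counting of a diluted suspension). Seeds
#' per level and replicate derive deterministically from `seed`.
#'
#' @param base_spec A [scene_spec]: the undiluted condition.
#' @param factors Positive dilution factors (default the serial dilution
#'   1, 2, 10, 500, 1000).
#' @param images_per_level Replicate images per dilution level.
#' @param seed Integer seed (defaults to the base spec's).
#' @return List over levels; each element has `factor`,
#'   `expected_counts` and `images` (a list of [generate_scene] results).
#' @export
generate_dilution_series <- function(base_spec,
                                     factors = c(1, 2, 10, 500, 1000),
                                     images_per_level = 1L,
                                     seed = NULL) {
  stopifnot(inherits(base_spec, "scene_spec"), all(factors > 0))
  if (is.null(seed)) seed <- base_spec$seed
  lapply(seq_along(factors), function(i) {
    expected <- base_spec$counts / factors[i]
    images <- lapply(seq_len(images_per_level), function(j) {
      sub_seed <- (seed + 9973L * i + 131L * j) %% .Machine$integer.max
      spec_ij <- base_spec
      spec_ij$seed <- as.integer(sub_seed)
      drawn <- withr::with_seed(sub_seed + 7L,
        stats::rpois(length(expected), expected))
      spec_ij$counts <- stats::setNames(as.integer(drawn), names(expected))
      generate_scene(spec_ij)
    })
    list(factor = factors[i], expected_counts = expected, images = images)
  })
}
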
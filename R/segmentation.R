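#' Learned binary pixel decision
#'
#' Holds the intensity threshold theta separating foreground from background
#' and the between-class variance it attains. Pixels with intensity >= theta
#' are foreground.
#'
#' @param theta Threshold on the native intensity scale.
#' @param between_class_variance Between-class variance attained at `theta`.
#' @param bit_depth Bit depth of the image the decision was learned on.
#' @return An object of class `binary_decision`.
#' @export
binary_decision <- function(theta, between_class_variance, bit_depth) {
  stopifnot(theta >= 0, theta <= 2^bit_depth - 1,
            between_class_variance >= 0)
  structure(list(theta = theta,
                 between_class_variance = between_class_variance,
                 bit_depth = as.integer(bit_depth)),
            class = "binary_decision")
}

#' @export
print.binary_decision <- function(x, ...) {
  cat(sprintf("<binary_decision> theta = %g (%d-bit), sigma2_B = %g\n",
              x$theta, x$bit_depth, x$between_class_variance))
  invisible(x)
}

#' Label field: foreground mask and connected-component labels
#'
#' @param mask Logical matrix, `TRUE` on foreground.
#' @param labels Optional integer matrix: labels `1..n_components` on
#'   foreground pixels, 0 on background.
#' @param n_components Number of components (`NA` if not yet labelled).
#' @param filtered_px Number of foreground pixels removed by the minimum-area
#'   filter during labelling.
#' @return An object of class `label_field`.
#' @export
label_field <- function(mask, labels = NULL, n_components = NA_integer_,
                        filtered_px = 0L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!is.null(labels)) {
    stopifnot(identical(dim(labels), dim(mask)))
    if (any((labels > 0L) != mask))
      stop("labels must be positive exactly on foreground pixels",
           call. = FALSE)
  }
  structure(list(mask = mask, labels = labels,
                 n_components = as.integer(n_components),
                 filtered_px = as.integer(filtered_px)),
            class = "label_field")
}

#' @export
print.label_field <- function(x, ...) {
  cat(sprintf("<label_field> %d x %d, %d fg px, %s components\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              ifelse(is.na(x$n_components), "unlabelled",
                     as.character(x$n_components))))
  invisible(x)
}

#' Learn the foreground threshold by between-class-variance maximization
#'
#' Chooses the intensity threshold theta that maximizes the between-class
#' variance of the background/foreground split of the training pixels (the
#' Otsu criterion). No distributional assumption is made about either class.
#' For 8-bit images every native gray level is a candidate; deeper images
#' are binned to 256 equal-width bins for the search and theta is mapped
#' back to the native scale (the lower edge of the winning bin). Among
#' thresholds attaining the maximal variance the lowest is returned.
#'
#' @param image A [mono_image].
#' @param training_region Optional rectangle `c(row0, col0, row1, col1)`
#'   restricting the training pixels; default is the whole image.
#' @return A [binary_decision].
#' @export
learn_threshold <- function(image, training_region = NULL) {
  stopifnot(inherits(image, "mono_image"))
  px <- image$pixels
  if (!is.null(training_region)) {
    r <- as.integer(training_region)
    if (length(r) != 4L || r[1] < 1L || r[2] < 1L ||
        r[3] > nrow(px) || r[4] > ncol(px) || r[1] > r[3] || r[2] > r[4])
      stop("`training_region` must be c(row0, col0, row1, col1) within the image",
           call. = FALSE)
    px <- px[r[1]:r[3], r[2]:r[4], drop = FALSE]
  }
  v <- as.vector(px)
  if (min(v) == max(v))
    stop("constant training region: no foreground/background split exists",
         call. = FALSE)
  levels_total <- 2^image$bit_depth
  if (levels_total <= 256) {
    bin_width <- 1
    nbins <- levels_total
    idx <- v + 1L                       # level k -> bin k+1
  } else {
    bin_width <- levels_total / 256
    nbins <- 256L
    idx <- pmin(floor(v / bin_width), 255) + 1L
  }
  counts <- tabulate(idx, nbins = nbins)
  n <- length(v)
  mids <- (seq_len(nbins) - 0.5) * bin_width   # bin-centre intensities
  w0 <- cumsum(counts) / n                     # P(class b), split after bin k
  s0 <- cumsum(counts * mids) / n
  mu <- s0[nbins]
  # threshold candidate theta_k = lower edge of bin k+1: background = bins <= k
  w0 <- w0[-nbins]; s0 <- s0[-nbins]
  valid <- w0 > 0 & w0 < 1
  sigma2 <- rep(0, nbins - 1L)
  sigma2[valid] <- (mu * w0[valid] - s0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  k <- which.max(sigma2)                       # which.max returns lowest tie
  binary_decision(theta = k * bin_width,
                  between_class_variance = sigma2[k],
                  bit_depth = image$bit_depth)
}

#' Apply a learned decision to an image
#'
#' Pixels with intensity >= theta are classified foreground; the boundary
#' value itself is foreground.
#'
#' @param image A [mono_image].
#' @param decision A [binary_decision] learned at the same bit depth.
#' @return A [label_field] carrying the mask (components not yet labelled).
#' @export
binarize <- function(image, decision) {
  stopifnot(inherits(image, "mono_image"),
            inherits(decision, "binary_decision"))
  if (image$bit_depth != decision$bit_depth)
    stop("bit depth mismatch between image (", image$bit_depth,
         ") and decision (", decision$bit_depth, ")", call. = FALSE)
  label_field(mask = image$pixels >= decision$theta)
}

#' Label connected foreground components
#'
#' Maximal connected foreground regions are labelled under the requested
#' pixel adjacency. Regions smaller than `min_area_px` are removed (their
#' pixel count is recorded in the result's `filtered_px`). Labels are
#' assigned in raster-scan order (row-major) of each component's first
#' pixel, so labelling is deterministic.
#'
#' @param mask Logical matrix or a [label_field].
#' @param connectivity 4 or 8 (default 8, which keeps diagonally joined
#'   filament segments in one component).
#' @param min_area_px Minimum component area in pixels (default 4).
#' @return A [label_field] with `labels` and `n_components` set.
#' @export
connected_components <- function(mask, connectivity = 8L, min_area_px = 4L) {
  if (inherits(mask, "label_field")) mask <- mask$mask
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!connectivity %in% c(4L, 8L))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)                     # column-major indices
  labels <- matrix(0L, nr, nc)
  if (length(fg) == 0L)
    return(label_field(mask, labels, 0L, 0L))

  vid <- integer(nr * nc); vid[fg] <- seq_along(fg)
  row_of <- ((fg - 1L) %% nr) + 1L
  col_of <- ((fg - 1L) %/% nr) + 1L
  edge_list <- list()
  add_edges <- function(dr, dc) {
    ok <- row_of + dr >= 1L & row_of + dr <= nr &
      col_of + dc >= 1L & col_of + dc <= nc
    nb <- fg[ok] + dr + dc * nr
    src <- vid[fg[ok]]; dst <- vid[nb]
    keep <- dst > 0L
    cbind(src[keep], dst[keep])
  }
  edge_list[[1]] <- add_edges(1L, 0L)   # down
  edge_list[[2]] <- add_edges(0L, 1L)   # right
  if (connectivity == 8L) {
    edge_list[[3]] <- add_edges(1L, 1L)   # down-right
    edge_list[[4]] <- add_edges(-1L, 1L)  # up-right
  }
  edges <- do.call(rbind, edge_list)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership

  sizes <- tabulate(memb)
  keep_comp <- sizes >= min_area_px
  filtered_px <- sum(sizes[!keep_comp])
  # raster-scan (row-major) order of each component's first pixel
  rm_order <- order(row_of, col_of)
  first_seen <- memb[rm_order][!duplicated(memb[rm_order])]
  new_id <- integer(length(sizes))
  new_id[first_seen[keep_comp[first_seen]]] <-
    seq_len(sum(keep_comp))
  lab_px <- new_id[memb]
  labels[fg] <- lab_px
  mask_out <- mask
  mask_out[fg[lab_px == 0L]] <- FALSE
  label_field(mask_out, labels, n_components = sum(keep_comp),
              filtered_px = filtered_px)
}

#' Segment an image end to end
#'
#' Convenience wrapper: learn the threshold, binarize, and label connected
#' components with the configured connectivity and minimum area.
#'
#' @param image A [mono_image].
#' @param config A [run_config].
#' @param training_region Optional training rectangle for threshold learning.
#' @return List with `decision` (a [binary_decision]) and `field`
#'   (a labelled [label_field]).
#' @export
segment_image <- function(image, config, training_region = NULL) {
  decision <- learn_threshold(image, training_region)
  lf <- binarize(image, decision)
  field <- connected_components(lf$mask, config$connectivity,
                                config$min_component_area_px)
  list(decision = decision, field = field)
}
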
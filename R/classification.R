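# Component classification: threshold rule cascade for the two-species
# case, quadratic-kernel SVM for three species, and confusion-matrix
# derived performance metrics.

#' Decision boundaries of the rule classifier
#'
#' The six empirical boundaries of the two-species rule cascade: omega on
#' eccentricity, tau on compactness, and per-species lower/upper area
#' bounds (in px^2). A component y is assigned
#' \itemize{
#'   \item the filamentous class `C_A` iff
#'     `ecc(y) >= omega & comp(y) <= tau & psi_al <= area(y) <= psi_au`,
#'   \item the unicellular class `C_M` iff
#'     `ecc(y) < omega & comp(y) > tau & psi_ml <= area(y) <= psi_mu`,
#'   \item `C_N` (neither) otherwise.
#' }
#' The defaults omega = 0.70 and tau = 0.80 are midpoints between
#' representative pure-culture values of the two taxa (eccentricity
#' 0.8537 vs 0.5205; compactness 0.6444 vs 0.9834); area bounds default to
#' fully open and are normally set from a unit-cell-area calibration with
#' [rule_thresholds_from_calibration].
#'
#' @param omega Eccentricity boundary in `[0, 1]`.
#' @param tau Compactness boundary, > 0.
#' @param psi_al,psi_au Filamentous-class (Anabaena) area bounds in px^2.
#' @param psi_ml,psi_mu Unicellular-class (Microcystis) area bounds in px^2.
#' @return An object of class `rule_thresholds`.
#' @export
rule_thresholds <- function(omega = 0.70, tau = 0.80,
                            psi_al = 0, psi_au = Inf,
                            psi_ml = 0, psi_mu = Inf) {
  if (omega < 0 || omega > 1) stop("`omega` must be in [0, 1]", call. = FALSE)
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  if (psi_al > psi_au) stop("psi_al must be <= psi_au", call. = FALSE)
  if (psi_ml > psi_mu) stop("psi_ml must be <= psi_mu", call. = FALSE)
  structure(list(omega = omega, tau = tau,
                 psi_al = psi_al, psi_au = psi_au,
                 psi_ml = psi_ml, psi_mu = psi_mu),
            class = "rule_thresholds")
}

#' @export
print.rule_thresholds <- function(x, ...) {
  cat(sprintf(paste0("<rule_thresholds> omega=%g tau=%g ",
                     "psi_A=[%g, %g] psi_M=[%g, %g] px^2\n"),
              x$omega, x$tau, x$psi_al, x$psi_au, x$psi_ml, x$psi_mu))
  invisible(x)
}

#' Derive rule thresholds from unit-cell-area calibrations
#'
#' Converts calibrated unit-cell areas (um^2) into component-area bounds in
#' px^2. For the unicellular class a component is a single cell, so its
#' bounds span a moderate factor around one unit-cell area. For the
#' filamentous class a component is a whole filament of many cells, so the
#' upper bound must admit long chains: the default span reaches 200
#' unit-cell areas.
#'
#' @param cal_anabaena,cal_microcystis [calibration_model] objects (either
#'   may be `NULL` to leave that species' bounds open).
#' @param um_per_pixel Spatial calibration in micrometres per pixel.
#' @param omega,tau Shape boundaries, see [rule_thresholds].
#' @param anabaena_span,microcystis_span Multiples of the unit-cell area
#'   giving `[lower, upper]` bounds.
#' @return A [rule_thresholds].
#' @export
rule_thresholds_from_calibration <- function(cal_anabaena = NULL,
                                             cal_microcystis = NULL,
                                             um_per_pixel,
                                             omega = 0.70, tau = 0.80,
                                             anabaena_span = c(0.5, 200),
                                             microcystis_span = c(0.25, 4)) {
  stopifnot(um_per_pixel > 0)
  px2 <- um_per_pixel^2
  a_bounds <- c(0, Inf)
  m_bounds <- c(0, Inf)
  if (!is.null(cal_anabaena)) {
    stopifnot(inherits(cal_anabaena, "calibration_model"))
    a_bounds <- anabaena_span * cal_anabaena$unit_cell_area_um2 / px2
  }
  if (!is.null(cal_microcystis)) {
    stopifnot(inherits(cal_microcystis, "calibration_model"))
    m_bounds <- microcystis_span * cal_microcystis$unit_cell_area_um2 / px2
  }
  rule_thresholds(omega = omega, tau = tau,
                  psi_al = a_bounds[1], psi_au = a_bounds[2],
                  psi_ml = m_bounds[1], psi_mu = m_bounds[2])
}

#' Class labels used by the classifiers
#' @return Character vector of the recognised labels: `C_A` (Anabaena,
#'   filamentous), `C_M` (Microcystis, unicellular), `C_K`
#'   (Ankistrodesmus, needle/spindle), `C_N` (neither).
#' @export
class_labels <- function() c("C_A", "C_M", "C_K", "C_N")

#' Rule-cascade classification of components
#'
#' Applies the two-species threshold rule (see [rule_thresholds]) to each
#' component. Boundary inclusivity follows the rule exactly: the
#' filamentous branch uses `>=`/`<=` on eccentricity and compactness, the
#' unicellular branch strict `<`/`>`, so the two branches are disjoint by
#' construction and every component receives exactly one label.
#'
#' @param features `data.frame` with columns `eccentricity`, `compactness`
#'   and `area_px` (as produced by [featurize]), or a single-row record.
#' @param thresholds A [rule_thresholds].
#' @return Factor of labels `C_A`, `C_M`, `C_N` (levels from
#'   [class_labels]).
#' @export
classify_rule <- function(features, thresholds = rule_thresholds()) {
  stopifnot(inherits(thresholds, "rule_thresholds"))
  need <- c("eccentricity", "compactness", "area_px")
  if (!all(need %in% names(features)))
    stop("`features` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  e <- features$eccentricity
  cc <- features$compactness
  a <- features$area_px
  is_a <- e >= thresholds$omega & cc <= thresholds$tau &
    a >= thresholds$psi_al & a <= thresholds$psi_au
  is_m <- e < thresholds$omega & cc > thresholds$tau &
    a >= thresholds$psi_ml & a <= thresholds$psi_mu
  out <- rep("C_N", length(e))
  out[is_a] <- "C_A"
  out[is_m] <- "C_M"
  factor(out, levels = class_labels())
}

#' Confusion matrix of true vs predicted labels
#'
#' @param truth,predicted Vectors of class labels of equal length.
#' @param classes Optional class ordering; defaults to the union of levels
#'   encountered.
#' @return An object of class `confusion_matrix`: integer matrix `counts`
#'   (rows = true class, cols = predicted class) and `class_names`.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted))
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  if (is.null(classes))
    classes <- union(levels(factor(truth)), levels(factor(predicted)))
  t_f <- factor(truth, levels = classes)
  p_f <- factor(predicted, levels = classes)
  counts <- unclass(table(truth = t_f, predicted = p_f))
  structure(list(counts = counts, class_names = classes),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = truth, cols = predicted\n")
  print(x$counts)
  invisible(x)
}

#' Train a quadratic-kernel support-vector machine on morphological features
#'
#' Fits a polynomial-kernel SVM (degree 2 by default, i.e. a quadratic
#' kernel) to a labelled feature table. Columns are standardized to z-scores
#' before kernel evaluation and the standardization parameters are stored
#' with the model. Multi-class problems use the one-vs-one reduction. The
#' canonical feature set is the seven morphological descriptors (area,
#' eccentricity, compactness, convex area, solidity, extent, perimeter),
#' but any all-numeric table is accepted.
#'
#' @param features Numeric `data.frame`/matrix, one row per component.
#' @param labels Class labels, length `nrow(features)`.
#' @param kernel_degree Polynomial degree (default 2).
#' @param cost Soft-margin regularization constant (default 1).
#' @param seed Integer seed (training is deterministic given the data; the
#'   seed is recorded and used for any randomized sub-steps).
#' @return An object of class `cell_svm`.
#' @export
train_svm <- function(features, labels, kernel_degree = 2L, cost = 1,
                      seed = 1L) {
  x <- as.data.frame(features)
  if (!all(vapply(x, is.numeric, TRUE)))
    stop("all feature columns must be numeric", call. = FALSE)
  if (!all(is.finite(as.matrix(x))))
    stop("non-finite feature values", call. = FALSE)
  y <- factor(labels)
  if (nlevels(y) < 2L)
    stop("need at least two classes to train a classifier", call. = FALSE)
  if (nrow(x) < 2L * nlevels(y))
    stop("need at least 2 rows per class", call. = FALSE)
  fit <- withr::with_seed(seed,
    e1071::svm(x = x, y = y, kernel = "polynomial",
               degree = kernel_degree, coef0 = 1, cost = cost,
               scale = TRUE))
  structure(list(fit = fit, feature_names = colnames(x),
                 levels = levels(y), kernel_degree = kernel_degree,
                 cost = cost, seed = as.integer(seed)),
            class = "cell_svm")
}

#' @export
predict.cell_svm <- function(object, newdata, ...) {
  x <- as.data.frame(newdata)
  missing <- setdiff(object$feature_names, colnames(x))
  if (length(missing))
    stop("newdata lacks feature column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  stats::predict(object$fit, x[, object$feature_names, drop = FALSE], ...)
}

#' @export
print.cell_svm <- function(x, ...) {
  cat(sprintf("<cell_svm> degree-%d polynomial kernel, %d classes, %d SVs\n",
              x$kernel_degree, length(x$levels), x$fit$tot.nSV))
  invisible(x)
}

#' Stratified k-fold cross-validation of the SVM classifier
#'
#' Splits each class separately into `k` folds (seeded, so reproducible),
#' trains on k-1 folds and predicts the held-out fold, so every instance is
#' predicted exactly once. Accuracy is the trace of the pooled confusion
#' matrix over its total.
#'
#' @param features,labels As in [train_svm].
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @param kernel_degree,cost Forwarded to [train_svm].
#' @return List with `accuracy` and `confusion` (a [confusion_matrix]).
#' @export
cross_validate <- function(features, labels, k = 5L, seed = 1L,
                           kernel_degree = 2L, cost = 1) {
  x <- as.data.frame(features)
  y <- factor(labels)
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  sizes <- table(y)
  if (any(sizes < k))
    stop("class ", names(sizes)[which(sizes < k)[1]],
         " has fewer than k = ", k, " members", call. = FALSE)
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      ix <- which(y == cl)
      fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  })
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- train_svm(x[tr, , drop = FALSE], y[tr],
                       kernel_degree = kernel_degree, cost = cost,
                       seed = seed + f)
    pred[!tr] <- predict(model, x[!tr, , drop = FALSE])
  }
  cm <- confusion_matrix(y, pred, classes = levels(y))
  list(accuracy = sum(diag(cm$counts)) / sum(cm$counts), confusion = cm)
}

#' One-vs-rest performance metrics from a confusion matrix
#'
#' Reduces the matrix to TP/TN/FP/FN for the given positive class and
#' returns specificity `TN/(TN+FP)`, sensitivity (= recall) `TP/(TP+FN)`,
#' accuracy `(TN+TP)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)` and the F1
#' score (harmonic mean of precision and recall). A ratio with a zero
#' denominator is undefined and reported as `NA` with a warning, never
#' as 0.
#'
#' @param matrix A [confusion_matrix].
#' @param positive_class Name of the class treated as positive.
#' @return Named list: `specificity`, `sensitivity`, `accuracy`,
#'   `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(matrix, positive_class) {
  stopifnot(inherits(matrix, "confusion_matrix"))
  cm <- matrix$counts
  if (sum(cm) == 0L) stop("empty confusion matrix", call. = FALSE)
  if (!positive_class %in% matrix$class_names)
    stop("class ", positive_class, " not present in matrix", call. = FALSE)
  p <- positive_class
  tp <- cm[p, p]
  fn <- sum(cm[p, ]) - tp
  fp <- sum(cm[, p]) - tp
  tn <- sum(cm) - tp - fn - fp
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  specificity <- safe_div(tn, tn + fp, "specificity")
  recall <- safe_div(tp, tp + fn, "sensitivity/recall")
  precision <- safe_div(tp, tp + fp, "precision")
  accuracy <- (tn + tp) / (tp + tn + fp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    if (is.na(precision) || is.na(recall))
      warning("F1 undefined", call. = FALSE)
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  list(specificity = specificity, sensitivity = recall,
       accuracy = accuracy, precision = precision, recall = recall,
       f1 = f1)
}

#' Macro-averaged one-vs-rest metrics
#'
#' Averages [classification_metrics] over every class of the matrix.
#'
#' @param matrix A [confusion_matrix].
#' @return Named list of macro-averaged metrics.
#' @export
macro_metrics <- function(matrix) {
  stopifnot(inherits(matrix, "confusion_matrix"))
  per <- lapply(matrix$class_names, classification_metrics, matrix = matrix)
  nm <- names(per[[1]])
  out <- lapply(nm, function(m)
    mean(vapply(per, function(x) x[[m]], 0), na.rm = TRUE))
  names(out) <- nm
  out
}
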
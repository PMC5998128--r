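test_that("the rule cascade separates representative culture feature values", {
  thr <- rule_thresholds()                 # omega 0.70, tau 0.80, open areas
  anab <- data.frame(eccentricity = 0.8537, compactness = 0.6444,
                     area_px = 150)
  micro <- data.frame(eccentricity = 0.5205, compactness = 0.9834,
                      area_px = 60)
  expect_equal(as.character(classify_rule(anab, thr)), "C_A")
  expect_equal(as.character(classify_rule(micro, thr)), "C_M")
})

test_that("rule boundaries are inclusive for the filamentous branch", {
  thr <- rule_thresholds(psi_al = 10, psi_au = 1000, psi_ml = 10,
                         psi_mu = 1000)
  on_boundary <- data.frame(eccentricity = thr$omega,
                            compactness = thr$tau, area_px = 100)
  expect_equal(as.character(classify_rule(on_boundary, thr)), "C_A")
  # strictly inside the unicellular branch
  uni <- data.frame(eccentricity = thr$omega - 1e-9,
                    compactness = thr$tau + 1e-9, area_px = 100)
  expect_equal(as.character(classify_rule(uni, thr)), "C_M")
  # area outside both windows falls through to neither
  out <- data.frame(eccentricity = 0.9, compactness = 0.5, area_px = 5000)
  expect_equal(as.character(classify_rule(out, thr)), "C_N")
})

test_that("the rule is a partition: every input gets exactly one label and the branches are disjoint", {
  set.seed(17)
  thr <- rule_thresholds(psi_al = 20, psi_au = 5000, psi_ml = 10,
                         psi_mu = 300)
  f <- data.frame(eccentricity = runif(500),
                  compactness = runif(500, 0, 1.5),
                  area_px = runif(500, 1, 6000))
  lab <- classify_rule(f, thr)
  expect_equal(length(lab), 500L)
  expect_false(anyNA(lab))
  in_a <- f$eccentricity >= thr$omega & f$compactness <= thr$tau &
    f$area_px >= thr$psi_al & f$area_px <= thr$psi_au
  in_m <- f$eccentricity < thr$omega & f$compactness > thr$tau &
    f$area_px >= thr$psi_ml & f$area_px <= thr$psi_mu
  expect_false(any(in_a & in_m))
  expect_identical(as.character(lab),
                   ifelse(in_a, "C_A", ifelse(in_m, "C_M", "C_N")))
})

test_that("thresholds derived from calibration bracket single cells and filaments", {
  cal_a <- suppressWarnings(calibration_model("C_A", 26.8, 2.5, 100))
  cal_m <- calibration_model("C_M", 24.6, 3.4, 100)
  thr <- rule_thresholds_from_calibration(cal_a, cal_m, um_per_pixel = 0.645)
  unit_m_px <- 24.6 / 0.645^2
  unit_a_px <- 26.8 / 0.645^2
  expect_equal(thr$psi_ml, 0.25 * unit_m_px)
  expect_equal(thr$psi_mu, 4 * unit_m_px)
  expect_lte(thr$psi_al, unit_a_px)       # single sonicated fragments pass
  expect_gte(thr$psi_au, 100 * unit_a_px) # long filaments pass
  expect_error(rule_thresholds(omega = 1.2), "omega")
  expect_error(rule_thresholds(psi_al = 10, psi_au = 5), "psi_al")
})

test_that("SVM training handles separable data, rejects degenerate input, and ignores duplication", {
  set.seed(23)
  n <- 40
  x <- data.frame(a = c(rnorm(n, 0), rnorm(n, 10)),
                  b = rnorm(2 * n), c = rnorm(2 * n), d = rnorm(2 * n),
                  e = rnorm(2 * n), f = rnorm(2 * n), g = rnorm(2 * n))
  y <- rep(c("u", "v"), each = n)
  model <- train_svm(x, y, seed = 1)
  expect_equal(mean(predict(model, x) == y), 1)

  doubled <- train_svm(rbind(x, x), c(y, y), seed = 1)
  grid <- x[sample(2 * n, 25), ]
  expect_identical(as.character(predict(model, grid)),
                   as.character(predict(doubled, grid)))

  expect_error(train_svm(x, rep("u", 2 * n)), "two classes")
  x_bad <- x; x_bad$a[1] <- NA
  expect_error(train_svm(x_bad, y), "non-finite")
})

test_that("stratified cross-validation predicts each instance once and is seed-stable", {
  tab <- generate_feature_table(n_per_class = 40, seed = 2)
  cv1 <- cross_validate(tab[, -1], tab$class, k = 5, seed = 9)
  cv2 <- cross_validate(tab[, -1], tab$class, k = 5, seed = 9)
  expect_equal(cv1$accuracy, cv2$accuracy)
  expect_equal(sum(cv1$confusion$counts), nrow(tab))
  expect_true(all(rowSums(cv1$confusion$counts) == 40))
  expect_error(cross_validate(tab[, -1], tab$class, k = 50),
               "fewer than k")
})

test_that("CV accuracy collapses to chance under label permutation", {
  tab <- generate_feature_table(n_per_class = 60, seed = 4)
  perm <- withr::with_seed(99, sample(tab$class))
  cv <- cross_validate(tab[, -1], perm, k = 5, seed = 4)
  expect_lt(abs(cv$accuracy - 1 / 3), 0.1)
})

test_that("confusion-matrix metrics match hand arithmetic and flag undefined ratios", {
  cm <- cm_from_counts(tp = 50, tn = 40, fp = 10, fn = 0)
  m <- classification_metrics(cm, "pos")
  expect_equal(m$precision, 50 / 60, tolerance = 1e-12)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 2 * (50 / 60) / (50 / 60 + 1), tolerance = 1e-12)
  expect_equal(m$accuracy, 0.9, tolerance = 1e-12)
  expect_equal(m$specificity, 0.8, tolerance = 1e-12)
  expect_equal(m$sensitivity, m$recall)

  perfect <- cm_from_counts(tp = 30, tn = 70, fp = 0, fn = 0)
  mp <- classification_metrics(perfect, "pos")
  expect_true(all(unlist(mp) == 1))

  degenerate <- cm_from_counts(tp = 0, tn = 90, fp = 0, fn = 10)
  expect_warning(
    expect_warning(md <- classification_metrics(degenerate, "pos"),
                   "precision undefined"),
    "F1 undefined")
  expect_true(is.na(md$precision))
  expect_true(is.na(md$f1))
  expect_error(classification_metrics(cm, "nope"), "not present")
})

test_that("F1 lies between min and max of precision and recall", {
  set.seed(31)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    counts <- matrix(rpois(k * k, 8), k, k,
                     dimnames = list(paste0("c", 1:k), paste0("c", 1:k)))
    if (sum(counts) == 0) next
    cm <- structure(list(counts = counts,
                         class_names = paste0("c", 1:k)),
                    class = "confusion_matrix")
    m <- suppressWarnings(classification_metrics(cm, "c1"))
    if (is.na(m$f1)) next
    expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
  }
})

test_that("macro metrics average the per-class one-vs-rest reductions", {
  cm <- confusion_matrix(rep(c("a", "b"), c(6, 4)),
                         c(rep("a", 5), "b", rep("b", 3), "a"))
  mm <- macro_metrics(cm)
  pa <- classification_metrics(cm, "a")
  pb <- classification_metrics(cm, "b")
  expect_equal(mm$f1, mean(c(pa$f1, pb$f1)))
  expect_equal(mm$accuracy, pa$accuracy)  # same trace for both reductions
})
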
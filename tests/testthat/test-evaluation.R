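test_that("stratified k-fold preserves per-class proportions within one sample", {
  labels <- rep(fdt_classes(), times = c(10, 10, 10, 10))
  fa <- stratified_split(labels, "kfold", k = 5)
  expect_equal(sort(unique(fa$assignment)), 1:5)
  for (f in 1:5) {
    tab <- table(labels[fa$assignment == f])
    expect_true(all(tab == 2))    # 10 per class / 5 folds
  }
  # arbitrary label vectors: fold sizes per class differ by at most 1
  fdtaudit:::with_seed(14, {
    for (i in 1:10) {
      lab <- sample(letters[1:3], 60, replace = TRUE, prob = c(0.5, 0.3, 0.2))
      if (min(table(lab)) < 4) next
      fa <- stratified_split(lab, "kfold", k = 4, seed = i)
      for (cl in unique(lab)) {
        sizes <- table(factor(fa$assignment[lab == cl], levels = 1:4))
        expect_lte(max(sizes) - min(sizes), 1)
      }
    }
  })
  expect_error(stratified_split(c("a", "a", "b"), "kfold", k = 5), "fewer samples")
})

test_that("holdout split is stratified 80/10/10 and deterministic", {
  labels <- rep(fdt_classes(), times = c(20, 22, 28, 30))
  fa <- stratified_split(labels, "holdout", seed = 42)
  fb <- stratified_split(labels, "holdout", seed = 42)
  expect_identical(fa$assignment, fb$assignment)
  tab <- table(fa$assignment)
  expect_equal(sum(tab), 100)
  expect_equal(unname(tab["test"]), 10, tolerance = 0)
  # test-set class proportions within +/- 1 sample of the cohort proportions
  test_tab <- table(factor(labels[fa$assignment == "test"], levels = fdt_classes()))
  expect_true(all(abs(test_tab - c(2, 2.2, 2.8, 3)) <= 1))
})

test_that("the classification report matches hand-computed values on a 2-class toy problem", {
  y_true <- c("A", "A", "B", "B")
  y_pred <- c("A", "B", "B", "B")
  rep <- classification_report(y_true, y_pred)
  expect_equal(unname(rep$precision["A"]), 1.0)
  expect_equal(unname(rep$recall["A"]), 0.5)
  expect_equal(unname(rep$f1["A"]), 2 / 3)
  expect_equal(unname(rep$precision["B"]), 2 / 3)
  expect_equal(unname(rep$recall["B"]), 1.0)
  expect_equal(unname(rep$f1["B"]), 0.8)
  expect_equal(rep$macro_f1, (2 / 3 + 0.8) / 2)
  expect_equal(rep$accuracy, 0.75)
  # weighted-F1 is the support-weighted mean
  expect_equal(rep$weighted_f1, (2 * (2 / 3) + 2 * 0.8) / 4)
  # normalized confusion rows sum to 1
  expect_equal(unname(rowSums(rep$confusion_normalized)), c(1, 1))
})

test_that("perfect and inverted predictions bound accuracy, F1 and AUC", {
  y <- rep(fdt_classes(), each = 5)
  scores <- matrix(0, 20, 4)
  scores[cbind(1:20, rep(1:4, each = 5))] <- 1
  rep <- classification_report(y, y, scores)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$macro_f1, 1)
  expect_equal(rep$macro_auc, 1)
  # anti-correlated scores: per-class AUC 0
  rep2 <- classification_report(y, y, 1 - scores)
  expect_equal(unname(rep2$per_class_auc), rep(0, 4))
})

test_that("macro-F1 is invariant under class relabeling", {
  fdtaudit:::with_seed(19, {
    y_true <- sample(fdt_classes(), 80, replace = TRUE)
    y_pred <- sample(fdt_classes(), 80, replace = TRUE)
  })
  r1 <- classification_report(y_true, y_pred)
  perm <- c(glioma = "meningioma", meningioma = "pituitary",
            pituitary = "no_tumor", no_tumor = "glioma")
  r2 <- classification_report(unname(perm[y_true]), unname(perm[y_pred]))
  expect_equal(r1$macro_f1, r2$macro_f1)
  expect_equal(r1$accuracy, r2$accuracy)
})

test_that("one-vs-rest AUC matches an established ROC implementation and is monotone-invariant", {
  skip_if_not_installed("pROC")
  fdtaudit:::with_seed(23, {
    for (i in 1:5) {
      y <- sample(c(0, 1), 40, replace = TRUE)
      if (length(unique(y)) < 2) next
      s <- round(stats::runif(40), 2)   # rounded scores force ties
      ours <- fdtaudit:::auc_ovr(s, y == 1)
      ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
      expect_equal(ours, ref, tolerance = 1e-12)
      # strictly monotone transform leaves AUC unchanged
      expect_equal(fdtaudit:::auc_ovr(exp(3 * s), y == 1), ours)
    }
  })
})

test_that("bootstrap CIs are deterministic, degenerate for perfect predictions, and match binomial width", {
  y <- rep("A", 30)
  ci <- bootstrap_ci(y, y, seed = 5)
  expect_equal(ci$lower, 1)
  expect_equal(ci$upper, 1)

  fdtaudit:::with_seed(7, {
    y_true <- sample(fdt_classes(), 1000, replace = TRUE)
    y_pred <- ifelse(stats::runif(1000) < 0.9, y_true,
                     sample(fdt_classes(), 1000, replace = TRUE))
  })
  a <- bootstrap_ci(y_true, y_pred, seed = 11)
  b <- bootstrap_ci(y_true, y_pred, seed = 11)
  expect_identical(a, b)
  # percentile CI width ~ 2 * 1.96 * sqrt(p(1-p)/n)
  p <- a$point
  expected_width <- 2 * 1.96 * sqrt(p * (1 - p) / 1000)
  expect_lt(abs((a$upper - a$lower) - expected_width), 0.012)
})

test_that("metrics reports serialize to JSON and CSV and predictions export as CSV", {
  rep <- classification_report(c("A", "A", "B"), c("A", "B", "B"))
  stem <- file.path(withr::local_tempdir(), "report")
  write_metrics_report(rep, stem)
  back <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(back$accuracy, rep$accuracy)
  expect_equal(back$macro_f1, rep$macro_f1)
  tab <- utils::read.csv(paste0(stem, ".csv"))
  expect_equal(tab$class, c("A", "B"))

  dir <- withr::local_tempdir()
  co <- generate_cohort(c(1, 0, 0, 1), image_size = 48, seed = 2)
  manifest <- write_cohort(co, dir)
  csv <- file.path(dir, "preds.csv")
  preds <- export_predictions(oracle_predictor(), manifest, csv)
  expect_equal(nrow(preds), 2)
  expect_true(file.exists(csv))
  expect_equal(preds$class, c("glioma", "no_tumor"))
})

test_that("confusion matrices render to PNG", {
  rep <- classification_report(c("A", "B"), c("A", "B"))
  path <- withr::local_tempfile(fileext = ".png")
  plot_confusion_png(rep, path)
  expect_true(file.size(path) > 0)
})
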
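## Partitioning protocols and the metric suite: stratified holdout
## (80/10/10) and stratified 5-fold assignment, per-class
## precision/recall/F1, macro and support-weighted F1, one-vs-rest
## macro-AUC with midrank tie handling, row-normalized confusion
## matrices, and percentile bootstrap confidence intervals.

#' Stratified partitioning of a label vector
#'
#' Deterministic given the seed. For `protocol = "holdout"` every class
#' is shuffled and split 80/10/10 into train/val/test; for
#' `protocol = "kfold"` each class is dealt round-robin into `k` folds
#' after shuffling, so per-class fold sizes differ by at most one sample.
#'
#' @param labels Character or factor vector of class labels.
#' @param protocol `"holdout"` or `"kfold"`.
#' @param k Number of folds for k-fold (default 5).
#' @param fractions Train/val/test fractions for holdout.
#' @param seed RNG seed (default 42).
#' @return Object of class `fdt_fold_assignment`: `assignment` (character
#'   vector "train"/"val"/"test", or integer fold ids), `protocol`,
#'   `seed`.
#' @export
stratified_split <- function(labels, protocol = c("holdout", "kfold"),
                             k = 5L, fractions = c(0.8, 0.1, 0.1),
                             seed = 42L) {
  protocol <- match.arg(protocol)
  labels <- as.character(labels)
  n <- length(labels)
  if (protocol == "kfold") {
    assignment <- integer(n)
    with_seed(seed, {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        if (length(idx) < k) stop_fdt("class '", cl, "' has fewer samples than folds")
        idx <- sample(idx)
        assignment[idx] <- rep_len(seq_len(k), length(idx))
      }
    })
  } else {
    if (abs(sum(fractions) - 1) > 1e-9) stop_fdt("holdout fractions must sum to 1")
    assignment <- character(n)
    with_seed(seed, {
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        m <- length(idx)
        n_train <- round(fractions[1] * m)
        n_val <- round(fractions[2] * m)
        n_val <- min(n_val, m - n_train)
        parts <- rep("test", m)
        parts[seq_len(n_train)] <- "train"
        if (n_val > 0) parts[n_train + seq_len(n_val)] <- "val"
        assignment[idx] <- parts
      }
    })
  }
  structure(list(assignment = assignment, protocol = protocol,
                 k = if (protocol == "kfold") as.integer(k) else NA_integer_,
                 seed = as.integer(seed)),
            class = "fdt_fold_assignment")
}

## one-vs-rest AUC with midrank tie handling (equals trapezoidal ROC area)
auc_ovr <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification report with macro-averaged metrics
#'
#' Computes accuracy, per-class precision/recall/F1, macro-F1 (unweighted
#' class mean), weighted-F1 (support-weighted mean), macro one-vs-rest
#' AUC (trapezoidal, midrank ties) and the row-normalized confusion
#' matrix (each row conditions on the true class).
#'
#' @param y_true,y_pred Aligned label vectors.
#' @param scores Optional matrix of per-class probabilities (columns in
#'   `classes` order) for the AUC.
#' @param classes Class universe; defaults to [fdt_classes()] when all
#'   labels belong to it, otherwise to the sorted observed labels.
#' @return Object of class `fdt_metrics_report`.
#' @export
classification_report <- function(y_true, y_pred, scores = NULL,
                                  classes = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop_fdt("y_true and y_pred lengths differ")
  if (is.null(classes)) {
    obs <- unique(c(y_true, y_pred))
    classes <- if (all(obs %in% fdt_classes())) fdt_classes()[fdt_classes() %in% obs] else sort(obs)
  }
  k <- length(classes)
  cm <- matrix(0, k, k, dimnames = list(true = classes, pred = classes))
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1
  }
  support <- rowSums(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  macro_f1 <- mean(f1)
  weighted_f1 <- sum(f1 * support) / sum(support)
  cm_norm <- cm / ifelse(support > 0, support, 1)
  auc <- rep(NA_real_, k)
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (ncol(scores) != k) stop_fdt("scores must have one column per class")
    for (j in seq_len(k)) {
      if (support[j] == 0) {
        warning("class '", classes[j], "' absent from y_true; AUC undefined, excluded from macro",
                call. = FALSE)
        next
      }
      auc[j] <- auc_ovr(scores[, j], y_true == classes[j])
    }
  }
  structure(list(
    classes = classes,
    accuracy = mean(y_true == y_pred),
    precision = stats::setNames(prec, classes),
    recall = stats::setNames(rec, classes),
    f1 = stats::setNames(f1, classes),
    support = stats::setNames(support, classes),
    macro_f1 = macro_f1,
    weighted_f1 = weighted_f1,
    per_class_auc = stats::setNames(auc, classes),
    macro_auc = if (all(is.na(auc))) NA_real_ else mean(auc, na.rm = TRUE),
    confusion = cm,
    confusion_normalized = cm_norm
  ), class = "fdt_metrics_report")
}

#' @export
print.fdt_metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("Accuracy: %.4f  Macro-F1: %.4f  Weighted-F1: %.4f", x$accuracy, x$macro_f1, x$weighted_f1))
  if (!is.na(x$macro_auc)) cat(sprintf("  Macro-AUC: %.4f", x$macro_auc))
  cat("\n")
  tab <- data.frame(precision = round(x$precision, digits),
                    recall = round(x$recall, digits),
                    f1 = round(x$f1, digits),
                    support = x$support)
  print(tab)
  invisible(x)
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples (y_true, y_pred) pairs i.i.d. with replacement and returns
#' the 2.5/97.5 percentile interval of the metric over resamples.
#'
#' @param y_true,y_pred Aligned label vectors.
#' @param metric Function `(y_true, y_pred) -> number`; default accuracy.
#' @param n_resamples Number of bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed RNG seed.
#' @return List with `point`, `lower`, `upper`, `n_resamples`.
#' @export
bootstrap_ci <- function(y_true, y_pred,
                         metric = function(yt, yp) mean(yt == yp),
                         n_resamples = 1000L, conf = 0.95, seed = 1L) {
  n <- length(y_true)
  if (n < 2) stop_fdt("need at least 2 samples")
  stats_v <- with_seed(seed, vapply(seq_len(n_resamples), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    metric(y_true[idx], y_pred[idx])
  }, numeric(1)))
  qs <- stats::quantile(stats_v, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  list(point = metric(y_true, y_pred), lower = qs[1], upper = qs[2],
       n_resamples = n_resamples)
}

#' Write a metrics report to JSON and CSV
#'
#' @param report An `fdt_metrics_report`.
#' @param stem Output path stem; writes `<stem>.json` (full report) and
#'   `<stem>.csv` (per-class table).
#' @return Invisibly, the two paths written.
#' @export
write_metrics_report <- function(report, stem) {
  stopifnot(inherits(report, "fdt_metrics_report"))
  json_path <- paste0(stem, ".json")
  csv_path <- paste0(stem, ".csv")
  jsonlite::write_json(list(
    accuracy = report$accuracy,
    macro_f1 = report$macro_f1,
    weighted_f1 = report$weighted_f1,
    macro_auc = report$macro_auc,
    per_class = lapply(stats::setNames(report$classes, report$classes), function(cl) {
      list(precision = report$precision[[cl]], recall = report$recall[[cl]],
           f1 = report$f1[[cl]], support = report$support[[cl]],
           auc = report$per_class_auc[[cl]])
    }),
    confusion_normalized = apply(report$confusion_normalized, 1, as.list, simplify = FALSE)
  ), json_path, auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(data.frame(
    class = report$classes,
    precision = report$precision, recall = report$recall, f1 = report$f1,
    support = report$support, auc = report$per_class_auc
  ), csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}

#' Export predictions for a set of slices as CSV
#'
#' One row per slice: slice id, predicted class, and the four softmax
#' columns, in the format consumed by the verifier's audit loop.
#'
#' @param predictor An object with a [predict_slice()] method.
#' @param manifest Data frame or manifest CSV path (`slice_id`, `path`).
#' @param out_csv Output CSV path.
#' @return The predictions data frame, invisibly.
#' @export
export_predictions <- function(predictor, manifest, out_csv) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_slice(manifest$path[i])
    if (!is.null(manifest$label)) attr(img, "fdt_label") <- manifest$label[i]
    p <- predict_slice(predictor, img)
    cbind(data.frame(slice_id = manifest$slice_id[i], class = p$class_label,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(p$softmax)))
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, out_csv, row.names = FALSE)
  invisible(out)
}

#' Render a normalized confusion matrix to PNG
#'
#' @param report An `fdt_metrics_report`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
plot_confusion_png <- function(report, path) {
  stopifnot(inherits(report, "fdt_metrics_report"))
  cm <- report$confusion_normalized
  k <- nrow(cm)
  grDevices::png(path, width = 640, height = 560)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(6, 6, 3, 1))
  graphics::image(seq_len(k), seq_len(k), t(cm[k:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "", zlim = c(0, 1),
                  main = "Normalized confusion matrix")
  graphics::axis(1, at = seq_len(k), labels = colnames(cm), las = 2)
  graphics::axis(2, at = seq_len(k), labels = rev(rownames(cm)), las = 1)
  graphics::mtext("predicted", side = 1, line = 4.5)
  graphics::mtext("true", side = 2, line = 4.5)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    graphics::text(j, k - i + 1, sprintf("%.2f", cm[i, j]),
                   col = if (cm[i, j] > 0.5) "white" else "black")
  }
  invisible(path)
}
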
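#' Inverse-frequency class weights
#'
#' Computes per-class relative frequencies f_c = n_c / sum(n), raw inverse
#' weights w_c = 1 / f_c, and normalized weights
#' w_c_norm = w_c / mean(w), so that the normalized weights sum to the
#' number of classes and average exactly 1. Weights are recomputed from the
#' counts of each training partition, never from global statistics.
#'
#' @param counts Named or unnamed integer vector of per-class sample
#'   counts, in the canonical class order (see [fdt_classes()]) when
#'   unnamed. All counts must be positive: a class with zero samples has
#'   an undefined inverse-frequency weight.
#' @return An object of class `fdt_class_weights`: list with `counts`,
#'   `frequencies`, `raw_weights`, `normalized_weights`.
#' @examples
#' w <- compute_class_weights(c(1608, 1768, 2251, 2413))
#' sum(w$normalized_weights)  # == number of classes
#' @export
compute_class_weights <- function(counts) {
  if (length(counts) < 2L) stop_fdt("need at least two classes")
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop_fdt("all class counts must be positive (zero-count classes have undefined inverse-frequency weight)")
  }
  counts <- as.numeric(counts)
  nm <- names(counts) %||% fdt_classes()[seq_along(counts)]
  f <- counts / sum(counts)
  w <- 1 / f
  w_norm <- w / mean(w)
  out <- list(
    counts = stats::setNames(counts, nm),
    frequencies = stats::setNames(f, nm),
    raw_weights = stats::setNames(w, nm),
    normalized_weights = stats::setNames(w_norm, nm)
  )
  class(out) <- "fdt_class_weights"
  out
}

#' @export
print.fdt_class_weights <- function(x, ...) {
  cat("Inverse-frequency class weights (", length(x$counts), " classes)\n", sep = "")
  tab <- data.frame(
    count = x$counts,
    frequency = round(x$frequencies, 4),
    raw_weight = round(x$raw_weights, 4),
    normalized = round(x$normalized_weights, 4)
  )
  print(tab, ...)
  cat("sum of normalized weights:", format(sum(x$normalized_weights)), "\n")
  invisible(x)
}

#' Class-weighted cross-entropy loss
#'
#' Loss for one sample: `-w_y * log(p_y)` with natural logarithm, where
#' `w_y` is the normalized inverse-frequency weight of the true class and
#' `p_y` the softmax probability assigned to it. For a matrix of softmax
#' rows the mean over samples is returned.
#'
#' @param softmax Numeric vector of class probabilities (one sample), or a
#'   matrix with one row per sample. Rows must sum to 1 (tolerance 1e-6).
#' @param true_label Integer class index/indices (1-based) or class-name
#'   character vector.
#' @param weights An `fdt_class_weights` object, or a numeric vector of
#'   per-class weights (defaults to uniform weight 1).
#' @param eps Probabilities are clamped below at `eps` before the log, with
#'   a warning, to keep the loss finite.
#' @return Mean weighted cross-entropy (a single number).
#' @export
weighted_cross_entropy <- function(softmax, true_label, weights = NULL,
                                   eps = 1e-12) {
  if (is.null(dim(softmax))) softmax <- matrix(softmax, nrow = 1)
  k <- ncol(softmax)
  if (any(abs(rowSums(softmax) - 1) > 1e-6) || any(softmax < -1e-12)) {
    stop_fdt("softmax rows must be non-negative and sum to 1")
  }
  if (is.character(true_label)) {
    true_label <- match(true_label, colnames(softmax) %||% fdt_classes()[seq_len(k)])
  }
  if (any(is.na(true_label)) || any(true_label < 1) || any(true_label > k)) {
    stop_fdt("invalid true_label")
  }
  w <- if (inherits(weights, "fdt_class_weights")) {
    weights$normalized_weights
  } else {
    weights %||% rep(1, k)
  }
  p <- softmax[cbind(seq_len(nrow(softmax)), true_label)]
  if (any(p < eps)) {
    warning("probability of true class below eps; clamped", call. = FALSE)
    p <- pmax(p, eps)
  }
  mean(-w[true_label] * log(p))
}
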
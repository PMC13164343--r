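## Synthetic phantom slices with analytically known symbolic features.
##
## Each phantom is a square grayscale slice in [0,1]: dark background
## (0.1), optional bright skull rim (0.95), and a class-specific lesion
## whose three symbolic features (in-mask intensity variance, central
## y-band overlap, border edge density) are controlled at generation time
## and recorded as exact ground truth.

PHANTOM_BG <- 0.1
PHANTOM_RIM <- 0.95

#' Specification of one synthetic phantom slice
#'
#' @param class_label One of `fdt_classes()`.
#' @param image_size Pixels per side (square), >= 32.
#' @param target_variance Desired population variance of lesion-pixel
#'   intensities, for glioma phantoms. The lesion is a two-level equal-mass
#'   mixture \{1 - 2*sqrt(v), 1.0\}; keeping both levels at or above 0.5
#'   (so Otsu's threshold falls in the background/lesion gap) caps the
#'   reachable variance at 0.0625.
#' @param target_band_overlap Desired fraction of lesion pixels inside the
#'   central 20% y-band, for pituitary phantoms.
#' @param target_border_density Desired Canny edge density in the outer 10%
#'   border band, for meningioma phantoms.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   (applied to the whole slice, then clipped to [0,1]).
#' @param seed Integer RNG seed; generation is deterministic given the spec.
#' @param rim If `TRUE` (default) a bright skull rim is drawn. Rim pixels
#'   join the Otsu foreground, so ground truth (which covers the lesion
#'   only) is recovered exactly only with `rim = FALSE`.
#' @return An object of class `fdt_phantom_spec`.
#' @export
phantom_spec <- function(class_label,
                         image_size = 224L,
                         target_variance = 0.04,
                         target_band_overlap = 0.8,
                         target_border_density = 0.08,
                         noise_sd = 0.01,
                         seed = 1L,
                         rim = TRUE) {
  class_label <- match.arg(class_label, fdt_classes())
  if (image_size < 32) stop_fdt("image_size must be >= 32")
  if (target_variance < 0 || target_variance > 0.25) {
    stop_fdt("target_variance must lie in [0, 0.25]")
  }
  if (target_variance > 0.0625 + 1e-12) {
    stop_fdt("unreachable target_variance: two-level lesions with both levels >= 0.5 cap the variance at 0.0625")
  }
  if (target_band_overlap < 0 || target_band_overlap > 1) {
    stop_fdt("target_band_overlap must lie in [0, 1]")
  }
  if (target_border_density < 0 || target_border_density > 1) {
    stop_fdt("target_border_density must lie in [0, 1]")
  }
  if (noise_sd < 0) stop_fdt("noise_sd must be >= 0")
  structure(list(
    class_label = class_label,
    image_size = as.integer(image_size),
    target_variance = target_variance,
    target_band_overlap = target_band_overlap,
    target_border_density = target_border_density,
    noise_sd = noise_sd,
    seed = as.integer(seed),
    rim = isTRUE(rim)
  ), class = "fdt_phantom_spec")
}

## Evaluate expr under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Deterministic per-slice seed from a master seed and slice index,
## kept below 2^31 (Knuth multiplicative mix on 31-bit arithmetic).
derive_seed <- function(master, index) {
  m <- 2147483647
  s <- (as.numeric(master) %% m) + 1
  s <- (s * 48271) %% m
  s <- (s + as.numeric(index) * 69621) %% m
  as.integer((s * 16807) %% m)
}

## 0-based central 20% y-band rows: [0.4 H, 0.6 H). Returns 1-based indices.
central_band_rows <- function(h) {
  lo <- floor(0.4 * h)        # first 0-based row in band
  hi <- floor(0.6 * h)        # first 0-based row past band
  seq.int(lo + 1L, hi)
}

## logical mask of the outer 10% border band
border_band_mask <- function(h, w = h) {
  m <- ceiling(0.1 * h)
  mw <- ceiling(0.1 * w)
  band <- matrix(TRUE, h, w)
  band[(m + 1):(h - m), (mw + 1):(w - mw)] <- FALSE
  band
}

disc_pixels <- function(h, w, cy, cx, r) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  which((rows - cy)^2 + (cols - cx)^2 <= r^2)
}

#' Generate one synthetic phantom slice
#'
#' Deterministic given the spec (including its seed). Returns the pixel
#' grid together with exact ground-truth symbolic features computed from
#' the construction geometry, before noise: lesion-pixel intensity
#' variance, fraction of lesion pixels in the central y-band, and the
#' predicted border-band Canny edge density.
#'
#' @param spec An [phantom_spec()] object.
#' @return List with `image` (image_size x image_size matrix in [0,1]) and
#'   `truth` (class `fdt_phantom_truth`): `true_features` (variance,
#'   band_overlap, border_density, mask_area) plus the echoed spec.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "fdt_phantom_spec"))
  n <- spec$image_size
  img <- matrix(PHANTOM_BG, n, n)

  lesion_idx <- integer(0)
  lesion_val <- numeric(0)
  border_edge_count <- 0

  band_rows <- central_band_rows(n)
  band_area <- sum(border_band_mask(n))

  if (spec$class_label == "glioma") {
    # off-center disc, two-level equal-mass mixture {1 - 2 sqrt(v), 1}
    r <- 0.16 * n
    cy <- round(0.30 * n); cx <- round(0.62 * n)
    idx <- disc_pixels(n, n, cy, cx, r)
    if (length(idx) %% 2L == 1L) idx <- idx[-length(idx)]  # exact equal split
    s <- 2 * sqrt(spec$target_variance)
    lo <- 1 - s
    vals <- rep(c(lo, 1), length.out = length(idx))
    lesion_idx <- idx
    lesion_val <- vals
  } else if (spec$class_label == "pituitary") {
    # compact bright rectangle; rows placed so that an exact fraction of
    # its area falls in the central y-band
    bh <- max(4L, round(0.12 * n)); bw <- max(4L, round(0.12 * n))
    k <- round(spec$target_band_overlap * bh)      # in-band rows
    if (k > length(band_rows)) stop_fdt("unreachable target_band_overlap for this lesion height")
    r0 <- band_rows[1] - (bh - k)                  # first lesion row
    if (r0 < 1) stop_fdt("lesion does not fit above the central band")
    rows <- seq.int(r0, r0 + bh - 1L)
    cols <- seq.int(round(n / 2 - bw / 2), length.out = bw)
    idx <- as.vector(outer(rows, (cols - 1L) * n, `+`))
    lesion_idx <- idx
    lesion_val <- rep(0.85, length(idx))
  } else if (spec$class_label == "meningioma") {
    # peripheral rectangle flush against the left border, plus short
    # high-contrast stripes in the top/bottom border margins whose count
    # sets the border edge density
    m <- ceiling(0.1 * n)                          # border margin width
    bh <- max(6L, round(0.15 * n)); bw <- max(3L, m - 1L)
    r0 <- round(0.30 * n)
    rows <- seq.int(r0, r0 + bh - 1L)
    cols <- seq.int(1L, bw)
    idx <- as.vector(outer(rows, (cols - 1L) * n, `+`))
    lesion_idx <- idx
    lesion_val <- rep(0.9, length(idx))
    # the blob lies wholly inside the left border band; an edge-flush
    # h x w rectangle on this background yields exactly 2h + 2w - 2
    # Canny edge pixels (calibrated against the detector geometry)
    blob_edges <- 2L * bh + 2L * bw - 2L
    target_edges <- spec$target_border_density * band_area
    stripe_h <- m                                  # flush with the image edge
    if (stripe_h < 3L) stop_fdt("image too small for border texture stripes")
    stripe_w <- 3L
    per_stripe <- 2L * stripe_h + 2L * stripe_w - 2L
    n_stripes <- max(0L, round((target_edges - blob_edges) / per_stripe))
    pitch <- stripe_w + 4L
    cap_per_margin <- floor((n - 2L * m - 2L) / pitch)
    if (n_stripes > 2L * cap_per_margin) {
      stop_fdt("unreachable target_border_density: not enough border-band room for texture stripes")
    }
    stripe_idx <- integer(0)
    for (s_i in seq_len(n_stripes)) {
      margin_top <- s_i %% 2L == 0L
      pos <- ceiling(s_i / 2L)
      c0 <- m + 2L + (pos - 1L) * pitch
      scols <- seq.int(c0, length.out = stripe_w)
      srows <- if (margin_top) seq.int(1L, stripe_h) else seq.int(n - stripe_h + 1L, n)
      stripe_idx <- c(stripe_idx, as.vector(outer(srows, (scols - 1L) * n, `+`)))
    }
    lesion_idx <- c(lesion_idx, stripe_idx)
    lesion_val <- c(lesion_val, rep(0.9, length(stripe_idx)))
    border_edge_count <- blob_edges + n_stripes * per_stripe
  }

  img[lesion_idx] <- lesion_val

  # exact ground truth from the construction (lesion pixels only, no noise)
  if (length(lesion_idx) > 0) {
    v <- lesion_val
    true_var <- mean(v^2) - mean(v)^2
    rows0 <- ((lesion_idx - 1L) %% n) + 1L
    true_overlap <- mean(rows0 %in% band_rows)
  } else {
    true_var <- 0
    true_overlap <- 0
  }
  true_density <- border_edge_count / band_area

  if (spec$rim) {
    ctr <- (n + 1) / 2
    rr <- 0.46 * n
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    d <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
    img[d >= rr - 1.5 & d <= rr + 1.5] <- PHANTOM_RIM
  }

  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed, img + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n))
    img <- pmin(pmax(img, 0), 1)
  }

  truth <- structure(list(
    class_label = spec$class_label,
    true_features = list(
      enhancement_variance = true_var,
      sellar_band_overlap = true_overlap,
      border_edge_density = true_density,
      mask_area = length(lesion_idx)
    ),
    spec = spec
  ), class = "fdt_phantom_truth")

  list(image = img, truth = truth)
}

#' Generate a phantom cohort with controlled class imbalance
#'
#' Produces exactly `class_counts[c]` slices per class, with per-slice
#' seeds derived deterministically from the master seed and feature
#' targets drawn uniformly from the given ranges. Defaults emulate a
#' moderately imbalanced clinical slice corpus
#' (glioma 20%, meningioma 22%, pituitary 28%, no tumor 30%).
#'
#' @param class_counts Integer vector of 4 per-class counts, canonical
#'   order (see [fdt_classes()]).
#' @param image_size Pixels per side.
#' @param variance_range,overlap_range,density_range Uniform sampling
#'   ranges for the class-specific feature targets.
#' @param noise_sd Additive noise level for every slice.
#' @param seed Master seed.
#' @param rim Draw the skull rim?
#' @return Object of class `fdt_phantom_cohort`: list of `slices` (each
#'   with `slice_id`, `image`, `truth`) and a `labels` character vector.
#' @export
generate_cohort <- function(class_counts,
                            image_size = 64L,
                            variance_range = c(0.03, 0.05),
                            overlap_range = c(0.6, 1.0),
                            density_range = c(0.06, 0.12),
                            noise_sd = 0.01,
                            seed = 1L,
                            rim = TRUE) {
  if (length(class_counts) != 4L || any(class_counts < 0)) {
    stop_fdt("class_counts must be 4 non-negative integers")
  }
  classes <- fdt_classes()
  labels <- rep(classes, times = class_counts)
  params <- with_seed(seed, data.frame(
    variance = stats::runif(length(labels), variance_range[1], variance_range[2]),
    overlap = stats::runif(length(labels), overlap_range[1], overlap_range[2]),
    density = stats::runif(length(labels), density_range[1], density_range[2])
  ))
  slices <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    sp <- phantom_spec(
      class_label = labels[i],
      image_size = image_size,
      target_variance = params$variance[i],
      target_band_overlap = params$overlap[i],
      target_border_density = params$density[i],
      noise_sd = noise_sd,
      seed = derive_seed(seed, i),
      rim = rim
    )
    ph <- generate_phantom(sp)
    slices[[i]] <- list(
      slice_id = sprintf("phantom_%04d_%s", i, labels[i]),
      image = ph$image,
      truth = ph$truth
    )
  }
  structure(list(slices = slices, labels = labels, seed = seed),
            class = "fdt_phantom_cohort")
}

#' @export
print.fdt_phantom_cohort <- function(x, ...) {
  cat("Phantom cohort:", length(x$slices), "slices\n")
  print(table(x$labels))
  invisible(x)
}

#' Write a phantom cohort to disk
#'
#' Writes one 8-bit grayscale PNG per slice, a JSON sidecar with the
#' per-slice ground truth, and a manifest CSV (`slice_id`, `path`,
#' `label`) consumable by [extract_features_batch()] and [audit_batch()].
#'
#' @param cohort An `fdt_phantom_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fdt_phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(cohort$slices)
  paths <- character(n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    sl <- cohort$slices[[i]]
    paths[i] <- file.path(dir, paste0(sl$slice_id, ".png"))
    png::writePNG(sl$image, paths[i])
    truths[[i]] <- list(
      slice_id = sl$slice_id,
      class_label = sl$truth$class_label,
      true_features = sl$truth$true_features
    )
  }
  manifest <- data.frame(
    slice_id = vapply(cohort$slices, `[[`, "", "slice_id"),
    path = paths,
    label = cohort$labels,
    stringsAsFactors = FALSE
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(truths, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
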
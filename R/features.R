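## Deterministic symbolic features for verification, computed directly
## from the pixel grid and independent of any learned model:
##   1. enhancement_variance — population variance of intensities inside
##      the Otsu-segmented foreground (heterogeneous-enhancement proxy),
##   2. sellar_band_overlap — fraction of mask pixels in the central 20%
##      y-band (sella turcica proximity proxy),
##   3. border_edge_density — Canny edge density in the outer 10% border
##      band (dural-contact proxy).

check_slice <- function(img) {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0) {
    stop_fdt("slice must be a non-empty numeric matrix")
  }
  if (anyNA(img) || min(img) < -1e-9 || max(img) > 1 + 1e-9) {
    stop_fdt("slice intensities must lie in [0, 1] (rescale 8-bit input by /255 first)")
  }
  invisible(img)
}

#' Otsu threshold of a [0,1] image on a 256-bin histogram
#'
#' Exhaustive maximization of the between-class variance over all 256
#' candidate thresholds. The returned threshold is the upper edge of the
#' chosen background bin, on the [0,1] intensity scale.
#'
#' @param img Numeric matrix with values in [0,1].
#' @return List with `threshold` and `degenerate` (TRUE for a constant
#'   image, whose histogram admits no split).
#' @export
otsu_threshold <- function(img) {
  check_slice(img)
  v <- as.vector(img)
  if (max(v) - min(v) < 1e-12) {
    return(list(threshold = NA_real_, degenerate = TRUE))
  }
  bins <- pmin(pmax(floor(v * 256), 0), 255)   # bin b covers [b/256,(b+1)/256)
  h <- tabulate(bins + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)                            # P(class0) for split after bin t
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  t_all <- 1:255
  w0 <- omega[t_all]
  num <- (mu_t * w0 - mu[t_all])^2
  den <- w0 * (1 - w0)
  sigma_b <- ifelse(den > 0, num / den, 0)
  best <- t_all[which.max(sigma_b)]             # split between bins best-1 and best
  list(threshold = best / 256, degenerate = FALSE)
}

#' Segment the candidate tumor foreground with Otsu's method
#'
#' The mask is all pixels strictly above the Otsu threshold. A constant
#' image has a degenerate histogram and yields an empty mask with the
#' `degenerate` flag set.
#'
#' @param img Numeric matrix with values in [0,1].
#' @return Object of class `fdt_tumor_mask`: list with `mask` (logical
#'   matrix), `pixel_count`, `threshold`, `degenerate`.
#' @export
segment_otsu <- function(img) {
  ot <- otsu_threshold(img)
  if (ot$degenerate) {
    mask <- matrix(FALSE, nrow(img), ncol(img))
  } else {
    mask <- img > ot$threshold
  }
  structure(list(
    mask = mask,
    pixel_count = sum(mask),
    threshold = ot$threshold,
    degenerate = ot$degenerate
  ), class = "fdt_tumor_mask")
}

#' In-mask intensity variance (enhancement heterogeneity)
#'
#' Population variance (denominator n, not n-1) of the [0,1]-normalized
#' intensities inside the segmentation mask. An empty mask yields 0 with
#' a degenerate flag. For intensities bounded in [0,1] the value cannot
#' exceed 0.25.
#'
#' @param img Numeric matrix in [0,1].
#' @param mask An `fdt_tumor_mask` (or logical matrix of the same shape).
#' @return List with `value` and `degenerate`.
#' @export
enhancement_variance <- function(img, mask) {
  check_slice(img)
  m <- if (inherits(mask, "fdt_tumor_mask")) mask$mask else mask
  if (!identical(dim(m), dim(img))) stop_fdt("mask and image shapes differ")
  v <- img[m]
  if (length(v) == 0) return(list(value = 0, degenerate = TRUE))
  list(value = mean(v^2) - mean(v)^2, degenerate = FALSE)
}

#' Central y-band overlap of the segmented mask
#'
#' Fraction of mask pixels whose row lies in the central 20% of the
#' y-axis (0-based rows `[0.4 H, 0.6 H)`, row 0 at the top). The
#' intensity-weighted image centroid is reported as auxiliary output.
#' An empty mask yields overlap 0 with a degenerate flag.
#'
#' @param img Numeric matrix in [0,1].
#' @param mask An `fdt_tumor_mask` (or logical matrix).
#' @return List with `value`, `centroid` (row, col; intensity-weighted),
#'   and `degenerate`.
#' @export
sellar_band_overlap <- function(img, mask) {
  check_slice(img)
  m <- if (inherits(mask, "fdt_tumor_mask")) mask$mask else mask
  if (!identical(dim(m), dim(img))) stop_fdt("mask and image shapes differ")
  h <- nrow(img)
  total_i <- sum(img)
  centroid <- if (total_i > 0) {
    c(row = sum(row(img) * img) / total_i, col = sum(col(img) * img) / total_i)
  } else {
    c(row = NA_real_, col = NA_real_)
  }
  if (!any(m)) return(list(value = 0, centroid = centroid, degenerate = TRUE))
  rows <- row(m)[m]
  inband <- rows %in% central_band_rows(h)
  list(value = mean(inband), centroid = centroid, degenerate = FALSE)
}

## separable Gaussian smoothing with reflected boundaries
gaussian_smooth <- function(img, sigma = 1.0) {
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_reflect <- function(x, r) {
    n <- length(x)
    c(x[(r + 1):2], x, x[(n - 1):(n - r)])
  }
  conv1 <- function(x) {
    xp <- pad_reflect(x, r)
    stats::filter(xp, k, sides = 2)[(r + 1):(r + length(x))]
  }
  tmp <- apply(img, 2, conv1)
  t(apply(tmp, 1, conv1))
}

shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Canny edge detection
#'
#' Standard Canny pipeline: Gaussian smoothing, Sobel gradients (scaled to
#' approximate the intensity derivative per pixel), non-maximum
#' suppression along the quantized gradient direction, and two-threshold
#' hysteresis (weak edges are kept only when connected to a strong edge).
#'
#' @param img Numeric matrix in [0,1].
#' @param sigma Gaussian smoothing bandwidth in pixels.
#' @param low,high Hysteresis thresholds on the gradient-magnitude scale
#'   of the [0,1] intensity range.
#' @return Logical matrix of edge pixels.
#' @export
canny_edges <- function(img, sigma = 1.0, low = 0.1, high = 0.2) {
  check_slice(img)
  s <- gaussian_smooth(img, sigma)
  # Sobel kernels / 8 approximate d/dx, d/dy in intensity units per pixel
  gx <- (shift_mat(s, 0, -1) - shift_mat(s, 0, 1)) * 2 +
    (shift_mat(s, -1, -1) - shift_mat(s, -1, 1)) +
    (shift_mat(s, 1, -1) - shift_mat(s, 1, 1))
  gy <- (shift_mat(s, -1, 0) - shift_mat(s, 1, 0)) * 2 +
    (shift_mat(s, -1, -1) - shift_mat(s, 1, -1)) +
    (shift_mat(s, -1, 1) - shift_mat(s, 1, 1))
  gx <- gx / 8; gy <- gy / 8
  mag <- sqrt(gx^2 + gy^2)

  # non-maximum suppression over 4 quantized directions
  ang <- atan2(gy, gx)                  # (-pi, pi]
  ang[ang < 0] <- ang[ang < 0] + pi     # fold to [0, pi)
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  n1 <- mag; n2 <- mag
  for (sec in 0:3) {
    d <- switch(as.character(sec),
                "0" = c(0L, 1L), "1" = c(1L, 1L),
                "2" = c(1L, 0L), "3" = c(1L, -1L))
    sel <- sector == sec
    n1[sel] <- shift_mat(mag, d[1], d[2])[sel]
    n2[sel] <- shift_mat(mag, -d[1], -d[2])[sel]
  }
  # strict on one side so a symmetric two-pixel plateau yields one edge
  peak <- mag > n1 & mag >= n2

  strong <- peak & mag >= high
  weak <- peak & mag >= low & !strong

  # hysteresis: grow strong edges into 8-connected weak pixels
  edges <- strong
  repeat {
    nb <- shift_mat(edges, 1, 0) | shift_mat(edges, -1, 0) |
      shift_mat(edges, 0, 1) | shift_mat(edges, 0, -1) |
      shift_mat(edges, 1, 1) | shift_mat(edges, 1, -1) |
      shift_mat(edges, -1, 1) | shift_mat(edges, -1, -1)
    grown <- edges | (weak & nb)
    if (identical(grown, edges)) break
    edges <- grown
  }
  edges
}

#' Border-band Canny edge density
#'
#' Density of Canny edge pixels (`sigma = 1`, hysteresis 0.1/0.2) inside
#' the border band formed by the outer 10% margin on all four sides:
#' edge pixels in the band divided by the band pixel count.
#'
#' @param img Numeric matrix in [0,1].
#' @inheritParams canny_edges
#' @return A single number in [0,1].
#' @export
border_edge_density <- function(img, sigma = 1.0, low = 0.1, high = 0.2) {
  check_slice(img)
  band <- border_band_mask(nrow(img), ncol(img))
  edges <- canny_edges(img, sigma = sigma, low = low, high = high)
  sum(edges & band) / sum(band)
}

#' Extract all symbolic verification features from a slice
#'
#' Composes Otsu segmentation, in-mask variance, central y-band overlap
#' and border edge density on the same slice. Purely deterministic and
#' independent of any classifier.
#'
#' @param img Numeric matrix in [0,1].
#' @param largest_component If `TRUE`, restrict the Otsu mask to its
#'   largest 8-connected component before computing mask features
#'   (sensitivity analysis; default keeps all above-threshold pixels).
#' @return Object of class `fdt_symbolic_features`: list with
#'   `enhancement_variance`, `sellar_band_overlap`, `border_edge_density`,
#'   `mask_area`, `centroid`, `degenerate_mask`.
#' @export
extract_features <- function(img, largest_component = FALSE) {
  check_slice(img)
  seg <- segment_otsu(img)
  if (largest_component && seg$pixel_count > 0) {
    seg$mask <- largest_component_mask(seg$mask)
    seg$pixel_count <- sum(seg$mask)
  }
  ev <- enhancement_variance(img, seg)
  so <- sellar_band_overlap(img, seg)
  structure(list(
    enhancement_variance = ev$value,
    sellar_band_overlap = so$value,
    border_edge_density = border_edge_density(img),
    mask_area = seg$pixel_count,
    centroid = so$centroid,
    degenerate_mask = seg$degenerate || ev$degenerate
  ), class = "fdt_symbolic_features")
}

#' @export
print.fdt_symbolic_features <- function(x, ...) {
  cat(sprintf(
    "Symbolic features: variance=%.4f band_overlap=%.4f border_density=%.4f (mask %d px%s)\n",
    x$enhancement_variance, x$sellar_band_overlap, x$border_edge_density,
    x$mask_area, if (x$degenerate_mask) ", degenerate" else ""
  ))
  invisible(x)
}

## largest 8-connected component of a logical mask (BFS labelling)
largest_component_mask <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  sizes <- integer(0)
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    size <- 0L
    while (length(queue) > 0) {
      pix <- queue
      queue <- integer(0)
      size <- size + length(pix)
      r <- ((pix - 1L) %% h) + 1L
      cc <- ((pix - 1L) %/% h) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        nr <- r + dr; ncl <- cc + dc
        ok <- nr >= 1 & nr <= h & ncl >= 1 & ncl <= w
        nidx <- (ncl[ok] - 1L) * h + nr[ok]
        nidx <- nidx[mask[nidx] & lab[nidx] == 0L]
        if (length(nidx) > 0) {
          lab[nidx] <- cur
          queue <- c(queue, nidx)
        }
      }
    }
    sizes[cur] <- size
  }
  if (cur == 0L) return(mask)
  lab == which.max(sizes)
}

#' Batch feature extraction over a manifest
#'
#' Reads a manifest CSV (`slice_id`, `path`, optionally `label`), loads
#' each image, and writes/returns one row of symbolic features per slice.
#'
#' @param manifest Data frame or path to a manifest CSV.
#' @param out_csv Optional path for the features CSV.
#' @return Data frame with slice_id, variance, overlap, density,
#'   mask_area, degenerate flag (and label when present).
#' @export
extract_features_batch <- function(manifest, out_csv = NULL) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_slice(manifest$path[i])
    f <- extract_features(img)
    data.frame(
      slice_id = manifest$slice_id[i],
      enhancement_variance = f$enhancement_variance,
      sellar_band_overlap = f$sellar_band_overlap,
      border_edge_density = f$border_edge_density,
      mask_area = f$mask_area,
      degenerate = f$degenerate_mask,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(manifest$label)) out$label <- manifest$label
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Read a grayscale slice image
#'
#' Reads a PNG and maps it to a [0,1] grayscale matrix (multi-channel
#' images are averaged across channels).
#'
#' @param path PNG file path.
#' @return Numeric matrix in [0,1].
#' @export
read_slice <- function(path) {
  if (!file.exists(path)) stop_fdt("image not found: ", path)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- apply(x[, , 1:min(3, dim(x)[3]), drop = FALSE], c(1, 2), mean)
  x
}
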
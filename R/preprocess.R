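## Evaluation-time preprocessing is fully deterministic: bilinear resize
## to a square target, pseudo-RGB channel replication, then fixed
## normalization (x - 0.5) / 0.5. Training-time augmentation is the only
## stochastic stage: horizontal flip (p = 0.5), rotation in +/-15 degrees,
## multiplicative brightness and contrast jitter in +/-20%.

## bilinear sampling at (continuous) row/col positions, half-pixel center
## convention; out-of-range samples take the fill value
bilinear_sample <- function(img, rows, cols, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  gv <- function(r, c) {
    r <- pmin(pmax(r, 1), h)
    c <- pmin(pmax(c, 1), w)
    img[cbind(r, c)]
  }
  inside <- rows >= 0.5 & rows <= h + 0.5 & cols >= 0.5 & cols <= w + 0.5
  v <- gv(r0, c0) * (1 - fr) * (1 - fc) +
    gv(r0 + 1, c0) * fr * (1 - fc) +
    gv(r0, c0 + 1) * (1 - fr) * fc +
    gv(r0 + 1, c0 + 1) * fr * fc
  v[!inside] <- fill
  v
}

#' Bilinear resize of a 2D intensity grid
#'
#' Half-pixel-center (area-aligned) sampling convention: output pixel
#' (i, j) samples the source at `(i - 0.5) * h / H + 0.5` in row
#' coordinates, matching the convention of mainstream image libraries.
#'
#' @param img Numeric matrix.
#' @param out_h,out_w Target size in pixels.
#' @return `out_h` x `out_w` numeric matrix.
#' @export
resize_bilinear <- function(img, out_h, out_w = out_h) {
  h <- nrow(img); w <- ncol(img)
  ry <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  rx <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  rows <- matrix(ry, out_h, out_w)
  cols <- matrix(rx, out_h, out_w, byrow = TRUE)
  matrix(bilinear_sample(img, as.vector(rows), as.vector(cols)), out_h, out_w)
}

#' Deterministic evaluation-time preprocessing
#'
#' Bilinear resize to `size` x `size`, replication of the grayscale
#' channel into three identical channels, then per-channel normalization
#' `(x - 0.5) / 0.5`, mapping [0,1] inputs to [-1,1]. No stochastic step.
#'
#' @param img Numeric matrix with values in [0,1].
#' @param size Target side length (default 224).
#' @param slice_id Optional provenance identifier.
#' @return Object of class `fdt_preprocessed_slice`: list with `tensor`
#'   (size x size x 3 array in [-1,1]), `channel_mean`, `channel_sd`,
#'   `provenance`.
#' @export
preprocess_eval <- function(img, size = 224L, slice_id = NULL) {
  check_slice(img)
  rs <- resize_bilinear(img, size, size)
  norm <- (rs - 0.5) / 0.5
  tensor <- array(norm, dim = c(size, size, 3))
  structure(list(
    tensor = tensor,
    channel_mean = 0.5,
    channel_sd = 0.5,
    provenance = list(
      slice_id = slice_id,
      transforms = c(
        sprintf("resize_bilinear(%dx%d -> %dx%d)", nrow(img), ncol(img), size, size),
        "replicate_channels(3)", "normalize(mean=0.5, sd=0.5)"
      )
    )
  ), class = "fdt_preprocessed_slice")
}

rotate_bilinear <- function(img, degrees, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  th <- degrees * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rows <- matrix(seq_len(h), h, w) - cy
  cols <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # inverse mapping: sample the source at the back-rotated position
  sr <- cos(th) * rows - sin(th) * cols + cy
  sc <- sin(th) * rows + cos(th) * cols + cx
  out <- bilinear_sample(img, as.vector(sr), as.vector(sc), fill = fill)
  matrix(out, h, w)
}

#' Brightness/contrast jitter with explicit factors
#'
#' Deterministic core of the augmentation jitter: multiplicative
#' brightness `x <- x * brightness`, then contrast about the image mean
#' `x <- mean + contrast * (x - mean)`, clipped to [0,1]. A constant
#' image is unchanged by the contrast step (its mean is its value).
#'
#' @param img Numeric matrix in [0,1].
#' @param brightness,contrast Multiplicative factors (1 = identity).
#' @return Jittered matrix in [0,1].
#' @export
jitter_transform <- function(img, brightness = 1, contrast = 1) {
  img <- img * brightness
  m <- mean(img)
  img <- m + contrast * (img - m)
  pmin(pmax(img, 0), 1)
}

#' Stochastic training-time augmentation
#'
#' Applies, in order: horizontal flip with probability `flip_p`, rotation
#' by an angle drawn uniformly from `[-rot_deg, rot_deg]` (bilinear
#' resampling, zero fill), multiplicative brightness jitter with a factor
#' uniform in `[1 - jitter_frac, 1 + jitter_frac]`, and contrast jitter
#' about the image mean (`x <- mean + f * (x - mean)`) with an
#' independent factor from the same range. Output is clipped to [0,1].
#' Vertical flips are never applied (they break the superior-inferior
#' orientation of axial slices).
#'
#' @param img Numeric matrix in [0,1].
#' @param seed Integer seed; the transform is deterministic given it.
#' @param flip_p Horizontal flip probability.
#' @param rot_deg Maximal absolute rotation in degrees.
#' @param jitter_frac Brightness/contrast jitter amplitude (0.2 = +/-20%).
#' @return Augmented matrix, same shape, values in [0,1].
#' @export
augment_train <- function(img, seed, flip_p = 0.5, rot_deg = 15,
                          jitter_frac = 0.2) {
  check_slice(img)
  with_seed(seed, {
    if (stats::runif(1) < flip_p) img <- img[, ncol(img):1, drop = FALSE]
    if (rot_deg > 0) {
      ang <- stats::runif(1, -rot_deg, rot_deg)
      img <- rotate_bilinear(img, ang)
    }
    if (jitter_frac > 0) {
      b <- stats::runif(1, 1 - jitter_frac, 1 + jitter_frac)
      f <- stats::runif(1, 1 - jitter_frac, 1 + jitter_frac)
      img <- jitter_transform(img, brightness = b, contrast = f)
    }
    pmin(pmax(img, 0), 1)
  })
}
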
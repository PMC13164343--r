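## Brute-force Otsu oracle: maximize between-class variance over all
## 256 histogram split points by direct enumeration.
otsu_bruteforce <- function(img) {
  v <- as.vector(img)
  bins <- pmin(pmax(floor(v * 256), 0), 255)
  best_t <- NA
  best_s <- -Inf
  for (t in 1:255) {
    g0 <- v[bins < t]
    g1 <- v[bins >= t]
    if (length(g0) == 0 || length(g1) == 0) next
    w0 <- length(g0) / length(v)
    # between-class variance on bin centers via bin means
    m0 <- mean(bins[bins < t]); m1 <- mean(bins[bins >= t])
    s <- w0 * (1 - w0) * (m0 - m1)^2
    if (s > best_s) { best_s <- s; best_t <- t }
  }
  best_t / 256
}

test_that("Otsu threshold equals brute-force between-class-variance maximization", {
  fdtaudit:::with_seed(4, {
    for (i in 1:10) {
      img <- matrix(sample(c(stats::runif(40, 0, 0.3), stats::runif(24, 0.6, 1))), 8, 8)
      expect_equal(otsu_threshold(img)$threshold, otsu_bruteforce(img))
    }
  })
  # bimodal half/half image: mask is exactly the bright half
  img <- matrix(rep(c(0.2, 0.8), each = 32), 8, 8)
  seg <- segment_otsu(img)
  expect_identical(seg$mask, img > 0.5)
  expect_equal(seg$pixel_count, 32)
})

test_that("constant images yield a degenerate empty mask", {
  seg <- segment_otsu(matrix(0.4, 6, 6))
  expect_true(seg$degenerate)
  expect_equal(seg$pixel_count, 0)
  f <- extract_features(matrix(0.4, 32, 32))
  expect_true(f$degenerate_mask)
  expect_equal(f$enhancement_variance, 0)
  expect_equal(f$sellar_band_overlap, 0)
})

test_that("Otsu segmentation of a rim-free glioma phantom recovers the lesion pixel set exactly", {
  ph <- generate_phantom(phantom_spec("glioma", 64, target_variance = 0.04,
                                      noise_sd = 0, rim = FALSE))
  seg <- segment_otsu(ph$image)
  expect_identical(seg$mask, ph$image > 0.2)
})

test_that("in-mask variance matches closed forms and two-level mixtures", {
  img <- matrix(0.5, 10, 10)
  img[1:5, ] <- 1.0
  mask <- matrix(TRUE, 10, 10)
  expect_equal(enhancement_variance(img, mask)$value, 0.0625) # equal mix {0.5, 1}
  img2 <- matrix(rep(c(0.6, 1.0), each = 50), 10, 10)
  expect_equal(enhancement_variance(img2, mask)$value, 0.04)  # 0.68 - 0.64
  # constant region -> zero variance
  expect_equal(enhancement_variance(matrix(0.7, 4, 4), matrix(TRUE, 4, 4))$value, 0)
  # two-level closed form p(1-p)(a-b)^2 for arbitrary mixing fractions
  for (p in c(0.1, 0.3, 0.5, 0.8)) {
    n_hi <- round(100 * p)
    vals <- c(rep(0.9, n_hi), rep(0.55, 100 - n_hi))
    img3 <- matrix(vals, 10, 10)
    pp <- n_hi / 100
    expect_equal(enhancement_variance(img3, mask)$value,
                 pp * (1 - pp) * (0.9 - 0.55)^2, tolerance = 1e-12)
  }
})

test_that("variance is invariant under in-mask pixel permutation and shape mismatches error", {
  fdtaudit:::with_seed(8, {
    img <- matrix(stats::runif(64), 8, 8)
    mask <- matrix(stats::runif(64) > 0.5, 8, 8)
    v1 <- enhancement_variance(img, mask)$value
    img2 <- img
    img2[mask] <- sample(img[mask])
    expect_equal(enhancement_variance(img2, mask)$value, v1)
  })
  expect_error(enhancement_variance(matrix(0.5, 4, 4), matrix(TRUE, 3, 3)), "shape")
})

test_that("central y-band overlap counts mask rows exactly", {
  n <- 50
  band <- fdtaudit:::central_band_rows(n)   # 0-based [20, 30) -> rows 21..30
  expect_equal(band, 21:30)
  img <- matrix(0.2, n, n)
  mask <- matrix(FALSE, n, n)
  mask[22:25, 10:19] <- TRUE                # fully inside band
  expect_equal(sellar_band_overlap(img, mask)$value, 1.0)
  mask2 <- matrix(FALSE, n, n)
  mask2[1:5, 1:10] <- TRUE                  # fully outside
  expect_equal(sellar_band_overlap(img, mask2)$value, 0.0)
  mask3 <- matrix(FALSE, n, n)
  mask3[21:23, 1:10] <- TRUE                # 30 in band
  mask3[41:43, 1:10] <- TRUE                # 30 out of band
  expect_equal(sellar_band_overlap(img, mask3)$value, 0.5)
})

test_that("intensity-weighted centroid is reported as auxiliary output", {
  img <- matrix(0, 11, 11)
  img[3, 8] <- 1
  out <- sellar_band_overlap(img, matrix(FALSE, 11, 11))
  expect_equal(unname(out$centroid), c(3, 8))
  expect_true(out$degenerate)
})

test_that("border edge density matches geometry on blank, interior and band-resident structures", {
  blank <- matrix(0.1, 64, 64)
  expect_equal(border_edge_density(blank), 0)
  # bright rectangle wholly inside the inner 80%: no edges in the band
  inner <- matrix(0.1, 64, 64)
  inner[25:40, 25:40] <- 0.9
  expect_equal(border_edge_density(inner), 0)
  # edge-flush rectangle inside the band: exactly 2h + 2w - 2 edge pixels
  flushed <- matrix(0.1, 64, 64)
  flushed[1:6, 20:25] <- 0.9
  band_area <- sum(fdtaudit:::border_band_mask(64))
  expect_equal(border_edge_density(flushed), (2 * 6 + 2 * 6 - 2) / band_area)
})

test_that("border edge density is invariant under horizontal flip", {
  ph <- generate_phantom(phantom_spec("meningioma", 64, target_border_density = 0.08,
                                      noise_sd = 0, rim = FALSE))
  img <- ph$image
  expect_equal(border_edge_density(img), border_edge_density(img[, ncol(img):1]))
})

test_that("extract_all composes the three features deterministically and matches phantom ground truth", {
  ph <- generate_phantom(phantom_spec("glioma", 64, target_variance = 0.04,
                                      noise_sd = 0, rim = FALSE))
  f1 <- extract_features(ph$image)
  f2 <- extract_features(ph$image)
  expect_identical(f1, f2)
  expect_lt(abs(f1$enhancement_variance - 0.04), 0.02)
  gt <- ph$truth$true_features
  expect_lt(abs(f1$sellar_band_overlap - gt$sellar_band_overlap), 0.05)
  expect_lt(abs(f1$border_edge_density - gt$border_edge_density), 0.05)

  nt <- generate_phantom(phantom_spec("no_tumor", 64, noise_sd = 0, rim = FALSE))
  fn <- extract_features(nt$image)
  expect_equal(fn$enhancement_variance, 0)
  expect_equal(fn$sellar_band_overlap, 0)
  expect_equal(fn$border_edge_density, 0)
})

test_that("batch extraction writes one feature row per manifest slice", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(c(1, 1, 1, 1), image_size = 48, seed = 3, rim = FALSE,
                        noise_sd = 0)
  manifest <- write_cohort(co, dir)
  out_csv <- file.path(dir, "features.csv")
  feats <- extract_features_batch(file.path(dir, "manifest.csv"), out_csv)
  expect_equal(nrow(feats), 4)
  expect_true(file.exists(out_csv))
  expect_true(all(c("enhancement_variance", "sellar_band_overlap",
                    "border_edge_density", "label") %in% names(feats)))
})
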
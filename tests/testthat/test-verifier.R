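test_that("predictions validate softmax normalization, argmax consistency and tie rules", {
  p <- prediction(c(0.7, 0.1, 0.1, 0.1))
  expect_equal(p$class_label, "glioma")
  expect_equal(p$confidence, 0.7)
  expect_error(prediction(c(0.3, 0.3, 0.3, 0.3)), "sum to 1")
  expect_error(prediction(c(0.5, 0.5, 0.1, -0.1)), ">= 0")
  expect_error(prediction(c(0.1, 0.7, 0.1, 0.1), "glioma"), "argmax")
  # exact four-way tie resolves to the lowest class index
  tie <- prediction(rep(0.25, 4))
  expect_equal(tie$class_label, "glioma")
  expect_equal(prediction(rep(0.25, 4), "glioma")$class_label, "glioma")
  expect_error(prediction(rep(0.25, 4), "pituitary"), "lowest")
})

test_that("decision traces alternate states and actions and end in a state", {
  tr <- make_trace("glioma", variance = 0.12)
  kinds <- vapply(tr$steps, `[[`, "", "kind")
  expect_equal(kinds, c("state", "action", "state", "action", "state"))
  names_ <- vapply(tr$steps, `[[`, "", "name")
  expect_equal(names_, c("raw", "extract_features", "featured", "predict", "predicted"))
  expect_error(build_trace("s", list(enhancement_variance = 0.1), prediction(c(1, 0, 0, 0)), "m"),
               "requires feature")
})

test_that("trace encoding renders exact decimals, tracked implications and is deterministic", {
  cs <- default_constraints()
  tr <- make_trace("glioma", variance = 0.098)
  fs <- encode_trace(tr, cs)
  expect_match(fs$text, "(= enhancement_variance 0.098000000000)", fixed = TRUE)
  expect_match(fs$text, "(! (=> is_glioma (> enhancement_variance 0.100000000000)) :named C1)",
               fixed = TRUE)
  expect_identical(fs$text, encode_trace(tr, cs)$text)
  expect_equal(fs$constraint_version, cs$version)
})

test_that("the worked low-variance glioma example is UNSAT with C1 in the core and flips to SAT above threshold", {
  cs <- default_constraints()
  tr_low <- make_trace("glioma", variance = 0.098, overlap = 0.8, density = 0.2)
  res <- smt_check(encode_trace(tr_low, cs))
  expect_equal(res$status, "UNSAT")
  expect_true("C1" %in% res$violated_ids)
  # C4 duplicates the heterogeneous-enhancement predicate under this
  # encoding, so it is violated alongside C1
  expect_setequal(res$violated_ids, c("C1", "C4"))

  tr_high <- make_trace("glioma", variance = 0.12, overlap = 0.8, density = 0.2)
  expect_equal(smt_check(encode_trace(tr_high, cs))$status, "SAT")
})

test_that("verdicts ignore softmax magnitudes and depend only on features, class and constraints", {
  cs <- default_constraints()
  f <- make_features(variance = 0.05)
  t1 <- build_trace("s", f, prediction(confident_softmax("glioma", 0.99)), "m")
  t2 <- build_trace("s", f, prediction(confident_softmax("glioma", 0.4)), "m")
  r1 <- dual_channel_verify(t1, cs)
  r2 <- dual_channel_verify(t2, cs)
  expect_equal(r1$status, r2$status)
  expect_equal(r1$violated_ids, r2$violated_ids)
})

test_that("dual channels agree across randomized and boundary traces, and UNSAT cores are sound", {
  cs <- default_constraints()
  traces <- random_traces(250, cs, seed = 17)
  for (tr in traces) {
    v <- dual_channel_verify(tr, cs)
    expect_true(v$agreement)
    if (v$status == "UNSAT") {
      # every core member must be individually false under direct evaluation
      expect_true(all(!v$per_constraint_truth[v$violated_ids]))
    } else {
      expect_true(all(v$per_constraint_truth))
    }
  }
})

test_that("a boundary-exact variance of 0.1 violates the strict constraint in both channels", {
  cs <- default_constraints()
  tr <- make_trace("glioma", variance = 0.1, overlap = 0.8, density = 0.2)
  v <- dual_channel_verify(tr, cs)
  expect_equal(v$status, "UNSAT")
  expect_false(v$per_constraint_truth[["C1"]])
  expect_true(v$agreement)
})

test_that("a corrupted encoder (flipped comparator) is caught by the dual channel", {
  cs <- default_constraints()
  tr <- make_trace("glioma", variance = 0.05, overlap = 0.8, density = 0.2)
  fs <- encode_trace(tr, cs)
  # fault injection: flip C1/C4's comparator in the solver-channel script only
  fs_bad <- fs
  fs_bad$text <- gsub("(> enhancement_variance 0.100000000000)",
                      "(< enhancement_variance 0.100000000000)",
                      fs$text, fixed = TRUE)
  solver <- smt_check(fs_bad)
  feats <- lapply(fs$rendered_features, as.numeric)
  names(feats) <- fdtaudit:::FEATURE_NAMES
  direct <- evaluate_constraints(cs, feats, fs$predicted_class)
  agreement <- (solver$status == "SAT") == all(direct)
  expect_false(agreement)   # the corrupted encoding must be flagged
})

test_that("UNKNOWN solver status leaves agreement undefined and flags the trace", {
  cs <- default_constraints()
  tr <- make_trace("glioma", variance = 0.2)
  v <- dual_channel_verify(tr, cs, timeout = -1)
  expect_equal(v$status, "UNKNOWN")
  expect_true(is.na(v$agreement))
  expect_true(v$flagged)
})

test_that("artifacts round-trip, verify, and detect any single-byte mutation", {
  cs <- default_constraints()
  tr <- make_trace("glioma", variance = 0.098)
  fs <- encode_trace(tr, cs)
  v <- dual_channel_verify(tr, cs)
  art <- build_artifact(tr, fs, v, timestamp = "2026-01-01T00:00:00Z")
  expect_match(art$sha256, "^[0-9a-f]{64}$")
  expect_true(verify_artifact(art))

  path <- withr::local_tempfile(fileext = ".json")
  write_artifact(art, path)
  art2 <- read_artifact(path)
  expect_true(verify_artifact(art2))
  expect_equal(art2$sha256, art$sha256)

  # single-byte mutations of the serialization change the digest
  payload <- canonical_json(art$payload)
  fdtaudit:::with_seed(9, positions <- sample(nchar(payload), 25))
  for (pos in positions) {
    mutated <- payload
    orig <- substr(mutated, pos, pos)
    repl <- if (orig == "x") "y" else "x"
    substr(mutated, pos, pos) <- repl
    expect_false(sha256_hex(mutated) == art$sha256)
  }
  # mutating a payload field is detected by verification
  art3 <- art
  art3$payload$result$status <- "SAT"
  expect_false(verify_artifact(art3))
})

test_that("a fixed reference trace yields a frozen attestation digest", {
  cs <- default_constraints()
  tr <- make_trace("glioma", variance = 0.098, overlap = 0.8, density = 0.2)
  fs <- encode_trace(tr, cs)
  v <- dual_channel_verify(tr, cs)
  v$solve_time <- 0   # timing excluded from the frozen fixture
  art <- build_artifact(tr, fs, v, timestamp = "2026-01-01T00:00:00Z")
  expect_equal(art$sha256, FROZEN_REFERENCE_DIGEST)
})

test_that("batch audits report the verification categories as a partition", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(c(2, 2, 2, 2), image_size = 64, seed = 13, rim = FALSE,
                        noise_sd = 0)
  manifest <- write_cohort(co, dir)
  # phantom-calibrated thresholds: generator targets sit above these
  cs <- default_constraints(edge_density_threshold = 0.05,
                            variance_threshold = 0.025,
                            overlap_threshold = 0.5,
                            version = "phantom-1.0")
  out_dir <- file.path(dir, "audit")
  rep <- audit_batch(file.path(dir, "manifest.csv"), oracle_predictor(), cs,
                     out_dir = out_dir, timestamp = "2026-01-01T00:00:00Z")
  expect_equal(rep$n, 8)
  expect_equal(rep$agreement_rate, 100)
  expect_equal(rep$sat_rate + rep$unsat_rate, 100)
  expect_equal(rep$unsat_correct_rate + rep$unsat_incorrect_rate, rep$unsat_rate)
  expect_equal(rep$sat_rate, 100)      # cohort engineered to satisfy all rules
  arts <- list.files(out_dir, pattern = "\\.fdt\\.json$", full.names = TRUE)
  expect_length(arts, 8)
  expect_true(all(vapply(arts, verify_artifact, logical(1))))
})

test_that("engineered violations produce the expected UNSAT rate", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(c(10, 0, 0, 0), image_size = 64, seed = 23, rim = FALSE,
                        noise_sd = 0, variance_range = c(0.03, 0.05))
  # depress the variance of 3 glioma slices below the phantom threshold
  for (i in 1:3) {
    sp <- phantom_spec("glioma", 64, target_variance = 0.005, noise_sd = 0,
                       seed = i, rim = FALSE)
    co$slices[[i]]$image <- generate_phantom(sp)$image
  }
  manifest <- write_cohort(co, dir)
  cs <- default_constraints(variance_threshold = 0.025, version = "phantom-1.0")
  rep <- audit_batch(file.path(dir, "manifest.csv"), oracle_predictor(), cs)
  expect_equal(rep$unsat_rate, 30)
  expect_equal(rep$agreement_rate, 100)
})
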
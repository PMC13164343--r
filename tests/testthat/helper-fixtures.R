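## shared fixtures: tiny deterministic traces and feature bundles

## attestation digest of the canonical reference artifact (glioma trace,
## variance 0.098, default constraints, fixed timestamp, solve_time 0),
## computed once with the canonicalization rules and frozen here
FROZEN_REFERENCE_DIGEST <- "189ebcc0bb51af9ba2f1f8f832604e39427744059051d1c979106c49b4676c1c"

make_features <- function(variance = 0.15, overlap = 0.8, density = 0.2) {
  list(enhancement_variance = variance,
       sellar_band_overlap = overlap,
       border_edge_density = density)
}

confident_softmax <- function(class_label, confidence = 0.9) {
  k <- match(class_label, fdt_classes())
  sm <- rep((1 - confidence) / 3, 4)
  sm[k] <- confidence
  sm
}

make_trace <- function(class_label, variance = 0.15, overlap = 0.8,
                       density = 0.2, slice_id = "s1", model_id = "test") {
  build_trace(slice_id, make_features(variance, overlap, density),
              prediction(confident_softmax(class_label)), model_id)
}

## random traces spanning all classes and threshold-boundary values
random_traces <- function(n, cs = default_constraints(), seed = 1) {
  thr <- unlist(lapply(cs$rules, `[[`, "threshold"))
  boundary_pool <- sort(unique(c(thr, thr - 1e-9, thr + 1e-9, thr - 0.01, thr + 0.01)))
  fdtaudit:::with_seed(seed, lapply(seq_len(n), function(i) {
    pick <- function() {
      if (stats::runif(1) < 0.4) sample(boundary_pool, 1) else stats::runif(1)
    }
    make_trace(sample(fdt_classes(), 1),
               variance = min(pick(), 0.25),
               overlap = min(max(pick(), 0), 1),
               density = min(max(pick(), 0), 1),
               slice_id = sprintf("r%04d", i))
  }))
}
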
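## The five-step verification pipeline: (1) symbolic feature extraction,
## (2) encoding of the decision trace into QF_LRA formulas, (3) solver
## check with unsat-core diagnosis, (4) tamper-evident artifact with
## SHA-256 attestation, (5) dual-channel validation against an
## independent direct Boolean evaluator.

#' Construct a prediction record
#'
#' @param softmax Numeric vector of 4 class probabilities (canonical
#'   order, see [fdt_classes()]); must be non-negative and sum to 1
#'   within 1e-6.
#' @param class_label Optional label; defaults to the argmax class (ties
#'   resolved to the lowest class index). A supplied label must be
#'   argmax-consistent.
#' @return Object of class `fdt_prediction`: `class_label`, `softmax`,
#'   `confidence`.
#' @export
prediction <- function(softmax, class_label = NULL) {
  classes <- fdt_classes()
  if (length(softmax) != 4) stop_fdt("softmax must have 4 entries")
  if (any(softmax < -1e-12)) stop_fdt("softmax entries must be >= 0")
  if (abs(sum(softmax) - 1) > 1e-6) stop_fdt("softmax must sum to 1 (got ", sum(softmax), ")")
  amax <- classes[which.max(softmax)]      # which.max takes the lowest index on ties
  if (is.null(class_label)) {
    class_label <- amax
  } else {
    class_label <- match.arg(class_label, classes)
    if (softmax[match(class_label, classes)] < max(softmax) - 1e-12) {
      stop_fdt("class_label is not an argmax of the softmax vector")
    }
    # ties: the label must be the lowest tied index
    tied <- which(softmax >= max(softmax) - 1e-12)
    if (match(class_label, classes) != tied[1]) {
      stop_fdt("tied softmax must resolve to the lowest class index")
    }
  }
  structure(list(
    class_label = class_label,
    softmax = stats::setNames(as.numeric(softmax), classes),
    confidence = max(softmax)
  ), class = "fdt_prediction")
}

#' Build a Formal Decision Trace
#'
#' Records one classification decision as an alternating state/action
#' sequence `<s0, a0, s1, a1, s2>`: raw state, feature-extraction action,
#' featured state, prediction action, predicted state. The trace is
#' append-only and deterministic given its inputs.
#'
#' @param slice_id Slice identifier.
#' @param features `fdt_symbolic_features` (or named list of the three
#'   feature values).
#' @param pred An [prediction()] object (or 4-vector softmax).
#' @param model_id Identifier of the predicting model.
#' @param preprocessing Optional preprocessing provenance record.
#' @return Object of class `fdt_decision_trace`.
#' @export
build_trace <- function(slice_id, features, pred, model_id,
                        preprocessing = NULL) {
  if (!inherits(pred, "fdt_prediction")) pred <- prediction(pred)
  fv <- lapply(FEATURE_NAMES, function(f) {
    v <- features[[f]]
    if (is.null(v) || !is.finite(v)) stop_fdt("trace requires feature: ", f)
    as.numeric(v)
  })
  names(fv) <- FEATURE_NAMES
  steps <- list(
    list(kind = "state", name = "raw",
         slice_id = slice_id, preprocessing = preprocessing),
    list(kind = "action", name = "extract_features", features = fv),
    list(kind = "state", name = "featured", slice_id = slice_id, features = fv),
    list(kind = "action", name = "predict", model_id = model_id,
         class_label = pred$class_label,
         softmax = as.list(pred$softmax), confidence = pred$confidence),
    list(kind = "state", name = "predicted", slice_id = slice_id,
         class_label = pred$class_label)
  )
  structure(list(
    slice_id = slice_id, model_id = model_id,
    features = fv, prediction = pred, steps = steps
  ), class = "fdt_decision_trace")
}

#' @export
print.fdt_decision_trace <- function(x, ...) {
  cat("Decision trace for slice", x$slice_id, "\n")
  cat("  steps:", paste(vapply(x$steps, `[[`, "", "name"), collapse = " -> "), "\n")
  cat(sprintf("  predicted %s (confidence %.3f)\n",
              x$prediction$class_label, x$prediction$confidence))
  invisible(x)
}

## exact decimal rendering shared by both verification channels
render_decimal <- function(x) sprintf("%.12f", x)

#' Encode a decision trace against a constraint set
#'
#' Renders the trace as a quantifier-free linear real arithmetic script:
#' one real constant assertion per symbolic feature (exact decimal
#' literals), one Boolean selector per class fixed to the predicted
#' class, one tracked implication per constraint, and a tracked one-hot
#' invariant. The conjunction of all assertions is the trace formula.
#'
#' @param trace An [build_trace()] object.
#' @param cs An `fdt_constraint_set`.
#' @return Object of class `fdt_formula_set`: `text` (full SMT-LIB
#'   script), `formulas` (named character, one rendered formula per
#'   tracked assertion), `rendered_features` (the decimal literals),
#'   `predicted_class`, `constraint_version`.
#' @export
encode_trace <- function(trace, cs) {
  stopifnot(inherits(trace, "fdt_decision_trace"), inherits(cs, "fdt_constraint_set"))
  classes <- fdt_classes()
  sel <- paste0("is_", classes)
  lines <- c("(set-logic QF_LRA)")
  for (f in FEATURE_NAMES) lines <- c(lines, sprintf("(declare-const %s Real)", f))
  for (s in sel) lines <- c(lines, sprintf("(declare-const %s Bool)", s))
  rendered <- vapply(FEATURE_NAMES, function(f) render_decimal(trace$features[[f]]), character(1))
  for (f in FEATURE_NAMES) {
    lines <- c(lines, sprintf("(assert (= %s %s))", f, rendered[[f]]))
  }
  for (k in seq_along(classes)) {
    lit <- if (classes[k] == trace$prediction$class_label) sel[k] else sprintf("(not %s)", sel[k])
    lines <- c(lines, sprintf("(assert %s)", lit))
  }
  formulas <- character(0)
  for (r in cs$rules) {
    pred_term <- sprintf("(%s %s %s)", r$comparator, r$feature, render_decimal(r$threshold))
    body <- if (r$antecedent_class == "any") pred_term else
      sprintf("(=> is_%s %s)", r$antecedent_class, pred_term)
    formulas[[r$id]] <- body
    lines <- c(lines, sprintf("(assert (! %s :named %s))", body, r$id))
  }
  onehot_terms <- vapply(seq_along(classes), function(k) {
    lits <- ifelse(seq_along(classes) == k, sel, sprintf("(not %s)", sel))
    sprintf("(and %s)", paste(lits, collapse = " "))
  }, character(1))
  onehot <- sprintf("(or %s)", paste(onehot_terms, collapse = " "))
  formulas[["one_hot"]] <- onehot
  lines <- c(lines, sprintf("(assert (! %s :named one_hot))", onehot), "(check-sat)")
  structure(list(
    text = paste(lines, collapse = "\n"),
    formulas = formulas,
    rendered_features = rendered,
    predicted_class = trace$prediction$class_label,
    constraint_version = cs$version
  ), class = "fdt_formula_set")
}

#' Solver-channel check of an encoded trace
#'
#' Runs the built-in QF_LRA satisfiability solver on the rendered script.
#' UNSAT verdicts carry an unsat core of tracked constraint ids; SAT
#' verdicts carry a satisfying assignment as certificate. A solver
#' timeout yields status UNKNOWN, flagged for manual review.
#'
#' @param fs An [encode_trace()] formula set.
#' @param timeout Solver wall-clock budget in seconds (default 1).
#' @return List with `status`, `violated_ids`, `certificate`,
#'   `solve_time`.
#' @export
smt_check <- function(fs, timeout = 1.0) {
  stopifnot(inherits(fs, "fdt_formula_set"))
  res <- smt_solve(fs$text, timeout = timeout)
  if (res$status == "SAT") {
    cert <- paste0("model: ",
                   paste(names(res$model),
                         vapply(res$model, function(v) {
                           if (is.logical(v)) tolower(as.character(v)) else render_decimal(v)
                         }, character(1)),
                         sep = " = ", collapse = "; "))
    return(list(status = "SAT", violated_ids = character(0),
                certificate = cert, solve_time = res$solve_time))
  }
  if (res$status == "UNSAT") {
    return(list(status = "UNSAT", violated_ids = res$core,
                certificate = paste0("unsat core: ", paste(res$core, collapse = ", ")),
                solve_time = res$solve_time))
  }
  list(status = "UNKNOWN", violated_ids = character(0),
       certificate = "solver timeout: flagged for manual review",
       solve_time = res$solve_time)
}

#' Dual-channel verification of a decision trace
#'
#' Channel 1 encodes the trace and runs the QF_LRA solver; channel 2
#' evaluates every constraint directly as a Boolean implication. Both
#' channels consume the same rendered decimal feature literals, so
#' agreement cannot hinge on floating-point rendering. The channels
#' agree when (solver SAT) == (all direct evaluations true); any
#' disagreement or UNKNOWN solver status is flagged for manual review.
#'
#' @param trace An [build_trace()] object.
#' @param cs An `fdt_constraint_set`.
#' @param timeout Solver budget in seconds.
#' @return Object of class `fdt_verification`: `status`, `violated_ids`,
#'   `per_constraint_truth`, `certificate`, `solve_time`, `agreement`
#'   (logical, `NA` when UNKNOWN), `flagged`.
#' @export
dual_channel_verify <- function(trace, cs, timeout = 1.0) {
  fs <- encode_trace(trace, cs)
  solver <- smt_check(fs, timeout = timeout)
  # direct channel: parse the same rendered decimals back to numerics
  feats <- lapply(fs$rendered_features, as.numeric)
  names(feats) <- FEATURE_NAMES
  direct <- evaluate_constraints(cs, feats, fs$predicted_class)
  all_true <- all(direct)
  agreement <- if (solver$status == "UNKNOWN") NA else
    (solver$status == "SAT") == all_true
  flagged <- is.na(agreement) || !agreement
  structure(list(
    status = solver$status,
    violated_ids = solver$violated_ids,
    per_constraint_truth = direct,
    certificate = solver$certificate,
    solve_time = solver$solve_time,
    agreement = agreement,
    flagged = flagged
  ), class = "fdt_verification")
}

#' @export
print.fdt_verification <- function(x, ...) {
  cat("Verification:", x$status)
  if (length(x$violated_ids)) cat(" [core:", paste(x$violated_ids, collapse = ", "), "]")
  cat("; dual-channel agreement:",
      if (is.na(x$agreement)) "undefined (UNKNOWN)" else x$agreement, "\n")
  invisible(x)
}

#' Assemble a tamper-evident FDT artifact
#'
#' Bundles the trace, rendered formulas, verification result and
#' metadata into one record, attested by the SHA-256 digest of its
#' canonical JSON serialization (sorted keys, fixed decimal rendering,
#' no insignificant whitespace; the digest field itself is excluded).
#' Pass a fixed `timestamp` for bit-reproducible artifacts.
#'
#' @param trace An [build_trace()] object.
#' @param fs The [encode_trace()] formula set.
#' @param result An `fdt_verification` (or [smt_check()] result).
#' @param model_id Model identifier for the metadata block.
#' @param timestamp Timestamp string; defaults to the current UTC time.
#' @return Object of class `fdt_artifact`: `payload` (trace, formulas,
#'   result, metadata) and `sha256`.
#' @export
build_artifact <- function(trace, fs, result, model_id = trace$model_id,
                           timestamp = NULL) {
  payload <- list(
    trace = list(
      slice_id = trace$slice_id,
      model_id = trace$model_id,
      steps = trace$steps
    ),
    formulas = list(
      script = fs$text,
      tracked = as.list(fs$formulas),
      conjunction = paste0("(and ", paste(fs$formulas, collapse = " "), ")")
    ),
    result = list(
      status = result$status,
      violated_ids = as.list(result$violated_ids),
      per_constraint_truth = as.list(result$per_constraint_truth %||% logical(0)),
      certificate = result$certificate,
      agreement = result$agreement %||% NA,
      solve_time = result$solve_time
    ),
    metadata = list(
      timestamp = timestamp %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      model_id = model_id,
      slice_id = trace$slice_id,
      constraint_version = fs$constraint_version
    )
  )
  structure(list(
    payload = payload,
    sha256 = sha256_hex(canonical_json(payload))
  ), class = "fdt_artifact")
}

#' Verify the attestation digest of an artifact
#'
#' Recomputes the SHA-256 digest over the canonical serialization of the
#' payload and compares it with the stored digest; any mutation of the
#' payload (or of its serialized form) is detected.
#'
#' @param artifact An `fdt_artifact`, or a path to an artifact JSON file.
#' @return `TRUE` if the digest matches, `FALSE` otherwise.
#' @export
verify_artifact <- function(artifact) {
  if (is.character(artifact)) artifact <- read_artifact(artifact)
  stopifnot(inherits(artifact, "fdt_artifact"))
  identical(sha256_hex(canonical_json(artifact$payload)), artifact$sha256)
}

#' Write / read an FDT artifact as a JSON document
#'
#' @param artifact An `fdt_artifact`.
#' @param path JSON file path.
#' @return `write_artifact` returns `path` invisibly; `read_artifact`
#'   returns the `fdt_artifact`.
#' @export
write_artifact <- function(artifact, path) {
  stopifnot(inherits(artifact, "fdt_artifact"))
  doc <- list(payload = artifact$payload, sha256 = artifact$sha256)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_artifact
#' @export
read_artifact <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(list(payload = doc$payload, sha256 = doc$sha256),
            class = "fdt_artifact")
}

#' Audit a batch of slices through the full predict-then-verify loop
#'
#' For each manifest row: read the slice, extract symbolic features, get
#' a prediction from the supplied predictor, verify it through both
#' channels, and (optionally) write one FDT artifact JSON per slice.
#' When the manifest carries ground-truth labels, UNSAT cases are split
#' into correct-label and incorrect-label categories.
#'
#' @param manifest Data frame or manifest CSV path with `slice_id`,
#'   `path`, optional `label`.
#' @param predictor An [fdt_predictor()] (anything with a
#'   `predict_slice` method).
#' @param cs An `fdt_constraint_set`.
#' @param out_dir Optional directory for per-slice artifact JSONs and the
#'   summary report.
#' @param timestamp Optional fixed timestamp for reproducible artifacts.
#' @return Object of class `fdt_audit_report`: per-slice results data
#'   frame and aggregate rates (percentages): `sat_rate`, `unsat_rate`,
#'   `unsat_correct_rate`, `unsat_incorrect_rate`, `agreement_rate`.
#' @export
audit_batch <- function(manifest, predictor, cs, out_dir = NULL,
                        timestamp = NULL) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$path[i]
    if (!file.exists(p)) {
      message("audit_batch: skipping missing image ", p)
      next
    }
    img <- read_slice(p)
    feats <- extract_features(img)
    if (!is.null(manifest$label)) attr(img, "fdt_label") <- manifest$label[i]
    pred <- predict_slice(predictor, img)
    trace <- build_trace(manifest$slice_id[i], feats, pred, predictor$model_id)
    fs <- encode_trace(trace, cs)
    ver <- dual_channel_verify(trace, cs)
    if (!is.null(out_dir)) {
      art <- build_artifact(trace, fs, ver, timestamp = timestamp)
      write_artifact(art, file.path(out_dir, paste0(manifest$slice_id[i], ".fdt.json")))
    }
    truth <- if (!is.null(manifest$label)) manifest$label[i] else NA_character_
    rows[[length(rows) + 1L]] <- data.frame(
      slice_id = manifest$slice_id[i],
      predicted = pred$class_label,
      label = truth,
      status = ver$status,
      violated = paste(ver$violated_ids, collapse = ";"),
      agreement = ver$agreement,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  n <- nrow(res)
  unsat <- res$status == "UNSAT"
  has_truth <- !all(is.na(res$label))
  report <- structure(list(
    results = res,
    n = n,
    sat_rate = 100 * mean(res$status == "SAT"),
    unsat_rate = 100 * mean(unsat),
    unsat_correct_rate = if (has_truth) 100 * mean(unsat & res$predicted == res$label) else NA_real_,
    unsat_incorrect_rate = if (has_truth) 100 * mean(unsat & res$predicted != res$label) else NA_real_,
    agreement_rate = 100 * mean(res$agreement %in% TRUE)
  ), class = "fdt_audit_report")
  if (!is.null(out_dir)) {
    utils::write.csv(res, file.path(out_dir, "audit_results.csv"), row.names = FALSE)
    jsonlite::write_json(report[c("n", "sat_rate", "unsat_rate",
                                  "unsat_correct_rate", "unsat_incorrect_rate",
                                  "agreement_rate")],
                         file.path(out_dir, "audit_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

#' @export
print.fdt_audit_report <- function(x, ...) {
  cat("Audit report over", x$n, "slices\n")
  cat(sprintf("  SAT:   %6.2f%%\n", x$sat_rate))
  cat(sprintf("  UNSAT: %6.2f%%", x$unsat_rate))
  if (!is.na(x$unsat_correct_rate)) {
    cat(sprintf("  (correct label %.2f%%, incorrect %.2f%%)",
                x$unsat_correct_rate, x$unsat_incorrect_rate))
  }
  cat("\n")
  cat(sprintf("  dual-channel agreement: %.1f%%\n", x$agreement_rate))
  invisible(x)
}
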
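## Declarative neuroradiologic plausibility constraints. Each rule is a
## guarded linear predicate over the symbolic features: IF the predicted
## class matches the guard THEN feature <comparator> threshold. The same
## rules feed both verification channels (SMT encoding and direct
## Boolean evaluation).

FEATURE_NAMES <- c("enhancement_variance", "sellar_band_overlap", "border_edge_density")
COMPARATORS <- c(">", ">=", "<", "<=")

#' Build a single constraint rule
#'
#' @param id Unique constraint identifier (e.g. "C1").
#' @param antecedent_class Predicted-class guard (one of [fdt_classes()])
#'   or `"any"` for an unguarded rule.
#' @param feature One of the symbolic feature names.
#' @param comparator One of `>`, `>=`, `<`, `<=`.
#' @param threshold Finite numeric threshold.
#' @param description Free-text rationale.
#' @return Object of class `fdt_constraint`.
#' @export
constraint_rule <- function(id, antecedent_class, feature, comparator,
                            threshold, description = "") {
  if (!antecedent_class %in% c(fdt_classes(), "any")) {
    stop_fdt("unknown antecedent class: ", antecedent_class)
  }
  if (!feature %in% FEATURE_NAMES) stop_fdt("unknown feature: ", feature)
  comparator <- match.arg(comparator, COMPARATORS)
  if (!is.finite(threshold)) stop_fdt("threshold must be finite")
  structure(list(
    id = id, antecedent_class = antecedent_class, feature = feature,
    comparator = comparator, threshold = threshold, description = description
  ), class = "fdt_constraint")
}

#' Default neuroradiologic constraint set
#'
#' The shipped rules, all in quantifier-free linear real arithmetic:
#' \describe{
#'   \item{C1}{glioma implies heterogeneous enhancement: in-mask intensity
#'     variance > `variance_threshold` (default 0.1).}
#'   \item{C2}{pituitary implies sellar proximity: central y-band overlap
#'     > `overlap_threshold` (default 0.5).}
#'   \item{C3}{meningioma implies dural-contact proxy: border edge density
#'     > `edge_density_threshold` (required; no published value exists, the
#'     default 0.05 was calibrated on phantom slices).}
#'   \item{C4}{consistency invariant: no glioma prediction without
#'     heterogeneous enhancement — tracked separately from C1 so unsat
#'     cores can distinguish the two assertions even though the predicate
#'     coincides.}
#' }
#' plus a one-hot invariant asserting that exactly one class is predicted.
#' Additional rules can be appended via `extra_rules`.
#'
#' @param edge_density_threshold Threshold for C3.
#' @param variance_threshold Threshold for C1/C4.
#' @param overlap_threshold Threshold for C2.
#' @param extra_rules Optional list of [constraint_rule()] objects.
#' @param version Version tag recorded into every artifact.
#' @return Object of class `fdt_constraint_set`: list of rules, `version`,
#'   `theory` ("QF_LRA").
#' @export
default_constraints <- function(edge_density_threshold = 0.05,
                                variance_threshold = 0.1,
                                overlap_threshold = 0.5,
                                extra_rules = list(),
                                version = "1.0") {
  if (is.null(edge_density_threshold) || !is.finite(edge_density_threshold)) {
    stop_fdt("edge_density_threshold must be provided (no published value exists)")
  }
  rules <- list(
    constraint_rule("C1", "glioma", "enhancement_variance", ">",
                    variance_threshold,
                    "glioma implies heterogeneous enhancement (in-mask intensity variance)"),
    constraint_rule("C2", "pituitary", "sellar_band_overlap", ">",
                    overlap_threshold,
                    "pituitary implies proximity to the sella turcica (central y-band overlap)"),
    constraint_rule("C3", "meningioma", "border_edge_density", ">",
                    edge_density_threshold,
                    "meningioma implies dural contact proxy (border-band edge density)"),
    constraint_rule("C4", "glioma", "enhancement_variance", ">",
                    variance_threshold,
                    "consistency invariant: no glioma prediction in the absence of heterogeneous enhancement")
  )
  rules <- c(rules, extra_rules)
  ids <- vapply(rules, `[[`, "", "id")
  if (anyDuplicated(ids)) stop_fdt("constraint ids must be unique")
  structure(list(rules = rules, version = version, theory = "QF_LRA"),
            class = "fdt_constraint_set")
}

#' @export
print.fdt_constraint_set <- function(x, ...) {
  cat("Constraint set v", x$version, " (", x$theory, "), ",
      length(x$rules), " rules + one-hot invariant\n", sep = "")
  for (r in x$rules) {
    guard <- if (r$antecedent_class == "any") "" else paste0("IF ", r$antecedent_class, " THEN ")
    cat(sprintf("  %s: %s%s %s %g\n", r$id, guard, r$feature, r$comparator, r$threshold))
  }
  invisible(x)
}

#' Direct Boolean evaluation of one constraint
#'
#' The independent evaluation primitive of the dual-channel check:
#' material implication `predicted class != guard OR predicate(features)`,
#' with comparator semantics exactly as configured (strict `>` at the
#' boundary: a value equal to the threshold fails a `>` rule).
#'
#' @param rule An [constraint_rule()].
#' @param features An `fdt_symbolic_features` object or named list with
#'   the three feature values.
#' @param predicted_class Predicted class label.
#' @return `TRUE` iff the rule is satisfied.
#' @export
evaluate_predicate <- function(rule, features, predicted_class) {
  stopifnot(inherits(rule, "fdt_constraint"))
  if (rule$antecedent_class != "any" && rule$antecedent_class != predicted_class) {
    return(TRUE)   # guard inactive: implication vacuously true
  }
  v <- features[[rule$feature]]
  if (is.null(v) || !is.finite(v)) stop_fdt("feature missing or non-finite: ", rule$feature)
  switch(rule$comparator,
         ">" = v > rule$threshold,
         ">=" = v >= rule$threshold,
         "<" = v < rule$threshold,
         "<=" = v <= rule$threshold)
}

#' Evaluate all rules of a constraint set directly
#'
#' @param cs An `fdt_constraint_set`.
#' @inheritParams evaluate_predicate
#' @return Named logical vector (one entry per rule id).
#' @export
evaluate_constraints <- function(cs, features, predicted_class) {
  stopifnot(inherits(cs, "fdt_constraint_set"))
  out <- vapply(cs$rules, evaluate_predicate, logical(1),
                features = features, predicted_class = predicted_class)
  stats::setNames(out, vapply(cs$rules, `[[`, "", "id"))
}

#' Write / read constraint sets as YAML
#'
#' @param cs An `fdt_constraint_set`.
#' @param path YAML file path.
#' @return `write_constraints` returns `path` invisibly;
#'   `read_constraints` returns the `fdt_constraint_set`.
#' @export
write_constraints <- function(cs, path) {
  stopifnot(inherits(cs, "fdt_constraint_set"))
  doc <- list(
    version = cs$version,
    theory = cs$theory,
    rules = lapply(cs$rules, function(r) {
      list(id = r$id, antecedent_class = r$antecedent_class,
           feature = r$feature, comparator = r$comparator,
           threshold = r$threshold, description = r$description)
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_constraints
#' @export
read_constraints <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$version)) stop_fdt("constraint YAML must carry a version tag")
  rules <- lapply(doc$rules, function(r) {
    constraint_rule(r$id, r$antecedent_class, r$feature, r$comparator,
                    as.numeric(r$threshold), r$description %||% "")
  })
  structure(list(rules = rules, version = as.character(doc$version),
                 theory = doc$theory %||% "QF_LRA"),
            class = "fdt_constraint_set")
}
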
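#' Canonical JSON serialization
#'
#' Deterministic JSON rendering used for content-hash attestation: object
#' keys are sorted, floats are rendered as fixed 12-decimal literals,
#' integers as plain integers, and no insignificant whitespace is emitted.
#' Two structurally equal R objects always serialize to the same byte
#' sequence, so `sha256_hex(canonical_json(x))` is a stable digest.
#'
#' @param x An R object built from named/unnamed lists, character, numeric,
#'   integer and logical vectors, and `NULL`.
#' @return A length-1 character string of JSON.
#' @export
canonical_json <- function(x) {
  paste0(cj_render(x), collapse = "")
}

cj_render <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) {
      if (anyDuplicated(nm)) stop_fdt("duplicate keys in canonical JSON object")
      ord <- order(nm, method = "radix")   # bytewise, locale-independent
      inner <- vapply(ord, function(i) {
        paste0(cj_string(nm[i]), ":", cj_render(x[[i]]))
      }, character(1))
      return(paste0("{", paste0(inner, collapse = ","), "}"))
    }
    inner <- vapply(seq_along(x), function(i) cj_render(x[[i]]), character(1))
    return(paste0("[", paste0(inner, collapse = ","), "]"))
  }
  if (length(x) != 1L) {
    inner <- vapply(seq_along(x), function(i) cj_scalar(x[i]), character(1))
    return(paste0("[", paste0(inner, collapse = ","), "]"))
  }
  cj_scalar(x)
}

cj_scalar <- function(x) {
  if (is.na(x)) return("null")
  if (is.character(x)) return(cj_string(x))
  if (is.logical(x)) return(if (x) "true" else "false")
  if (is.integer(x)) return(as.character(x))
  if (is.numeric(x)) {
    if (!is.finite(x)) stop_fdt("non-finite number in canonical JSON")
    if (x == round(x) && abs(x) < 2^53) {
      # integral doubles render without a fraction part for stability
      return(sprintf("%.0f", x))
    }
    return(sprintf("%.12f", x))
  }
  stop_fdt("unsupported type in canonical JSON: ", class(x)[1])
}

cj_string <- function(s) {
  s <- enc2utf8(s)
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  paste0("\"", s, "\"")
}
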
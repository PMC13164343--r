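#' SHA-256 digest of a character string or raw vector
#'
#' Content-hash primitive used for tamper-evident attestation of decision
#' trace artifacts. Character input is serialized as UTF-8 bytes (no
#' trailing newline) before hashing.
#'
#' @param x A length-1 character vector or a raw vector.
#' @return Lower-case 64-character hexadecimal digest.
#' @examples
#' sha256_hex("abc")
#' @export
sha256_hex <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L) stop_fdt("sha256_hex() expects a single string")
    x <- charToRaw(enc2utf8(x))
  }
  if (!is.raw(x)) stop_fdt("sha256_hex() expects a string or raw vector")
  .Call(C_sha256_hex, x)
}
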
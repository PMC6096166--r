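#' @importFrom stats rbinom runif setNames var
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize a term or affix form
#'
#' Lowercases and applies Unicode NFC normalization.  Spanish diacritics
#' are preserved: stripping them would create spurious affix matches
#' (e.g. between accented and unaccented Spanish forms).
#'
#' @param x character vector.
#' @param strip_hyphens if `TRUE`, leading/trailing hyphen markers (as
#'   printed in affix tables, e.g. `"adip-"`, `"-opsia"`) are removed.
#' @return normalized character vector.
#' @export
mg_normalize <- function(x, strip_hyphens = FALSE) {
  x <- stringi::stri_trans_nfc(stringi::stri_trans_tolower(x))
  if (strip_hyphens) {
    x <- stringi::stri_replace_all_regex(x, "^[-‐‑]+|[-‐‑]+$", "")
  }
  x
}

# letters-only check used by affix validation
has_only_letters <- function(x) {
  stringi::stri_detect_regex(x, "^\\p{L}+$")
}

mg_stop <- function(...) stop(..., call. = FALSE)

mg_assert <- function(cond, ...) if (!isTRUE(cond)) mg_stop(...)
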
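# Identifier parsing, validation and classification: CAS Registry Numbers,
# NOCAS placeholders, DTX* registry identifiers, and name normalization.

#' Compute the CAS Registry Number check digit
#'
#' The final digit of a CAS RN is a checksum over the digits of the first two
#' segments: counting from the rightmost of those digits leftward, each digit
#' is weighted 1, 2, 3, ..., the weighted digits are summed, and the sum is
#' reduced modulo 10.
#'
#' @param digits Character vector of digit strings (the registry segment
#'   followed by the two-digit middle segment, 4--9 digits total, hyphens
#'   permitted and ignored).
#' @return Integer vector of check digits (0--9).
#' @examples
#' cas_check_digit("2506838")  # 6, completing 25068-38-6
#' cas_check_digit("7732-18")  # 5, completing 7732-18-5 (water)
#' @export
cas_check_digit <- function(digits) {
  digits <- gsub("-", "", as.character(digits), fixed = TRUE)
  bad <- !grepl("^[0-9]{4,9}$", digits)
  if (any(bad)) {
    stop("cas_check_digit: input must be 4-9 digits (got ",
         paste(utils::head(digits[bad], 3L), collapse = ", "), ")",
         call. = FALSE)
  }
  vapply(digits, function(d) {
    v <- rev(as.integer(strsplit(d, "")[[1L]]))
    as.integer(sum(v * seq_along(v)) %% 10L)
  }, integer(1L), USE.NAMES = FALSE)
}

cas_shape_regex <- "^[0-9]{2,7}-[0-9]{2}-[0-9]$"

#' Validate a CAS Registry Number
#'
#' A string is accepted as a potentially valid CAS RN when it has the
#' three-segment numeric form `##...##-##-#` and its final digit equals the
#' checksum of the preceding digits (see [cas_check_digit()]). Failures are
#' returned as values, not errors, so that noisy source identifiers can be
#' routed (e.g. stored as searchable synonyms) rather than rejected outright.
#'
#' @param text A single character string.
#' @return An object of class `casrn` (fields `text`, `registry_part`,
#'   `middle_part`, `check_digit`) on success, otherwise an object of class
#'   `cas_failure` whose `reason` is `"format"` or `"checksum"`.
#' @examples
#' validate_casrn("25068-38-6")  # valid
#' validate_casrn("25068-38-5")  # checksum failure
#' validate_casrn("1234-5")      # format failure
#' @export
validate_casrn <- function(text) {
  stopifnot(length(text) == 1L)
  text <- trimws(as.character(text))
  if (!grepl(cas_shape_regex, text)) {
    return(structure(list(text = text, reason = "format"),
                     class = "cas_failure"))
  }
  parts <- strsplit(text, "-", fixed = TRUE)[[1L]]
  expected <- cas_check_digit(paste0(parts[1L], parts[2L]))
  if (as.integer(parts[3L]) != expected) {
    return(structure(list(text = text, reason = "checksum",
                          expected = expected),
                     class = "cas_failure"))
  }
  structure(list(text = text,
                 registry_part = parts[1L],
                 middle_part = parts[2L],
                 check_digit = as.integer(parts[3L])),
            class = "casrn")
}

#' Test whether strings are valid CAS Registry Numbers
#'
#' Vectorized predicate combining the format and checksum rules of
#' [validate_casrn()].
#'
#' @param text Character vector.
#' @return Logical vector.
#' @export
is_valid_casrn <- function(text) {
  text <- trimws(as.character(text))
  ok <- !is.na(text) & grepl(cas_shape_regex, text)
  if (any(ok)) {
    sub <- text[ok]
    pre <- sub("-[0-9]$", "", sub)
    last <- as.integer(sub("^.*-", "", sub))
    ok[ok] <- cas_check_digit(pre) == last
  }
  ok
}

#' @export
print.casrn <- function(x, ...) {
  cat("<CAS RN>", x$text, "\n")
  invisible(x)
}

#' @export
print.cas_failure <- function(x, ...) {
  cat("<invalid CAS RN>", x$text, "- rule failed:", x$reason, "\n")
  invisible(x)
}

#' Format a NOCAS placeholder identifier
#'
#' Substances with no CAS RN on record are registered under a `NOCAS_#####`
#' placeholder sharing the CAS namespace. Serials are zero-padded to at least
#' five digits and expand as needed.
#'
#' @param serial Positive integer vector.
#' @return Character vector like `"NOCAS_00017"`.
#' @export
nocas_format <- function(serial) {
  serial <- as.integer(serial)
  stopifnot(all(serial >= 1L))
  sprintf("NOCAS_%05d", serial)
}

nocas_regex <- "^NOCAS_[0-9]{5,}$"

dtx_kinds <- c("DTXRID", "DTXSID", "DTXCID")
dtx_regex <- "^DTX[RSC]ID[0-9]+$"

#' Format and parse DTX registry identifiers
#'
#' The registry mints three identifier families: `DTXRID` (raw source
#' record), `DTXSID` (generic substance) and `DTXCID` (structure). The text
#' form is the kind tag followed by a zero-padded serial; serials increase
#' strictly per kind and carry no embedded check digit.
#'
#' @param kind One of `"DTXRID"`, `"DTXSID"`, `"DTXCID"`.
#' @param serial Positive integer vector.
#' @return `dtx_format()`: character vector. `dtx_parse()`: a list with
#'   `kind` and `serial`, or `NULL` when `text` is not a DTX identifier.
#' @export
dtx_format <- function(kind, serial) {
  kind <- match.arg(kind, dtx_kinds)
  serial <- as.integer(serial)
  stopifnot(all(serial >= 1L))
  sprintf("%s%07d", kind, serial)
}

#' @rdname dtx_format
#' @param text A single string.
#' @export
dtx_parse <- function(text) {
  text <- as.character(text)
  stopifnot(length(text) == 1L)
  if (!grepl(dtx_regex, text)) return(NULL)
  list(kind = substr(text, 1L, 6L),
       serial = as.integer(substr(text, 7L, nchar(text))))
}

#' Classify a free-text query
#'
#' Routes a search-box style query to one of four identifier classes. A
#' CAS-shaped string whose checksum fails is classified as a `name`: public
#' lists contain malformed registry numbers, and those strings must remain
#' searchable as synonyms rather than being rejected.
#'
#' @param text A single non-empty string.
#' @return One of `"casrn"`, `"nocas"`, `"dsstox_id"`, `"name"`.
#' @examples
#' classify_query("DTXSID0050479")
#' classify_query("25068-38-6")
#' classify_query("Bisphenol A/Epichlorohydrin resin")
#' @export
classify_query <- function(text) {
  stopifnot(length(text) == 1L)
  text <- trimws(as.character(text))
  if (is.na(text) || !nzchar(text)) {
    stop("classify_query: query must be a non-empty string", call. = FALSE)
  }
  if (grepl(dtx_regex, text)) return("dsstox_id")
  if (grepl(nocas_regex, text)) return("nocas")
  if (is_valid_casrn(text)) return("casrn")
  "name"
}

#' Normalize a chemical name for identity comparison
#'
#' Name uniqueness in the registry is enforced on a normalized form:
#' Unicode NFC, case-folded, with internal whitespace collapsed to single
#' spaces and outer whitespace trimmed. Punctuation, digits and stereo
#' descriptors are preserved untouched -- chemical names are semantically
#' sensitive to both (e.g. `1,2-` vs `1,3-`, `(R)-` vs `(S)-`). The function
#' is idempotent.
#'
#' @param text Character vector of names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_name("  Bisphenol  A ")  # "bisphenol a"
#' @export
normalize_name <- function(text) {
  x <- stringi::stri_trans_nfc(as.character(text))
  x <- stringi::stri_trans_tolower(x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}
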
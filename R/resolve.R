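# Four-outcome query resolution against the registry.

resolution <- function(outcome, matches = character(), via = NULL) {
  structure(list(outcome = outcome, matches = matches, via = via),
            class = "resolution_result")
}

#' @export
print.resolution_result <- function(x, ...) {
  cat("<resolution>", x$outcome,
      if (length(x$matches)) paste("->", paste(x$matches, collapse = ", "))
      else "",
      if (!is.null(x$via)) paste("(via", x$via, ")") else "", "\n")
  invisible(x)
}

smiles_like <- function(text) {
  # Conservative: only strings with structural punctuation are tried as
  # SMILES, so plain words are never mistaken for structure queries. Pure
  # element-chain SMILES (e.g. "CCO") must be submitted with type="smiles".
  !grepl("[[:space:]]", text) && grepl("[][()=#@\\\\/]", text)
}

#' Resolve a query to registered substances
#'
#' The resolution procedure runs four steps strictly in order, returning at
#' the first applicable outcome:
#' 1. exact match on an active identifier (CAS RN, NOCAS id, DTX id, or
#'    preferred name) -- outcome `exact`;
#' 2. reroute through the deleted-CAS-RN table or the synonym table to a
#'    single substance -- outcome `redirected` (with `via` saying which
#'    table); when the two tables disagree, both candidates are surfaced as
#'    `multiple`;
#' 3. an ambiguous synonym shared by two or more substances -- outcome
#'    `multiple` listing all of them;
#' 4. otherwise `not_found`.
#'
#' Structure queries (SMILES, or `type = "smiles"`) are converted to an
#' InChIKey and resolved by key equality against registered structures; a
#' SMILES matching no structure is `not_found` and never falls through to
#' name matching.
#'
#' @param reg Registry.
#' @param text Query string.
#' @param type `"auto"` (classify the query) or `"smiles"`.
#' @return An object of class `resolution_result`: `outcome` in
#'   `exact`/`redirected`/`multiple`/`not_found`, `matches` (DTXSIDs), and
#'   `via` (`"deleted_cas"` or `"synonym"` for redirects).
#' @export
resolve_query <- function(reg, text, type = c("auto", "smiles")) {
  stopifnot(inherits(reg, "chem_registry"))
  type <- match.arg(type)
  text <- trimws(as.character(text))
  if (!nzchar(text)) return(resolution("not_found"))

  if (type == "smiles" ||
      (type == "auto" && classify_query(text) == "name" &&
       smiles_like(text) && !is.na(structure_key(text)))) {
    key <- structure_key(text)
    if (is.na(key)) return(resolution("not_found"))
    dtxcid <- reg$idx_key[[key]]
    if (is.null(dtxcid)) return(resolution("not_found"))
    owner <- reg$struct_owner[[dtxcid]]
    if (is.null(owner)) return(resolution("not_found"))
    return(resolution("exact", owner))
  }

  cls <- classify_query(text)

  if (cls == "dsstox_id") {
    p <- dtx_parse(text)
    if (p$kind == "DTXSID" && !is.null(reg$substances[[text]])) {
      return(resolution("exact", text))
    }
    if (p$kind == "DTXCID" && !is.null(reg$struct_owner[[text]])) {
      return(resolution("exact", reg$struct_owner[[text]]))
    }
    if (p$kind == "DTXRID" && !is.null(reg$source_records[[text]])) {
      mapped <- reg$source_records[[text]]$mapped_to
      if (!is.na(mapped)) return(resolution("exact", mapped))
    }
    return(resolution("not_found"))
  }

  if (cls %in% c("casrn", "nocas")) {
    # step 1: active identifier
    hit <- reg$idx_cas[[text]]
    if (!is.null(hit)) return(resolution("exact", hit))
    # step 2: deleted CAS RN table, then synonym table
    del <- reg$idx_deleted[[text]]
    syn <- reg$synonyms[[normalize_name(text)]]
    syn_targets <- if (is.null(syn)) character() else unique(syn$targets)
    if (!is.null(del)) {
      if (length(syn_targets) && !all(syn_targets == del)) {
        return(resolution("multiple", unique(c(del, syn_targets))))
      }
      return(resolution("redirected", del, via = "deleted_cas"))
    }
    if (length(syn_targets) == 1L) {
      return(resolution("redirected", syn_targets, via = "synonym"))
    }
    if (length(syn_targets) >= 2L) {
      return(resolution("multiple", syn_targets))
    }
    return(resolution("not_found"))
  }

  # names: step 1 preferred name, step 2 synonym redirect, step 3 ambiguous
  norm <- normalize_name(text)
  hit <- reg$idx_name[[norm]]
  if (!is.null(hit)) return(resolution("exact", hit))
  syn <- reg$synonyms[[norm]]
  if (!is.null(syn)) {
    targets <- unique(syn$targets)
    if (length(targets) == 1L) {
      return(resolution("redirected", targets, via = "synonym"))
    }
    if (length(targets) >= 2L) return(resolution("multiple", targets))
  }
  resolution("not_found")
}
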
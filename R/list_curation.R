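# Registration of source lists against the core: auto-mapping, typed
# conflict binning, and curator resolution actions.

curation_bins <- c("auto_mapped", "cas_name_split", "cas_only_hit",
                   "name_only_hit", "deleted_cas_hit", "ambiguous_name",
                   "no_hit", "structure_mismatch", "structure_only_hit")

#' Bin a source list against the core registry
#'
#' Stage one of list registration. For each record, its CAS RN, its name and
#' (when present) its structure key are resolved *independently* against the
#' core; a record is auto-mapped only when every identifier it carries
#' agrees on a single substance. Any disagreement lands in a typed conflict
#' bin for manual curation -- the engine never silently picks a best guess,
#' because silent guessing is precisely how public mappings rot. The
#' operation is read-only on the core.
#'
#' Bins: `auto_mapped`; `cas_name_split` (CAS and name hit different
#' substances); `cas_only_hit` (CAS resolves, name unknown); `name_only_hit`
#' (name resolves, CAS absent/unknown); `deleted_cas_hit` (CAS on file only
#' as a deleted CAS RN); `ambiguous_name` (name is an ambiguous synonym and
#' no CAS pins it down); `structure_mismatch` (the structure key disagrees
#' with where CAS/name point); `structure_only_hit`; `no_hit`.
#'
#' @param reg Core registry.
#' @param records Data.frame of source records (`record_id`, `raw_name`,
#'   `raw_cas`, `raw_smiles`), e.g. from [read_source_csv()].
#' @return An object of class `curation_binning`: a data.frame `detail`
#'   (per-record bin and targets) plus `bins`, a named list of record-id
#'   vectors; `table(x)` gives bin totals.
#' @export
bin_source_list <- function(reg, records) {
  stopifnot(inherits(reg, "chem_registry"))
  df <- prepare_source_records(records)
  n <- nrow(df)
  bin <- character(n)
  target <- rep(NA_character_, n)
  cas_t <- rep(NA_character_, n)
  name_t <- rep(NA_character_, n)
  key_t <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    a <- df$cas_clean[i]
    nn <- df$name_norm[i]
    k <- df$key[i]

    cas_hit <- if (!is.na(a)) reg$idx_cas[[a]] else NULL
    del_hit <- if (!is.na(a) && is.null(cas_hit))
      reg$idx_deleted[[a]] else NULL
    name_hits <- character()
    if (!is.na(nn)) {
      ph <- reg$idx_name[[nn]]
      if (!is.null(ph)) name_hits <- ph
      else {
        syn <- reg$synonyms[[nn]]
        if (!is.null(syn)) name_hits <- unique(syn$targets)
      }
    }
    key_hit <- NULL
    if (!is.na(k)) {
      cid <- reg$idx_key[[k]]
      if (!is.null(cid)) key_hit <- reg$struct_owner[[cid]]
    }

    cas_t[i] <- cas_hit %||% del_hit %||% NA_character_
    name_t[i] <- if (length(name_hits)) paste(name_hits, collapse = ";")
                 else NA_character_
    key_t[i] <- key_hit %||% NA_character_

    bin[i] <- classify_bin(a, nn, k, cas_hit, del_hit, name_hits, key_hit)
    # the agreed / primary target for downstream mapping
    target[i] <- switch(bin[i],
      auto_mapped = cas_hit %||% (if (length(name_hits) == 1L) name_hits
                                  else key_hit),
      cas_only_hit = cas_hit,
      name_only_hit = name_hits[1L],
      deleted_cas_hit = del_hit,
      structure_only_hit = key_hit,
      NA_character_)
  }

  detail <- data.frame(record_id = df$record_id, bin = bin,
                       target = target, cas_target = cas_t,
                       name_target = name_t, key_target = key_t,
                       raw_name = df$raw_name, raw_cas = df$raw_cas,
                       cas_clean = df$cas_clean, name_norm = df$name_norm,
                       key = df$key, stringsAsFactors = FALSE)
  bins <- split(detail$record_id, factor(detail$bin, levels = curation_bins))
  structure(list(detail = detail, bins = bins), class = "curation_binning")
}

# A record is auto-mapped when every identifier it carries that the core
# knows at all agrees on one substance; an identifier the core has never
# seen is no evidence either way, *except* that a present-but-unknown CAS
# (resp. name) alongside a resolving name (resp. CAS) is flagged as
# name_only_hit (resp. cas_only_hit) for curator attention.
classify_bin <- function(a, nn, k, cas_hit, del_hit, name_hits, key_hit) {
  any_hit <- !is.null(cas_hit) || !is.null(del_hit) ||
    length(name_hits) > 0L || !is.null(key_hit)
  if (!any_hit) return("no_hit")
  if (is.null(cas_hit) && !is.null(del_hit)) return("deleted_cas_hit")
  if (!is.null(cas_hit)) {
    if (!is.null(key_hit) && !identical(key_hit, cas_hit)) {
      return("structure_mismatch")
    }
    if (length(name_hits)) {
      if (!(cas_hit %in% name_hits)) return("cas_name_split")
      return("auto_mapped")
    }
    if (is.na(nn)) return("auto_mapped")
    return("cas_only_hit")
  }
  # no active-CAS hit
  if (length(name_hits) >= 2L) return("ambiguous_name")
  if (length(name_hits) == 1L) {
    if (!is.null(key_hit) && !identical(key_hit, name_hits)) {
      return("structure_mismatch")
    }
    if (is.na(a)) return("auto_mapped")
    return("name_only_hit")
  }
  if (!is.null(key_hit)) return("structure_only_hit")
  "no_hit"
}

#' @export
print.curation_binning <- function(x, ...) {
  tab <- table(factor(x$detail$bin, levels = curation_bins))
  cat("<curation_binning>", nrow(x$detail), "records\n")
  for (b in names(tab)) if (tab[[b]]) cat(" ", b, ":", tab[[b]], "\n")
  invisible(x)
}

#' Start a registered list
#'
#' @param reg Core registry.
#' @param list_id Short identifier for the list.
#' @param name Display name.
#' @param visibility `"public"` or `"internal"`.
#' @return The list state (class `registered_list`), also stored in the
#'   registry.
#' @export
register_list <- function(reg, list_id, name = list_id,
                          visibility = c("public", "internal")) {
  visibility <- match.arg(visibility)
  lst <- structure(list(list_id = list_id, name = name,
                        visibility = visibility,
                        members = character(), provenance = character(),
                        unresolved = character()),
                   class = "registered_list")
  reg$lists[[list_id]] <- lst
  lst
}

#' Apply a curator resolution to a binned record
#'
#' Legal actions: `map_to` (attach the record to substance `target`;
#' required for conflict bins, implicit target for `auto_mapped`),
#' `register_new` (mint a substance from the record's identifiers),
#' `reject`, and `defer` (leave unresolved; partial list registration
#' proceeds). Mapping a `cas_name_split` record stores the discordant source
#' name as a `source_name` synonym candidate of the target. All registry
#' invariants are preserved; an action that would violate them fails with no
#' state change.
#'
#' @param reg Core registry.
#' @param list_id A list started with [register_list()].
#' @param binning A [bin_source_list()] result.
#' @param record_id Record to resolve.
#' @param action One of `map_to`, `register_new`, `reject`, `defer`.
#' @param target DTXSID, required for `map_to` when the bin has no implied
#'   target.
#' @return The updated `registered_list`, invisibly.
#' @export
apply_resolution <- function(reg, list_id, binning, record_id,
                             action = c("map_to", "register_new", "reject",
                                        "defer"),
                             target = NULL) {
  action <- match.arg(action)
  stopifnot(inherits(reg, "chem_registry"),
            inherits(binning, "curation_binning"))
  lst <- reg$lists[[list_id]]
  if (is.null(lst)) stop("apply_resolution: unknown list ", list_id,
                         call. = FALSE)
  row <- binning$detail[binning$detail$record_id == record_id, , drop = FALSE]
  if (!nrow(row)) stop("apply_resolution: unknown record ", record_id,
                       call. = FALSE)
  row <- row[1L, ]

  if (action == "defer") {
    lst$unresolved <- union(lst$unresolved, record_id)
    reg$lists[[list_id]] <- lst
    return(invisible(lst))
  }
  if (action == "reject") {
    lst$unresolved <- setdiff(lst$unresolved, record_id)
    reg$lists[[list_id]] <- lst
    return(invisible(lst))
  }
  if (action == "register_new") {
    res <- register_substance(
      reg, name = if (is.na(row$raw_name)) paste("unnamed", record_id)
                  else row$raw_name,
      cas = if (is.na(row$cas_clean)) NULL else row$cas_clean,
      structure_key = if (is.na(row$key)) NULL else row$key,
      qc = "Public_Low")
    if (is_conflict(res)) {
      stop("apply_resolution: register_new conflicts (", res$type, ")",
           call. = FALSE)
    }
    target <- res$dtxsid
  }
  if (action == "map_to") {
    if (is.null(target)) target <- row$target
    if (is.null(target) || is.na(target)) {
      stop("apply_resolution: map_to requires a target substance",
           call. = FALSE)
    }
    if (is.null(reg$substances[[target]])) {
      stop("apply_resolution: target ", target, " does not exist",
           call. = FALSE)
    }
    # harvest the source name; for a cas/name split the discordant name
    # becomes a synonym candidate of the mapped substance
    if (!is.na(row$raw_name)) {
      add_synonym(reg, target, row$raw_name, "source_name")
    }
  }

  rid <- mint_id(reg, "DTXRID")
  reg$source_records[[rid]] <- list(dtxrid = rid, list_id = list_id,
                                    raw_name = row$raw_name,
                                    raw_cas = row$raw_cas,
                                    raw_smiles = NA_character_,
                                    mapped_to = target)
  lst$members <- union(lst$members, target)
  lst$provenance[target] <- rid
  lst$unresolved <- setdiff(lst$unresolved, record_id)
  reg$lists[[list_id]] <- lst
  invisible(lst)
}

#' Elevate the quality-control level of a substance
#'
#' Curator review can raise confidence (e.g. `Public_Low` to `DSSTox_Low`
#' after public-source consensus, or to `DSSTox_High` after definitive
#' confirmation). Only strict elevations are allowed here; demotion is a
#' separate, deliberately distinct operation.
#'
#' @param reg Registry.
#' @param dtxsid Substance.
#' @param new_level Target qc level, strictly higher confidence than the
#'   current one.
#' @param evidence_note Free-text justification, appended to the substance
#'   notes.
#' @return The updated substance record.
#' @export
elevate_qc <- function(reg, dtxsid, new_level, evidence_note = "") {
  stopifnot(inherits(reg, "chem_registry"))
  sub <- reg$substances[[dtxsid]]
  if (is.null(sub)) stop("elevate_qc: unknown substance ", dtxsid,
                         call. = FALSE)
  if (qc_rank(new_level) >= qc_rank(sub$qc_level)) {
    stop("elevate_qc: ", new_level, " is not a strict elevation from ",
         sub$qc_level, call. = FALSE)
  }
  sub$qc_level <- new_level
  if (nzchar(evidence_note)) {
    sub$notes <- paste0(sub$notes, if (nzchar(sub$notes)) "\n",
                        "[elevated to ", new_level, "] ", evidence_note)
  }
  reg$substances[[dtxsid]] <- sub
  sub
}

#' Overlap between two registered lists
#'
#' @param reg Registry.
#' @param a,b List identifiers.
#' @return Character vector of DTXSIDs in both lists.
#' @export
list_overlap <- function(reg, a, b) {
  la <- reg$lists[[a]]
  lb <- reg$lists[[b]]
  if (is.null(la) || is.null(lb)) {
    stop("list_overlap: both lists must be registered", call. = FALSE)
  }
  intersect(la$members, lb$members)
}
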
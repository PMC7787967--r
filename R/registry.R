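# The core substance registry: generic substances, structures, synonyms,
# deleted CAS RNs, relationships, and the registration transaction that
# enforces the 1:1:1 CAS RN - preferred name - structure rule.
#
# The registry is a mutable environment (reference semantics) holding hash
# indexes; every public mutation either completes with all invariants intact
# or leaves the state untouched and returns a typed conflict report.

#' Quality-control levels, ordered by descending curator confidence
#'
#' Five in-registry tiers; quarantined content is marked with the
#' out-of-registry label `Public_Untrusted` (see [autoload_sequence()]) and
#' never enters the uniqueness indexes.
#'
#' @return Character vector of the five levels, highest confidence first.
#' @export
qc_levels <- function() {
  c("DSSTox_High", "DSSTox_Low", "Public_High", "Public_Medium", "Public_Low")
}

#' Rank of a qc level (1 = highest confidence)
#' @param level Character vector of qc levels.
#' @return Integer ranks.
#' @export
qc_rank <- function(level) {
  r <- match(level, qc_levels())
  if (anyNA(r)) {
    stop("unknown qc level: ",
         paste(unique(level[is.na(r)]), collapse = ", "), call. = FALSE)
  }
  r
}

#' Create an empty substance registry
#'
#' @return An object of class `chem_registry` (an environment).
#' @examples
#' reg <- registry_new()
#' register_substance(reg, "benzene", "71-43-2", "c1ccccc1")
#' @export
registry_new <- function() {
  reg <- new.env(parent = emptyenv())
  reg$substances <- new.env(parent = emptyenv())   # dtxsid -> record
  reg$structures <- new.env(parent = emptyenv())   # dtxcid -> structure
  reg$idx_cas <- new.env(parent = emptyenv())      # active cas/NOCAS -> dtxsid
  reg$idx_name <- new.env(parent = emptyenv())     # normalized name -> dtxsid
  reg$idx_key <- new.env(parent = emptyenv())      # InChIKey -> dtxcid
  reg$struct_owner <- new.env(parent = emptyenv()) # dtxcid -> dtxsid
  reg$idx_deleted <- new.env(parent = emptyenv())  # deleted cas -> dtxsid
  reg$synonyms <- new.env(parent = emptyenv())     # norm -> list(display, targets, types)
  reg$relationships <- list()
  reg$source_records <- new.env(parent = emptyenv()) # dtxrid -> record
  reg$lists <- new.env(parent = emptyenv())          # list_id -> registered list
  reg$quarantine <- list()
  reg$counters <- new.env(parent = emptyenv())
  for (k in c("DTXSID", "DTXCID", "DTXRID", "NOCAS")) reg$counters[[k]] <- 0L
  class(reg) <- "chem_registry"
  reg
}

#' @export
print.chem_registry <- function(x, ...) {
  cat("<chem_registry>", length(ls(x$substances)), "substances,",
      length(ls(x$structures)), "structures,",
      length(ls(x$idx_deleted)), "deleted CAS RNs,",
      length(x$quarantine), "quarantined records\n")
  invisible(x)
}

mint_id <- function(reg, kind) {
  n <- reg$counters[[kind]] + 1L
  reg$counters[[kind]] <- n
  if (kind == "NOCAS") nocas_format(n) else dtx_format(kind, n)
}

conflict_report <- function(type, existing = NULL, detail = "") {
  structure(list(type = type, existing = existing, detail = detail),
            class = "conflict_report")
}

#' @export
print.conflict_report <- function(x, ...) {
  cat("<conflict>", x$type,
      if (!is.null(x$existing)) paste("with", x$existing) else "",
      x$detail, "\n")
  invisible(x)
}

#' Test for a registration conflict result
#' @param x Object returned by [register_substance()] and friends.
#' @return Logical.
#' @export
is_conflict <- function(x) inherits(x, "conflict_report")

# Intern a structure: reuse the existing DTXCID when the key is known,
# otherwise mint one. Returns list(dtxcid, key, owner) where owner is the
# current owning substance (NULL when unowned).
intern_structure <- function(reg, smiles = NULL, key = NULL) {
  if (is.null(key)) {
    key <- structure_key(smiles)
    if (is.na(key)) {
      stop("unparseable structure: ", smiles, call. = FALSE)
    }
  }
  dtxcid <- reg$idx_key[[key]]
  if (is.null(dtxcid)) {
    list(dtxcid = NULL, key = key, owner = NULL, smiles = smiles)
  } else {
    list(dtxcid = dtxcid, key = key, owner = reg$struct_owner[[dtxcid]],
         smiles = smiles)
  }
}

#' Register a generic substance
#'
#' The registration transaction. A new substance is accepted only when none
#' of its identifiers collide with existing content: the CAS RN must not
#' equal any active or deleted CAS RN on file, the normalized preferred name
#' must be new, and the structure (when given) must not already be mapped to
#' a substance. On any collision the registry is left untouched and a typed
#' conflict report is returned. When no CAS RN is supplied a `NOCAS_#####`
#' placeholder is minted in the shared CAS namespace.
#'
#' @param reg A [registry_new()] registry.
#' @param name Preferred name (display casing preserved; uniqueness is
#'   enforced on the normalized form).
#' @param cas CAS RN string, or `NULL` for a NOCAS substance. Strings
#'   failing format or checksum raise a validation error (distinct from a
#'   conflict).
#' @param smiles Optional structure as SMILES.
#' @param qc Quality-control level, see [qc_levels()].
#' @param structure_key Optional precomputed InChIKey for `smiles` (skips
#'   recomputation during bulk loads).
#' @param notes Free-text curator notes.
#' @return The substance record (class `chem_substance`) on success, or a
#'   `conflict_report` (types `cas_collision`, `deleted_cas_collision`,
#'   `name_collision`, `structure_collision`) with no state change.
#' @export
register_substance <- function(reg, name, cas = NULL, smiles = NULL,
                               qc = "DSSTox_Low", structure_key = NULL,
                               notes = "") {
  stopifnot(inherits(reg, "chem_registry"))
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name))) {
    stop("register_substance: name must be a non-empty string",
         call. = FALSE)
  }
  qc <- match.arg(qc, qc_levels())
  if (!is.null(cas)) {
    v <- validate_casrn(cas)
    if (inherits(v, "cas_failure")) {
      stop(structure(class = c("cas_validation_error", "error", "condition"),
                     list(message = paste0("invalid CAS RN '", cas, "' (",
                                           v$reason, " rule failed)"),
                          call = sys.call())))
    }
    cas <- v$text
  }
  nname <- normalize_name(name)

  # ---- conflict detection (no state change yet) ----
  if (!is.null(cas)) {
    ex <- reg$idx_cas[[cas]]
    if (!is.null(ex)) return(conflict_report("cas_collision", ex))
    exd <- reg$idx_deleted[[cas]]
    if (!is.null(exd)) {
      return(conflict_report("deleted_cas_collision", exd,
                             "CAS RN is on file as a deleted CAS RN"))
    }
  }
  exn <- reg$idx_name[[nname]]
  if (!is.null(exn)) return(conflict_report("name_collision", exn))
  st <- NULL
  if (!is.null(smiles) || !is.null(structure_key)) {
    st <- intern_structure(reg, smiles, structure_key)
    if (!is.null(st$owner)) {
      return(conflict_report("structure_collision", st$owner))
    }
  }

  # ---- commit ----
  dtxsid <- mint_id(reg, "DTXSID")
  if (is.null(cas)) {
    cas <- mint_id(reg, "NOCAS")
    cas_kind <- "nocas"
  } else {
    cas_kind <- "casrn"
  }
  dtxcid <- NA_character_
  if (!is.null(st)) {
    if (is.null(st$dtxcid)) {
      dtxcid <- mint_id(reg, "DTXCID")
      props <- if (!is.null(st$smiles)) mol_properties(st$smiles) else NULL
      reg$structures[[dtxcid]] <- list(
        dtxcid = dtxcid, smiles = st$smiles, key = st$key,
        formula = if (is.null(props)) NA_character_ else props$formula,
        average_mass = if (is.null(props)) NA_real_ else props$average_mass,
        monoisotopic_mass = if (is.null(props)) NA_real_ else
          props$monoisotopic_mass)
      reg$idx_key[[st$key]] <- dtxcid
    } else {
      dtxcid <- st$dtxcid
    }
    reg$struct_owner[[dtxcid]] <- dtxsid
  }
  sub <- structure(list(dtxsid = dtxsid, preferred_name = name,
                        name_norm = nname, cas = cas, cas_kind = cas_kind,
                        dtxcid = dtxcid, qc_level = qc, notes = notes),
                   class = "chem_substance")
  reg$substances[[dtxsid]] <- sub
  reg$idx_cas[[cas]] <- dtxsid
  reg$idx_name[[nname]] <- dtxsid
  sub
}

#' @export
print.chem_substance <- function(x, ...) {
  cat("<substance>", x$dtxsid, "|", x$preferred_name, "|", x$cas,
      "|", if (is.na(x$dtxcid)) "no structure" else x$dtxcid,
      "|", x$qc_level, "\n")
  invisible(x)
}

#' Fetch a substance record
#' @param reg Registry.
#' @param dtxsid Substance identifier.
#' @return The substance record, or `NULL`.
#' @export
get_substance <- function(reg, dtxsid) reg$substances[[dtxsid]]

#' Fetch a structure record
#' @param reg Registry.
#' @param dtxcid Structure identifier.
#' @return The structure record, or `NULL`.
#' @export
get_structure <- function(reg, dtxcid) reg$structures[[dtxcid]]

#' Record a deleted CAS RN redirect
#'
#' A deleted CAS RN is a formerly issued registry number now redirecting to
#' the active CAS RN of a substance; queries for it resolve with outcome
#' `redirected`. Adding the same redirect twice is a no-op; a deleted CAS RN
#' that equals any active CAS RN, or is already redirecting elsewhere, is a
#' conflict error.
#'
#' @param reg Registry.
#' @param dtxsid Target substance.
#' @param deleted The deleted CAS RN (must pass [validate_casrn()]).
#' @return Invisibly, the registry.
#' @export
add_deleted_casrn <- function(reg, dtxsid, deleted) {
  stopifnot(inherits(reg, "chem_registry"))
  if (is.null(reg$substances[[dtxsid]])) {
    stop("add_deleted_casrn: unknown substance ", dtxsid, call. = FALSE)
  }
  v <- validate_casrn(deleted)
  if (inherits(v, "cas_failure")) {
    stop("add_deleted_casrn: '", deleted, "' is not a valid CAS RN (",
         v$reason, ")", call. = FALSE)
  }
  deleted <- v$text
  if (!is.null(reg$idx_cas[[deleted]])) {
    stop("add_deleted_casrn: ", deleted,
         " is the active CAS RN of ", reg$idx_cas[[deleted]], call. = FALSE)
  }
  cur <- reg$idx_deleted[[deleted]]
  if (!is.null(cur)) {
    if (identical(cur, dtxsid)) return(invisible(reg))  # idempotent
    stop("add_deleted_casrn: ", deleted, " already redirects to ", cur,
         call. = FALSE)
  }
  reg$idx_deleted[[deleted]] <- dtxsid
  invisible(reg)
}

#' Attach a synonym to a substance
#'
#' Synonyms are advisory search redirects, never uniqueness-bearing. A
#' synonym whose normalized text maps to two or more substances is flagged
#' ambiguous and resolves with outcome `multiple`.
#'
#' @param reg Registry.
#' @param dtxsid Target substance.
#' @param text Synonym text.
#' @param type One of `valid_synonym`, `unique_synonym`, `source_name`.
#' @return Invisibly, the registry.
#' @export
add_synonym <- function(reg, dtxsid, text,
                        type = c("valid_synonym", "unique_synonym",
                                 "source_name")) {
  type <- match.arg(type)
  stopifnot(inherits(reg, "chem_registry"))
  if (is.null(reg$substances[[dtxsid]])) {
    stop("add_synonym: unknown substance ", dtxsid, call. = FALSE)
  }
  norm <- normalize_name(text)
  if (!nzchar(norm)) return(invisible(reg))
  entry <- reg$synonyms[[norm]]
  if (is.null(entry)) {
    entry <- list(display = text, targets = character(), types = character())
  }
  if (!(dtxsid %in% entry$targets)) {
    entry$targets <- c(entry$targets, dtxsid)
    entry$types <- c(entry$types, type)
  }
  reg$synonyms[[norm]] <- entry
  invisible(reg)
}

#' Is a synonym ambiguous?
#' @param reg Registry.
#' @param text Synonym text (normalized internally).
#' @return Logical: `TRUE` when the synonym maps to two or more substances.
#' @export
synonym_is_ambiguous <- function(reg, text) {
  entry <- reg$synonyms[[normalize_name(text)]]
  !is.null(entry) && length(unique(entry$targets)) >= 2L
}

relationship_types <- c("component_of_mixture", "monomer_of_polymer",
                        "salt_to_parent", "representative_structure_of",
                        "other")

#' Link two substances with a typed, directed relationship
#'
#' Relationships capture curated linkages such as a mixture record to its
#' components or a polymer record to its monomer. Edges are directed
#' (predecessor to successor) and typed; adding the identical edge twice is
#' a no-op.
#'
#' @param reg Registry.
#' @param predecessor,successor DTXSIDs of existing, distinct substances.
#' @param rel_type One of `component_of_mixture`, `monomer_of_polymer`,
#'   `salt_to_parent`, `representative_structure_of`, `other`.
#' @param annotation Free-text note.
#' @return The relationship record, invisibly.
#' @export
add_relationship <- function(reg, predecessor, successor,
                             rel_type = relationship_types,
                             annotation = "") {
  rel_type <- match.arg(rel_type)
  stopifnot(inherits(reg, "chem_registry"))
  if (identical(predecessor, successor)) {
    stop("add_relationship: self-edges are not allowed", call. = FALSE)
  }
  for (id in c(predecessor, successor)) {
    if (is.null(reg$substances[[id]])) {
      stop("add_relationship: unknown substance ", id, call. = FALSE)
    }
  }
  rel <- list(predecessor = predecessor, successor = successor,
              rel_type = rel_type, annotation = annotation)
  for (r in reg$relationships) {
    if (identical(r[1:3], rel[1:3])) return(invisible(r))  # idempotent
  }
  reg$relationships[[length(reg$relationships) + 1L]] <- rel
  invisible(rel)
}

#' Query relationships touching a substance
#'
#' @param reg Registry.
#' @param dtxsid Substance identifier.
#' @param direction `"out"` (as predecessor), `"in"` (as successor) or
#'   `"both"`.
#' @return A data.frame with columns `predecessor`, `successor`, `rel_type`,
#'   `annotation`.
#' @export
get_relationships <- function(reg, dtxsid = NULL,
                              direction = c("both", "out", "in")) {
  direction <- match.arg(direction)
  rels <- reg$relationships
  if (!is.null(dtxsid)) {
    rels <- Filter(function(r) {
      switch(direction,
             out = identical(r$predecessor, dtxsid),
             `in` = identical(r$successor, dtxsid),
             both = identical(r$predecessor, dtxsid) ||
               identical(r$successor, dtxsid))
    }, rels)
  }
  if (!length(rels)) {
    return(data.frame(predecessor = character(), successor = character(),
                      rel_type = character(), annotation = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(rels, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
}

#' Strip a representative structure from a substance
#'
#' Mixtures and other substances that cannot carry a single defined
#' structure are sometimes loaded with a "representative" structure really
#' belonging to a component. This repair removes the structure from the
#' flagged substance, ensures the structure is owned by exactly one
#' substance (registering a new owner when none exists), and records a
#' `representative_structure_of` relationship from the stripped substance to
#' the owner.
#'
#' @param reg Registry.
#' @param dtxsid Substance flagged as carrying a representative structure.
#' @param owner_name Preferred name for a newly registered owner when the
#'   structure has no other substance; defaults to a name derived from the
#'   stripped substance.
#' @return The relationship record, invisibly.
#' @export
strip_representative_structure <- function(reg, dtxsid, owner_name = NULL) {
  stopifnot(inherits(reg, "chem_registry"))
  sub <- reg$substances[[dtxsid]]
  if (is.null(sub)) {
    stop("strip_representative_structure: unknown substance ", dtxsid,
         call. = FALSE)
  }
  if (is.na(sub$dtxcid)) {
    stop("strip_representative_structure: ", dtxsid, " has no structure",
         call. = FALSE)
  }
  dtxcid <- sub$dtxcid

  # detach the structure from the flagged substance
  sub$dtxcid <- NA_character_
  reg$substances[[dtxsid]] <- sub
  if (!is.null(reg$struct_owner[[dtxcid]])) {
    rm(list = dtxcid, envir = reg$struct_owner)
  }

  # find (or register) the unique owner
  owner <- NULL
  for (sid in ls(reg$substances)) {
    other <- reg$substances[[sid]]
    if (!identical(sid, dtxsid) && identical(other$dtxcid, dtxcid)) {
      owner <- sid
      break
    }
  }
  if (is.null(owner)) {
    st <- reg$structures[[dtxcid]]
    if (is.null(owner_name)) {
      owner_name <- paste0(sub$preferred_name, " (defined component)")
    }
    new_sub <- register_substance(reg, owner_name, cas = NULL,
                                  smiles = NULL, qc = sub$qc_level,
                                  structure_key = st$key)
    if (is_conflict(new_sub)) {
      # restore and report
      sub$dtxcid <- dtxcid
      reg$substances[[dtxsid]] <- sub
      stop("strip_representative_structure: cannot register owner (",
           new_sub$type, ")", call. = FALSE)
    }
    owner <- new_sub$dtxsid
  }
  reg$struct_owner[[dtxcid]] <- owner
  add_relationship(reg, dtxsid, owner, "representative_structure_of",
                   "structure stripped as representative")
}

#' Scan the registry for 1:1:1 invariant violations
#'
#' Exhaustively recomputes uniqueness from the substance records themselves
#' (not the lookup indexes), so corruption injected past the public API is
#' detected. An empty result certifies: active CAS RNs and NOCAS ids unique;
#' normalized preferred names unique; each structure owned by exactly one
#' substance; no deleted CAS RN equal to an active CAS RN.
#'
#' @param reg Registry.
#' @return A list of violations, each `list(type, ids, value)`; empty when
#'   all invariants hold.
#' @export
check_invariants <- function(reg) {
  stopifnot(inherits(reg, "chem_registry"))
  subs <- lapply(ls(reg$substances), function(s) reg$substances[[s]])
  out <- list()
  if (length(subs)) {
    cas <- vapply(subs, `[[`, character(1L), "cas")
    ids <- vapply(subs, `[[`, character(1L), "dtxsid")
    nm <- vapply(subs, `[[`, character(1L), "name_norm")
    cid <- vapply(subs, `[[`, character(1L), "dtxcid")
    for (d in unique(cas[duplicated(cas)])) {
      out[[length(out) + 1L]] <- list(type = "cas_collision",
                                      ids = ids[cas == d], value = d)
    }
    for (d in unique(nm[duplicated(nm)])) {
      out[[length(out) + 1L]] <- list(type = "name_collision",
                                      ids = ids[nm == d], value = d)
    }
    has <- !is.na(cid)
    for (d in unique(cid[has][duplicated(cid[has])])) {
      out[[length(out) + 1L]] <- list(type = "structure_collision",
                                      ids = ids[has & cid == d], value = d)
    }
    del <- ls(reg$idx_deleted)
    bad <- del[del %in% cas]
    for (d in bad) {
      out[[length(out) + 1L]] <- list(
        type = "deleted_cas_is_active",
        ids = c(reg$idx_deleted[[d]], ids[cas == d]), value = d)
    }
  }
  out
}

# ---- internal corruption hooks -------------------------------------------
# Used by fixtures and tests to emulate curation-backlog states (e.g. a
# representative structure shared by two substances) that the public API
# refuses to create.

plant_shared_structure <- function(reg, dtxsid_from, dtxsid_to) {
  src <- reg$substances[[dtxsid_from]]
  dst <- reg$substances[[dtxsid_to]]
  stopifnot(!is.null(src), !is.null(dst), !is.na(src$dtxcid))
  dst$dtxcid <- src$dtxcid
  reg$substances[[dtxsid_to]] <- dst
  invisible(reg)
}

plant_duplicate_cas <- function(reg, dtxsid_from, dtxsid_to) {
  src <- reg$substances[[dtxsid_from]]
  dst <- reg$substances[[dtxsid_to]]
  stopifnot(!is.null(src), !is.null(dst))
  dst$cas <- src$cas
  reg$substances[[dtxsid_to]] <- dst
  invisible(reg)
}
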
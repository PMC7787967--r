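# Sequential, quality-filtered bulk loading of external source databases
# into the core registry. Each database passes three screens in order --
# internal identifier consistency, comparison against the next-level (less
# trusted) database, and an audit against the overlapping core content --
# before surviving records are registered at the database's assigned
# qc level. Every conflicted record is quarantined as Public_Untrusted with
# full provenance; quarantined content never enters the uniqueness indexes.

#' Construct a source database for bulk loading
#'
#' @param name Database name (e.g. `"srs"`).
#' @param records A data.frame with columns `record_id`, `raw_name`,
#'   `raw_cas`, `raw_smiles` (the latter may hold several alternative
#'   representations separated by `;` when a source provides multiple
#'   renderings of one record). Missing values as `NA`.
#' @param qc Quality-control level assigned to content loaded from this
#'   database; fixed before loading.
#' @return An object of class `source_db` with derived columns: validated
#'   CAS (`cas_clean`), normalized name (`name_norm`), primary structure
#'   key (`key`) and all keys (`all_keys`).
#' @export
source_db <- function(name, records, qc = "Public_Low") {
  qc <- match.arg(qc, qc_levels())
  recs <- prepare_source_records(records)
  structure(list(name = name, records = recs, assigned_qc = qc),
            class = "source_db")
}

#' @export
print.source_db <- function(x, ...) {
  cat("<source_db>", x$name, "-", nrow(x$records), "records, qc",
      x$assigned_qc, "\n")
  invisible(x)
}

prepare_source_records <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("record_id", "raw_name", "raw_cas", "raw_smiles")) {
    if (is.null(df[[col]])) df[[col]] <- NA_character_
    df[[col]] <- as.character(df[[col]])
  }
  if (all(is.na(df$record_id))) {
    df$record_id <- sprintf("rec-%05d", seq_len(nrow(df)))
  }
  df$name_norm <- ifelse(is.na(df$raw_name), NA_character_,
                         normalize_name(df$raw_name))
  df$cas_clean <- ifelse(is_valid_casrn(df$raw_cas), trimws(df$raw_cas),
                         NA_character_)
  if (is.null(df$all_keys)) {
    df$all_keys <- vapply(df$raw_smiles, function(s) {
      if (is.na(s)) return(NA_character_)
      parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
      parts <- parts[nzchar(parts)]
      keys <- unique(stats::na.omit(structure_key(parts)))
      if (!length(keys)) NA_character_ else paste(keys, collapse = ";")
    }, character(1L), USE.NAMES = FALSE)
  }
  df$key <- vapply(strsplit(ifelse(is.na(df$all_keys), "", df$all_keys),
                            ";", fixed = TRUE),
                   function(k) {
                     k <- unique(k[nzchar(k)])
                     if (length(k) == 1L) k else NA_character_
                   }, character(1L))
  df$n_keys <- vapply(strsplit(ifelse(is.na(df$all_keys), "", df$all_keys),
                               ";", fixed = TRUE),
                      function(k) length(unique(k[nzchar(k)])), integer(1L))
  rownames(df) <- NULL
  df
}

#' Screen a source database for internal identifier conflicts
#'
#' A record is internally conflicted when its identifiers participate in any
#' violation of the 1:1:1 rule *within* the database:
#' * its own alternative structure representations yield disagreeing keys;
#' * its CAS RN is associated with a different structure key elsewhere in
#'   the database (or with a structureless record);
#' * its structure key is associated with a different CAS RN elsewhere;
#' * for structureless records, its CAS RN/name pairing disagrees with
#'   another structureless record.
#'
#' Names are otherwise advisory (public names are too noisy to be
#' uniqueness-bearing at this stage).
#'
#' @param db A [source_db()].
#' @return A list: `clean` and `conflicted` data.frames partitioning the
#'   input, the latter with a `reason` column.
#' @export
internal_consistency_filter <- function(db) {
  stopifnot(inherits(db, "source_db"))
  df <- db$records
  n <- nrow(df)
  conflicted <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  mark <- function(idx, why) {
    newly <- idx[!conflicted[idx]]
    conflicted[newly] <<- TRUE
    reason[newly] <<- why
    reason[idx] <<- ifelse(is.na(reason[idx]), why, reason[idx])
  }

  # own representations disagree
  mark(which(df$n_keys >= 2L), "own_keys_disagree")

  structured <- df$n_keys >= 1L
  # CAS associated with >1 distinct key, or key with >1 distinct CAS
  with_both <- which(structured & !is.na(df$cas_clean) & !is.na(df$key))
  if (length(with_both)) {
    cas_keys <- tapply(df$key[with_both], df$cas_clean[with_both],
                       function(k) length(unique(k)))
    bad_cas <- names(cas_keys)[cas_keys >= 2L]
    mark(with_both[df$cas_clean[with_both] %in% bad_cas],
         "cas_maps_to_multiple_structures")
    key_cas <- tapply(df$cas_clean[with_both], df$key[with_both],
                      function(c) length(unique(c)))
    bad_key <- names(key_cas)[key_cas >= 2L]
    mark(with_both[df$key[with_both] %in% bad_key],
         "structure_maps_to_multiple_cas")
  }

  # CAS shared between structured and structureless records
  cas_struct <- unique(df$cas_clean[structured & !is.na(df$cas_clean)])
  cas_nostruct <- unique(df$cas_clean[!structured & !is.na(df$cas_clean)])
  both <- intersect(cas_struct, cas_nostruct)
  mark(which(!is.na(df$cas_clean) & df$cas_clean %in% both),
       "cas_shared_between_structured_and_structureless")

  # structureless block: CAS <-> name must pair one-to-one
  ns <- which(!structured & !is.na(df$cas_clean) & !is.na(df$name_norm))
  if (length(ns)) {
    cn <- tapply(df$name_norm[ns], df$cas_clean[ns],
                 function(x) length(unique(x)))
    bad <- names(cn)[cn >= 2L]
    mark(ns[df$cas_clean[ns] %in% bad], "cas_maps_to_multiple_names")
    nc <- tapply(df$cas_clean[ns], df$name_norm[ns],
                 function(x) length(unique(x)))
    bad <- names(nc)[nc >= 2L]
    mark(ns[df$name_norm[ns] %in% bad], "name_maps_to_multiple_cas")
  }

  clean <- df[!conflicted, , drop = FALSE]
  confl <- df[conflicted, , drop = FALSE]
  confl$reason <- reason[conflicted]
  rownames(clean) <- rownames(confl) <- NULL
  list(clean = clean, conflicted = confl)
}

#' Compare internally clean records against the next-level database
#'
#' Each structured record is checked against the next (less trusted, larger)
#' database: the record conflicts when that database associates its CAS RN
#' with a different structure key, or its structure key with a different CAS
#' RN. Records absent from the next-level database cannot be evaluated and
#' pass through as consistent; structureless records are not cross-checked.
#'
#' @param clean Data.frame of internally consistent records (from
#'   [internal_consistency_filter()]).
#' @param next_db A [source_db()], or `NULL` (everything passes; the last
#'   database in a load order has no next level).
#' @return List of data.frames `consistent` and `conflicted` (the latter
#'   with a `reason` column).
#' @export
cross_db_compare <- function(clean, next_db) {
  if (is.null(next_db)) {
    return(list(consistent = clean,
                conflicted = clean[0, , drop = FALSE]))
  }
  stopifnot(inherits(next_db, "source_db"))
  nx <- next_db$records
  nx <- nx[nx$n_keys >= 1L, , drop = FALSE]
  cas_key <- split(nx$key[!is.na(nx$cas_clean) & !is.na(nx$key)],
                   nx$cas_clean[!is.na(nx$cas_clean) & !is.na(nx$key)])
  key_cas <- split(nx$cas_clean[!is.na(nx$cas_clean) & !is.na(nx$key)],
                   nx$key[!is.na(nx$cas_clean) & !is.na(nx$key)])
  n <- nrow(clean)
  conflicted <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    k <- clean$key[i]
    a <- clean$cas_clean[i]
    if (is.na(k)) next
    if (!is.na(a)) {
      nk <- cas_key[[a]]
      if (!is.null(nk) && any(nk != k)) {
        conflicted[i] <- TRUE
        reason[i] <- "next_level_maps_cas_to_other_structure"
        next
      }
    }
    nc <- key_cas[[k]]
    if (!is.null(nc) && !is.na(a) && any(nc != a)) {
      conflicted[i] <- TRUE
      reason[i] <- "next_level_maps_structure_to_other_cas"
    }
  }
  confl <- clean[conflicted, , drop = FALSE]
  confl$reason <- reason[conflicted]
  cons <- clean[!conflicted, , drop = FALSE]
  rownames(cons) <- rownames(confl) <- NULL
  list(consistent = cons, conflicted = confl)
}

#' Audit cleaned records against the overlapping core content
#'
#' The portion of a cleaned set that overlaps the core (by CAS RN or by
#' structure key) measures the residual mapping-error rate: within the
#' overlap, a record either agrees with the core's mapping
#' (`already_present`) or disagrees (`conflicted`). Non-overlapping records
#' are `new`. The conflict rate is `conflicted / overlap` (0 for an empty
#' overlap); both the CAS-based and the CAS-or-structure overlap
#' denominators are reported.
#'
#' @param clean Data.frame of records that survived the earlier screens.
#' @param core A `chem_registry`.
#' @return List: data.frames `new`, `already_present`, `conflicted` (with
#'   `reason` and `core_match` columns), counts `overlap_n`,
#'   `overlap_cas_n`, and `conflict_rate`.
#' @export
core_overlap_audit <- function(clean, core) {
  stopifnot(inherits(core, "chem_registry"))
  n <- nrow(clean)
  disposition <- rep("new", n)
  reason <- rep(NA_character_, n)
  match_id <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    a <- clean$cas_clean[i]
    k <- clean$key[i]
    s1 <- if (!is.na(a)) core$idx_cas[[a]] else NULL
    s2 <- NULL
    if (!is.na(k)) {
      cid <- core$idx_key[[k]]
      if (!is.null(cid)) s2 <- core$struct_owner[[cid]]
    }
    if (is.null(s1) && is.null(s2)) next
    if (!is.null(s1) && !is.null(s2)) {
      if (identical(s1, s2)) {
        disposition[i] <- "already_present"
        match_id[i] <- s1
      } else {
        disposition[i] <- "conflicted"
        reason[i] <- "cas_and_structure_map_to_different_substances"
        match_id[i] <- s1
      }
    } else if (!is.null(s1)) {
      if (!is.na(k)) {
        disposition[i] <- "conflicted"
        reason[i] <- "core_maps_cas_to_other_structure"
        match_id[i] <- s1
      } else {
        sub <- core$substances[[s1]]
        agree <- identical(sub$name_norm, clean$name_norm[i])
        if (!agree && !is.na(clean$name_norm[i])) {
          syn <- core$synonyms[[clean$name_norm[i]]]
          agree <- !is.null(syn) && s1 %in% syn$targets
        }
        disposition[i] <- if (agree) "already_present" else "conflicted"
        if (!agree) reason[i] <- "core_maps_cas_to_other_name"
        match_id[i] <- s1
      }
    } else {  # structure known to core, CAS not
      if (!is.na(a)) {
        disposition[i] <- "conflicted"
        reason[i] <- "core_maps_structure_to_other_cas"
        match_id[i] <- s2
      } else {
        disposition[i] <- "already_present"
        match_id[i] <- s2
      }
    }
  }
  overlap <- disposition != "new"
  new <- clean[disposition == "new", , drop = FALSE]
  ap <- clean[disposition == "already_present", , drop = FALSE]
  ap$core_match <- match_id[disposition == "already_present"]
  cf <- clean[disposition == "conflicted", , drop = FALSE]
  cf$reason <- reason[disposition == "conflicted"]
  cf$core_match <- match_id[disposition == "conflicted"]
  rownames(new) <- rownames(ap) <- rownames(cf) <- NULL
  overlap_cas_n <- sum(vapply(seq_len(n), function(i)
    !is.na(clean$cas_clean[i]) &&
      !is.null(core$idx_cas[[clean$cas_clean[i]]]), logical(1L)))
  list(new = new, already_present = ap, conflicted = cf,
       overlap_n = sum(overlap),
       overlap_cas_n = overlap_cas_n,
       conflict_rate = if (any(overlap)) sum(disposition == "conflicted") /
         sum(overlap) else 0)
}

quarantine_records <- function(core, db_name, stage, records) {
  if (!nrow(records)) return(invisible(core))
  for (i in seq_len(nrow(records))) {
    core$quarantine[[length(core$quarantine) + 1L]] <- list(
      db = db_name, stage = stage, qc_level = "Public_Untrusted",
      record = as.list(records[i, , drop = FALSE]))
  }
  invisible(core)
}

#' Load a sequence of source databases into the core
#'
#' Databases must be supplied in descending trust order (their assigned qc
#' levels monotonically decreasing in confidence). For each database, in
#' order: the internal consistency screen, the comparison against the next
#' database in the sequence (skipped for the last one, which has no next
#' level), and the core overlap audit. Surviving `new` records are
#' registered at the database's qc level; every conflicted record is
#' quarantined as `Public_Untrusted` with stage and provenance. Raw names of
#' loaded and matched records are harvested as `source_name` synonyms.
#' Should registration leave the core in violation of its invariants, the
#' whole database's load is rolled back.
#'
#' @param dbs List of [source_db()] in load order (most trusted first).
#' @param core A `chem_registry` (mutated in place).
#' @return A list of `load_report` objects, one per database, in order.
#' @export
autoload_sequence <- function(dbs, core) {
  stopifnot(inherits(core, "chem_registry"), length(dbs) >= 1L)
  ranks <- vapply(dbs, function(d) qc_rank(d$assigned_qc), integer(1L))
  if (is.unsorted(ranks)) {
    stop("autoload_sequence: databases must be ordered by descending trust",
         call. = FALSE)
  }
  reports <- vector("list", length(dbs))
  for (i in seq_along(dbs)) {
    db <- dbs[[i]]
    next_db <- if (i < length(dbs)) dbs[[i + 1L]] else NULL
    snapshot <- registry_snapshot(core)
    res <- tryCatch(
      load_one_db(core, db, next_db),
      error = function(e) {
        registry_restore(core, snapshot)
        stop("autoload_sequence: load of '", db$name,
             "' failed and was rolled back: ", conditionMessage(e),
             call. = FALSE)
      })
    if (length(check_invariants(core))) {
      registry_restore(core, snapshot)
      stop("autoload_sequence: invariant violation after '", db$name,
           "'; load rolled back", call. = FALSE)
    }
    reports[[i]] <- res
  }
  reports
}

load_one_db <- function(core, db, next_db) {
  input_n <- nrow(db$records)
  ic <- internal_consistency_filter(db)
  quarantine_records(core, db$name, "internal", ic$conflicted)

  cd <- cross_db_compare(ic$clean, next_db)
  quarantine_records(core, db$name, "cross_db", cd$conflicted)

  audit <- core_overlap_audit(cd$consistent, core)
  quarantine_records(core, db$name, "core_overlap", audit$conflicted)

  loaded <- 0L
  dup_present <- 0L
  reg_conflicts <- 0L
  newdf <- audit$new
  for (j in seq_len(nrow(newdf))) {
    r <- newdf[j, , drop = FALSE]
    res <- register_source_record(core, db, r)
    if (res == "loaded") loaded <- loaded + 1L
    else if (res == "already_present") dup_present <- dup_present + 1L
    else {
      reg_conflicts <- reg_conflicts + 1L
      r$reason <- res
      quarantine_records(core, db$name, "registration", r)
    }
  }

  # synonym harvest for records matched to existing core substances
  ap <- audit$already_present
  for (j in seq_len(nrow(ap))) {
    if (!is.na(ap$raw_name[j]) && !is.na(ap$core_match[j])) {
      add_synonym(core, ap$core_match[j], ap$raw_name[j], "source_name")
    }
  }

  structure(list(
    db = db$name, assigned_qc = db$assigned_qc,
    input_n = input_n,
    internal_conflicts = nrow(ic$conflicted),
    cross_db_conflicts = nrow(cd$conflicted),
    core_overlap_checked = audit$overlap_n,
    core_overlap_cas = audit$overlap_cas_n,
    core_overlap_conflicts = nrow(audit$conflicted),
    conflict_rate = audit$conflict_rate,
    already_present = nrow(ap) + dup_present,
    registration_conflicts = reg_conflicts,
    loaded = loaded,
    quarantined = nrow(ic$conflicted) + nrow(cd$conflicted) +
      nrow(audit$conflicted) + reg_conflicts),
    class = "load_report")
}

# Register one cleaned source record; returns "loaded", "already_present"
# or a conflict label.
register_source_record <- function(core, db, r) {
  name <- if (is.na(r$raw_name)) paste0("unnamed substance ", r$record_id)
          else r$raw_name
  cas <- if (is.na(r$cas_clean)) NULL else r$cas_clean
  key <- if (is.na(r$key)) NULL else r$key
  smiles <- if (is.na(r$raw_smiles)) NULL else
    trimws(strsplit(r$raw_smiles, ";", fixed = TRUE)[[1L]][1L])
  res <- register_substance(core, name, cas = cas, smiles = smiles,
                            qc = db$assigned_qc, structure_key = key)
  if (is_conflict(res) && res$type == "name_collision") {
    # public preferred names collide freely; disambiguate, keep the raw
    # name as a searchable synonym
    alt <- paste0(name, " (", if (is.null(cas)) r$record_id else cas, ")")
    res <- register_substance(core, alt, cas = cas, smiles = smiles,
                              qc = db$assigned_qc, structure_key = key)
    if (!is_conflict(res)) add_synonym(core, res$dtxsid, name, "source_name")
  }
  if (is_conflict(res)) {
    if (res$type %in% c("cas_collision", "structure_collision")) {
      # an identical substance registered moments ago from this same batch?
      ex <- core$substances[[res$existing]]
      same_cas <- is.null(cas) || identical(ex$cas, cas)
      ex_key <- if (is.na(ex$dtxcid)) NULL else
        core$structures[[ex$dtxcid]]$key
      same_key <- is.null(key) || identical(ex_key, key)
      if (same_cas && same_key) {
        if (!is.na(r$raw_name)) {
          add_synonym(core, ex$dtxsid, r$raw_name, "source_name")
        }
        return("already_present")
      }
    }
    return(res$type)
  }
  rid <- mint_id(core, "DTXRID")
  core$source_records[[rid]] <- list(dtxrid = rid, list_id = db$name,
                                     raw_name = r$raw_name,
                                     raw_cas = r$raw_cas,
                                     raw_smiles = r$raw_smiles,
                                     mapped_to = res$dtxsid)
  "loaded"
}

#' @export
print.load_report <- function(x, ...) {
  pct <- function(k) if (x$input_n) sprintf("%.1f%%", 100 * k / x$input_n)
                     else "-"
  cat("<load_report>", x$db, "(", x$assigned_qc, ")\n",
      " input:             ", x$input_n, "\n",
      " internal conflicts:", x$internal_conflicts,
      pct(x$internal_conflicts), "\n",
      " cross-db conflicts:", x$cross_db_conflicts,
      pct(x$cross_db_conflicts), "\n",
      " core overlap:      ", x$core_overlap_checked, "checked,",
      x$core_overlap_conflicts,
      sprintf("conflicted (rate %.1f%%)", 100 * x$conflict_rate), "\n",
      " already present:   ", x$already_present, "\n",
      " loaded:            ", x$loaded, pct(x$loaded), "\n",
      " quarantined:       ", x$quarantined, "\n")
  invisible(x)
}
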
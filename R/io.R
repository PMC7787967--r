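# Format readers/writers: SDF record I/O, source-list CSV with header
# aliases, and JSON persistence of registry state and load reports.

#' Read an SD file into records
#'
#' Parses each record independently: a malformed mol block yields a typed
#' error entry carrying the record index while the remaining records are
#' still returned, so one corrupt record never poisons a load.
#'
#' @param path Path to an SD file.
#' @return A list of records. Good records are lists with `molblock`,
#'   `smiles`, `key` (InChIKey) and `fields` (named character vector of SD
#'   data fields); failed records are of class `sdf_record_error` with
#'   `index` and `message`.
#' @export
read_sdf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines)))) return(list())
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends) || max(ends) < length(lines)) {
    last <- if (length(ends)) max(ends) else 0L
    if (any(nzchar(trimws(lines[(last + 1L):length(lines)])))) {
      ends <- c(ends, length(lines))
    }
  }
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- vector("list", length(ends))
  for (i in seq_along(ends)) {
    rec_lines <- lines[starts[i]:ends[i]]
    rec_lines <- rec_lines[!grepl("^\\$\\$\\$\\$", rec_lines)]
    out[[i]] <- parse_sdf_record(rec_lines, i)
  }
  out
}

parse_sdf_record <- function(rec_lines, index) {
  mend <- grep("^M  END", rec_lines)
  if (!length(mend)) {
    return(structure(list(index = index, message = "no 'M  END' terminator"),
                     class = "sdf_record_error"))
  }
  molblock <- paste(rec_lines[1L:mend[1L]], collapse = "\n")
  key <- molblock_keys(molblock)
  if (is.na(key)) {
    return(structure(list(index = index,
                          message = "mol block failed structure perception"),
                     class = "sdf_record_error"))
  }
  smiles <- molblock_smiles(molblock)
  fields <- character()
  tail_lines <- rec_lines[-(1L:mend[1L])]
  tag_at <- grep("^>", tail_lines)
  for (t in tag_at) {
    nm <- sub("^>.*<([^>]+)>.*$", "\\1", tail_lines[t])
    val_end <- t
    while (val_end < length(tail_lines) &&
           nzchar(trimws(tail_lines[val_end + 1L])) &&
           !grepl("^>", tail_lines[val_end + 1L])) {
      val_end <- val_end + 1L
    }
    val <- if (val_end > t) {
      paste(tail_lines[(t + 1L):val_end], collapse = "\n")
    } else ""
    fields[nm] <- val
  }
  list(molblock = molblock, smiles = smiles, key = key, fields = fields)
}

#' Write records to an SD file
#'
#' @param records A list of records: each a list with either `molblock` or
#'   `smiles`, and optionally `fields` (named character vector written as SD
#'   data fields).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sdf <- function(records, path) {
  chunks <- vapply(records, function(r) {
    mb <- r$molblock
    if (is.null(mb)) {
      if (is.null(r$smiles)) stop("write_sdf: record needs molblock or smiles",
                                  call. = FALSE)
      mb <- ChemmineOB::convertFormat("SMI", "SDF",
                                      paste0(r$smiles, "\n"),
                                      options = no_ops())
      mb <- sub("\\n?\\$\\$\\$\\$\\n?$", "", mb)
    }
    mb <- sub("\n+$", "", mb)
    fields <- r$fields
    field_txt <- ""
    if (length(fields)) {
      field_txt <- paste0(
        paste0(vapply(names(fields), function(nm)
          paste0(">  <", nm, ">\n", fields[[nm]], "\n"), character(1L)),
          collapse = "\n"), "\n")
      field_txt <- paste0("\n", field_txt)
    }
    paste0(mb, field_txt, "$$$$")
  }, character(1L))
  writeLines(chunks, path)
  invisible(path)
}

source_column_aliases <- list(
  record_id = c("record_id", "id", "source_id", "extid"),
  raw_name = c("raw_name", "name", "chemical_name", "substance_name",
               "preferred_name"),
  raw_cas = c("raw_cas", "cas", "casrn", "cas_rn", "cas_number"),
  raw_smiles = c("raw_smiles", "smiles", "structure_smiles")
)

#' Read a source list/database CSV
#'
#' Accepts UTF-8, comma-separated files with a header row. Column names are
#' matched case-insensitively against a set of aliases (`name`,
#' `chemical_name`, ...; `cas`, `casrn`, ...; `smiles`) to absorb
#' heterogeneous source-list headers.
#'
#' @param path CSV path.
#' @param aliases Alias table; see `source_column_aliases` for the default.
#' @return A data.frame with columns `record_id`, `raw_name`, `raw_cas`,
#'   `raw_smiles` (missing ones filled with `NA`).
#' @export
read_source_csv <- function(path, aliases = source_column_aliases) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", check.names = FALSE)
  lc <- tolower(names(df))
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (target in names(aliases)) {
    idx <- match(aliases[[target]], lc)
    idx <- idx[!is.na(idx)]
    out[[target]] <- if (length(idx)) as.character(df[[idx[1L]]])
                     else NA_character_
  }
  if (all(is.na(out$record_id))) {
    out$record_id <- sprintf("rec-%05d", seq_len(nrow(out)))
  }
  out[out == ""] <- NA
  out
}

# ---- registry persistence -------------------------------------------------

env_to_list <- function(e) {
  keys <- ls(e)
  stats::setNames(lapply(keys, function(k) e[[k]]), keys)
}

list_to_env <- function(l) {
  e <- new.env(parent = emptyenv())
  for (k in names(l)) e[[k]] <- l[[k]]
  e
}

#' Serialize a registry to a plain list (and back)
#'
#' Used for JSON persistence ([save_registry()]) and for transactional
#' snapshots during bulk loads.
#'
#' @param reg Registry.
#' @return `registry_to_list()`: a named list. `registry_from_list()`: a
#'   `chem_registry`.
#' @export
registry_to_list <- function(reg) {
  stopifnot(inherits(reg, "chem_registry"))
  list(substances = lapply(env_to_list(reg$substances), unclass),
       structures = env_to_list(reg$structures),
       idx_cas = env_to_list(reg$idx_cas),
       idx_name = env_to_list(reg$idx_name),
       idx_key = env_to_list(reg$idx_key),
       struct_owner = env_to_list(reg$struct_owner),
       idx_deleted = env_to_list(reg$idx_deleted),
       synonyms = env_to_list(reg$synonyms),
       relationships = reg$relationships,
       source_records = env_to_list(reg$source_records),
       lists = lapply(env_to_list(reg$lists), unclass),
       quarantine = reg$quarantine,
       counters = env_to_list(reg$counters))
}

#' @rdname registry_to_list
#' @param state A list produced by `registry_to_list()`.
#' @export
registry_from_list <- function(state) {
  reg <- registry_new()
  for (nm in c("substances", "structures", "idx_cas", "idx_name", "idx_key",
               "struct_owner", "idx_deleted", "synonyms", "source_records",
               "lists", "counters")) {
    reg[[nm]] <- list_to_env(state[[nm]])
  }
  reg$relationships <- state$relationships %||% list()
  reg$quarantine <- state$quarantine %||% list()
  for (k in c("DTXSID", "DTXCID", "DTXRID", "NOCAS")) {
    reg$counters[[k]] <- as.integer(reg$counters[[k]] %||% 0L)
  }
  for (s in ls(reg$substances)) {
    reg$substances[[s]] <- restore_class(reg$substances[[s]],
                                         "chem_substance")
  }
  for (k in ls(reg$lists)) {
    l <- reg$lists[[k]]
    l$members <- as.character(unlist(l$members))
    prov <- unlist(l$provenance)
    l$provenance <- if (length(prov)) prov else character()
    l$unresolved <- as.character(unlist(l$unresolved))
    class(l) <- "registered_list"
    reg$lists[[k]] <- l
  }
  reg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

restore_class <- function(x, cls) {
  x <- lapply(x, function(v) if (is.null(v)) NA_character_ else v)
  class(x) <- cls
  x
}

#' Save / load a registry as a single JSON store
#'
#' @param reg Registry.
#' @param path File path for the JSON store.
#' @return `save_registry()`: invisibly, `path`. `load_registry()`: a
#'   `chem_registry`.
#' @export
save_registry <- function(reg, path) {
  jsonlite::write_json(registry_to_list(reg), path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname save_registry
#' @param path File path for the JSON store.
#' @export
load_registry <- function(path) {
  state <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE,
                               simplifyMatrix = FALSE)
  registry_from_list(state)
}

# Deep copy for transactional rollback.
registry_snapshot <- function(reg) registry_to_list(reg)

registry_restore <- function(reg, snapshot) {
  fresh <- registry_from_list(snapshot)
  for (nm in ls(fresh)) reg[[nm]] <- fresh[[nm]]
  invisible(reg)
}
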
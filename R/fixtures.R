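# Seeded synthetic source databases and registries with a ground-truth
# ledger. The generators emulate the *statistical structure* of a
# quality-filtered public-database load -- clean records, shared-structure
# and shared-CAS internal conflicts, cross-database disagreements, deleted
# CAS RN aliases, ambiguous synonyms -- not chemical realism: structures are
# drawn from an internal combinatorial library of small molecules so every
# structure key is computable offline, and CAS RNs are minted (with valid
# check digits) from a reserved high registry-number range that avoids real
# CAS RNs.

# ---- deterministic RNG scope ---------------------------------------------

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# ---- internal molecule library -------------------------------------------

#' The internal fixture molecule library
#'
#' A combinatorially generated set of ~540 distinct small molecules
#' (difunctionalized alkyl chains), so fixture structures never require an
#' external download and all structure keys are computable offline.
#' Distinctness of the resulting InChIKeys is asserted in the test suite.
#'
#' @return Character vector of SMILES.
#' @export
chemlib_smiles <- function() {
  if (!is.null(.chemreg_cache$chemlib)) return(.chemreg_cache$chemlib)
  groups <- list(
    C    = c(prefix = "C",      suffix = "C"),
    O    = c(prefix = "O",      suffix = "O"),
    N    = c(prefix = "N",      suffix = "N"),
    Cl   = c(prefix = "Cl",     suffix = "Cl"),
    Br   = c(prefix = "Br",     suffix = "Br"),
    F    = c(prefix = "F",      suffix = "F"),
    S    = c(prefix = "S",      suffix = "S"),
    CN   = c(prefix = "N#C",    suffix = "C#N"),
    COOH = c(prefix = "OC(=O)", suffix = "C(=O)O")
  )
  smiles <- character()
  gn <- names(groups)
  for (len in 3:14) {
    chain <- strrep("C", len)
    for (i in seq_along(gn)) {
      for (j in i:length(gn)) {
        smiles <- c(smiles,
                    paste0(groups[[gn[i]]]["prefix"], chain,
                           groups[[gn[j]]]["suffix"]))
      }
    }
  }
  smiles <- unname(smiles)
  .chemreg_cache$chemlib <- smiles
  smiles
}

chemlib_keys <- function() {
  if (is.null(.chemreg_cache$chemlib_keys)) {
    .chemreg_cache$chemlib_keys <- structure_key(chemlib_smiles())
  }
  .chemreg_cache$chemlib_keys
}

# Library slots are handed out in disjoint blocks so that distinct fixture
# artifacts never share a structure by accident.
lib_slice <- function(start, n) {
  lib <- chemlib_smiles()
  if (start + n - 1L > length(lib)) {
    stop("fixture generator: requested ", n, " structures at offset ", start,
         " but the molecule library holds only ", length(lib), call. = FALSE)
  }
  lib[seq.int(start, length.out = n)]
}

# ---- reserved-range CAS RNs ----------------------------------------------

# Registry parts 9,0xx,xxx-9,9xx,xxx; blocks of 100k keep artifact families
# (core, each database, aliases, ...) collision-free by construction.
make_fixture_cas <- function(serial, block = 0L) {
  serial <- as.integer(serial)
  block <- as.integer(block)
  stopifnot(all(serial >= 1L), all(serial < 100000L),
            all(block >= 0L), all(block <= 9L))
  reg_part <- sprintf("%07d", 9000000L + block * 100000L + serial)
  middle <- "10"
  sprintf("%s-%s-%d", reg_part, middle,
          cas_check_digit(paste0(reg_part, middle)))
}

fixture_name <- function(prefix, serial) {
  sprintf("%s substance %05d", prefix, serial)
}

# ---- fixture specification -----------------------------------------------

#' Specify a synthetic source database / registry fixture
#'
#' Defaults are chosen to mirror, at desk scale, the double-digit
#' identifier-conflict percentages observed when large public chemical
#' databases are screened against the 1:1:1 rule: a ~60-record database
#' with 5 internal conflict pairs (~14% of records internally conflicted)
#' and a handful of cross-database disagreements, with most records
#' carrying structures.
#'
#' @param n_clean Number of clean records (also the core size for
#'   [generate_core()]).
#' @param n_internal_conflict_pairs Pairs of records planted to violate the
#'   1:1:1 rule within the database (alternating shared-structure and
#'   shared-CAS archetypes).
#' @param n_crossdb_conflict Records whose mapping the next-level database
#'   contradicts (realized by [generate_next_level()]).
#' @param n_deleted_cas_aliases Deleted CAS RN redirects planted on core
#'   substances.
#' @param n_ambiguous_synonyms Synonyms planted on two core substances each.
#' @param structure_fraction Fraction of clean records carrying a structure.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_clean = 60L, n_internal_conflict_pairs = 5L,
                         n_crossdb_conflict = 6L,
                         n_deleted_cas_aliases = 5L,
                         n_ambiguous_synonyms = 3L,
                         structure_fraction = 0.8, seed = 1L) {
  spec <- list(n_clean = as.integer(n_clean),
               n_internal_conflict_pairs =
                 as.integer(n_internal_conflict_pairs),
               n_crossdb_conflict = as.integer(n_crossdb_conflict),
               n_deleted_cas_aliases = as.integer(n_deleted_cas_aliases),
               n_ambiguous_synonyms = as.integer(n_ambiguous_synonyms),
               structure_fraction = as.numeric(structure_fraction),
               seed = as.integer(seed))
  counts <- unlist(spec[1:5])
  if (any(counts < 0L)) {
    stop("fixture_spec: counts must be non-negative", call. = FALSE)
  }
  if (spec$structure_fraction < 0 || spec$structure_fraction > 1) {
    stop("fixture_spec: structure_fraction must be in [0, 1]", call. = FALSE)
  }
  if (spec$n_deleted_cas_aliases > spec$n_clean ||
      2L * spec$n_ambiguous_synonyms > spec$n_clean) {
    stop("fixture_spec: alias/synonym counts exceed core capacity",
         call. = FALSE)
  }
  structure(spec, class = "fixture_spec")
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat("<fixture_spec> clean:", x$n_clean,
      "internal pairs:", x$n_internal_conflict_pairs,
      "cross-db:", x$n_crossdb_conflict,
      "deleted aliases:", x$n_deleted_cas_aliases,
      "ambiguous synonyms:", x$n_ambiguous_synonyms,
      "structure fraction:", x$structure_fraction,
      "seed:", x$seed, "\n")
  invisible(x)
}

# ---- source database generator -------------------------------------------

#' Generate a synthetic source database with a ground-truth ledger
#'
#' Produces a [source_db()] containing exactly the archetype counts of the
#' spec, shuffled, together with a ledger stating every record's expected
#' disposition under [internal_consistency_filter()] /
#' [cross_db_compare()]: `clean`, `internal_conflict`, or
#' `crossdb_conflict` (the latter realized by pairing with
#' [generate_next_level()]).
#'
#' @param spec A [fixture_spec()].
#' @param name Database name.
#' @param qc Assigned qc level.
#' @param cas_block,lib_start Reserved CAS block (0-9) and molecule-library
#'   offset; change them when combining several fixtures so content stays
#'   disjoint.
#' @return List with `db` (a `source_db`) and `ledger` (a data.frame:
#'   `record_id`, `disposition`, `cas`, `smiles`).
#' @export
generate_source_db <- function(spec, name = "fixdb", qc = "Public_High",
                               cas_block = 1L, lib_start = 1L) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    n_struct_needed <- spec$n_clean + 2L * spec$n_internal_conflict_pairs +
      spec$n_crossdb_conflict
    lib <- lib_slice(lib_start, max(n_struct_needed, 1L))
    li <- 0L
    next_smiles <- function() {
      li <<- li + 1L
      lib[li]
    }
    serial <- 0L
    next_serial <- function() {
      serial <<- serial + 1L
      serial
    }

    rows <- list()
    led <- list()
    push <- function(rid, nm, cas, smi, disposition) {
      rows[[length(rows) + 1L]] <<- data.frame(
        record_id = rid, raw_name = nm, raw_cas = cas,
        raw_smiles = if (is.null(smi)) NA_character_ else smi,
        stringsAsFactors = FALSE)
      led[[length(led) + 1L]] <<- data.frame(
        record_id = rid, disposition = disposition,
        cas = cas, smiles = if (is.null(smi)) NA_character_ else smi,
        stringsAsFactors = FALSE)
    }

    has_structure <- stats::runif(spec$n_clean) < spec$structure_fraction
    for (i in seq_len(spec$n_clean)) {
      s <- next_serial()
      push(sprintf("%s-c%04d", name, i),
           fixture_name(name, s),
           make_fixture_cas(s, cas_block),
           if (has_structure[i]) next_smiles() else NULL,
           "clean")
    }

    for (p in seq_len(spec$n_internal_conflict_pairs)) {
      s1 <- next_serial()
      s2 <- next_serial()
      if (p %% 2L == 1L) {
        # shared-structure archetype: one structure, two CAS/name records
        smi <- next_smiles()
        push(sprintf("%s-i%04da", name, p), fixture_name(name, s1),
             make_fixture_cas(s1, cas_block), smi, "internal_conflict")
        push(sprintf("%s-i%04db", name, p), fixture_name(name, s2),
             make_fixture_cas(s2, cas_block), smi, "internal_conflict")
      } else {
        # shared-CAS archetype: one CAS, two different structures
        cas <- make_fixture_cas(s1, cas_block)
        push(sprintf("%s-i%04da", name, p), fixture_name(name, s1),
             cas, next_smiles(), "internal_conflict")
        push(sprintf("%s-i%04db", name, p), fixture_name(name, s2),
             cas, next_smiles(), "internal_conflict")
      }
    }

    for (x in seq_len(spec$n_crossdb_conflict)) {
      s <- next_serial()
      push(sprintf("%s-x%04d", name, x), fixture_name(name, s),
           make_fixture_cas(s, cas_block), next_smiles(),
           "crossdb_conflict")
    }

    df <- do.call(rbind, rows)
    ledger <- do.call(rbind, led)
    ord <- sample.int(nrow(df))
    df <- df[ord, , drop = FALSE]
    ledger <- ledger[ord, , drop = FALSE]
    rownames(df) <- rownames(ledger) <- NULL
    list(db = source_db(name, df, qc = qc), ledger = ledger)
  })
}

#' Realize the next-level database for a generated fixture
#'
#' Builds the less-trusted companion database that [cross_db_compare()]
#' checks against: every `crossdb_conflict` record of the fixture appears
#' with the same CAS RN but a different structure; a seeded share of the
#' clean structured records appears with an agreeing entry; filler records
#' unrelated to the fixture are added.
#'
#' @param fix Result of [generate_source_db()].
#' @param name,qc Name and qc level of the companion database.
#' @param agree_fraction Fraction of clean structured records that get an
#'   agreeing next-level entry.
#' @param n_filler Unrelated records to add.
#' @param cas_block,lib_start Reserved blocks for the contradicting and
#'   filler content.
#' @param seed Integer seed.
#' @return A `source_db`.
#' @export
generate_next_level <- function(fix, name = "nextdb", qc = "Public_Medium",
                                agree_fraction = 0.5, n_filler = 10L,
                                cas_block = 2L, lib_start = 300L,
                                seed = 42L) {
  led <- fix$ledger
  with_seed(seed, {
    li <- 0L
    lib <- lib_slice(lib_start,
                     sum(led$disposition == "crossdb_conflict") + n_filler)
    next_smiles <- function() {
      li <<- li + 1L
      lib[li]
    }
    rows <- list()
    k <- 0L
    for (i in which(led$disposition == "crossdb_conflict")) {
      k <- k + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = sprintf("%s-x%04d", name, k),
        raw_name = paste0(led$record_id[i], " as seen downstream"),
        raw_cas = led$cas[i],
        raw_smiles = next_smiles(),  # contradicts the fixture's structure
        stringsAsFactors = FALSE)
    }
    clean_struct <- which(led$disposition == "clean" & !is.na(led$smiles))
    agree <- clean_struct[stats::runif(length(clean_struct)) < agree_fraction]
    for (i in agree) {
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = paste0(name, "-a-", led$record_id[i]),
        raw_name = paste0(led$record_id[i], " downstream name"),
        raw_cas = led$cas[i],
        raw_smiles = led$smiles[i],  # agrees
        stringsAsFactors = FALSE)
    }
    for (f in seq_len(n_filler)) {
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = sprintf("%s-f%04d", name, f),
        raw_name = fixture_name(name, f),
        raw_cas = make_fixture_cas(f, cas_block),
        raw_smiles = next_smiles(),
        stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    source_db(name, df, qc = qc)
  })
}

# ---- core registry generator ---------------------------------------------

#' Generate a valid core registry with planted redirects and synonyms
#'
#' Builds a registry of `n_clean` substances (structures on a seeded
#' `structure_fraction` share), then plants `n_deleted_cas_aliases` deleted
#' CAS RN redirects and `n_ambiguous_synonyms` synonyms that each map to two
#' substances. The result always passes [check_invariants()].
#'
#' @param spec A [fixture_spec()].
#' @param cas_block,alias_block,lib_start Reserved CAS blocks for substances
#'   and aliases, and the molecule-library offset.
#' @return List with `core` (a `chem_registry`) and `ledger`: data.frames
#'   `substances` (`dtxsid`, `cas`, `name`, `smiles`), `aliases`
#'   (`deleted_cas` -> `dtxsid`) and `synonyms` (`text`, `dtxsid_a`,
#'   `dtxsid_b`).
#' @export
generate_core <- function(spec, cas_block = 0L, alias_block = 3L,
                          lib_start = 150L) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed + 1L, {
    core <- registry_new()
    lib <- lib_slice(lib_start, max(spec$n_clean, 1L))
    has_structure <- stats::runif(spec$n_clean) < spec$structure_fraction
    subs <- list()
    for (i in seq_len(spec$n_clean)) {
      cas <- make_fixture_cas(i, cas_block)
      nm <- fixture_name("core", i)
      smi <- if (has_structure[i]) lib[i] else NULL
      sub <- register_substance(core, nm, cas = cas, smiles = smi,
                                qc = "DSSTox_Low")
      stopifnot(!is_conflict(sub))
      subs[[i]] <- data.frame(dtxsid = sub$dtxsid, cas = cas, name = nm,
                              smiles = if (is.null(smi)) NA_character_
                                       else smi,
                              stringsAsFactors = FALSE)
    }
    subs <- do.call(rbind, subs)

    aliases <- NULL
    if (spec$n_deleted_cas_aliases > 0L) {
      targets <- sample(subs$dtxsid, spec$n_deleted_cas_aliases)
      deleted <- make_fixture_cas(seq_len(spec$n_deleted_cas_aliases),
                                  alias_block)
      for (i in seq_along(targets)) {
        add_deleted_casrn(core, targets[i], deleted[i])
      }
      aliases <- data.frame(deleted_cas = deleted, dtxsid = targets,
                            stringsAsFactors = FALSE)
    } else {
      aliases <- data.frame(deleted_cas = character(), dtxsid = character(),
                            stringsAsFactors = FALSE)
    }

    synonyms <- NULL
    if (spec$n_ambiguous_synonyms > 0L) {
      pick <- sample(subs$dtxsid, 2L * spec$n_ambiguous_synonyms)
      a <- pick[seq_len(spec$n_ambiguous_synonyms)]
      b <- pick[spec$n_ambiguous_synonyms + seq_len(spec$n_ambiguous_synonyms)]
      text <- sprintf("shared trade name %03d", seq_along(a))
      for (i in seq_along(a)) {
        add_synonym(core, a[i], text[i], "valid_synonym")
        add_synonym(core, b[i], text[i], "valid_synonym")
      }
      synonyms <- data.frame(text = text, dtxsid_a = a, dtxsid_b = b,
                             stringsAsFactors = FALSE)
    } else {
      synonyms <- data.frame(text = character(), dtxsid_a = character(),
                             dtxsid_b = character(), stringsAsFactors = FALSE)
    }

    list(core = core,
         ledger = list(substances = subs, aliases = aliases,
                       synonyms = synonyms))
  })
}

# ---- core-overlap fixture -------------------------------------------------

#' Generate a database overlapping a fixture core with a planted
#' conflict fraction
#'
#' Draws `n_overlap` structured substances from the core and emits one
#' record each: a planted share get a *different* structure (so the core
#' maps their CAS to another structure -- a conflict), the rest agree
#' exactly. `n_new` unrelated records are appended. The ledger's planted
#' conflict fraction is exactly `n_conflict / n_overlap`, which
#' [core_overlap_audit()] must recover.
#'
#' @param corefix Result of [generate_core()].
#' @param n_overlap Number of overlapping records.
#' @param conflict_fraction Fraction of the overlap to contradict
#'   (`n_conflict = round(conflict_fraction * n_overlap)`).
#' @param n_new Unrelated (non-overlapping) records.
#' @param seed Integer seed.
#' @param name,qc Database name and qc level.
#' @param cas_block,lib_start Reserved blocks for the new content.
#' @return List with `db`, `ledger` (per-record `disposition`:
#'   `overlap_conflict`, `overlap_present`, `new`) and `planted_rate`.
#' @export
generate_overlap_db <- function(corefix, n_overlap, conflict_fraction,
                                n_new = 5L, seed = 1L, name = "overlapdb",
                                qc = "Public_Medium", cas_block = 4L,
                                lib_start = 220L) {
  subs <- corefix$ledger$substances
  subs <- subs[!is.na(subs$smiles), , drop = FALSE]
  if (n_overlap > nrow(subs)) {
    stop("generate_overlap_db: core has only ", nrow(subs),
         " structured substances", call. = FALSE)
  }
  n_conflict <- round(conflict_fraction * n_overlap)
  with_seed(seed + 7L, {
    pick <- subs[sample.int(nrow(subs), n_overlap), , drop = FALSE]
    flip <- seq_len(nrow(pick)) <= n_conflict  # pick order is random
    lib <- lib_slice(lib_start, n_conflict + n_new)
    li <- 0L
    next_smiles <- function() {
      li <<- li + 1L
      lib[li]
    }
    rows <- list()
    led <- list()
    for (i in seq_len(nrow(pick))) {
      smi <- if (flip[i]) next_smiles() else pick$smiles[i]
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = sprintf("%s-o%04d", name, i),
        raw_name = pick$name[i], raw_cas = pick$cas[i], raw_smiles = smi,
        stringsAsFactors = FALSE)
      led[[length(led) + 1L]] <- data.frame(
        record_id = sprintf("%s-o%04d", name, i),
        disposition = if (flip[i]) "overlap_conflict" else "overlap_present",
        core_dtxsid = pick$dtxsid[i], stringsAsFactors = FALSE)
    }
    for (j in seq_len(n_new)) {
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = sprintf("%s-n%04d", name, j),
        raw_name = fixture_name(name, j),
        raw_cas = make_fixture_cas(j, cas_block),
        raw_smiles = next_smiles(), stringsAsFactors = FALSE)
      led[[length(led) + 1L]] <- data.frame(
        record_id = sprintf("%s-n%04d", name, j), disposition = "new",
        core_dtxsid = NA_character_, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    ledger <- do.call(rbind, led)
    ord <- sample.int(nrow(df))
    df <- df[ord, , drop = FALSE]
    ledger <- ledger[ord, , drop = FALSE]
    rownames(df) <- rownames(ledger) <- NULL
    list(db = source_db(name, df, qc = qc), ledger = ledger,
         planted_rate = if (n_overlap) n_conflict / n_overlap else 0)
  })
}

# ---- full three-database load fixture ------------------------------------

#' Generate a full three-database autoload scenario with expected counts
#'
#' Composes a core registry and three source databases of decreasing trust
#' (qc `Public_High`, `Public_Medium`, `Public_Low`), with planted internal
#' conflict pairs in each, cross-database contradictions between consecutive
#' databases, and core overlap (agreeing and conflicting) -- the archetypal
#' sequential quality-filtered load. The ledger carries the exact per-stage
#' counts every [autoload_sequence()] report must reproduce.
#'
#' @param seed Integer seed.
#' @return List: `core`, `dbs` (list of three `source_db`), and `expected`
#'   (per-database list of `internal_conflicts`, `cross_db_conflicts`,
#'   `core_overlap_conflicts`, `already_present`, `loaded`).
#' @export
generate_autoload_fixture <- function(seed = 1L) {
  spec0 <- fixture_spec(n_clean = 40L, n_internal_conflict_pairs = 0L,
                        n_crossdb_conflict = 0L, n_deleted_cas_aliases = 0L,
                        n_ambiguous_synonyms = 0L, structure_fraction = 1,
                        seed = seed)
  corefix <- generate_core(spec0, cas_block = 0L, lib_start = 1L)
  core <- corefix$core
  subs <- corefix$ledger$substances

  build_db <- function(name, qc, n_clean, n_pairs, n_cross, cas_block,
                       lib_start, overlap_rows, realize = NULL,
                       realize_lib = NULL) {
    with_seed(seed + cas_block, {
      li <- 0L
      lib <- lib_slice(lib_start, n_clean + 2L * n_pairs + n_cross)
      next_smiles <- function() {
        li <<- li + 1L
        lib[li]
      }
      rows <- list()
      push <- function(rid, nm, cas, smi) {
        rows[[length(rows) + 1L]] <<- data.frame(
          record_id = rid, raw_name = nm, raw_cas = cas, raw_smiles = smi,
          stringsAsFactors = FALSE)
      }
      for (i in seq_len(n_clean)) {
        push(sprintf("%s-c%04d", name, i), fixture_name(name, i),
             make_fixture_cas(i, cas_block), next_smiles())
      }
      for (p in seq_len(n_pairs)) {
        smi <- next_smiles()
        push(sprintf("%s-i%04da", name, p),
             fixture_name(name, 1000L + 2L * p),
             make_fixture_cas(1000L + 2L * p, cas_block), smi)
        push(sprintf("%s-i%04db", name, p),
             fixture_name(name, 1001L + 2L * p),
             make_fixture_cas(1001L + 2L * p, cas_block), smi)
      }
      cross <- list()
      for (x in seq_len(n_cross)) {
        cas <- make_fixture_cas(2000L + x, cas_block)
        smi <- next_smiles()
        push(sprintf("%s-x%04d", name, x),
             fixture_name(name, 2000L + x), cas, smi)
        cross[[x]] <- list(cas = cas, smiles = smi)
      }
      for (r in seq_len(nrow(overlap_rows))) {
        push(sprintf("%s-o%04d", name, r), overlap_rows$raw_name[r],
             overlap_rows$raw_cas[r], overlap_rows$raw_smiles[r])
      }
      if (!is.null(realize)) {
        rl <- lib_slice(realize_lib, length(realize))
        for (x in seq_along(realize)) {
          push(sprintf("%s-r%04d", name, x),
               fixture_name(paste0(name, " downstream"), x),
               realize[[x]]$cas, rl[x])
        }
      }
      df <- do.call(rbind, rows)
      df <- df[sample.int(nrow(df)), , drop = FALSE]
      rownames(df) <- NULL
      list(db = source_db(name, df, qc = qc), cross = cross)
    })
  }

  overlap_rows <- function(idx, n_flip, flip_lib) {
    rows <- subs[idx, , drop = FALSE]
    out <- data.frame(raw_name = rows$name, raw_cas = rows$cas,
                      raw_smiles = rows$smiles, stringsAsFactors = FALSE)
    if (n_flip > 0L) {
      out$raw_smiles[seq_len(n_flip)] <- lib_slice(flip_lib, n_flip)
    }
    out
  }

  d1 <- build_db("srsfix", "Public_High", n_clean = 30L, n_pairs = 3L,
                 n_cross = 4L, cas_block = 1L, lib_start = 41L,
                 overlap_rows = overlap_rows(1:6, 2L, flip_lib = 460L))
  d2 <- build_db("chemidfix", "Public_Medium", n_clean = 25L, n_pairs = 2L,
                 n_cross = 3L, cas_block = 2L, lib_start = 90L,
                 overlap_rows = overlap_rows(7:10, 1L, flip_lib = 470L),
                 realize = d1$cross, realize_lib = 480L)
  d3 <- build_db("pubchemfix", "Public_Low", n_clean = 20L, n_pairs = 1L,
                 n_cross = 0L, cas_block = 5L, lib_start = 130L,
                 overlap_rows = overlap_rows(11:13, 1L, flip_lib = 490L),
                 realize = d2$cross, realize_lib = 500L)

  expected <- list(
    srsfix = list(internal_conflicts = 6L, cross_db_conflicts = 4L,
                  core_overlap_conflicts = 2L, already_present = 4L,
                  loaded = 30L),
    chemidfix = list(internal_conflicts = 4L, cross_db_conflicts = 3L,
                     core_overlap_conflicts = 1L, already_present = 3L,
                     loaded = 25L + 4L),  # clean + realizations of srsfix
    pubchemfix = list(internal_conflicts = 2L, cross_db_conflicts = 0L,
                      core_overlap_conflicts = 1L, already_present = 2L,
                      loaded = 20L + 3L)  # clean + realizations of chemidfix
  )

  list(core = core, corefix = corefix,
       dbs = list(d1$db, d2$db, d3$db), expected = expected)
}
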
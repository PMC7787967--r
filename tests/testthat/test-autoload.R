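# Sequential quality-filtered loading: internal screen, cross-database
# comparison, core overlap audit, and the full pipeline.

test_that("internal screen flags the shared-structure pair archetype", {
  # two records, different CAS and name, identical structure
  db <- source_db("pairdb", data.frame(
    record_id = c("a", "b", "c"),
    raw_name = c("hexan-1-ol", "mystery alcohol", "benzoic acid"),
    raw_cas = c("111-27-3", "999999-99-4", "65-85-0"),
    raw_smiles = c("CCCCCCO", "OCCCCCC", "OC(=O)c1ccccc1")))
  # note: 999999-99-4 is checksum-valid by construction
  expect_true(is_valid_casrn("999999-99-4"))
  ic <- internal_consistency_filter(db)
  expect_setequal(ic$conflicted$record_id, c("a", "b"))
  expect_identical(ic$clean$record_id, "c")
})

test_that("internal screen flags a record whose own renderings disagree", {
  db <- source_db("selfdb", data.frame(
    record_id = "r1",
    raw_name = "doubly rendered",
    raw_cas = "111-27-3",
    raw_smiles = "CCCCCCO;CCCCCO"))  # two different molecules
  ic <- internal_consistency_filter(db)
  expect_identical(ic$conflicted$record_id, "r1")
  expect_identical(ic$conflicted$reason, "own_keys_disagree")
})

test_that("internal screen checks CAS-name pairing for structureless records", {
  db <- source_db("nsdb", data.frame(
    record_id = c("a", "b", "c"),
    raw_name = c("uvcb alpha", "uvcb beta", "uvcb gamma"),
    raw_cas = c("111-27-3", "111-27-3", "65-85-0"),
    raw_smiles = NA_character_))
  ic <- internal_consistency_filter(db)
  expect_setequal(ic$conflicted$record_id, c("a", "b"))
})

test_that("a pairwise-distinct database passes the internal screen intact", {
  fix <- generate_source_db(fixture_spec(n_clean = 15,
                                         n_internal_conflict_pairs = 0,
                                         n_crossdb_conflict = 0, seed = 9))
  ic <- internal_consistency_filter(fix$db)
  expect_identical(nrow(ic$conflicted), 0L)
  expect_identical(nrow(ic$clean), 15L)
})

test_that("internal screen equals the quadratic oracle on planted fixtures", {
  for (seed in c(21, 22, 23)) {
    fix <- generate_source_db(fixture_spec(
      n_clean = 30, n_internal_conflict_pairs = 4, n_crossdb_conflict = 3,
      structure_fraction = 0.7, seed = seed))
    ic <- internal_consistency_filter(fix$db)
    expected <- fix$ledger$record_id[fix$ledger$disposition ==
                                       "internal_conflict"]
    expect_setequal(ic$conflicted$record_id, expected)
    bad <- oracle_internal_conflicts(fix$db$records)
    expect_setequal(ic$conflicted$record_id,
                    fix$db$records$record_id[bad])
  }
})

test_that("cross-database comparison needs evidence to conflict", {
  nx <- source_db("next", data.frame(
    record_id = c("n1", "n2"),
    raw_name = c("agreeing", "disagreeing"),
    raw_cas = c("111-27-3", "65-85-0"),
    raw_smiles = c("CCCCCCO", "CCCCCO")))  # n2 contradicts benzoic acid
  clean <- source_db("this", data.frame(
    record_id = c("a", "b", "c"),
    raw_name = c("hexanol", "benzoic acid", "unrelated"),
    raw_cas = c("111-27-3", "65-85-0", "50-00-0"),
    raw_smiles = c("CCCCCCO", "OC(=O)c1ccccc1", "C=O")))$records
  cd <- cross_db_compare(clean, nx)
  # agreement passes, contradiction is set aside, absence passes
  expect_identical(cd$conflicted$record_id, "b")
  expect_setequal(cd$consistent$record_id, c("a", "c"))
  # the same structure under a different CAS in the next level also conflicts
  nx2 <- source_db("next2", data.frame(
    record_id = "m1", raw_name = "same structure other cas",
    raw_cas = "50-00-0", raw_smiles = "CCCCCCO"))
  cd2 <- cross_db_compare(clean, nx2)
  # "a" shares the structure under another CAS; "c" shares the CAS under
  # another structure -- both are contradicted
  expect_setequal(cd2$conflicted$record_id, c("a", "c"))
  # no next level: everything passes
  cd3 <- cross_db_compare(clean, NULL)
  expect_identical(nrow(cd3$conflicted), 0L)
})

test_that("core overlap audit recovers planted conflict rates exactly", {
  spec <- fixture_spec(n_clean = 40, structure_fraction = 1, seed = 31)
  corefix <- generate_core(spec)
  for (f in c(0, 0.2, 0.5)) {
    ov <- generate_overlap_db(corefix, n_overlap = 20, conflict_fraction = f,
                              n_new = 6, seed = 32)
    audit <- core_overlap_audit(ov$db$records, corefix$core)
    expect_identical(audit$conflict_rate, ov$planted_rate)
    expect_identical(audit$overlap_n, 20L)
    expect_identical(nrow(audit$new), 6L)
    # dispositions match the construction ledger record by record
    led <- ov$ledger
    expect_setequal(audit$conflicted$record_id,
                    led$record_id[led$disposition == "overlap_conflict"])
    expect_setequal(audit$already_present$record_id,
                    led$record_id[led$disposition == "overlap_present"])
  }
  # empty core: everything is new, rate 0
  empty <- registry_new()
  a0 <- core_overlap_audit(generate_source_db(spec)$db$records, empty)
  expect_identical(a0$conflict_rate, 0)
  expect_identical(a0$overlap_n, 0L)
})

test_that("the full pipeline reproduces the fixture's per-stage counts", {
  tri <- generate_autoload_fixture(seed = 55)
  reports <- autoload_sequence(tri$dbs, tri$core)
  for (r in reports) {
    e <- tri$expected[[r$db]]
    expect_identical(r$internal_conflicts, e$internal_conflicts, info = r$db)
    expect_identical(r$cross_db_conflicts, e$cross_db_conflicts, info = r$db)
    expect_identical(r$core_overlap_conflicts, e$core_overlap_conflicts,
                     info = r$db)
    expect_identical(r$already_present, e$already_present, info = r$db)
    expect_identical(r$loaded, e$loaded, info = r$db)
    # partition: every input record lands in exactly one disposition
    expect_identical(r$internal_conflicts + r$cross_db_conflicts +
                       r$core_overlap_conflicts + r$registration_conflicts +
                       r$already_present + r$loaded,
                     r$input_n, info = r$db)
  }
  expect_identical(check_invariants(tri$core), list())
  # quarantined records carry stage and provenance
  stages <- vapply(tri$core$quarantine, `[[`, character(1), "stage")
  expect_setequal(unique(stages), c("internal", "cross_db", "core_overlap"))
  qc <- unique(vapply(tri$core$quarantine, `[[`, character(1), "qc_level"))
  expect_identical(qc, "Public_Untrusted")
})

test_that("reloading the same databases adds nothing (idempotence)", {
  tri <- generate_autoload_fixture(seed = 56)
  autoload_sequence(tri$dbs, tri$core)
  n_before <- length(ls(tri$core$substances))
  reports2 <- autoload_sequence(tri$dbs, tri$core)
  expect_identical(sum(vapply(reports2, `[[`, integer(1), "loaded")), 0L)
  expect_identical(length(ls(tri$core$substances)), n_before)
})

test_that("earlier loads keep their qc level against later duplicates", {
  core <- registry_new()
  rec <- data.frame(record_id = "dup", raw_name = "duplicated substance",
                    raw_cas = "111-27-3", raw_smiles = "CCCCCCO")
  autoload_sequence(list(source_db("first", rec, qc = "Public_High")), core)
  sid <- core$idx_cas[["111-27-3"]]
  expect_identical(get_substance(core, sid)$qc_level, "Public_High")
  r2 <- autoload_sequence(list(source_db("second", rec, qc = "Public_Low")),
                          core)
  expect_identical(r2[[1]]$already_present, 1L)
  expect_identical(r2[[1]]$loaded, 0L)
  expect_identical(get_substance(core, sid)$qc_level, "Public_High")
})

test_that("final CAS content is invariant to permuting disjoint clean databases", {
  mk <- function(block, n, lib_start) {
    cas <- vapply(seq_len(n), function(i)
      chemregistry:::make_fixture_cas(i, block), character(1))
    data.frame(record_id = sprintf("b%d-%03d", block, seq_len(n)),
               raw_name = sprintf("block %d substance %03d", block,
                                  seq_len(n)),
               raw_cas = cas,
               raw_smiles = chemregistry:::lib_slice(lib_start, n))
  }
  contents <- list(mk(6, 8, 1), mk(7, 8, 20), mk(8, 8, 40))
  qcs <- c("Public_High", "Public_Medium", "Public_Low")
  load_in_order <- function(ord) {
    core <- registry_new()
    dbs <- lapply(seq_along(ord), function(i)
      source_db(paste0("db", i), contents[[ord[i]]], qc = qcs[i]))
    autoload_sequence(dbs, core)
    sort(vapply(ls(core$substances), function(s)
      get_substance(core, s)$cas, character(1), USE.NAMES = FALSE))
  }
  base <- load_in_order(c(1, 2, 3))
  expect_identical(load_in_order(c(3, 1, 2)), base)
  expect_identical(load_in_order(c(2, 3, 1)), base)
})

test_that("databases out of trust order are refused", {
  core <- registry_new()
  rec <- data.frame(record_id = "r", raw_name = "x", raw_cas = "111-27-3",
                    raw_smiles = "CCCCCCO")
  dbs <- list(source_db("low", rec, qc = "Public_Low"),
              source_db("high", rec, qc = "Public_High"))
  expect_error(autoload_sequence(dbs, core), "descending trust")
})

test_that("snapshot and restore give transactional rollback", {
  tri <- generate_autoload_fixture(seed = 57)
  core <- tri$core
  snap <- chemregistry:::registry_snapshot(core)
  before <- registry_to_list(core)
  autoload_sequence(tri$dbs[1], core)
  expect_gt(length(ls(core$substances)), length(before$substances))
  chemregistry:::registry_restore(core, snap)
  expect_identical(registry_to_list(core), before)
})
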
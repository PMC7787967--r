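# List registration: binning, curator actions, qc elevation, overlap.

curation_core <- function() {
  reg <- registry_new()
  b <- register_substance(reg, "Benzene", "71-43-2", "c1ccccc1")
  t <- register_substance(reg, "Toluene", "108-88-3", "Cc1ccccc1")
  p <- register_substance(reg, "Phenol", "108-95-2", "Oc1ccccc1")
  add_deleted_casrn(reg, b$dtxsid, "1076-43-3")
  add_synonym(reg, t$dtxsid, "shared label")
  add_synonym(reg, p$dtxsid, "shared label")
  add_synonym(reg, p$dtxsid, "carbolic acid")
  list(reg = reg, b = b, t = t, p = p)
}

test_that("binning types every identifier disagreement", {
  cc <- curation_core()
  lst <- data.frame(
    record_id = sprintf("r%d", 1:9),
    raw_name = c("Benzene",        # r1 auto: cas+name agree
                 "Toluene",        # r2 split: cas of benzene, name of toluene
                 "unknown name",   # r3 cas-only: name unknown to the core
                 "Phenol",         # r4 name-only: cas unknown to the core
                 "old benzene",    # r5 deleted-cas hit
                 "shared label",   # r6 ambiguous synonym
                 "nothing known",  # r7 no hit
                 "Benzene",        # r8 structure mismatch: phenol structure
                 NA),              # r9 structure-only hit
    raw_cas = c("71-43-2", "71-43-2", "108-88-3", "50-00-0", "1076-43-3",
                NA, "999999-99-4", "71-43-2", NA),
    raw_smiles = c(NA, NA, NA, NA, NA, NA, NA, "Oc1ccccc1", "Cc1ccccc1"))
  binning <- bin_source_list(cc$reg, lst)
  d <- binning$detail
  bin_of <- function(id) d$bin[d$record_id == id]
  expect_identical(bin_of("r1"), "auto_mapped")
  expect_identical(bin_of("r2"), "cas_name_split")
  expect_identical(bin_of("r3"), "cas_only_hit")
  expect_identical(bin_of("r4"), "name_only_hit")
  expect_identical(bin_of("r5"), "deleted_cas_hit")
  expect_identical(bin_of("r6"), "ambiguous_name")
  expect_identical(bin_of("r7"), "no_hit")
  expect_identical(bin_of("r8"), "structure_mismatch")
  expect_identical(bin_of("r9"), "structure_only_hit")
  # binning partitions the list
  expect_identical(sum(lengths(binning$bins)), nrow(lst))
  # and is read-only on the core
  before <- registry_to_list(cc$reg)
  bin_source_list(cc$reg, lst)
  expect_identical(registry_to_list(cc$reg), before)
})

test_that("resolution actions update list membership under core invariants", {
  cc <- curation_core()
  lst <- data.frame(
    record_id = c("n1", "n2", "n3", "n4"),
    raw_name = c("Benzene", "novel substance", "Toluene sample",
                 "deferred record"),
    raw_cas = c("71-43-2", "999999-99-4", NA, NA),
    raw_smiles = NA_character_)
  binning <- bin_source_list(cc$reg, lst)
  register_list(cc$reg, "demo-list", "Demo list")

  # auto-mapped record attaches directly
  apply_resolution(cc$reg, "demo-list", binning, "n1", "map_to")
  # no_hit + register_new mints a substance and adds it
  apply_resolution(cc$reg, "demo-list", binning, "n2", "register_new")
  # manual map with discordant name stores a synonym candidate
  apply_resolution(cc$reg, "demo-list", binning, "n3", "map_to",
                   target = cc$t$dtxsid)
  # defer leaves the record unresolved, registration still proceeds
  apply_resolution(cc$reg, "demo-list", binning, "n4", "defer")

  l <- cc$reg$lists[["demo-list"]]
  expect_identical(length(l$members), 3L)
  expect_true(cc$b$dtxsid %in% l$members)
  expect_identical(l$unresolved, "n4")
  expect_identical(check_invariants(cc$reg), list())
  # the new substance is findable by its CAS
  expect_identical(resolve_query(cc$reg, "999999-99-4")$outcome, "exact")
  # the discordant source name now redirects to toluene
  r <- resolve_query(cc$reg, "Toluene sample")
  expect_identical(r$outcome, "redirected")
  expect_identical(r$matches, cc$t$dtxsid)
  # provenance: one DTXRID per resolved record
  expect_identical(length(l$provenance), 3L)
  expect_error(apply_resolution(cc$reg, "demo-list", binning, "n4",
                                "map_to"),
               "target")
})

test_that("after full resolution the list re-bins as 100% auto-mapped", {
  cc <- curation_core()
  lst <- data.frame(
    record_id = c("m1", "m2"),
    raw_name = c("brand new acid", "Toluene alias"),
    raw_cas = c("999999-99-4", NA),
    raw_smiles = NA_character_)
  binning <- bin_source_list(cc$reg, lst)
  expect_false(any(binning$detail$bin == "auto_mapped"))
  register_list(cc$reg, "lst2")
  apply_resolution(cc$reg, "lst2", binning, "m1", "register_new")
  apply_resolution(cc$reg, "lst2", binning, "m2", "map_to",
                   target = cc$t$dtxsid)
  rebin <- bin_source_list(cc$reg, lst)
  expect_true(all(rebin$detail$bin == "auto_mapped"))
})

test_that("qc elevation is strict and demotion is refused", {
  cc <- curation_core()
  sid <- register_substance(cc$reg, "public record", "999999-99-4",
                            qc = "Public_Low")$dtxsid
  s <- elevate_qc(cc$reg, sid, "DSSTox_Low", "public consensus reached")
  expect_identical(s$qc_level, "DSSTox_Low")
  expect_match(s$notes, "public consensus")
  expect_error(elevate_qc(cc$reg, sid, "DSSTox_Low"), "strict elevation")
  expect_error(elevate_qc(cc$reg, sid, "Public_Medium"), "strict elevation")
  expect_error(qc_rank("NotALevel"), "unknown qc level")
  expect_identical(qc_rank(c("DSSTox_High", "Public_Low")), c(1L, 5L))
})

test_that("list overlap equals the naive set intersection", {
  cc <- curation_core()
  set.seed(408)
  ids <- c(cc$b$dtxsid, cc$t$dtxsid, cc$p$dtxsid)
  extra <- vapply(1:10, function(i)
    register_substance(cc$reg, sprintf("bulk substance %02d", i))$dtxsid,
    character(1))
  pool <- c(ids, extra)
  for (trial in 1:5) {
    a <- sample(pool, sample(3:10, 1))
    b <- sample(pool, sample(3:10, 1))
    la <- register_list(cc$reg, paste0("la", trial))
    lb <- register_list(cc$reg, paste0("lb", trial))
    la$members <- a
    lb$members <- b
    cc$reg$lists[[paste0("la", trial)]] <- la
    cc$reg$lists[[paste0("lb", trial)]] <- lb
    got <- list_overlap(cc$reg, paste0("la", trial), paste0("lb", trial))
    naive <- character()
    for (x in a) for (y in b) if (identical(x, y)) naive <- c(naive, x)
    expect_setequal(got, unique(naive))
  }
  # disjoint and nested cases
  expect_identical(list_overlap(cc$reg, "la1", "la1"),
                   cc$reg$lists[["la1"]]$members)
  empty_a <- register_list(cc$reg, "empty-a")
  expect_identical(list_overlap(cc$reg, "empty-a", "la1"), character())
  expect_error(list_overlap(cc$reg, "missing", "la1"), "registered")
})
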
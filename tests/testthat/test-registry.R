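# The 1:1:1 registry: registration transactions, redirects, relationships,
# invariants, and query resolution.

test_that("registration mints identifiers and refuses every collision type", {
  reg <- registry_new()
  s <- register_substance(reg, "Benzene", "71-43-2", "c1ccccc1")
  expect_s3_class(s, "chem_substance")
  expect_match(s$dtxsid, "^DTXSID")
  expect_match(s$dtxcid, "^DTXCID")

  # duplicate active CAS
  c1 <- register_substance(reg, "benzol", "71-43-2")
  expect_true(is_conflict(c1))
  expect_identical(c1$type, "cas_collision")
  expect_identical(c1$existing, s$dtxsid)

  # duplicate normalized preferred name (typography differs)
  c2 <- register_substance(reg, "  BENZENE ", "108-88-3")
  expect_identical(c2$type, "name_collision")

  # duplicate structure via a different SMILES rendering
  c3 <- register_substance(reg, "cyclohexatriene", NULL, "C1=CC=CC=C1")
  expect_identical(c3$type, "structure_collision")

  # collision with a stored deleted CAS RN
  add_deleted_casrn(reg, s$dtxsid, "1076-43-3")
  c4 <- register_substance(reg, "fresh thing", "1076-43-3")
  expect_identical(c4$type, "deleted_cas_collision")
  expect_identical(c4$existing, s$dtxsid)

  # no CAS supplied: NOCAS placeholder in the shared namespace
  s2 <- register_substance(reg, "uncatalogued mixture")
  expect_match(s2$cas, "^NOCAS_")
  expect_identical(s2$cas_kind, "nocas")

  # invalid CAS is a validation error, not a conflict
  expect_error(register_substance(reg, "bad", "25068-38-5"),
               class = "cas_validation_error")
  expect_error(register_substance(reg, "bad", "12-3"),
               class = "cas_validation_error")
})

test_that("a refused registration leaves the registry bit-identical", {
  reg <- registry_new()
  register_substance(reg, "Benzene", "71-43-2", "c1ccccc1")
  before <- registry_to_list(reg)
  res <- register_substance(reg, "other", "71-43-2", "Cc1ccccc1")
  expect_true(is_conflict(res))
  expect_identical(registry_to_list(reg), before)
  res2 <- register_substance(reg, "benzene", NULL, "CCO")
  expect_true(is_conflict(res2))
  expect_identical(registry_to_list(reg), before)
})

test_that("deleted CAS RNs redirect, idempotently, and never shadow active ones", {
  reg <- registry_new()
  x <- register_substance(reg, "substance X", "71-43-2")
  y <- register_substance(reg, "substance Y", "108-88-3")
  add_deleted_casrn(reg, x$dtxsid, "1076-43-3")
  r <- resolve_query(reg, "1076-43-3")
  expect_identical(r$outcome, "redirected")
  expect_identical(r$matches, x$dtxsid)
  expect_identical(r$via, "deleted_cas")
  # idempotent re-add
  expect_silent(add_deleted_casrn(reg, x$dtxsid, "1076-43-3"))
  # a deleted CAS equal to an active CAS is a conflict error
  expect_error(add_deleted_casrn(reg, x$dtxsid, "108-88-3"),
               "active CAS RN")
  # re-pointing an existing redirect elsewhere is refused
  expect_error(add_deleted_casrn(reg, y$dtxsid, "1076-43-3"),
               "already redirects")
})

test_that("relationships are typed, directed, deduplicated and queryable", {
  reg <- registry_new()
  mix <- register_substance(reg, "technical mixture")
  comp <- register_substance(reg, "major component", "71-43-2", "c1ccccc1")
  poly <- register_substance(reg, "polymer record")
  add_relationship(reg, mix$dtxsid, comp$dtxsid, "component_of_mixture")
  add_relationship(reg, poly$dtxsid, comp$dtxsid, "monomer_of_polymer")
  # duplicate edge is a no-op
  add_relationship(reg, mix$dtxsid, comp$dtxsid, "component_of_mixture")
  expect_identical(nrow(get_relationships(reg)), 2L)
  expect_identical(nrow(get_relationships(reg, comp$dtxsid, "in")), 2L)
  expect_identical(
    get_relationships(reg, mix$dtxsid, "out")$rel_type,
    "component_of_mixture")
  expect_error(add_relationship(reg, mix$dtxsid, mix$dtxsid, "other"),
               "self-edge")
  expect_error(add_relationship(reg, mix$dtxsid, "DTXSID9999999", "other"),
               "unknown substance")
})

test_that("stripping representative structures repairs every planted sharing", {
  set.seed(406)
  for (trial in 1:5) {
    reg <- registry_new()
    lib <- sample(chemlib_smiles(), 12)
    subs <- character(12)
    for (i in 1:12) {
      subs[i] <- register_substance(
        reg, sprintf("trial substance %d", i),
        cas = sprintf("%07d-10-%d", 9700000 + i,
                      cas_check_digit(sprintf("%07d10", 9700000 + i))),
        smiles = if (i <= 8) lib[i] else NULL)$dtxsid
    }
    # plant k representative-structure sharings: structureless records 9..12
    # borrow structures of records 1..k
    k <- sample(1:4, 1)
    for (j in seq_len(k)) {
      chemregistry:::plant_shared_structure(reg, subs[j], subs[8 + j])
    }
    expect_identical(length(check_invariants(reg)), k)

    for (j in seq_len(k)) {
      rel <- strip_representative_structure(reg, subs[8 + j])
      expect_identical(rel$rel_type, "representative_structure_of")
      expect_identical(rel$successor, subs[j])
    }
    expect_identical(check_invariants(reg), list())
    # quadratic scan confirms no shared dtxcids remain
    expect_identical(oracle_registry_violations(reg), character())
    edges <- get_relationships(reg)
    expect_identical(sum(edges$rel_type == "representative_structure_of"),
                     as.integer(k))
  }
})

test_that("stripping registers a fresh owner when the structure has none", {
  reg <- registry_new()
  mix <- register_substance(reg, "mixture with representative structure",
                            "71-43-2", "c1ccccc1")
  rel <- strip_representative_structure(reg, mix$dtxsid)
  owner <- rel$successor
  expect_false(identical(owner, mix$dtxsid))
  expect_true(is.na(get_substance(reg, mix$dtxsid)$dtxcid))
  expect_identical(get_substance(reg, owner)$dtxcid,
                   reg$idx_key[[structure_key("c1ccccc1")]])
  expect_identical(check_invariants(reg), list())
  expect_error(strip_representative_structure(reg, mix$dtxsid),
               "no structure")
})

test_that("query resolution walks the four steps in order", {
  d <- make_demo_registry()
  reg <- d$reg
  # step 1: exact on active CAS, preferred name, DTX ids
  expect_identical(resolve_query(reg, "71-43-2")$outcome, "exact")
  expect_identical(resolve_query(reg, "  benzene ")$outcome, "exact")
  expect_identical(resolve_query(reg, d$benzene$dtxsid)$matches,
                   d$benzene$dtxsid)
  expect_identical(resolve_query(reg, d$benzene$dtxcid)$matches,
                   d$benzene$dtxsid)
  # step 2: redirects
  add_deleted_casrn(reg, d$benzene$dtxsid, "1076-43-3")
  r <- resolve_query(reg, "1076-43-3")
  expect_identical(r$outcome, "redirected")
  expect_identical(r$via, "deleted_cas")
  add_synonym(reg, d$toluene$dtxsid, "methylbenzene")
  r2 <- resolve_query(reg, "Methylbenzene")
  expect_identical(r2$outcome, "redirected")
  expect_identical(r2$via, "synonym")
  # step 3: ambiguous synonym lists all matches
  add_synonym(reg, d$benzene$dtxsid, "coal naphtha")
  add_synonym(reg, d$phenol$dtxsid, "coal naphtha")
  r3 <- resolve_query(reg, "coal naphtha")
  expect_identical(r3$outcome, "multiple")
  expect_setequal(r3$matches, c(d$benzene$dtxsid, d$phenol$dtxsid))
  expect_true(synonym_is_ambiguous(reg, "Coal Naphtha"))
  expect_false(synonym_is_ambiguous(reg, "methylbenzene"))
  # step 4: nothing matched
  expect_identical(resolve_query(reg, "completely unknown")$outcome,
                   "not_found")
  # structure queries never fall through to names
  expect_identical(resolve_query(reg, "C1=CC=CC=C1")$matches,
                   d$benzene$dtxsid)
  expect_identical(resolve_query(reg, "CCCCCCCCC=O", type = "smiles")$outcome,
                   "not_found")
})

test_that("invariant scan matches the quadratic oracle under injected corruption", {
  set.seed(407)
  for (trial in 1:10) {
    reg <- registry_new()
    n <- sample(5:25, 1)
    lib <- sample(chemlib_smiles(), n)
    ids <- character(n)
    for (i in seq_len(n)) {
      ids[i] <- register_substance(
        reg, sprintf("inv substance %03d", i),
        cas = sprintf("%07d-10-%d", 9600000 + i,
                      cas_check_digit(sprintf("%07d10", 9600000 + i))),
        smiles = if (i %% 3 != 0) lib[i] else NULL)$dtxsid
    }
    expect_identical(check_invariants(reg), list())
    # inject corruption past the public API
    n_cas <- sample(0:2, 1)
    n_struct <- sample(0:2, 1)
    if (n_cas > 0) {
      for (z in seq_len(n_cas)) {
        pair <- sample(ids, 2)
        chemregistry:::plant_duplicate_cas(reg, pair[1], pair[2])
      }
    }
    if (n_struct > 0) {
      with_struct <- ids[vapply(ids, function(s)
        !is.na(get_substance(reg, s)$dtxcid), logical(1))]
      if (length(with_struct) >= 2) {
        for (z in seq_len(n_struct)) {
          pair <- sample(with_struct, 2)
          chemregistry:::plant_shared_structure(reg, pair[1], pair[2])
        }
      }
    }
    got <- sort(unique(vapply(check_invariants(reg), function(v)
      paste0(v$type, ":", v$value), character(1))))
    expect_identical(got, oracle_registry_violations(reg))
  }
})
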
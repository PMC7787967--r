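# CAS RN checksum, validation, query classification and name normalization.

test_that("check digit reproduces known registry numbers and oracle", {
  # the resin registered as 25068-38-6: leading segments 25068-38
  expect_identical(cas_check_digit("2506838"), 6L)
  expect_identical(cas_check_digit("25068-38"), 6L)
  # degenerate all-zero input
  expect_identical(cas_check_digit("0000000"), 0L)
  # brute-force weighted sum: 0*1 + 0*2 + 0*3 + 5*4 = 20 -> 0
  expect_identical(cas_check_digit("5000"), 0L)
  expect_identical(oracle_check_digit("5000"), 0L)
  # a handful of well-known registry numbers
  known <- c(water = "7732-18-5", benzene = "71-43-2",
             toluene = "108-88-3", caffeine = "58-08-2")
  for (rn in known) {
    parts <- strsplit(rn, "-")[[1]]
    expect_identical(cas_check_digit(paste0(parts[1], parts[2])),
                     as.integer(parts[3]))
  }
})

test_that("check digit agrees with the brute-force oracle on random prefixes", {
  set.seed(401)
  for (i in 1:200) {
    len <- sample(4:9, 1)
    digits <- paste(sample(0:9, len, replace = TRUE), collapse = "")
    expect_identical(cas_check_digit(digits), oracle_check_digit(digits),
                     info = digits)
  }
})

test_that("check digit errors on malformed input", {
  expect_error(cas_check_digit("12x45"), "4-9 digits")
  expect_error(cas_check_digit("123"), "4-9 digits")
  expect_error(cas_check_digit("1234567890"), "4-9 digits")
})

test_that("appending the check digit always round-trips through validation", {
  set.seed(402)
  for (i in 1:100) {
    reg_part <- paste(sample(0:9, sample(2:7, 1), replace = TRUE),
                      collapse = "")
    middle <- sprintf("%02d", sample(0:99, 1))
    d <- cas_check_digit(paste0(reg_part, middle))
    full <- sprintf("%s-%s-%d", reg_part, middle, d)
    expect_s3_class(validate_casrn(full), "casrn")
    # the checksum is a bijection mod 10 in the final digit: exactly one
    # of the ten candidates validates
    ok <- vapply(0:9, function(k)
      is_valid_casrn(sprintf("%s-%s-%d", reg_part, middle, k)), logical(1))
    expect_identical(sum(ok), 1L)
    expect_true(ok[d + 1L])
  }
})

test_that("validation distinguishes format and checksum failures", {
  v <- validate_casrn("25068-38-6")
  expect_s3_class(v, "casrn")
  expect_identical(v$registry_part, "25068")
  expect_identical(v$check_digit, 6L)

  bad_sum <- validate_casrn("25068-38-5")
  expect_s3_class(bad_sum, "cas_failure")
  expect_identical(bad_sum$reason, "checksum")

  bad_fmt <- validate_casrn("1234-5")
  expect_s3_class(bad_fmt, "cas_failure")
  expect_identical(bad_fmt$reason, "format")

  expect_identical(validate_casrn("71-43-2  ")$text, "71-43-2")
  expect_false(is_valid_casrn("71-43-3"))
  expect_identical(is_valid_casrn(c("71-43-2", "x", NA)),
                   c(TRUE, FALSE, FALSE))
})

test_that("query classification routes identifiers and names", {
  expect_identical(classify_query("DTXSID0050479"), "dsstox_id")
  expect_identical(classify_query("DTXCID123"), "dsstox_id")
  expect_identical(classify_query("NOCAS_00017"), "nocas")
  expect_identical(classify_query("25068-38-6"), "casrn")
  expect_identical(classify_query("Bisphenol A/Epichlorohydrin resin"),
                   "name")
  # CAS-shaped but checksum-failing strings stay searchable as names
  expect_identical(classify_query("25068-38-5"), "name")
  expect_error(classify_query(""), "non-empty")
  expect_error(classify_query("   "), "non-empty")
})

test_that("query classification is total and deterministic over printable strings", {
  set.seed(403)
  pool <- c(LETTERS, letters, 0:9, "-", "_", " ", "(", ")", ",", "/")
  for (i in 1:150) {
    s <- paste(sample(pool, sample(1:20, 1), replace = TRUE), collapse = "")
    if (!nzchar(trimws(s))) next
    c1 <- classify_query(s)
    expect_true(c1 %in% c("casrn", "nocas", "dsstox_id", "name"))
    expect_identical(classify_query(s), c1)
  }
})

test_that("name normalization folds case and whitespace but keeps punctuation", {
  expect_identical(normalize_name("  Bisphenol  A "), "bisphenol a")
  expect_identical(normalize_name("PFAS"), normalize_name("pfas"))
  expect_identical(normalize_name("(R)-1,2-epoxypropane"),
                   "(r)-1,2-epoxypropane")
  set.seed(404)
  pool <- c(LETTERS, letters, 0:9, " ", "\t", "-", ",", "(", ")")
  for (i in 1:100) {
    s <- paste(sample(pool, sample(1:30, 1), replace = TRUE), collapse = "")
    expect_identical(normalize_name(normalize_name(s)), normalize_name(s))
  }
})

test_that("NOCAS and DTX identifiers format and parse round-trip", {
  expect_identical(nocas_format(17L), "NOCAS_00017")
  expect_identical(nocas_format(123456L), "NOCAS_123456")
  id <- dtx_format("DTXSID", 50479L)
  p <- dtx_parse(id)
  expect_identical(p$kind, "DTXSID")
  expect_identical(p$serial, 50479L)
  expect_null(dtx_parse("DTXXID123"))
  expect_identical(classify_query(nocas_format(1L)), "nocas")
})
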
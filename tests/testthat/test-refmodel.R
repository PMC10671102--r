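test_that("haplotype strings parse into the expected variant sets", {
  h <- parse_haplotype("263G 315.1C", ref = REF)
  expect_equal(n_variants(h), 2L)
  expect_equal(h$variants$kind, c("sub", "ins"))
  expect_equal(h$variants$pos, c(263L, 315L))
  expect_equal(h$variants$obs, c("G", "C"))
  expect_equal(h$variants$idx[2], "1")

  expect_equal(n_variants(parse_haplotype("", ref = REF)), 0L)

  h10 <- parse_haplotype(HAP_H2A1N, ref = REF)
  expect_equal(n_variants(h10), 10L)
  expect_true("x" %in% h10$variants$idx)
})

test_that("serialization is canonical and round-trips", {
  expect_equal(serialize_haplotype(mt_haplotype()), "")
  # shuffled input comes out in canonical order
  h <- parse_haplotype("315.1C 263G", ref = REF)
  expect_equal(serialize_haplotype(h), "263G 315.1C")
  # both deletion dialects are read; DEL is emitted
  expect_equal(serialize_haplotype(parse_haplotype("8281-")), "8281DEL")
  expect_equal(serialize_haplotype(parse_haplotype("8281DEL")), "8281DEL")
})

test_that("parse/serialize round-trips randomly generated haplotypes", {
  set.seed(42)
  syms <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M")
  for (rep in 1:40) {
    n <- sample(0:30, 1)
    pos <- sort(sample(seq_len(MT_LENGTH), n))
    tokens <- vapply(pos, function(p) {
      kind <- sample(c("sub", "ins", "del"), 1, prob = c(0.8, 0.1, 0.1))
      if (kind == "del") paste0(p, "DEL")
      else if (kind == "ins") paste0(p, ".", sample(c(1:3, "x"), 1),
                                     sample(c("A", "C", "G", "T"), 1))
      else paste0(p, sample(syms, 1))
    }, character(1))
    text <- paste(sample(tokens), collapse = " ")
    h1 <- parse_haplotype(text)
    h2 <- parse_haplotype(serialize_haplotype(h1))
    expect_identical(h1$variants, h2$variants)
  }
})

test_that("malformed and duplicate tokens are rejected with the token named", {
  expect_error(parse_haplotype("263Z"), "263Z")
  expect_error(parse_haplotype("abc"), "abc")
  expect_error(parse_haplotype("315.0C"), "315\\.0C")
  expect_error(parse_haplotype("263G 263G"), "duplicate")
  expect_error(parse_haplotype("99999G"), "outside")
  # substitution equal to the reference base is invalid when ref is known
  expect_error(parse_haplotype("263A", ref = REF), "reference")
})

test_that("range restriction keeps exactly the in-range variants", {
  h <- parse_haplotype(HAP_H2A1N, ref = REF)
  hv <- restrict_to_range(h, standard_range("hvs"))
  expect_equal(serialize_haplotype(hv), "146C 263G 309.xC 315.1C 16354T")
  # full range: unchanged; empty window: empty; idempotent and monotone
  expect_equal(serialize_haplotype(restrict_to_range(h, standard_range("mitogenome"))),
               serialize_haplotype(h))
  expect_equal(n_variants(restrict_to_range(h, mt_range("w", 5000, 6000))), 0L)
  expect_equal(serialize_haplotype(restrict_to_range(hv, standard_range("hvs"))),
               serialize_haplotype(hv))
  cr <- restrict_to_range(h, standard_range("cr"))
  expect_true(all(hv$variants$pos %in% cr$variants$pos))
})

test_that("out-of-range tokens are rejected or dropped per configuration", {
  expect_error(parse_haplotype("750G", range = standard_range("hvs")), "750G")
  expect_warning(
    h <- parse_haplotype("263G 750G", range = standard_range("hvs"),
                         outside = "drop"),
    "750G")
  expect_equal(serialize_haplotype(h), "263G")
})

test_that("the control region spans the circular origin", {
  cr <- standard_range("cr")
  expect_true(all(in_mt_range(c(1L, 576L, 16024L, 16569L), cr)))
  expect_false(any(in_mt_range(c(577L, 16023L, 8000L), cr)))
  expect_equal(mt_wrap(MT_LENGTH + 1L), 1L)
})

test_that("IUPAC matching follows the literal and pattern policies", {
  expect_true(iupac_match("Y", "C", "pattern"))
  expect_false(iupac_match("Y", "C", "literal"))
  expect_true(iupac_match("A", "A", "literal"))
  expect_error(iupac_match("Z", "A", "literal"))

  syms <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")
  for (a in syms) for (b in syms) {
    # reflexive and symmetric; literal implies pattern
    expect_true(iupac_match(a, a, "pattern"))
    expect_equal(iupac_match(a, b, "pattern"), iupac_match(b, a, "pattern"))
    if (iupac_match(a, b, "literal")) expect_true(iupac_match(a, b, "pattern"))
  }
})

test_that("haplotype files round-trip through the TSV format", {
  hs <- list(parse_haplotype(HAP_U5B1B1A, sample_id = "A1", ref = REF),
             parse_haplotype("", sample_id = "A2", ref = REF))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_haplotypes(hs, path)
  back <- read_haplotypes(path, ref = REF)
  expect_equal(vapply(back, serialize_haplotype, character(1)),
               vapply(hs, serialize_haplotype, character(1)))
  expect_equal(back[[1]]$sample_id, "A1")
})

test_that("the packaged reference has the documented anchor structure", {
  expect_equal(REF$length, 16569L)
  expect_equal(ref_base(REF, c(263L, 13105L, 16189L)), c("A", "G", "T"))
  expect_true(all(ref_base(REF, 303:309) == "C"))
  expect_equal(ref_base(REF, 310L), "T")
  # FASTA round trip
  path <- withr::local_tempfile(fileext = ".fasta")
  write_reference_fasta(REF, path)
  back <- read_reference_fasta(path)
  expect_identical(back$bases, REF$bases)
})
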
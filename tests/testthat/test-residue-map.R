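test_that("the packaged ortholog site table parses faithfully", {
  sites <- dicer2_sites()
  expect_s3_class(sites, "site_map")
  # 5 species x (4+4 catalytic + 9+9 pocket entries)
  expect_equal(nrow(sites), 5 * 26)
  expect_setequal(unique(sites$site),
                  c("RIII_A", "RIII_B", "pocket_3prime", "pocket_5prime"))

  dmel_riiia <- dplyr::filter(sites, structure_id == "dmel", site == "RIII_A")
  expect_equal(dmel_riiia$resno, c(1213L, 1217L, 1368L, 1371L))
  expect_equal(dmel_riiia$expected_aa[1], "E")
  expect_equal(dmel_riiia$chain[1], "A")

  # one unresolved 3' pocket entry per non-reference species
  unres <- dplyr::filter(sites, !resolved)
  expect_equal(nrow(unres), 4)
  expect_true(all(unres$site == "pocket_3prime"))
  expect_true(all(is.na(unres$resno)))
})

test_that("site tables round-trip through TSV and reject malformed input", {
  sites <- dicer2_sites()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sites(sites, f)
  back <- read_sites(f)
  expect_equal(as.data.frame(back), as.data.frame(sites))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("structure_id\tsite_name\tchain_id\tresidue_number\texpected_aa",
               "x\tRIII_A\tA\t10\tE",
               "x\tRIII_A\tA\t10\tE"), f2)
  expect_error(read_sites(f2), class = "dicerruler_error_parse")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("structure_id\tsite_name\tchain_id\tresidue_number",
               "x\tRIII_A\tA\t10"), f3)
  expect_error(read_sites(f3), class = "dicerruler_error_parse")

  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("structure_id\tsite_name\tchain_id\tresidue_number\texpected_aa",
               "x\tnot_a_site\tA\t10\tE"), f4)
  expect_error(read_sites(f4), class = "dicerruler_error_parse")
})

test_that("validate_map reports absent residues and identity mismatches only", {
  sc <- generate_scaffold("v", 60, 61, seed = 2)
  expect_equal(nrow(validate_map(sc$sites, sc$structure)), 0)

  missing <- dplyr::filter(sc$structure, resno != 1201L)
  d1 <- validate_map(sc$sites, missing)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$problem, "absent_residue")
  expect_equal(d1$resno, 1201L)

  mutated <- sc$structure
  mutated$aa[mutated$resno == 1202L] <- "D"
  d2 <- validate_map(sc$sites, mutated)
  expect_equal(nrow(d2), 1)
  expect_equal(d2$problem, "identity_mismatch")
  expect_equal(d2$found_aa, "D")
})

test_that("global alignment scores are optimal and inputs are validated", {
  ident <- score_matrix(1, 0)
  al <- align_global("ACDE", "ACDE", matrix = ident, gap_open = -5,
                     gap_extend = -1)
  expect_equal(al$score, 4)
  expect_equal(al$ref_to_tgt, 1:4)

  # frozen value computed with the enumeration oracle:
  # all global alignments of ACD/AD under match 1, mismatch -1, gaps -1/-1
  m2 <- score_matrix(1, -1)
  expect_equal(nw_enumerate_oracle("ACD", "AD", m2, -1, -1), 0)
  al2 <- align_global("ACD", "AD", matrix = m2, gap_open = -1, gap_extend = -1)
  expect_equal(al2$score, 0)

  expect_error(align_global("", "ACD", matrix = ident),
               class = "dicerruler_error_empty_sequence")
  expect_error(align_global("AC1", "ACD", matrix = ident),
               class = "dicerruler_error_alphabet")
})

test_that("alignment scores equal the independent Gotoh oracle", {
  m <- score_matrix(2, -1)
  # validate the DP oracle against pure enumeration at tiny n first
  withr::with_seed(31, {
    for (i in 1:10) {
      a <- random_aa_string(sample(1:4, 1))
      b <- random_aa_string(sample(1:4, 1))
      expect_equal(nw_score_oracle(a, b, m, -2, -1),
                   nw_enumerate_oracle(a, b, m, -2, -1))
    }
  })
  withr::with_seed(32, {
    for (i in 1:50) {
      a <- random_aa_string(sample(1:8, 1))
      b <- random_aa_string(sample(1:8, 1))
      al <- align_global(a, b, matrix = m, gap_open = -2, gap_extend = -1)
      expect_equal(al$score, nw_score_oracle(a, b, m, -2, -1))
    }
  })
})

test_that("alignment invariants: gapped strings and monotone mapping", {
  withr::with_seed(33, {
    for (i in 1:20) {
      a <- random_aa_string(sample(3:12, 1))
      b <- random_aa_string(sample(3:12, 1))
      al <- align_global(a, b)
      expect_equal(gsub("-", "", al$aligned_ref), a)
      expect_equal(gsub("-", "", al$aligned_tgt), b)
      mapped <- al$ref_to_tgt[!is.na(al$ref_to_tgt)]
      expect_true(all(diff(mapped) > 0))
    }
  })
})

test_that("site transfer: identity, N-terminal truncation offset, gaps", {
  # identity alignment is the identity on resolved entries
  seq_ref <- random_aa_string(120)
  al <- align_global(seq_ref, seq_ref)
  sites <- tiny_sites("ref", "RIII_A", 100, aa = substr(seq_ref, 100, 100))
  out <- transfer_sites(sites, al, structure_id = "tgt")
  expect_equal(out$resno, 100L)
  expect_equal(out$expected_aa, substr(seq_ref, 100, 100))
  expect_true(out$resolved)

  # reference numbered 1114..1213 with the caliper glutamate at author 1213;
  # the ortholog lacks the first 48 residues, its own numbering starting at
  # 1114 -> the residue must land at author 1165 (the published offset
  # pattern between the reference and the beetle ortholog)
  withr::with_seed(7, base <- random_aa_string(99))
  seq_ref2 <- paste0(base, "E")
  seq_tgt2 <- substr(seq_ref2, 49, 100)
  al2 <- align_global(seq_ref2, seq_tgt2)
  sites2 <- tiny_sites("ref", "RIII_A", 1213, aa = "E")
  out2 <- transfer_sites(sites2, al2,
                         ref_numbering = 1114:1213,
                         tgt_numbering = 1114:1165, structure_id = "tcas_like")
  expect_equal(out2$resno, 1165L)
  expect_equal(out2$expected_aa, "E")

  # a reference residue aligned opposite a gap becomes unresolved
  seq_ref3 <- "ACDEFGHIKL"
  seq_tgt3 <- "ACDEGHIKL"   # F deleted
  al3 <- align_global(seq_ref3, seq_tgt3, matrix = score_matrix(5, -2))
  sites3 <- tiny_sites("ref", "pocket_3prime", 5, aa = "F")
  out3 <- transfer_sites(sites3, al3)
  expect_false(out3$resolved)
  expect_equal(out3$expected_aa, "?")
  expect_true(is.na(out3$resno))

  # numbering outside the reference errors
  expect_error(transfer_sites(tiny_sites("r", "RIII_A", 999), al3),
               class = "dicerruler_error_length_mismatch")
})

test_that("transferred author numbers are strictly increasing", {
  withr::with_seed(40, {
    ref <- random_aa_string(80)
    # delete a block to force gaps
    tgt <- paste0(substr(ref, 1, 30), substr(ref, 41, 80))
    al <- align_global(ref, tgt)
    sites <- tiny_sites("ref", rep("pocket_5prime", 6),
                        c(5L, 15L, 25L, 45L, 60L, 75L))
    out <- transfer_sites(sites, al)
    got <- out$resno[out$resolved]
    expect_true(all(diff(got) > 0))
  })
})

test_that("strict transfer drops entries whose target residue differs", {
  ref <- "ACDEFGHIKL"
  tgt <- "ACDQFGHIKL"  # E -> Q substitution at position 4
  al <- align_global(ref, tgt, matrix = score_matrix(5, -2))
  sites <- tiny_sites("ref", "RIII_B", 4, aa = "E")
  lax <- transfer_sites(sites, al)
  expect_true(lax$resolved)
  expect_equal(lax$expected_aa, "Q")
  strict <- transfer_sites(sites, al, strict = TRUE)
  expect_false(strict$resolved)
})
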
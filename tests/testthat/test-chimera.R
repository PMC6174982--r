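test_that("domain swap crosses N/C segments and conserves residues", {
  a <- sequence_record("A", "MKLV")
  b <- sequence_record("B", "GGHHH")
  fs <- swap_domains(a, b, 2, 3)
  expect_equal(fs$fusion1$residues, "MKHH")
  expect_equal(fs$fusion2$residues, "GGHLV")
  expect_equal(fs$fusion1$id, "NTA/CTB")
  expect_equal(attr(fs$fusion1, "junction"), 2L)

  set.seed(7)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:25) {
    sa <- paste(sample(alphabet, sample(2:30, 1), TRUE), collapse = "")
    sb <- paste(sample(alphabet, sample(2:30, 1), TRUE), collapse = "")
    ba <- sample(nchar(sa), 1)
    bb <- sample(nchar(sb), 1)
    fs <- swap_domains(sequence_record("a", sa), sequence_record("b", sb),
                       ba, bb)
    expect_equal(nchar(fs$fusion1$residues) + nchar(fs$fusion2$residues),
                 nchar(sa) + nchar(sb))
    # involution: swapping the fusions back recovers the parents
    back <- swap_domains(fs$fusion1, fs$fusion2, ba, bb)
    expect_equal(back$fusion1$residues, sa)
    expect_equal(back$fusion2$residues, sb)
  }
})

test_that("swap boundary at full length leaves the first parent unchanged", {
  a <- sequence_record("A", "MKLV")
  b <- sequence_record("B", "GGHHH")
  fs <- swap_domains(a, b, 4, 5)
  expect_equal(fs$fusion1$residues, "MKLV")
  expect_error(swap_domains(a, b, 5, 1), "region error")
})

test_that("region replacement grafts the donor segment with provenance", {
  acc <- sequence_record("T3", paste(rep(c("K", "A"), 25), collapse = ""))
  don <- sequence_record("T2", paste(rep(c("E", "G"), 30), collapse = ""))
  ch <- replace_region(acc, region_spec(26, 41), don, region_spec(26, 47))
  expect_equal(nchar(ch$residues), nchar(acc$residues) + 6)
  expect_equal(attr(ch, "length_delta"), 6L)
  prov <- attr(ch, "provenance")
  expect_equal(nrow(prov), nchar(ch$residues))
  expect_equal(prov$source[26], "T2")
  expect_equal(prov$source_pos[26:47], 26:47)
  expect_equal(prov$source[25], "T3")
  expect_equal(prov$source_pos[48], 42)  # acceptor resumes after the graft

  # replacing a region with itself is the identity
  same <- replace_region(acc, region_spec(5, 9), acc, region_spec(5, 9))
  expect_equal(same$residues, acc$residues)
})

test_that("replacement length arithmetic holds for random regions", {
  set.seed(11)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:30) {
    pick <- function(x) x[sample.int(length(x), 1)]
    acc <- paste(sample(alphabet, sample(5:40, 1), TRUE), collapse = "")
    don <- paste(sample(alphabet, sample(5:40, 1), TRUE), collapse = "")
    a1 <- pick(seq_len(nchar(acc))); a2 <- pick(a1:nchar(acc))
    d1 <- pick(seq_len(nchar(don))); d2 <- pick(d1:nchar(don))
    ch <- replace_region(sequence_record("a", acc), region_spec(a1, a2),
                         sequence_record("d", don), region_spec(d1, d2))
    expect_equal(nchar(ch$residues),
                 nchar(acc) + (d2 - d1) - (a2 - a1))
  }
})

test_that("pure deletion requires the explicit empty-donor flag", {
  acc <- sequence_record("x", "ACDEFGHIKL")
  don <- sequence_record("d", "AAAA")
  expect_error(replace_region(acc, region_spec(3, 5), don, NULL),
               "allow_empty_donor")
  del <- replace_region(acc, region_spec(3, 5), don, NULL,
                        allow_empty_donor = TRUE)
  expect_equal(del$residues, "ACGHIKL")
  expect_equal(attr(del, "length_delta"), -3L)
  expect_error(replace_region(acc, region_spec(3, 50), don, region_spec(1, 2)),
               "region error")
})

test_that("identical sequences align at 100% identity with no gaps", {
  s <- sequence_record("s", "HEAGAWGHEE")
  al <- global_align(s, s)
  expect_equal(al$identity, 100)
  expect_equal(al$similarity, 100)
  expect_false(grepl("-", al$alignedA))
  expect_equal(al$alignedA, al$alignedB)
})

test_that("alignment score equals the exhaustive enumeration oracle", {
  submat <- blosum62()
  set.seed(5)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:8) {
    a <- paste(sample(alphabet, sample(2:5, 1), TRUE), collapse = "")
    b <- paste(sample(alphabet, sample(2:5, 1), TRUE), collapse = "")
    got <- global_align(sequence_record("a", a), sequence_record("b", b))
    want <- oracle_align_score(a, b, submat)
    expect_equal(got$score, want, info = paste(a, b))
    # symmetry
    rev <- global_align(sequence_record("b", b), sequence_record("a", a))
    expect_equal(rev$score, got$score)
  }
})

test_that("alignment invariants: ungapping recovers inputs, bounds hold", {
  a <- sequence_record("a", "HEAGAWGHEE")
  b <- sequence_record("b", "PAWHEAE")
  al <- global_align(a, b)
  expect_equal(gsub("-", "", al$alignedA), a$residues)
  expect_equal(gsub("-", "", al$alignedB), b$residues)
  expect_equal(nchar(al$alignedA), nchar(al$alignedB))
  expect_true(al$identity >= 0 && al$identity <= al$similarity &&
                al$similarity <= 100)
  expect_equal(length(al$column_class), al$length)
})

test_that("residues outside the substitution matrix raise an alphabet error", {
  a <- sequence_record("a", "ACDO", validate = FALSE)
  b <- sequence_record("b", "ACD")
  expect_error(global_align(a, b), "alphabet error")
})

test_that("chemical annotation follows the four-class table", {
  got <- annotate_chemistry(sequence_record("x", "DKSA"))
  expect_equal(got, c("acidic", "basic", "hydroxyl_amine", "small_hydrophobic"))

  cls <- chemistry_classes()
  all_residues <- sort(unlist(cls, use.names = FALSE))
  expect_equal(all_residues, sort(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))

  set.seed(3)
  seq1 <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 200, TRUE),
                collapse = "")
  ann <- annotate_chemistry(sequence_record("r", seq1))
  aa <- strsplit(seq1, "")[[1]]
  expect_equal(sum(ann == "basic"), sum(aa %in% c("R", "K", "H")))
  expect_equal(sum(ann == "acidic"), sum(aa %in% c("D", "E")))
})

test_that("FASTA round trip preserves ids and residues", {
  recs <- list(sequence_record("alpha", "MKLVHE"),
               sequence_record("beta", "GGHHHWW"))
  tf <- tempfile(fileext = ".fasta")
  write_fasta_records(recs, tf)
  back <- read_fasta_records(tf)
  expect_equal(vapply(back, `[[`, "", "id"), c("alpha", "beta"))
  expect_equal(vapply(back, `[[`, "", "residues"), c("MKLVHE", "GGHHHWW"))
  unlink(tf)
})
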
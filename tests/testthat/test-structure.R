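test_that("a toy single-residue PDB parses into the expected atoms", {
  s <- read_pdb(toy_ala_pdb(), label = "ala")
  expect_s3_class(s, "protein_structure")
  expect_equal(nrow(s$atoms), 5)
  expect_equal(s$atoms$name, c("N", "CA", "C", "O", "CB"))
  expect_equal(s$atoms$element, c("N", "C", "C", "O", "C"))
  expect_equal(unique(s$atoms$resno), 1)
  expect_equal(s$atoms$b, c(10, 11, 12, 13, 14))
  expect_equal(s$chains[["A"]]$residues, "A")
})

test_that("only the first MODEL of a multi-model file is read", {
  s <- read_pdb(two_model_pdb())
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x, c(0, 1.458))
})

test_that("HETATM, waters, hydrogens and non-A altlocs are discarded", {
  txt <- paste(
    c("ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
      "ATOM      2  CA AGLY A   1       1.458   0.000   0.000  0.50  0.00           C",
      "ATOM      3  CA BGLY A   1       1.470   0.100   0.000  0.50  0.00           C",
      "ATOM      4  H   GLY A   1       0.300   0.900   0.000  1.00  0.00           H",
      "HETATM    5 ZN    ZN A  90      10.000  10.000  10.000  1.00  0.00          ZN",
      "HETATM    6  O   HOH A  99      12.000  12.000  12.000  1.00  0.00           O",
      "END"), collapse = "\n")
  s <- read_pdb(txt)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$name, c("N", "CA"))
  expect_equal(s$atoms$x[2], 1.458)  # altloc A kept, B dropped
})

test_that("malformed ATOM records fail with the offending line number", {
  txt <- paste(
    c("ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
      "ATOM      2  CA  GLY A   1       bad.xx   0.000   0.000  1.00  0.00           C"),
    collapse = "\n")
  expect_error(read_pdb(txt), "line 2")
  expect_error(read_pdb("REMARK nothing here"), "no ATOM records")
})

test_that("read -> write -> read round trip preserves the atomic model", {
  s1 <- read_pdb(toy_ala_pdb())
  txt <- write_annotated_pdb(s1, per_atom_score = s1$atoms$b)
  s2 <- read_pdb(paste(txt, collapse = "\n"))
  expect_equal(s2$atoms$name, s1$atoms$name)
  expect_equal(s2$atoms$resno, s1$atoms$resno)
  expect_equal(s2$atoms$chain, s1$atoms$chain)
  expect_equal(s2$atoms$x, s1$atoms$x, tolerance = 1e-3)
  expect_equal(s2$atoms$y, s1$atoms$y, tolerance = 1e-3)
  expect_equal(s2$atoms$z, s1$atoms$z, tolerance = 1e-3)
  expect_equal(s2$atoms$b, s1$atoms$b, tolerance = 1e-2)
})

test_that("score annotation lands in B-factor columns 61-66, clamped", {
  s <- read_pdb(toy_ala_pdb())
  zero <- write_annotated_pdb(s, 0)
  atom_lines <- grep("^ATOM", zero, value = TRUE)
  expect_true(all(substr(atom_lines, 61, 66) == "  0.00"))
  one <- write_annotated_pdb(s, c(25, 0, 0, 0, 0))
  expect_equal(substr(grep("^ATOM", one, value = TRUE)[1], 61, 66), " 25.00")
  big <- write_annotated_pdb(s, c(12345.6, -12345.6, 0, 0, 0))
  lines <- grep("^ATOM", big, value = TRUE)
  expect_equal(substr(lines[1], 61, 66), "999.99")
  expect_equal(substr(lines[2], 61, 66), "-99.99")
})

test_that("pH-7 charge assignment matches the declared formal-charge rules", {
  gly <- assign_parameters(read_pdb(example_gly_pdb()))
  expect_equal(net_charge(gly), 0)  # zwitterion
  # C-terminal -1 split over O/OXT, N-terminal +1 on N
  expect_equal(gly$atoms$charge[gly$atoms$name == "N"], 1)
  expect_equal(gly$atoms$charge[gly$atoms$name == "OXT"], -0.5)

  k5 <- assign_parameters(make_peptide_structure("KKKKK"))
  expect_equal(net_charge(k5), 5)

  de <- assign_parameters(make_peptide_structure("DEED"))
  side_chain <- de$atoms[de$atoms$name %in% c("OD1", "OD2", "OE1", "OE2"), ]
  expect_true(all(side_chain$charge < 0))
  expect_equal(net_charge(de), -4)
})

test_that("net charge equals the closed-form residue tally for random sequences", {
  set.seed(42)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:20) {
    seq1 <- paste(sample(alphabet, sample(3:12, 1), replace = TRUE),
                  collapse = "")
    st <- assign_parameters(make_peptide_structure(seq1))
    expect_equal(net_charge(st), sequence_net_charge(seq1), info = seq1)
  }
})

test_that("polarity partition is exhaustive and exclusive", {
  st <- assign_parameters(make_peptide_structure("ADKRESTWY"))
  expect_true(all(st$atoms$polarity %in% c("nonpolar", "polar")))
  expect_false(anyNA(st$atoms$polarity))
  expect_setequal(unique(st$atoms$polarity[st$atoms$element %in% c("C", "S")]),
                  "nonpolar")
  expect_setequal(unique(st$atoms$polarity[st$atoms$element %in% c("N", "O")]),
                  "polar")
})

test_that("unknown atoms without a scheme entry raise a parameterization error", {
  at <- make_atoms(2)
  at$element[2] <- "ZZ"
  st <- protein_structure(at)
  expect_error(assign_parameters(st), "parameterization error")
})

test_that("duplicate atom keys and empty structures are rejected", {
  at <- make_atoms(2)
  at$name <- "CA"
  at$resno <- 1L
  expect_error(protein_structure(at), "duplicate")
  expect_error(protein_structure(make_atoms(2)[0, ]), "empty-structure")
})
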
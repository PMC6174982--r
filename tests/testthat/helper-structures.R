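# In-code fixtures: tiny PDB texts and pseudo-structure builders.

toy_ala_pdb <- function() {
  paste(
    c("HEADER    TOY ALANINE",
      "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
      "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 11.00           C",
      "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 12.00           C",
      "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00 13.00           O",
      "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00 14.00           C",
      "END"),
    collapse = "\n")
}

two_model_pdb <- function() {
  paste(
    c("MODEL        1",
      "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
      "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
      "ENDMDL",
      "MODEL        2",
      "ATOM      1  N   GLY A   1       5.000   5.000   5.000  1.00  0.00           N",
      "ATOM      2  CA  GLY A   1       6.458   5.000   5.000  1.00  0.00           C",
      "ENDMDL",
      "END"),
    collapse = "\n")
}

# Pseudo-structure with arbitrary atom table defaults; coordinates spaced
# so nothing overlaps unless asked.
make_atoms <- function(n, element = "C", radius = 1.7, charge = 0,
                       polarity = "nonpolar", spacing = 10) {
  data.frame(
    serial = seq_len(n), name = paste0("X", seq_len(n)), element = element,
    resid = "BLB", resno = seq_len(n), chain = "A",
    x = (seq_len(n) - 1) * spacing, y = 0, z = 0, o = 1, b = 0,
    radius = radius, charge = charge, polarity = polarity,
    stringsAsFactors = FALSE)
}

make_pseudo_structure <- function(atoms, label = "pseudo") {
  st <- protein_structure(atoms, label = label)
  st$parameterized <- TRUE
  st
}

# Minimal peptide structure for charge-assignment tests: backbone N/CA/C/O
# per residue plus the charged-group tip atoms of D/E/K/R, OXT on the last
# residue. Coordinates are spread out; only the charge bookkeeping matters.
make_peptide_structure <- function(seq1, chain = "A") {
  aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR")
  tips <- list(D = c(OD1 = "O", OD2 = "O"), E = c(OE1 = "O", OE2 = "O"),
               K = c(NZ = "N"), R = c(NH1 = "N", NH2 = "N"))
  aa <- strsplit(seq1, "")[[1]]
  rows <- list()
  for (i in seq_along(aa)) {
    names_i <- c(N = "N", CA = "C", C = "C", O = "O")
    if (aa[i] %in% names(tips)) names_i <- c(names_i, tips[[aa[i]]])
    if (i == length(aa)) names_i <- c(names_i, OXT = "O")
    for (k in seq_along(names_i)) {
      rows[[length(rows) + 1L]] <- data.frame(
        serial = 0L, name = names(names_i)[k], element = names_i[[k]],
        resid = aa3[[aa[i]]], resno = i, chain = chain,
        x = i * 5, y = k * 2, z = 0, o = 1, b = 0,
        stringsAsFactors = FALSE)
    }
  }
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  protein_structure(at, label = seq1)
}

random_rotation <- function() {
  # QR-based uniform random rotation
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
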
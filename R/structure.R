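#' Construct a protein structure object
#'
#' The central atomic container: a data frame of heavy atoms with
#' coordinates (Angstrom) plus, after [assign_parameters()], radii, formal
#' charges and polarity classes. Per-chain one-letter sequences are derived
#' from the residue records.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resid` (3-letter residue code), `resno` (1-based residue number),
#'   `chain`, `x`, `y`, `z` and optionally `o` (occupancy), `b` (B-factor),
#'   `radius`, `charge`, `polarity`.
#' @param label character tag used in reports.
#' @return object of class `protein_structure`.
#' @export
protein_structure <- function(atoms, label = "structure") {
  need <- c("serial", "name", "element", "resid", "resno", "chain",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty-structure error: no atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom name): ",
         paste(head(key[duplicated(key)], 3), collapse = "; "))
  for (col in c("o", "b")) if (is.null(atoms[[col]])) atoms[[col]] <- if (col == "o") 1 else 0
  for (col in c("radius", "charge")) if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  if (is.null(atoms$polarity)) atoms$polarity <- NA_character_
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, label = label, chains = derive_chains(atoms),
         parameterized = all(is.finite(atoms$radius))),
    class = "protein_structure"
  )
}

derive_chains <- function(atoms) {
  chains <- list()
  for (ch in unique(atoms$chain)) {
    sub <- atoms[atoms$chain == ch, ]
    resno <- unique(sub$resno)
    resid3 <- sub$resid[match(resno, sub$resno)]
    one <- suppressWarnings(bio3d::aa321(resid3))
    one[is.na(one)] <- "X"
    chains[[as.character(ch)]] <- sequence_record(
      id = as.character(ch), residues = paste(one, collapse = ""),
      validate = FALSE)
  }
  chains
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> %s: %d atoms, %d residues, %d chain(s)%s\n",
              x$label, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              length(x$chains),
              if (isTRUE(x$parameterized))
                sprintf(", net charge %+.1f e", sum(x$atoms$charge)) else ""))
  invisible(x)
}

coords <- function(structure) as.matrix(structure$atoms[, c("x", "y", "z")])

#' Net formal charge of a parameterized structure
#' @param structure a parameterized `protein_structure`
#' @return numeric, units of e
#' @export
net_charge <- function(structure) {
  stopifnot(isTRUE(structure$parameterized))
  sum(structure$atoms$charge)
}

#' Read a PDB-format structure
#'
#' Parses ATOM records (via bio3d) into a [protein_structure()]. HETATM
#' records, waters, hydrogens and alternate locations other than 'A'/' '
#' are discarded; when the file holds several MODELs only the first is
#' used. Occupancy and B-factor are preserved as metadata.
#'
#' @param x path to a PDB file, or PDB-format text (single string with
#'   newlines, or a character vector of lines).
#' @param label structure label; defaults to the file name.
#' @return a `protein_structure` (radii/charges unassigned; see
#'   [assign_parameters()]).
#' @examples
#' s <- read_pdb(example_gly_pdb())
#' nrow(s$atoms)  # 5 heavy atoms
#' @export
read_pdb <- function(x, label = NULL) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    if (is.null(label)) label <- sub("\\.pdb$", "", basename(x), ignore.case = TRUE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
    if (is.null(label)) label <- "structure"
  }

  is_rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(is_rec)) {
    ln <- lines[i]
    ok <- nchar(ln) >= 54 &&
      !anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                           substr(ln, 39, 46),
                                           substr(ln, 47, 54)))))
    if (!ok) stop(sprintf("malformed ATOM record at line %d: '%s'", i, ln))
  }
  if (!any(is_rec)) stop("empty-structure error: no ATOM records")

  # keep only the first MODEL, if any
  endm <- grep("^ENDMDL", lines)
  if (length(endm)) lines <- lines[seq_len(endm[1] - 1)]
  lines <- lines[!grepl("^MODEL", lines)]

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = TRUE, verbose = FALSE)

  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  ele <- at$elesy
  fix <- is.na(ele) | ele == ""
  if (any(fix)) ele[fix] <- guess_element(at$elety[fix])
  at <- at[!(ele %in% c("H", "D")), , drop = FALSE]
  ele <- ele[!(ele %in% c("H", "D"))]
  if (nrow(at) == 0) stop("empty-structure error: no atoms left after filtering")

  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- " "
  atoms <- data.frame(
    serial = at$eleno, name = at$elety, element = toupper(ele),
    resid = at$resid, resno = at$resno, chain = chain,
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b),
    stringsAsFactors = FALSE
  )
  protein_structure(atoms, label = label)
}

# Element symbol from a PDB atom name (used when columns 77-78 are absent).
guess_element <- function(elety) {
  nm <- gsub("[0-9']", "", elety)
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE"),
         two, toupper(substr(nm, 1, 1)))
}

#' Write a structure as PDB text with per-atom scores in the B-factor field
#'
#' Standard ATOM records; the score occupies columns 61-66 (`%6.2f`),
#' clamped to `[-99.99, 999.99]` so the fixed-width field never overflows.
#' This is the hand-off format for molecular-graphics colour-coding of
#' surface potentials or nonpolar:polar ratios.
#'
#' @param structure a `protein_structure`.
#' @param per_atom_score numeric vector, one score per atom (recycled if
#'   length 1); `NULL` uses the stored B-factors; missing values become 0.
#' @param file optional path; when given the text is also written there.
#' @return character vector of PDB lines, invisibly when `file` is given.
#' @export
write_annotated_pdb <- function(structure, per_atom_score = NULL, file = NULL) {
  at <- structure$atoms
  b <- per_atom_score %||% at$b
  if (length(b) == 1) b <- rep(b, nrow(at))
  if (length(b) != nrow(at))
    stop("per_atom_score must have one value per atom")
  b[!is.finite(b)] <- 0
  b <- pmin(pmax(b, -99.99), 999.99)

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  bio3d::write.pdb(
    pdb = NULL, file = tf,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(at)),
    eleno = at$serial, elety = at$name, resid = at$resid,
    chain = ifelse(at$chain == " ", "", at$chain), resno = at$resno,
    o = at$o, b = b, elesy = at$element
  )
  txt <- readLines(tf, warn = FALSE)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' A minimal example PDB: one free glycine (with OXT)
#' @return character scalar of PDB-format text
#' @export
example_gly_pdb <- function() {
  paste(
    c("ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
      "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
      "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C",
      "ATOM      4  O   GLY A   1       1.251   2.390   0.000  1.00  0.00           O",
      "ATOM      5  OXT GLY A   1       3.246   1.590   0.000  1.00  0.00           O",
      "END"),
    collapse = "\n")
}
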
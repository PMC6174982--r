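#' Default atomic parameter scheme (radii, pH-7 charges, polarity)
#'
#' The scheme carries everything needed to turn bare coordinates into a
#' parameterized structure: a Bondi-style element radius table, rule-based
#' formal charges for the titratable groups at pH 7, and a binary polarity
#' classification used by the nonpolar:polar surface measure.
#'
#' Charge rules at pH 7 (formal charges placed on group tip atoms):
#' Asp/Glu side chains carry -1 split -0.5/-0.5 over the carboxylate
#' oxygens; Lys +1 on NZ; Arg +1 split +0.5/+0.5 over NH1/NH2; His neutral;
#' the N-terminus +1 on the backbone N; the C-terminus -1, split over
#' OXT/O when OXT is present, otherwise on O. Polarity: carbon and sulfur
#' atoms are nonpolar, nitrogen and oxygen polar — the common solvent
#' accessible surface convention.
#'
#' @param radii named numeric vector, element symbol to radius in Angstrom.
#' @param nonpolar_elements,polar_elements element symbols per polarity class.
#' @param atom_radii optional named numeric vector of per-atom-name radius
#'   overrides (names like `"CA"`), taking precedence over element radii.
#' @return an object of class `parameter_scheme`.
#' @examples
#' sch <- default_scheme()
#' sch$radii[["C"]]
#' @export
default_scheme <- function(radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                                     H = 1.20, P = 1.80),
                           nonpolar_elements = c("C", "S"),
                           polar_elements = c("N", "O", "P"),
                           atom_radii = NULL) {
  side_chain_charges <- list(
    ASP = c(OD1 = -0.5, OD2 = -0.5),
    GLU = c(OE1 = -0.5, OE2 = -0.5),
    LYS = c(NZ = 1),
    ARG = c(NH1 = 0.5, NH2 = 0.5)
  )
  structure(
    list(
      radii = radii,
      atom_radii = atom_radii,
      nonpolar_elements = nonpolar_elements,
      polar_elements = polar_elements,
      side_chain_charges = side_chain_charges,
      nterm_charge = c(N = 1),
      cterm_charge = -1,
      pH = 7
    ),
    class = "parameter_scheme"
  )
}

#' Assign radii, charges and polarity classes to a structure
#'
#' Applies a [default_scheme()]-style parameter scheme: every atom receives
#' a radius (Angstrom), a formal charge at pH 7 (units of e) and a polarity
#' class (`"nonpolar"` or `"polar"`). Chain termini are charged per chain:
#' +1 on the first residue's backbone N, -1 on the last residue's
#' carboxylate (split over OXT/O when OXT is present).
#'
#' @param structure a `protein_structure` from [read_pdb()] or a generator.
#' @param scheme a `parameter_scheme`; defaults to [default_scheme()].
#' @return the structure with `radius`, `charge` and `polarity` columns
#'   filled in; net charge is `sum(structure$atoms$charge)`.
#' @examples
#' pdb <- example_gly_pdb()
#' s <- assign_parameters(read_pdb(pdb))
#' sum(s$atoms$charge)  # free glycine zwitterion: 0
#' @export
assign_parameters <- function(structure, scheme = default_scheme()) {
  stopifnot(inherits(structure, "protein_structure"))
  at <- structure$atoms

  known <- names(scheme$radii)
  bad <- !(at$element %in% known)
  if (!is.null(scheme$atom_radii)) bad <- bad & !(at$name %in% names(scheme$atom_radii))
  if (any(bad)) {
    stop("parameterization error: no radius for atoms: ",
         paste(unique(paste0(at$resid[bad], at$resno[bad], ":", at$name[bad],
                             " [", at$element[bad], "]")), collapse = ", "))
  }
  at$radius <- unname(scheme$radii[at$element])
  if (!is.null(scheme$atom_radii)) {
    ov <- at$name %in% names(scheme$atom_radii)
    at$radius[ov] <- unname(scheme$atom_radii[at$name[ov]])
  }

  pol_bad <- !(at$element %in% c(scheme$nonpolar_elements, scheme$polar_elements))
  if (any(pol_bad)) {
    stop("parameterization error: no polarity class for elements: ",
         paste(unique(at$element[pol_bad]), collapse = ", "))
  }
  at$polarity <- ifelse(at$element %in% scheme$nonpolar_elements,
                        "nonpolar", "polar")

  at$charge <- 0
  # side-chain formal charges
  for (res in names(scheme$side_chain_charges)) {
    qs <- scheme$side_chain_charges[[res]]
    for (an in names(qs)) {
      hit <- at$resid == res & at$name == an
      at$charge[hit] <- at$charge[hit] + qs[[an]]
    }
  }
  # termini, per chain
  for (ch in unique(at$chain)) {
    idx <- which(at$chain == ch)
    res_first <- min(at$resno[idx])
    res_last <- max(at$resno[idx])
    for (an in names(scheme$nterm_charge)) {
      hit <- idx[at$resno[idx] == res_first & at$name[idx] == an]
      at$charge[hit] <- at$charge[hit] + scheme$nterm_charge[[an]]
    }
    last <- idx[at$resno[idx] == res_last]
    oxt <- last[at$name[last] == "OXT"]
    o <- last[at$name[last] == "O"]
    if (length(oxt) && length(o)) {
      at$charge[c(oxt, o)] <- at$charge[c(oxt, o)] + scheme$cterm_charge / 2
    } else if (length(o)) {
      at$charge[o] <- at$charge[o] + scheme$cterm_charge
    } else if (length(oxt)) {
      at$charge[oxt] <- at$charge[oxt] + scheme$cterm_charge
    }
  }

  structure$atoms <- at
  structure$parameterized <- TRUE
  structure
}

#' Expected net charge of a sequence under the default pH-7 scheme
#'
#' Closed-form residue tally: +1 per Lys/Arg, -1 per Asp/Glu, +1 N-terminus,
#' -1 C-terminus per chain. Used as an independent check on
#' [assign_parameters()].
#'
#' @param sequences character vector of one-letter chain sequences.
#' @return numeric net charge in e.
#' @export
sequence_net_charge <- function(sequences) {
  per_chain <- vapply(sequences, function(s) {
    aa <- strsplit(s, "")[[1]]
    sum(aa %in% c("K", "R")) - sum(aa %in% c("D", "E"))
  }, numeric(1))
  sum(per_chain)  # termini cancel: +1 - 1 per chain
}
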
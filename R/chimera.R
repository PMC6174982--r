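AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Sequence record (1-based residue numbering)
#'
#' @param id identifier
#' @param residues one-letter amino-acid string
#' @param numbering_offset integer added to the 1-based index to obtain the
#'   biological position (default 0, so position i = index i)
#' @param validate check the 20-letter alphabet (generated chain sequences
#'   may carry `X` for nonstandard residues)
#' @return object of class `sequence_record`
#' @export
sequence_record <- function(id, residues, numbering_offset = 0L,
                            validate = TRUE) {
  residues <- toupper(residues)
  if (nchar(residues) < 1) stop("sequence must have length >= 1")
  if (validate) {
    bad <- setdiff(strsplit(residues, "")[[1]], AA1)
    if (length(bad))
      stop("invalid residues in '", id, "': ", paste(unique(bad), collapse = ""))
  }
  structure(list(id = id, residues = residues,
                 numbering_offset = as.integer(numbering_offset)),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s (%d aa)\n", x$id, nchar(x$residues)))
  invisible(x)
}

seq_len_aa <- function(seq) nchar(seq$residues)

#' Inclusive 1-based region of a sequence
#' @param start,end 1-based inclusive bounds, `start <= end`
#' @return object of class `region_spec`
#' @export
region_spec <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1 || end < start) stop("region error: need 1 <= start <= end")
  structure(list(start = start, end = end), class = "region_spec")
}

check_region <- function(seq, region, what = "region") {
  if (region$end > seq_len_aa(seq))
    stop(sprintf("region error: %s [%d,%d] out of range for '%s' (length %d)",
                 what, region$start, region$end, seq$id, seq_len_aa(seq)))
  invisible(TRUE)
}

#' Exchange N- and C-terminal segments of two sequences (domain swap)
#'
#' Splits each parent after its boundary position and rejoins crosswise —
#' the construction used for TIMP-family N/C domain-exchange constructs
#' (e.g. boundary E127 of one parent with N121 of the other). Fusion 1 is
#' `A[1..boundaryA] + B[boundaryB+1..]`, fusion 2 the complement, so total
#' length is conserved.
#'
#' @param seqA,seqB `sequence_record` parents.
#' @param boundaryA,boundaryB 1-based positions; the boundary residue stays
#'   with the N-terminal segment.
#' @return list of two `sequence_record`s named `fusion1`, `fusion2`, ids
#'   `"NT<A>/CT<B>"` and `"NT<B>/CT<A>"`, each with a `junction` attribute
#'   (last position of the N-terminal segment in the fusion).
#' @examples
#' a <- sequence_record("A", "MKLV"); b <- sequence_record("B", "GGHHH")
#' swap_domains(a, b, 2, 3)$fusion1$residues  # "MKHH"
#' @export
swap_domains <- function(seqA, seqB, boundaryA, boundaryB) {
  if (boundaryA < 1 || boundaryA > seq_len_aa(seqA))
    stop("region error: boundaryA out of range")
  if (boundaryB < 1 || boundaryB > seq_len_aa(seqB))
    stop("region error: boundaryB out of range")
  a <- seqA$residues; b <- seqB$residues
  f1 <- sequence_record(paste0("NT", seqA$id, "/CT", seqB$id),
                        paste0(substr(a, 1, boundaryA),
                               substr(b, boundaryB + 1, nchar(b))))
  f2 <- sequence_record(paste0("NT", seqB$id, "/CT", seqA$id),
                        paste0(substr(b, 1, boundaryB),
                               substr(a, boundaryA + 1, nchar(a))))
  attr(f1, "junction") <- as.integer(boundaryA)
  attr(f2, "junction") <- as.integer(boundaryB)
  list(fusion1 = f1, fusion2 = f2)
}

#' Replace a region of an acceptor sequence with a donor region
#'
#' The graft used for the secretion-rescued enTIMP-3 chimera: acceptor
#' positions K26-I41 replaced by the corresponding donor segment E26-I47,
#' lengthening the product by 6 residues. Every product residue carries
#' provenance (parent id and original position).
#'
#' @param acceptor,donor `sequence_record`s.
#' @param acc_region,donor_region `region_spec`s (1-based inclusive).
#' @param allow_empty_donor pure deletion (donor span 0) must be requested
#'   explicitly by passing `donor_region = NULL` with this flag, so a
#'   silent mis-specified region cannot delete sequence.
#' @return `sequence_record` with attributes `provenance` (data.frame:
#'   `source`, `source_pos`) and `length_delta`.
#' @examples
#' acc <- sequence_record("T3", paste(rep("A", 50), collapse = ""))
#' don <- sequence_record("T2", paste(rep("G", 60), collapse = ""))
#' ch <- replace_region(acc, region_spec(26, 41), don, region_spec(26, 47))
#' attr(ch, "length_delta")  # +6
#' @export
replace_region <- function(acceptor, acc_region, donor,
                           donor_region, allow_empty_donor = FALSE) {
  stopifnot(inherits(acc_region, "region_spec"))
  check_region(acceptor, acc_region, "acceptor region")
  if (is.null(donor_region)) {
    if (!allow_empty_donor)
      stop("region error: empty donor region requires allow_empty_donor = TRUE")
    donor_seg <- ""
    donor_pos <- integer(0)
  } else {
    stopifnot(inherits(donor_region, "region_spec"))
    check_region(donor, donor_region, "donor region")
    donor_seg <- substr(donor$residues, donor_region$start, donor_region$end)
    donor_pos <- donor_region$start:donor_region$end
  }
  a <- acceptor$residues
  left <- substr(a, 1, acc_region$start - 1)
  right <- substr(a, acc_region$end + 1, nchar(a))
  out <- sequence_record(paste0("en", acceptor$id),
                         paste0(left, donor_seg, right))
  prov <- data.frame(
    source = c(rep(acceptor$id, nchar(left)),
               rep(donor$id, length(donor_pos)),
               rep(acceptor$id, nchar(right))),
    source_pos = c(seq_len(nchar(left)), donor_pos,
                   seq.int(acc_region$end + 1, length.out = nchar(right))),
    stringsAsFactors = FALSE
  )
  attr(out, "provenance") <- prov
  attr(out, "length_delta") <-
    length(donor_pos) - (acc_region$end - acc_region$start + 1L)
  out
}

#' Needleman-Wunsch global alignment with affine gaps
#'
#' Optimal global alignment (EMBOSS-Needle-style defaults: BLOSUM62, gap
#' open 10, gap extend 0.5). Percent identity is identical columns over the
#' full alignment length (gap columns included); percent similarity counts
#' columns whose substitution score is positive.
#'
#' @param seqA,seqB `sequence_record`s.
#' @param substitution_matrix matrix name (`"BLOSUM62"`) or a scoring matrix.
#' @param gap_open,gap_extend affine gap penalties (a gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @return object of class `alignment_result`: gapped strings `alignedA`,
#'   `alignedB`, `score`, `identity`, `similarity` (percent), and
#'   `column_class` (`"identity"`, `"similar"`, `"mismatch"`, `"gap"`).
#' @examples
#' a <- sequence_record("a", "HEAGAWGHEE")
#' b <- sequence_record("b", "PAWHEAE")
#' global_align(a, b)$identity
#' @export
global_align <- function(seqA, seqB, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  submat <- if (is.character(substitution_matrix)) {
    get(data(list = substitution_matrix, package = "Biostrings",
             envir = environment()))
  } else substitution_matrix
  for (s in list(seqA, seqB)) {
    bad <- setdiff(strsplit(s$residues, "")[[1]], rownames(submat))
    if (length(bad))
      stop("alphabet error: residues absent from substitution matrix: ",
           paste(unique(bad), collapse = ""))
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA$residues), Biostrings::AAString(seqB$residues),
    type = "global", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  ga <- as.character(Biostrings::alignedPattern(al))
  gb <- as.character(Biostrings::alignedSubject(al))
  alignment_result(seqA, seqB, ga, gb, Biostrings::score(al), submat)
}

alignment_result <- function(seqA, seqB, ga, gb, score, submat) {
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  stopifnot(length(ca) == length(cb))
  gap <- ca == "-" | cb == "-"
  ident <- !gap & ca == cb
  colscore <- rep(NA_real_, length(ca))
  colscore[!gap] <- submat[cbind(ca[!gap], cb[!gap])]
  simil <- !gap & colscore > 0
  cls <- ifelse(gap, "gap",
                ifelse(ident, "identity",
                       ifelse(simil, "similar", "mismatch")))
  structure(
    list(idA = seqA$id, idB = seqB$id, alignedA = ga, alignedB = gb,
         score = score, length = length(ca),
         identity = 100 * sum(ident) / length(ca),
         similarity = 100 * sum(simil | ident) / length(ca),
         column_class = cls),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %s vs %s: length %d, score %.1f, %.1f%% identity, %.1f%% similarity\n",
              x$idA, x$idB, x$length, x$score, x$identity, x$similarity))
  invisible(x)
}

#' Chemical class annotation of a sequence
#'
#' Maps every residue to one of four classes used for alignment
#' colour-coding: small/hydrophobic (AVFPMILWG), acidic (DE), basic (RKH),
#' hydroxyl/sulfhydryl/amine (STYCNQ). The four classes partition the
#' 20-letter alphabet.
#'
#' @param seq a `sequence_record`.
#' @return character vector, one class per residue.
#' @export
annotate_chemistry <- function(seq) {
  classes <- chemistry_classes()
  lut <- unlist(lapply(names(classes), function(cl)
    setNames(rep(cl, length(classes[[cl]])), classes[[cl]])))
  aa <- strsplit(seq$residues, "")[[1]]
  unname(lut[aa])
}

#' The four-way residue chemistry partition
#' @return named list of residue vectors
#' @export
chemistry_classes <- function() {
  list(
    small_hydrophobic = strsplit("AVFPMILWG", "")[[1]],
    acidic = c("D", "E"),
    basic = c("R", "K", "H"),
    hydroxyl_amine = strsplit("STYCNQ", "")[[1]]
  )
}

#' Read/write FASTA sequence records
#' @param path FASTA file path
#' @return list of `sequence_record`s
#' @export
read_fasta_records <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  lapply(seq_along(ss), function(i)
    sequence_record(sub("\\s.*", "", names(ss)[i]), as.character(ss[[i]])))
}

#' @rdname read_fasta_records
#' @param records list of `sequence_record`s (or a single one)
#' @export
write_fasta_records <- function(records, path) {
  if (inherits(records, "sequence_record")) records <- list(records)
  ss <- Biostrings::AAStringSet(vapply(records, `[[`, "", "residues"))
  names(ss) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
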
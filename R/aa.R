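#' Canonical amino-acid alphabet
#'
#' Fixed alphabet order used for all PSSM/logit matrices in the package:
#' `"ACDEFGHIKLMNPQRSTVWY"`.
#'
#' @return Character vector of the 20 canonical one-letter codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# 3-letter -> 1-letter, canonical residues only
.aa321 <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y"
)

# common modified residues mapped to their parent (permissive mode)
.aa321_permissive <- c(
  .aa321,
  MSE = "M", SEC = "C", CSO = "C", SEP = "S", TPO = "T",
  PTR = "Y", MLY = "K", HYP = "P", PCA = "Q", CME = "C",
  KCX = "K", LLP = "K", M3L = "K", FME = "M"
)

.aa123 <- stats::setNames(names(.aa321), unname(.aa321))

#' Polar and apolar residue sets
#'
#' The apolar set is exactly `GPAVILMFYW`; the polar set used for
#' inverse-folding sampling bias is `D,E,H,K,N,Q,R,S,T,Y`.
#'
#' @name residue_sets
#' @return Character vector of one-letter codes.
#' @export
aa_apolar <- function() strsplit("GPAVILMFYW", "")[[1]]

#' @rdname residue_sets
#' @export
aa_polar <- function() c("D", "E", "H", "K", "N", "Q", "R", "S", "T", "Y")

#' Validate a protein sequence
#'
#' Checks that a sequence uses only the 20 canonical one-letter codes
#' (after upper-casing) and has length at least one.
#'
#' @param seq Character scalar.
#' @param what Label used in error messages.
#' @return The normalized (upper-case) sequence, invisibly usable.
#' @export
validate_sequence <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string")
  seq <- toupper(seq)
  if (nchar(seq) < 1L) stop(what, " has length 0")
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% aa_alphabet())
  if (length(bad))
    stop(what, ": illegal character '", chars[bad[1]], "' at position ", bad[1])
  seq
}

seq_to_int <- function(seq) {
  match(strsplit(seq, "")[[1]], aa_alphabet())
}

int_to_seq <- function(idx) {
  paste(aa_alphabet()[idx], collapse = "")
}
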
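## Amino-acid code tables shared across modules.

#' The 20 standard amino acids, one-letter codes in alphabetical order
#'
#' This fixed ordering indexes the rows of every potential table and the
#' rows of serialized potential files.
#'
#' @format Character vector of length 20.
#' @export
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# three-letter -> one-letter, standard residues
.AA_THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y"
)

# modified residues mapped onto a standard parent; anything else
# non-standard is skipped with a warning
.AA_NONSTANDARD <- c(MSE = "MET", SEC = "CYS")

.aa_one <- function(res_name) {
  res_name <- toupper(res_name)
  mapped <- .AA_NONSTANDARD[res_name]
  res_name[!is.na(mapped)] <- mapped[!is.na(mapped)]
  unname(.AA_THREE_TO_ONE[res_name])
}

.aa_index <- function(aa) {
  idx <- match(aa, AA_CODES)
  if (anyNA(idx)) {
    stop("unknown amino-acid code(s): ",
         paste(unique(aa[is.na(idx)]), collapse = ", "))
  }
  idx
}
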
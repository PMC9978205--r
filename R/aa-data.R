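# Amino-acid reference data shared across modules.

.AA321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

.AA123 <- structure(names(.AA321), names = unname(.AA321))

# Average residue masses (Da); free peptide weight adds one water.
.RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.WATER_MASS <- 18.0153

# Side-chain heavy atoms per standard residue (PDB v3 names), in bond order
# out from CB; backbone N/CA/C/O are implicit for all residues.
.SIDE_CHAIN_ATOMS <- list(
  ALA = c("CB"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

.WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Canonical heavy-atom dictionary of the 20 standard residues
#'
#' One row per (residue, atom) pair: the four backbone atoms plus the
#' side-chain heavy atoms of each standard amino acid. Used to validate
#' pharmacophore typing tables and to build synthetic residues.
#'
#' @return A data.frame with columns `residue` (3-letter code) and `atom`
#'   (PDB v3 atom name).
#' @export
canonical_heavy_atoms <- function() {
  res <- names(.SIDE_CHAIN_ATOMS)
  rows <- lapply(res, function(r) {
    data.frame(residue = r, atom = c("N", "CA", "C", "O", .SIDE_CHAIN_ATOMS[[r]]))
  })
  do.call(rbind, rows)
}
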
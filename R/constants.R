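# Alphabets and residue property tables used across the package.

# 20 standard amino acids, alphabetical one-letter order.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHARS <- c("-", ".")

RNA4 <- c("A", "C", "G", "U")

#' Chemical classes used by the conserved-position caller
#'
#' Named list of overlapping residue classes, in the priority order used to
#' break ties when more than one class passes the majority threshold.
#'
#' @format Named list of character vectors of one-letter residue codes.
#' @export
chemicalClasses <- list(
  hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "C"),
  aromatic    = c("F", "W", "Y", "H"),
  positive    = c("K", "R", "H"),
  negative    = c("D", "E"),
  polar       = c("S", "T", "N", "Q", "Y", "C", "G")
)

# Backbone atom names; everything else on a residue counts as side chain.
# Glycine has no side chain and is represented by CA instead.
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# Side-chain hydrogen-bond donor / acceptor heavy atoms. Backbone excluded:
# the interface analysis concerns side-chain pairing.
SIDECHAIN_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", TRP = "NE1",
  ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"),
  SER = "OG", THR = "OG1", TYR = "OH"
)
SIDECHAIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2"),
  SER = "OG", THR = "OG1", TYR = "OH"
)

# Formal side-chain charges at neutral pH; histidine deliberately excluded
# from salt-bridge calling (protonation state unknown).
POSITIVE_RESIDUES <- c("LYS", "ARG")
NEGATIVE_RESIDUES <- c("ASP", "GLU")

AROMATIC_RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

# Watson-Crick + G:U wobble pairing for RNA stems.
.rnaPairs <- matrix(FALSE, 4, 4, dimnames = list(RNA4, RNA4))
.rnaPairs["A", "U"] <- .rnaPairs["U", "A"] <- TRUE
.rnaPairs["G", "C"] <- .rnaPairs["C", "G"] <- TRUE
.rnaPairs["G", "U"] <- .rnaPairs["U", "G"] <- TRUE
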
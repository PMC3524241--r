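# Internal amino-acid lookup tables shared across modules.

# Three-letter -> one-letter map for the 20 standard residues.
.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

.AA1 <- unname(.AA3TO1)
.AA3 <- names(.AA3TO1)

.AA1TO3 <- structure(names(.AA3TO1), names = unname(.AA3TO1))

# Backbone atom names excluded from side-chain interaction counting
# (OXT is the terminal carboxylate oxygen, i.e. backbone).
.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

.GAP_CHARS <- c("-", ".")

.is_gap <- function(x) x %in% .GAP_CHARS
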
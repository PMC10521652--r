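# Residue-level constant tables: 1/3-letter codes, mean residue volumes,
# theoretical maximum side-chain accessibilities, van der Waals radii.

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

AA3 <- stats::setNames(names(AA1), AA1)

#' Mean amino-acid residue volumes
#'
#' Mean residue volumes in cubic Angstrom (Zamyatnin's tabulation), used as
#' the numeric proxy for steric size in strip/face enrichment statistics.
#'
#' @return Named numeric vector over the 20 one-letter codes.
#' @export
residue_volumes <- function() {
  c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5, Q = 143.8,
    E = 138.4, G = 60.1, H = 153.2, I = 166.7, L = 166.7, K = 168.6,
    M = 162.9, F = 189.9, P = 112.7, S = 89.0, T = 116.1, W = 227.8,
    Y = 193.6, V = 140.0)
}

# Element -> van der Waals radius (Angstrom), heavy atoms only.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

atom_element <- function(atom_name) {
  # first alphabetic character of a PDB atom name gives the element for
  # standard protein heavy atoms (CA, CB, CG1, OD1, NE2, SD, ...)
  substr(gsub("[^A-Za-z].*", "", gsub("^[0-9]*", "", atom_name)), 1, 1)
}

HYDROPHOBIC_AA <- c("A", "V", "I", "L", "M", "F", "W", "Y", "C")
ILV_AA <- c("I", "L", "V")
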
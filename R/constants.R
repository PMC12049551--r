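## Fixed physico-chemical tables.  All constants are hard-coded so that
## results do not depend on any external library version.

#' Van der Waals radius for an element
#'
#' Fixed internal element table (Bondi-style radii, Angstrom).  Unknown
#' elements raise an error so that silent mis-parsing of atom names cannot
#' corrupt surface-area or accessible-volume calculations.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
           P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
           I = 1.98, FE = 1.80, ZN = 1.39, MG = 1.73, CA = 2.31,
           MN = 1.80, CU = 1.40, "NA" = 2.27, K = 2.75, NI = 1.63)
  r <- tab[toupper(element)]
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    stop("no van der Waals radius for element(s): ", paste(bad, collapse = ", "))
  }
  unname(r)
}

## the 20 standard three-letter codes
STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

## common chemically modified residues mapped to their parent amino acid
NONSTANDARD_AA_MAP <- c(MSE = "MET", SEC = "CYS", CSO = "CYS", CME = "CYS",
                        CSD = "CYS", OCS = "CYS", SEP = "SER", TPO = "THR",
                        PTR = "TYR", MLY = "LYS", KCX = "LYS", LLP = "LYS",
                        HYP = "PRO", PCA = "GLU", FME = "MET", CSS = "CYS",
                        MLE = "LEU", AIB = "ALA", DAL = "ALA", SAR = "GLY")

## Theoretical maximum accessible surface areas (A^2) per residue in a
## Gly-X-Gly tripeptide (Tien et al. 2013, "Wilke" theoretical values).
WILKE_MAX_ASA <- c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0,
                   CYS = 167.0, GLN = 225.0, GLU = 223.0, GLY = 104.0,
                   HIS = 224.0, ILE = 197.0, LEU = 201.0, LYS = 236.0,
                   MET = 224.0, PHE = 240.0, PRO = 159.0, SER = 155.0,
                   THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

## Average residue masses (Da, residue in chain, i.e. minus water).
AA_MASS <- c(ALA = 71.08, ARG = 156.19, ASN = 114.10, ASP = 115.09,
             CYS = 103.14, GLN = 128.13, GLU = 129.12, GLY = 57.05,
             HIS = 137.14, ILE = 113.16, LEU = 113.16, LYS = 128.17,
             MET = 131.19, PHE = 147.18, PRO = 97.12, SER = 87.08,
             THR = 101.10, TRP = 186.21, TYR = 163.18, VAL = 99.13)

## Residue volumes (A^3, Zamyatnin 1972).
AA_VOLUME <- c(ALA = 88.6, ARG = 173.4, ASN = 114.1, ASP = 111.1,
               CYS = 108.5, GLN = 143.8, GLU = 138.4, GLY = 60.1,
               HIS = 153.2, ILE = 166.7, LEU = 166.7, LYS = 168.6,
               MET = 162.9, PHE = 189.9, PRO = 112.7, SER = 89.0,
               THR = 116.1, TRP = 227.8, TYR = 193.6, VAL = 140.0)

## Side-chain charge class at physiological pH.
AA_CHARGE <- c(ALA = "neutral", ARG = "positive", ASN = "neutral",
               ASP = "negative", CYS = "neutral", GLN = "neutral",
               GLU = "negative", GLY = "neutral", HIS = "positive",
               ILE = "neutral", LEU = "neutral", LYS = "positive",
               MET = "neutral", PHE = "neutral", PRO = "neutral",
               SER = "neutral", THR = "neutral", TRP = "neutral",
               TYR = "neutral", VAL = "neutral")

## one-letter <-> three-letter conversion
AA_THREE_TO_ONE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                     GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                     LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                     SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Guess the element symbol from a PDB atom name
#'
#' Used when the element column of a file is blank.  Handles two-letter
#' elements found in proteins (SE of selenomethionine) and the PDB
#' convention that hydrogen names may start with a digit.
#'
#' @param name atom-name string(s), e.g. "CA", "OXT", "SE".
#' @return character vector of element symbols.
#' @export
guess_element <- function(name) {
  nm <- toupper(trimws(name))
  nm <- sub("^[0-9']+", "", nm)
  el <- substr(nm, 1, 1)
  el[nm %in% c("SE", "SEG")] <- "SE"
  el[substr(nm, 1, 2) == "FE"] <- "FE"
  el[substr(nm, 1, 2) == "ZN"] <- "ZN"
  el[substr(nm, 1, 2) == "MG"] <- "MG"
  el
}
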
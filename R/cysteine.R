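## Cysteine resemblance: how similar the native amino acid is to the
## cysteine it would be mutated to (identity, mass, charge, volume) -- a
## proxy for mutational tolerance of the exchange.

#' Cysteine-resemblance descriptors for an amino acid
#'
#' @param aa three-letter amino-acid code(s) (standard residues).
#' @return data.frame with `aa` (identity), `mass_delta` (Da vs Cys),
#'   `charge` (positive/negative/neutral), `volume_delta` (A^3 vs Cys);
#'   non-standard codes give NA rows.
#' @export
compute_cysteine_resemblance <- function(aa) {
  aa <- toupper(aa)
  ok <- aa %in% STANDARD_AA
  data.frame(aa = ifelse(ok, aa, NA_character_),
             mass_delta = ifelse(ok, AA_MASS[aa] - AA_MASS[["CYS"]], NA_real_),
             charge = ifelse(ok, AA_CHARGE[aa], NA_character_),
             volume_delta = ifelse(ok, AA_VOLUME[aa] - AA_VOLUME[["CYS"]],
                                   NA_real_),
             stringsAsFactors = FALSE)
}
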
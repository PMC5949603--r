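# Residue chemistry tables for the BBP notation.
#
# Residue formulas are chain residues (amino acid minus one water). Special
# codes: z = branching gamma-thia-homoglutamate, which contributes a cysteine
# residue formula (the two thioether-bridge carbons and the carbonyl oxygen
# of the chloroacetyl unit live on the closure bond, not on the residue);
# B = benzoylphenylalanine; "K(biot)" = N-epsilon-biotinyl-lysine.

RESIDUE_FORMULA <- c(
  G = "C2H3NO",  A = "C3H5NO",   S = "C3H5NO2",  C = "C3H5NOS",
  P = "C5H7NO",  V = "C5H9NO",   T = "C4H7NO2",  L = "C6H11NO",
  I = "C6H11NO", N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3", M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",  R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O",
  Z = "C3H5NOS",          # gamma-thia-homoglutamate, built from cysteine
  B = "C16H13NO2",        # benzoylphenylalanine
  "K(biot)" = "C16H26N4O3S"
)

# Codes that are achiral or always written in a fixed case.
ACHIRAL_CODES <- "G"
SPECIAL_CODES <- c("B", "K(biot)")

residue_formula <- function(base) {
  f <- RESIDUE_FORMULA[base]
  if (any(is.na(f))) stop("unknown residue code: ",
                          paste(base[is.na(f)], collapse = ", "))
  unname(f)
}
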
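# Exact-mass chemistry for cyclized peptide graphs.

#' Supported ESI positive-mode adducts
#'
#' Each adduct is defined by the electron-corrected cation masses added to
#' the neutral molecule and the resulting charge: m/z = (M + sum(cations))/z.
#'
#' @format data.frame with columns name, delta (Da, total cation mass), z.
#' @export
ADDUCTS <- data.frame(
  name = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+2H]2+", "[M+Na+H]2+",
           "[M+K+H]2+"),
  delta = c(CATION_MASS["H+"], CATION_MASS["Na+"], CATION_MASS["K+"],
            2 * CATION_MASS["H+"], CATION_MASS["Na+"] + CATION_MASS["H+"],
            CATION_MASS["K+"] + CATION_MASS["H+"]),
  z = c(1L, 1L, 1L, 2L, 2L, 2L),
  stringsAsFactors = FALSE
)

#' Elemental formula of a peptide graph
#'
#' Sums chain-residue formulas plus one water for the linear peptide, then
#' applies per-modification deltas: C-terminal amide (-O +N +H), one water
#' loss per lactam closure, a net +C2O for a chloroacetyl-cysteine thioether
#' closure (chloroacetylation followed by HCl loss; the two bridge carbons
#' and carbonyl oxygen belong to the bond), and +CH2 per N-methyl group.
#'
#' @param g A \code{bbp_graph} from \code{\link{parse_bbp}}.
#' @return A \code{bbp_formula}.
#' @examples
#' ef_string(formula_of(parse_bbp("l1 G k2 f P E1 a2")))  # "C36H52N8O8"
#' @export
formula_of <- function(g) {
  f <- ef(H = 2, O = 1)  # the linear peptide's terminal water
  for (b in g$residues$base) f <- f + parse_ef(residue_formula(b))
  if (g$c_terminus == "amide")
    f <- f + ef(N = 1, H = 1) - ef(O = 1)
  cls <- g$bonds$bond_class
  n_lactam <- sum(cls == "sidechain_lactam")
  n_thio <- sum(cls == "thioether")
  if (n_lactam > 0)
    f <- f - ef(H = 2 * n_lactam, O = n_lactam)
  if (n_thio > 0)
    f <- f + ef(C = 2 * n_thio, O = n_thio)
  n_me <- sum(g$residues$n_methyl)
  if (n_me > 0)
    f <- f + ef(C = n_me, H = 2 * n_me)
  f
}

#' Adduct m/z from a neutral monoisotopic mass
#'
#' @param M Neutral monoisotopic mass in Da.
#' @param adduct Adduct name, one of \code{ADDUCTS$name}.
#' @return List with \code{mz} (full precision) and \code{mz2} (rounded
#'   half-up to 2 decimals, journal style).
#' @export
adduct_mz <- function(M, adduct) {
  if (M <= 0) stop("neutral mass must be positive")
  i <- match(adduct, ADDUCTS$name)
  if (is.na(i)) stop("unsupported adduct: ", adduct)
  mz <- (M + ADDUCTS$delta[i]) / ADDUCTS$z[i]
  list(mz = mz, mz2 = round_half_up(mz, 2))
}

#' Formula, mass and adduct m/z report for a peptide graph
#'
#' @param g A \code{bbp_graph}, or a notation string passed to
#'   \code{\link{parse_bbp}}.
#' @param adducts Character vector of adduct names (may be empty).
#' @param ... Passed to \code{parse_bbp} when \code{g} is a string.
#' @return data.frame with columns adduct, z, mz, mz_2dp plus attributes
#'   \code{formula} and \code{neutral_mass}.
#' @examples
#' mz_report("l1 G k2 y P E1 a2", c("[M+H]+", "[M+Na]+"))
#' @export
mz_report <- function(g, adducts = c("[M+H]+", "[M+Na]+"), ...) {
  if (is.character(g)) g <- parse_bbp(g, ...)
  f <- formula_of(g)
  M <- monoisotopic_mass(f)
  rows <- lapply(adducts, function(a) {
    r <- adduct_mz(M, a)
    data.frame(adduct = a, z = ADDUCTS$z[match(a, ADDUCTS$name)],
               mz = r$mz, mz_2dp = r$mz2, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(adduct = character(0), z = integer(0), mz = numeric(0),
               mz_2dp = numeric(0))
  attr(out, "formula") <- ef_string(f)
  attr(out, "neutral_mass") <- M
  out
}
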
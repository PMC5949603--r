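# Elemental formula bookkeeping and monoisotopic masses.

#' Monoisotopic atomic masses (Da)
#'
#' IUPAC monoisotopic masses of the elements handled by the mass engine,
#' plus electron-corrected cation masses used for ESI adducts.
#'
#' @format Named numeric vector, element symbol -> mass in Da.
#' @export
MONOISOTOPIC_MASS <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163,
  Na = 22.9897692809,
  K = 38.96370668
)

# Cation masses with the electron mass subtracted; these are what an ESI
# positive-mode instrument actually weighs.
CATION_MASS <- c(
  "H+" = 1.007276467,
  "Na+" = 22.989218,
  "K+" = 38.963158
)

#' Construct an elemental formula
#'
#' An elemental formula is a named integer vector (element -> count) with
#' class \code{"bbp_formula"}. Counts must be non-negative; zero-count
#' elements are dropped.
#'
#' @param ... Element counts, e.g. \code{ef(C = 36, H = 52, N = 8, O = 8)}.
#' @return A \code{bbp_formula} object.
#' @export
ef <- function(...) {
  x <- c(...)
  if (length(x) == 0) x <- stats::setNames(numeric(0), character(0))
  if (is.null(names(x)) || any(names(x) == ""))
    stop("all elements must be named")
  if (any(x < 0)) stop("negative element count")
  if (any(x != round(x))) stop("element counts must be integers")
  x <- x[x > 0]
  structure(x, class = "bbp_formula")
}

#' Parse a formula string such as "C36H52N8O8"
#'
#' @param s Formula string (element symbols followed by optional counts).
#' @return A \code{bbp_formula}.
#' @export
parse_ef <- function(s) {
  s <- gsub("\\s", "", s)
  if (!nzchar(s)) return(ef())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (sum(nchar(toks)) != nchar(s)) stop("cannot parse formula: ", s)
  el <- sub("[0-9]*$", "", toks)
  ct <- as.numeric(sub("^[A-Za-z]+", "", toks))
  ct[is.na(ct)] <- 1
  out <- tapply(ct, el, sum)
  do.call(ef, as.list(out))
}

#' @export
"+.bbp_formula" <- function(e1, e2) {
  el <- union(names(e1), names(e2))
  x <- stats::setNames(numeric(length(el)), el)
  x[names(e1)] <- x[names(e1)] + unclass(e1)
  x[names(e2)] <- x[names(e2)] + unclass(e2)
  do.call(ef, as.list(x))
}

#' @export
"-.bbp_formula" <- function(e1, e2) {
  el <- union(names(e1), names(e2))
  x <- stats::setNames(numeric(length(el)), el)
  x[names(e1)] <- x[names(e1)] + unclass(e1)
  x[names(e2)] <- x[names(e2)] - unclass(e2)
  if (any(x < 0))
    stop("formula subtraction underflow for element(s): ",
         paste(el[x < 0], collapse = ", "))
  do.call(ef, as.list(x))
}

#' Format a formula in Hill order (C, H, then alphabetical)
#'
#' @param f A \code{bbp_formula}.
#' @return Character scalar, e.g. \code{"C36H52N8O8"}.
#' @export
ef_string <- function(f) {
  x <- unclass(f)
  if (length(x) == 0) return("")
  el <- names(x)
  rest <- sort(setdiff(el, c("C", "H")))
  ord <- c(intersect(c("C", "H"), el), rest)
  paste0(ord, ifelse(x[ord] == 1, "", x[ord]), collapse = "")
}

#' @export
print.bbp_formula <- function(x, ...) {
  cat("<formula>", ef_string(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of an elemental formula
#'
#' @param f A \code{bbp_formula} (or string parseable by \code{parse_ef}).
#' @return Mass in Da (double precision).
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_ef(f)
  x <- unclass(f)
  if (length(x) == 0) return(0)
  unknown <- setdiff(names(x), names(MONOISOTOPIC_MASS))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  sum(x * MONOISOTOPIC_MASS[names(x)])
}

# Round half away from zero, as journals print calc. m/z values.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
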
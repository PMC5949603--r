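# Parser for the plain-text BBP sequence dialect.
#
# One token per residue, N- to C-terminus, whitespace separated. Upper case =
# L-residue, lower case = D-residue (glycine "G" is achiral). A trailing digit
# (1 or 2) marks the two residues joined by that cyclization. "Me-" prefixes
# an N-methylated residue. "B" is benzoylphenylalanine, "K(biot)" is
# N-epsilon-biotinyl-lysine, "z" the branching gamma-thia-homoglutamate formed
# by chloroacetyl-cysteine thioether ligation.
#
# Closure chemistry is inferred from the residue identities of a label pair:
#   Glu/glu paired with the chain head  -> side-chain-to-alpha-amine lactam
#   Lys/lys paired with the chain tail  -> epsilon-amine-to-C-terminal lactam
#   Glu/glu paired with Lys/lys         -> side-chain-to-side-chain lactam
#   z paired with the chain head        -> chloroacetyl-cysteine thioether

TOKEN_RE <- "^(Me-)?(K\\(biot\\)|[A-Za-z])([12])?$"

#' Parse a BBP sequence string into a peptide graph
#'
#' @param text Sequence in the plain-text notation, e.g.
#'   \code{"l1 G k2 f P E1 a2"}.
#' @param c_term C-terminus chemistry, \code{"acid"} or \code{"amide"}.
#' @param thioether Logical; assert that the sequence closes one ring by
#'   chloroacetyl-cysteine thioether ligation (requires a \code{z} residue
#'   labelled together with the chain head). The chemistry is inferred from
#'   the residues either way; the flag is validated against it.
#' @return A \code{bbp_graph}: list with \code{residues} (data.frame:
#'   position, code, base, chirality, n_methyl, label), \code{bonds}
#'   (data.frame: from, to, bond_class, chem), \code{c_terminus},
#'   \code{n_terminus}.
#' @examples
#' g <- parse_bbp("l1 G k2 f P E1 a2")
#' cyclomatic_number(g)  # 2
#' @export
parse_bbp <- function(text, c_term = c("acid", "amide"), thioether = FALSE) {
  c_term <- match.arg(c_term)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  if (length(toks) == 0) stop("empty sequence")
  m <- regmatches(toks, regexec(TOKEN_RE, toks))
  bad <- vapply(m, length, 1L) == 0
  if (any(bad)) stop("unparseable token(s): ", paste(toks[bad], collapse = ", "))
  code <- vapply(m, `[`, "", 3)
  n_methyl <- vapply(m, `[`, "", 2) != ""
  label <- suppressWarnings(as.integer(vapply(m, `[`, "", 4)))

  base <- ifelse(code == "K(biot)", "K(biot)", toupper(code))
  if (any(is.na(residue_formula(base)))) stop("unknown residue code")
  chirality <- ifelse(base %in% ACHIRAL_CODES, "achiral",
               ifelse(code %in% SPECIAL_CODES, "L",
               ifelse(code == toupper(code), "L", "D")))
  n <- length(code)
  residues <- data.frame(position = seq_len(n), code = code, base = base,
                         chirality = chirality, n_methyl = n_methyl,
                         label = label, stringsAsFactors = FALSE)

  bonds <- data.frame(from = integer(0), to = integer(0),
                      bond_class = character(0), chem = character(0),
                      stringsAsFactors = FALSE)
  if (n > 1)
    bonds <- data.frame(from = 1:(n - 1), to = 2:n,
                        bond_class = "backbone_amide", chem = "backbone",
                        stringsAsFactors = FALSE)

  n_terminus <- "free"
  seen_thioether <- FALSE
  for (lab in sort(unique(label[!is.na(label)]))) {
    pos <- which(label == lab)
    if (length(pos) != 2)
      stop("cyclization label ", lab, " must appear on exactly two residues")
    b <- resolve_closure(residues, pos, n)
    if (b$bond_class == "thioether") {
      seen_thioether <- TRUE
      n_terminus <- "chloroacetylated"
    } else if (b$chem == "lactam_head") {
      n_terminus <- "lactam"
    }
    bonds <- rbind(bonds, data.frame(from = b$from, to = b$to,
                                     bond_class = b$bond_class, chem = b$chem,
                                     stringsAsFactors = FALSE))
  }
  if (thioether && !seen_thioether)
    stop("thioether flag set but no chloroacetyl-cysteine closure found")

  deg <- tabulate(c(bonds$from, bonds$to), nbins = n)
  if (any(deg > 3))
    stop("residue degree > 3 at position(s): ",
         paste(which(deg > 3), collapse = ", "))

  structure(list(residues = residues, bonds = bonds,
                 c_terminus = c_term, n_terminus = n_terminus),
            class = "bbp_graph")
}

# Decide the chemistry of the closure bond joining the two positions of a
# label pair. Returns from/to in peptide-bond C -> N direction where that is
# meaningful (acyl donor first).
resolve_closure <- function(residues, pos, n) {
  b <- residues$base[pos]
  is_head <- pos == 1L
  is_tail <- pos == n
  if (any(b == "Z")) {
    other <- pos[b != "Z"]
    zpos <- pos[b == "Z"]
    if (length(other) != 1 || other != 1L)
      stop("thioether closure requires z paired with the chain head")
    return(list(from = 1L, to = zpos, bond_class = "thioether",
                chem = "thioether"))
  }
  if (any(b == "E" & !is_head) && any(is_head))
    return(list(from = pos[b == "E" & !is_head][1], to = 1L,
                bond_class = "sidechain_lactam", chem = "lactam_head"))
  if (any(b == "K" & !is_tail) && any(is_tail))
    return(list(from = n, to = pos[b == "K" & !is_tail][1],
                bond_class = "sidechain_lactam", chem = "lactam_tail"))
  if (any(b == "E") && any(b == "K"))
    return(list(from = pos[b == "E"][1], to = pos[b == "K"][1],
                bond_class = "sidechain_lactam", chem = "lactam_side"))
  if (sum(b == "K") == 2 || sum(b == "E") == 2)
    stop("ambiguous closure: two ", b[1],
         " residues share a label; chemistry cannot be inferred")
  stop("chemically incompatible closure between ",
       paste(b, collapse = " and "))
}

#' Serialize a peptide graph back to notation
#'
#' Left inverse of \code{parse_bbp} up to whitespace normalization.
#'
#' @param g A \code{bbp_graph}.
#' @return Character scalar.
#' @export
serialize_bbp <- function(g) {
  r <- g$residues
  paste0(ifelse(r$n_methyl, "Me-", ""), r$code,
         ifelse(is.na(r$label), "", r$label), collapse = " ")
}

#' Cyclomatic number of a peptide graph
#'
#' Edges minus nodes plus one for a connected graph: 0 = linear,
#' 1 = monocyclic, 2 = bicyclic.
#'
#' @param g A \code{bbp_graph}.
#' @return Integer.
#' @export
cyclomatic_number <- function(g) {
  nrow(g$bonds) - nrow(g$residues) + 1L
}

#' @export
print.bbp_graph <- function(x, ...) {
  cat("<bbp_graph> ", nrow(x$residues), " residues, ", nrow(x$bonds),
      " bonds (cyclomatic ", cyclomatic_number(x), "), C-terminus ",
      x$c_terminus, "\n", sep = "")
  cat("  ", serialize_bbp(x), "\n", sep = "")
  invisible(x)
}

#' Classify the ring topology of a bicyclic peptide graph
#'
#' Prunes pendant (acyclic tail) residues, locates the two degree-3
#' bridgehead residues and measures the three bridge paths joining them.
#' Bridge sizes count non-bridgehead residues per path and are reported as
#' a >= b >= c; the scaffold is "bridged" when c >= 1 and "fused" (two rings
#' sharing an edge) when c = 0.
#'
#' @param g A \code{bbp_graph} with cyclomatic number 2.
#' @return A \code{bbp_topology}: list(a, b, c, n_ring, class, descriptor,
#'   n_pendant, bridgeheads).
#' @examples
#' classify_topology(parse_bbp("l1 G k2 f P E1 a2"))  # bicyclo[2.2.1]
#' @export
classify_topology <- function(g) {
  cyc <- cyclomatic_number(g)
  if (cyc != 2)
    stop("graph is not bicyclic (cyclomatic number ", cyc, ")")
  n <- nrow(g$residues)
  adj <- vector("list", n)
  for (i in seq_len(nrow(g$bonds))) {
    a <- g$bonds$from[i]; b <- g$bonds$to[i]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  alive <- rep(TRUE, n)
  repeat {
    deg <- vapply(seq_len(n), function(i)
      if (alive[i]) sum(alive[adj[[i]]]) else 0L, 0L)
    leaves <- which(alive & deg <= 1)
    if (length(leaves) == 0) break
    alive[leaves] <- FALSE
  }
  ring <- which(alive)
  deg <- vapply(ring, function(i) sum(alive[adj[[i]]]), 0L)
  bh <- ring[deg == 3]
  if (length(bh) != 2 || any(deg > 3))
    stop("unsupported ring system for a bicyclo descriptor: expected ",
         "exactly two degree-3 bridgeheads, found ", length(bh))
  u <- bh[1]; v <- bh[2]
  sizes <- integer(0)
  for (nb in adj[[u]][alive[adj[[u]]]]) {
    path <- 0L
    prev <- u; cur <- nb
    while (cur != v) {
      path <- path + 1L
      nxt <- setdiff(adj[[cur]][alive[adj[[cur]]]], prev)
      prev <- cur; cur <- nxt
    }
    sizes <- c(sizes, path)
  }
  sizes <- sort(sizes, decreasing = TRUE)
  topology(sizes[1], sizes[2], sizes[3],
           n_pendant = n - length(ring), bridgeheads = bh)
}

#' Construct a residue-anonymous bicyclic topology
#'
#' @param a,b,c Bridge sizes (non-bridgehead residues per bridge path),
#'   a >= b >= c >= 0.
#' @param n_pendant Number of pendant (tail) residues outside the ring.
#' @param bridgeheads Optional bridgehead positions of a realizing graph.
#' @return A \code{bbp_topology}.
#' @export
topology <- function(a, b, c, n_pendant = 0L, bridgeheads = NULL) {
  s <- sort(c(a, b, c), decreasing = TRUE)
  if (s[3] < 0) stop("bridge sizes must be >= 0")
  if (s[2] == 0) stop("at most one bridge may be empty")
  structure(list(a = s[1], b = s[2], c = s[3],
                 n_ring = s[1] + s[2] + s[3] + 2L,
                 class = if (s[3] >= 1) "bridged" else "fused",
                 descriptor = sprintf("bicyclo[%d.%d.%d]", s[1], s[2], s[3]),
                 n_pendant = as.integer(n_pendant),
                 bridgeheads = bridgeheads),
            class = "bbp_topology")
}

#' Bicyclo ring descriptor string
#'
#' @param t A \code{bbp_topology}.
#' @return Character scalar such as \code{"bicyclo[2.2.1]"}.
#' @export
bicyclo_descriptor <- function(t) t$descriptor

#' @export
print.bbp_topology <- function(x, ...) {
  cat("<bbp_topology> ", x$descriptor, " (", x$class, "), ", x$n_ring,
      " ring residues", if (x$n_pendant > 0)
        paste0(" + ", x$n_pendant, " pendant"), "\n", sep = "")
  invisible(x)
}
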
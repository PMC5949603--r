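# Backbone geometry: torsions, cis/trans amides, Ramachandran regions,
# beta-turn typing, and intramolecular hydrogen bonds.

#' Construct a backbone structure
#'
#' @param residues data.frame with columns position, code, chirality.
#' @param atoms data.frame with columns residue, atom (N/CA/C/O/CB), x, y, z.
#' @return A \code{bbp_structure}.
#' @export
backbone_structure <- function(residues, atoms) {
  stopifnot(all(c("residue", "atom", "x", "y", "z") %in% names(atoms)),
            all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
  s <- structure(list(residues = residues, atoms = atoms),
                 class = "bbp_structure")
  d <- peptide_bond_lengths(s)
  if (any(!is.na(d) & (d < 1.2 | d > 1.5)))
    warning("C-N distance outside 1.2-1.5 A for bonded pair(s): ",
            paste(which(!is.na(d) & (d < 1.2 | d > 1.5)), collapse = ", "))
  s
}

#' @export
print.bbp_structure <- function(x, ...) {
  cat("<bbp_structure> ", nrow(x$residues), " residues, ", nrow(x$atoms),
      " atoms\n", sep = "")
  invisible(x)
}

atom_xyz <- function(s, i, name) {
  r <- s$atoms[s$atoms$residue == i & s$atoms$atom == name, c("x", "y", "z")]
  if (nrow(r) == 0) return(NULL)
  as.numeric(r[1, ])
}

peptide_bond_lengths <- function(s) {
  n <- nrow(s$residues)
  if (n < 2) return(numeric(0))
  vapply(seq_len(n - 1), function(i) {
    c1 <- atom_xyz(s, i, "C"); n2 <- atom_xyz(s, i + 1, "N")
    if (is.null(c1) || is.null(n2)) return(NA_real_)
    sqrt(sum((c1 - n2)^2))
  }, 0)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed torsion angle of four points
#'
#' IUPAC sign convention, degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinates (Angstrom).
#' @return Angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9)
    stop("degenerate geometry: collinear points in torsion")
  b2h <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross3(n1, b2h) * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone torsions phi/psi/omega of a structure
#'
#' Torsions are taken along the written chain; angles undefined at the
#' termini are NA. omega(i) is the torsion of the peptide bond joining
#' residue i-1 to residue i.
#'
#' @param s A \code{bbp_structure}.
#' @return data.frame with columns residue, phi, psi, omega (degrees).
#' @export
backbone_torsions <- function(s) {
  n <- nrow(s$residues)
  out <- data.frame(residue = seq_len(n), phi = NA_real_, psi = NA_real_,
                    omega = NA_real_)
  for (i in seq_len(n)) {
    Ni <- atom_xyz(s, i, "N"); CAi <- atom_xyz(s, i, "CA")
    Ci <- atom_xyz(s, i, "C")
    if (is.null(Ni) || is.null(CAi) || is.null(Ci)) next
    if (i > 1) {
      Cp <- atom_xyz(s, i - 1, "C"); CAp <- atom_xyz(s, i - 1, "CA")
      if (!is.null(Cp)) out$phi[i] <- dihedral(Cp, Ni, CAi, Ci)
      if (!is.null(Cp) && !is.null(CAp))
        out$omega[i] <- dihedral(CAp, Cp, Ni, CAi)
    }
    if (i < n) {
      Nn <- atom_xyz(s, i + 1, "N")
      if (!is.null(Nn)) out$psi[i] <- dihedral(Ni, CAi, Ci, Nn)
    }
  }
  out
}

#' Classify a peptide-bond omega torsion as cis or trans
#'
#' @param omega Torsion in degrees.
#' @return \code{"cis"} when |omega| < 90, else \code{"trans"}.
#' @export
omega_class <- function(omega) {
  ifelse(abs(omega) < 90, "cis", "trans")
}

# Coarse convex polygons approximating the standard generic Ramachandran
# contours for an L-residue (phi, psi in degrees). Documented constants; a
# finer published contour set can be substituted.
RAMA_PREFERRED <- list(
  beta   = cbind(phi = c(-170, -50, -50, -170), psi = c(95, 95, 180, 180)),
  alphaR = cbind(phi = c(-100, -30, -30, -100), psi = c(-67, -67, -7, -7))
)
RAMA_ALLOWED <- list(
  broad_upper = cbind(phi = c(-180, -20, -20, -180), psi = c(45, 45, 180, 180)),
  broad_mid   = cbind(phi = c(-180, -20, -20, -180), psi = c(-90, -90, 45, 45)),
  broad_low   = cbind(phi = c(-180, -20, -20, -180),
                      psi = c(-180, -180, -150, -150)),
  alphaL      = cbind(phi = c(20, 100, 100, 20), psi = c(-40, -40, 90, 90))
)

in_any_region <- function(phi, psi, regions) {
  for (poly in regions)
    if (pracma::inpolygon(phi, psi, poly[, "phi"], poly[, "psi"],
                          boundary = TRUE))
      return(TRUE)
  FALSE
}

#' Ramachandran region of a (phi, psi) pair
#'
#' D-residues are assessed against the mirrored regions
#' (phi, psi) -> (-phi, -psi).
#'
#' @param phi,psi Torsions in degrees.
#' @param chirality \code{"L"}, \code{"D"} or \code{"achiral"} (treated as L).
#' @return \code{"preferred"}, \code{"allowed"} or \code{"outlier"}.
#' @export
ramachandran_region <- function(phi, psi, chirality = "L") {
  if (is.na(phi) || is.na(psi)) return(NA_character_)
  if (identical(chirality, "D")) { phi <- -phi; psi <- -psi }
  if (in_any_region(phi, psi, RAMA_PREFERRED)) return("preferred")
  if (in_any_region(phi, psi, RAMA_ALLOWED)) return("allowed")
  "outlier"
}

# Canonical beta-turn centre angles (phi_{i+1}, psi_{i+1}, phi_{i+2},
# psi_{i+2}); type VI requires a cis peptide bond between i+1 and i+2.
TURN_TYPES <- list(
  I     = list(angles = c(-60, -30, -90, 0),    cis = FALSE),
  Iprime  = list(angles = c(60, 30, 90, 0),     cis = FALSE),
  II    = list(angles = c(-60, 120, 80, 0),     cis = FALSE),
  IIprime = list(angles = c(60, -120, -80, 0),  cis = FALSE),
  VIII  = list(angles = c(-60, -30, -120, 120), cis = FALSE),
  VIa   = list(angles = c(-60, 120, -90, 0),    cis = TRUE),
  VIb   = list(angles = c(-135, 135, -75, 160), cis = TRUE)
)

circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

#' Classify a four-residue window as a beta-turn type
#'
#' Nearest canonical type with all four central torsions within tolerance
#' (each within \code{tol}, at most one within \code{tol_one}); type VI
#' requires a cis omega between residues i+1 and i+2. Ties are broken by the
#' smallest summed angular deviation; windows matching nothing are type
#' \code{"IV"}.
#'
#' @param dihedrals data.frame from \code{\link{backbone_torsions}}.
#' @param i Window start (the turn spans residues i..i+3).
#' @param tol,tol_one Tolerances in degrees (default 30 and 45).
#' @return List: window, type, deviations (per-angle), total_deviation,
#'   omega_i2, ca_distance (NA unless supplied by \code{\link{find_turns}}).
#' @export
classify_turn <- function(dihedrals, i, tol = 30, tol_one = 45) {
  if (i < 1 || (i + 3) > max(dihedrals$residue))
    stop("turn window out of range")
  a <- c(dihedrals$phi[dihedrals$residue == i + 1],
         dihedrals$psi[dihedrals$residue == i + 1],
         dihedrals$phi[dihedrals$residue == i + 2],
         dihedrals$psi[dihedrals$residue == i + 2])
  if (any(is.na(a))) stop("undefined torsions in turn window")
  om <- dihedrals$omega[dihedrals$residue == i + 2]
  om_cis <- !is.na(om) && omega_class(om) == "cis"
  best <- NULL
  for (ty in names(TURN_TYPES)) {
    spec <- TURN_TYPES[[ty]]
    if (spec$cis != om_cis) next
    dev <- circ_diff(a, spec$angles)
    if (sum(dev > tol) > 1 || any(dev > tol_one)) next
    tot <- sum(dev)
    if (is.null(best) || tot < best$total_deviation)
      best <- list(type = ty, deviations = dev, total_deviation = tot)
  }
  if (is.null(best))
    best <- list(type = "IV", deviations = rep(NA_real_, 4),
                 total_deviation = NA_real_)
  c(list(window = i:(i + 3)), best,
    list(omega_i2 = om, ca_distance = NA_real_))
}

#' Scan a structure for beta-turn windows
#'
#' Windows are enumerated along the written chain; the Calpha(i)-Calpha(i+3)
#' distance is attached to each assignment.
#'
#' @param s A \code{bbp_structure}.
#' @param tol,tol_one Passed to \code{\link{classify_turn}}.
#' @return data.frame with one row per window.
#' @export
find_turns <- function(s, tol = 30, tol_one = 45) {
  dh <- backbone_torsions(s)
  n <- nrow(s$residues)
  rows <- list()
  for (i in seq_len(max(0, n - 3))) {
    a <- dh[dh$residue %in% c(i + 1, i + 2), c("phi", "psi")]
    if (any(is.na(unlist(a)))) next
    t <- classify_turn(dh, i, tol, tol_one)
    ca1 <- atom_xyz(s, i, "CA"); ca4 <- atom_xyz(s, i + 3, "CA")
    d <- if (is.null(ca1) || is.null(ca4)) NA_real_ else
      sqrt(sum((ca1 - ca4)^2))
    rows[[length(rows) + 1]] <-
      data.frame(i = i, type = t$type,
                 total_deviation = t$total_deviation,
                 ca_distance = d, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(i = integer(0), type = character(0),
                      total_deviation = numeric(0), ca_distance = numeric(0)))
  do.call(rbind, rows)
}

# Reconstruct the amide H of residue i: in the C(i-1)/N(i)/CA(i) plane,
# N-H 1.01 A, bisecting the exterior angle at N.
amide_h <- function(s, i) {
  if (i < 2) return(NULL)
  Cp <- atom_xyz(s, i - 1, "C"); Ni <- atom_xyz(s, i, "N")
  CAi <- atom_xyz(s, i, "CA")
  if (is.null(Cp) || is.null(Ni) || is.null(CAi)) return(NULL)
  u1 <- (Cp - Ni) / sqrt(sum((Cp - Ni)^2))
  u2 <- (CAi - Ni) / sqrt(sum((CAi - Ni)^2))
  d <- -(u1 + u2)
  Ni + 1.01 * d / sqrt(sum(d^2))
}

#' Detect intramolecular backbone hydrogen bonds
#'
#' Amide protons are reconstructed from backbone geometry (prolines and
#' N-methylated residues carry no NH and are skipped). A donor N(i) /
#' acceptor O(j) pair is reported when the N...O distance is at most
#' \code{dist_cutoff} and the N-H...O angle at least \code{angle_cutoff};
#' the trivial contacts j = i and j = i-1 are excluded.
#'
#' @param s A \code{bbp_structure}.
#' @param dist_cutoff N...O cutoff in Angstrom (default 3.5).
#' @param angle_cutoff D-H...A cutoff in degrees (default 120).
#' @return data.frame: donor, acceptor, distance, angle.
#' @export
detect_hbonds <- function(s, dist_cutoff = 3.5, angle_cutoff = 120) {
  n <- nrow(s$residues)
  rows <- list()
  no_nh <- toupper(s$residues$code) == "P" |
    (("n_methyl" %in% names(s$residues)) & isTRUE_vec(s$residues$n_methyl))
  for (i in 2:max(2, n)) {
    if (n < 2) break
    if (no_nh[i]) next
    Ni <- atom_xyz(s, i, "N")
    H <- amide_h(s, i)
    if (is.null(Ni) || is.null(H)) next
    for (j in seq_len(n)) {
      if (j == i || j == i - 1) next
      Oj <- atom_xyz(s, j, "O")
      if (is.null(Oj)) next
      d <- sqrt(sum((Ni - Oj)^2))
      if (d > dist_cutoff) next
      v1 <- Ni - H; v2 <- Oj - H
      ang <- acos(sum(v1 * v2) /
                    sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (ang < angle_cutoff) next
      rows[[length(rows) + 1]] <-
        data.frame(donor = i, acceptor = j, distance = d, angle = ang)
    }
  }
  if (length(rows) == 0)
    return(data.frame(donor = integer(0), acceptor = integer(0),
                      distance = numeric(0), angle = numeric(0)))
  do.call(rbind, rows)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x
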
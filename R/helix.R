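# Alpha-helix mimicry: ideal helix construction, residue-triplet
# enumeration, optimal rigid superposition (Kabsch) and overlap scoring.

#' Build an ideal poly-alanine alpha-helix
#'
#' Textbook helix torsions phi = -57, psi = -47, omega = 180, with CB atoms
#' placed tetrahedrally.
#'
#' @param n Residue count (>= 2).
#' @return A \code{bbp_structure}.
#' @export
build_ideal_helix <- function(n = 7) {
  stopifnot(n >= 2)
  build_backbone(torsion_spec(n, phi = -57, psi = -47, omega = 180,
                              code = "A", chirality = "L"))
}

#' All ordered residue triplets i < j < k
#'
#' @param n Residue count (>= 3).
#' @return Integer matrix, choose(n, 3) rows by 3 columns.
#' @examples
#' nrow(enumerate_triplets(7))  # 35
#' @export
enumerate_triplets <- function(n) {
  if (n < 3) stop("need at least 3 residues")
  t(utils::combn(n, 3))
}

#' Optimal rigid superposition of two point sets (Kabsch)
#'
#' Least-squares rotation and translation mapping A onto B, restricted to
#' proper rotations (no reflection). Collinear point sets are flagged with
#' a warning.
#'
#' @param A,B Numeric matrices, same dimensions, one 3D point per row
#'   (>= 3 points).
#' @return List: rotation (3x3, applied as \code{A \%*\% rotation}),
#'   translation (length 3), rmsd.
#' @export
superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(nrow(A) == nrow(B), ncol(A) == 3, ncol(B) == 3, nrow(A) >= 3)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(A0) %*% B0
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    warning("degenerate (collinear) point set in superposition")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  At <- A0 %*% R
  rmsd <- sqrt(mean(rowSums((At - B0)^2)))
  list(rotation = R, translation = cb - ca %*% R, rmsd = rmsd)
}

#' Gaussian atom-pair overlap score of superposed point sets
#'
#' Mean over matched pairs of exp(-d^2 / (2 sigma^2)): 1 for perfect
#' overlap, tending to 0 as pairs separate, monotone decreasing in every
#' pairwise distance.
#'
#' @param A,B Superposed point sets (matrices, one point per row).
#' @param sigma Gaussian width in Angstrom (> 0).
#' @return Score in [0, 1].
#' @export
atom_pair_score <- function(A, B, sigma = 1.0) {
  stopifnot(sigma > 0)
  d2 <- rowSums((as.matrix(A) - as.matrix(B))^2)
  mean(exp(-d2 / (2 * sigma^2)))
}

triplet_points <- function(s, idx, mode) {
  pts <- NULL
  for (i in idx) {
    if (mode %in% c("CA", "both")) {
      p <- atom_xyz(s, i, "CA")
      if (is.null(p)) return(NULL)
      pts <- rbind(pts, p)
    }
    if (mode %in% c("CB", "both")) {
      p <- atom_xyz(s, i, "CB")
      if (is.null(p)) return(NULL)
      pts <- rbind(pts, p)
    }
  }
  pts
}

#' Rank structure-vs-helix triplet matches
#'
#' Every residue triplet of the query structure is superposed onto every
#' triplet of the reference helix, in the requested atom mode (CA, CB or
#' both: 3, 3 or 6 points per triplet), with residues corresponded in
#' sequence order. Triplets lacking a required CB (glycine) are skipped with
#' a notice. Results are sorted by ascending RMSD, ties broken by descending
#' overlap score.
#'
#' @param s Query \code{bbp_structure}.
#' @param helix Reference \code{bbp_structure} (e.g.
#'   \code{\link{build_ideal_helix}}).
#' @param mode \code{"CA"}, \code{"CB"} or \code{"both"}.
#' @param sigma Width for \code{\link{atom_pair_score}}.
#' @param include_reversed Also try the reversed residue correspondence
#'   (k, j, i); off by default.
#' @return data.frame: s_i, s_j, s_k, h_p, h_q, h_r, rmsd, score, reversed.
#' @export
rank_matches <- function(s, helix, mode = c("CA", "CB", "both"),
                         sigma = 1.0, include_reversed = FALSE) {
  mode <- match.arg(mode)
  ns <- nrow(s$residues); nh <- nrow(helix$residues)
  ts_ <- enumerate_triplets(ns); th <- enumerate_triplets(nh)
  skipped <- 0L
  rows <- vector("list", nrow(ts_) * nrow(th))
  k <- 0L
  spts <- lapply(seq_len(nrow(ts_)),
                 function(r) triplet_points(s, ts_[r, ], mode))
  hpts <- lapply(seq_len(nrow(th)),
                 function(r) triplet_points(helix, th[r, ], mode))
  for (a in seq_len(nrow(ts_))) {
    A <- spts[[a]]
    if (is.null(A)) { skipped <- skipped + nrow(th); next }
    for (b in seq_len(nrow(th))) {
      B <- hpts[[b]]
      if (is.null(B)) { skipped <- skipped + 1L; next }
      sp <- superpose(A, B)
      best <- c(sp$rmsd,
                atom_pair_score(sweep(A %*% sp$rotation, 2,
                                      as.numeric(sp$translation), `+`),
                                B, sigma))
      rev_used <- FALSE
      if (include_reversed) {
        Ar <- A[rev(seq_len(nrow(A))), , drop = FALSE]
        spr <- superpose(Ar, B)
        if (spr$rmsd < best[1]) {
          best <- c(spr$rmsd,
                    atom_pair_score(sweep(Ar %*% spr$rotation, 2,
                                          as.numeric(spr$translation), `+`),
                                    B, sigma))
          rev_used <- TRUE
        }
      }
      k <- k + 1L
      rows[[k]] <- data.frame(s_i = ts_[a, 1], s_j = ts_[a, 2],
                              s_k = ts_[a, 3], h_p = th[b, 1],
                              h_q = th[b, 2], h_r = th[b, 3],
                              rmsd = best[1], score = best[2],
                              reversed = rev_used)
    }
  }
  if (skipped > 0)
    message(skipped, " triplet pair(s) skipped (missing CB)")
  out <- do.call(rbind, rows[seq_len(k)])
  out <- out[order(out$rmsd, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Rise per residue of a helical CA trace
#'
#' Projects consecutive CA positions onto the principal axis of the trace.
#'
#' @param s A \code{bbp_structure}.
#' @return Mean rise in Angstrom.
#' @export
helix_rise <- function(s) {
  ca <- do.call(rbind, lapply(seq_len(nrow(s$residues)),
                              function(i) atom_xyz(s, i, "CA")))
  ax <- stats::prcomp(ca)$rotation[, 1]
  mean(abs(diff(ca %*% ax)))
}
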
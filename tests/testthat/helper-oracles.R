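# Independent oracles used across the suite.

# Number of partitions of n into exactly k positive parts, by the standard
# recursion p(n, k) = p(n-1, k-1) + p(n-k, k).
partitions_exact <- function(n, k) {
  if (k == 0) return(as.numeric(n == 0))
  if (n < k) return(0)
  partitions_exact(n - 1, k - 1) + partitions_exact(n - k, k)
}

# Theta graph with bridge sizes (a, b, c) as an igraph object (c = 0 gives a
# direct bridgehead-bridgehead edge).
theta_igraph <- function(a, b, c) {
  edges <- integer(0)
  nxt <- 3L
  for (len in c(a, b, c)) {
    if (len == 0) {
      edges <- c(edges, 1L, 2L)
    } else {
      chain <- c(1L, nxt:(nxt + len - 1L), 2L)
      for (i in seq_len(length(chain) - 1))
        edges <- c(edges, chain[i], chain[i + 1])
      nxt <- nxt + len
    }
  }
  igraph::make_graph(edges, directed = FALSE)
}

# Count isomorphism classes among theta graphs for all ordered bridge-size
# triples with total ring size n (a >= 1, b >= 1, c >= 0 per class rules).
count_theta_classes <- function(n_ring, fused = FALSE) {
  m <- n_ring - 2
  triples <- list()
  lo_c <- if (fused) 0 else 1
  for (a in 1:m) for (b in 1:m) for (cc in lo_c:m)
    if (a + b + cc == m && (fused == (cc == 0)))
      triples[[length(triples) + 1]] <- c(a, b, cc)
  if (length(triples) == 0) return(0L)
  graphs <- lapply(triples, function(t) theta_igraph(t[1], t[2], t[3]))
  classes <- list()
  for (g in graphs) {
    found <- FALSE
    for (h in classes)
      if (igraph::isomorphic(g, h)) { found <- TRUE; break }
    if (!found) classes[[length(classes) + 1]] <- g
  }
  length(classes)
}

# Brute-force minimal RMSD over rigid motions: coarse Euler-angle grid
# followed by direct Nelder-Mead refinement of the rotation angles
# (translation handled by centering). Independent of the SVD route.
euler_rot <- function(ang) {
  ca <- cos(ang[1]); sa <- sin(ang[1])
  cb <- cos(ang[2]); sb <- sin(ang[2])
  cg <- cos(ang[3]); sg <- sin(ang[3])
  Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE)
  Rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz1 %*% Ry %*% Rz2
}

grid_rmsd_oracle <- function(A, B, step = 30) {
  A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
  f <- function(ang) sqrt(mean(rowSums((A0 %*% euler_rot(ang) - B0)^2)))
  best <- Inf; best_ang <- c(0, 0, 0)
  as <- seq(0, 2 * pi, by = step * pi / 180)
  bs <- seq(0, pi, by = step * pi / 180)
  for (a in as) for (b in bs) for (g in as) {
    v <- f(c(a, b, g))
    if (v < best) { best <- v; best_ang <- c(a, b, g) }
  }
  opt <- stats::optim(best_ang, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  opt$value
}

# Build a small structure directly from an atom table.
make_structure <- function(codes, atoms, chirality = NULL) {
  n <- length(codes)
  if (is.null(chirality))
    chirality <- ifelse(toupper(codes) == "G", "achiral", "L")
  suppressWarnings(backbone_structure(
    residues = data.frame(position = seq_len(n), code = codes,
                          chirality = chirality, stringsAsFactors = FALSE),
    atoms = atoms))
}

mirror_structure <- function(s) {
  s$atoms$x <- -s$atoms$x
  s$atoms$y <- -s$atoms$y
  s$atoms$z <- -s$atoms$z
  flip <- c(L = "D", D = "L", achiral = "achiral")
  s$residues$chirality <- unname(flip[s$residues$chirality])
  s
}
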
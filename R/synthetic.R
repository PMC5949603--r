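# Synthetic-data generators: torsion-driven backbone construction (NeRF
# sequential atom placement), coordinate perturbation, and seeded forward
# simulation of ITC and MST experiments.

# Standard peptide geometry (Engh-Huber-style values), one constants table.
BACKBONE_GEOM <- c(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.530,
  a_n_ca_c = 111.2, a_ca_c_n = 117.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.5, a_n_ca_cb = 110.4,
  t_cb_improper = 122.5  # dihedral C-N-CA-CB for an L-residue; negated for D
)

# Place a new atom at distance `bond` from c, with angle new-c-b and torsion
# new-c-b-a (natural extension reference frame).
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         -bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Build a peptide backbone from torsion angles
#'
#' Sequential atom placement with standard peptide geometry. phi of the
#' first residue and psi of the last drive only O placement (psi defaults to
#' 180 when NA). D-residues receive the mirrored CB position; glycine gets
#' no CB.
#'
#' @param spec data.frame with columns code, chirality, phi, psi, omega
#'   (degrees); omega(i) is the bond joining residue i-1 to i.
#' @return A \code{bbp_structure}.
#' @examples
#' helix <- build_backbone(torsion_spec(5, phi = -57, psi = -47))
#' @export
build_backbone <- function(spec) {
  n <- nrow(spec)
  g <- BACKBONE_GEOM
  atoms <- list()
  add <- function(res, name, p)
    atoms[[length(atoms) + 1]] <<- data.frame(residue = res, atom = name,
                                              x = p[1], y = p[2], z = p[3])
  N <- c(0, 0, 0)
  CA <- c(g["b_n_ca"], 0, 0)
  th <- (180 - g["a_n_ca_c"]) * pi / 180
  C <- CA + g["b_ca_c"] * c(cos(th), sin(th), 0)
  add(1, "N", N); add(1, "CA", CA); add(1, "C", C)
  prev <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n)) {
    if (i > 1) {
      psi_prev <- spec$psi[i - 1]
      if (is.na(psi_prev)) psi_prev <- 180
      Ni <- nerf_place(prev$N, prev$CA, prev$C,
                       g["b_c_n"], g["a_ca_c_n"], psi_prev)
      om <- spec$omega[i]; if (is.na(om)) om <- 180
      CAi <- nerf_place(prev$CA, prev$C, Ni,
                        g["b_n_ca"], g["a_c_n_ca"], om)
      phi <- spec$phi[i]; if (is.na(phi)) phi <- 180
      Ci <- nerf_place(prev$C, Ni, CAi, g["b_ca_c"], g["a_n_ca_c"], phi)
      add(i, "N", Ni); add(i, "CA", CAi); add(i, "C", Ci)
      # carbonyl O of residue i-1, anti to N(i)
      Oi1 <- nerf_place(prev$N, prev$CA, prev$C,
                        g["b_c_o"], g["a_ca_c_o"],
                        psi_prev + 180)
      add(i - 1, "O", Oi1)
      prev <- list(N = Ni, CA = CAi, C = Ci)
    }
    if (toupper(spec$code[i]) != "G") {
      sgn <- if (identical(spec$chirality[i], "D")) -1 else 1
      CB <- nerf_place(prev$C, prev$N, prev$CA,
                       g["b_ca_cb"], g["a_n_ca_cb"],
                       sgn * g["t_cb_improper"])
      add(i, "CB", CB)
    }
  }
  psi_n <- spec$psi[n]; if (is.na(psi_n)) psi_n <- 180
  On <- nerf_place(prev$N, prev$CA, prev$C,
                   g["b_c_o"], g["a_ca_c_o"], psi_n + 180)
  add(n, "O", On)
  backbone_structure(
    residues = data.frame(position = seq_len(n), code = spec$code,
                          chirality = spec$chirality,
                          stringsAsFactors = FALSE),
    atoms = do.call(rbind, atoms))
}

#' Convenience constructor for a uniform torsion specification
#'
#' @param n Residue count.
#' @param phi,psi,omega Torsions in degrees, recycled to length n.
#' @param code Residue one-letter codes, recycled.
#' @param chirality Recycled; \code{"achiral"} is forced for glycine.
#' @return data.frame suitable for \code{\link{build_backbone}}.
#' @export
torsion_spec <- function(n, phi = -57, psi = -47, omega = 180,
                         code = "A", chirality = "L") {
  out <- data.frame(code = rep_len(code, n),
                    chirality = rep_len(chirality, n),
                    phi = rep_len(phi, n), psi = rep_len(psi, n),
                    omega = rep_len(omega, n), stringsAsFactors = FALSE)
  out$chirality[toupper(out$code) == "G"] <- "achiral"
  out$phi[1] <- NA; out$omega[1] <- NA; out$psi[n] <- NA
  out
}

#' Perturb structure coordinates with Gaussian noise
#'
#' @param s A \code{bbp_structure}.
#' @param sigma Standard deviation per coordinate (Angstrom).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A \code{bbp_structure}.
#' @export
perturb <- function(s, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(s)
  set.seed(seed)
  m <- nrow(s$atoms)
  s$atoms$x <- s$atoms$x + stats::rnorm(m, 0, sigma)
  s$atoms$y <- s$atoms$y + stats::rnorm(m, 0, sigma)
  s$atoms$z <- s$atoms$z + stats::rnorm(m, 0, sigma)
  s
}

#' Simulate an ITC isotherm with additive noise
#'
#' Forward pass of \code{\link{itc_model}} plus seeded Gaussian noise scaled
#' to the largest absolute heat.
#'
#' @param n,Ka,dH One-set-of-sites parameters (sites, 1/M, kcal/mol).
#' @param expt An \code{\link{itc_experiment}}.
#' @param noise_sd Noise as a fraction of the maximum |heat| (0 = noiseless).
#' @param seed Integer seed.
#' @return data.frame as \code{itc_model}, with noisy \code{heat}.
#' @export
gen_itc <- function(n, Ka, dH, expt = itc_experiment(), noise_sd = 0,
                    seed = 1L) {
  iso <- itc_model(n, Ka, dH, expt)
  if (noise_sd > 0) {
    set.seed(seed)
    iso$heat <- iso$heat +
      stats::rnorm(nrow(iso), 0, noise_sd * max(abs(iso$heat)))
  }
  iso
}

#' Simulate an MST dose-response series with additive noise
#'
#' @param KD Dissociation constant (M).
#' @param design A \code{\link{mst_design}} list (ligand concentrations and
#'   labeled-protein concentration).
#' @param s_free,s_bound Plateau signals of the free and bound states.
#' @param noise_sd Noise as a fraction of the plateau separation.
#' @param seed Integer seed.
#' @return data.frame: ligand (M), signal.
#' @export
gen_mst <- function(KD, design = mst_design(), s_free = 0, s_bound = 1,
                    noise_sd = 0, seed = 1L) {
  fb <- mst_model(design$ligand, design$protein, KD)
  sig <- s_free + (s_bound - s_free) * fb
  if (noise_sd > 0) {
    set.seed(seed)
    sig <- sig + stats::rnorm(length(sig), 0, noise_sd * abs(s_bound - s_free))
  }
  data.frame(ligand = design$ligand, signal = sig)
}

FIXTURE_FILES <- c(sequences = "sequences.csv",
                   formulas_mz = "formulas_mz.csv",
                   temp_coeffs = "temp_coeffs.csv",
                   mst_design = "mst_design.csv",
                   itc_design = "itc_design.csv",
                   nmethyl = "nmethyl.csv")

#' Load a packaged data fixture
#'
#' Plain-text tables shipped with the package: \code{"sequences"} (all final
#' products with notation, flags and printed formula/m/z), \code{"formulas_mz"}
#' (every printed calc. formula/adduct/m/z, including monocyclic
#' intermediates), \code{"temp_coeffs"} (amide-proton temperature
#' coefficients with boldface flags), \code{"itc_design"} and
#' \code{"mst_design"} (assay protocols), \code{"nmethyl"} (the N-methylated
#' series).
#'
#' @param name Fixture name.
#' @return data.frame.
#' @export
load_fixtures <- function(name) {
  f <- FIXTURE_FILES[name]
  if (is.na(f)) stop("unknown fixture: ", name, "; available: ",
                     paste(names(FIXTURE_FILES), collapse = ", "))
  path <- system.file("extdata", f, package = "bbpkit")
  if (!nzchar(path)) path <- file.path("inst", "extdata", f)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
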
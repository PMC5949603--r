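test_that("torsion angles follow the IUPAC sign convention", {
  p2 <- c(0, 0, 0); p3 <- c(0, 0, 1.5)
  p1 <- c(1, 0, 0)
  # eclipsed (cis) arrangement
  expect_equal(dihedral(p1, p2, p3, c(1, 0, 1.5)), 0, tolerance = 1e-9)
  # anti arrangement maps to +180, the closed end of (-180, 180]
  expect_equal(dihedral(p1, p2, p3, c(-1, 0, 1.5)), 180, tolerance = 1e-9)
  # staggered positions at +/-60
  th <- 60 * pi / 180
  d_plus <- dihedral(p1, p2, p3, c(cos(th), sin(th), 1.5))
  d_minus <- dihedral(p1, p2, p3, c(cos(th), -sin(th), 1.5))
  expect_equal(sort(c(d_plus, d_minus)), c(-60, 60), tolerance = 1e-9)
  expect_error(dihedral(p1, p2, p3, c(0, 0, 3)), "degenerate")
})

test_that("omega classification splits cis and trans at 90 degrees", {
  expect_equal(omega_class(180), "trans")
  expect_equal(omega_class(0), "cis")
  expect_equal(omega_class(-95), "trans")
  expect_equal(omega_class(c(5, -170, 89.9)), c("cis", "trans", "cis"))
})

test_that("Ramachandran regions are mirrored for D-residues", {
  expect_equal(ramachandran_region(-57, -47, "L"), "preferred")
  expect_equal(ramachandran_region(57, 47, "D"), "preferred")
  expect_equal(ramachandran_region(-120, 140, "L"), "preferred")  # beta
  expect_equal(ramachandran_region(60, 40, "L"), "allowed")       # alpha-L
  expect_equal(ramachandran_region(120, -120, "L"), "outlier")
  set.seed(7)
  for (i in 1:200) {
    phi <- stats::runif(1, -180, 180); psi <- stats::runif(1, -180, 180)
    expect_identical(ramachandran_region(phi, psi, "L"),
                     ramachandran_region(-phi, -psi, "D"))
  }
})

test_that("canonical turn angles classify to their own type", {
  canon <- list(I = c(-60, -30, -90, 0), Iprime = c(60, 30, 90, 0),
                II = c(-60, 120, 80, 0), IIprime = c(60, -120, -80, 0),
                VIII = c(-60, -30, -120, 120),
                VIa = c(-60, 120, -90, 0), VIb = c(-135, 135, -75, 160))
  for (ty in names(canon)) {
    a <- canon[[ty]]
    om <- if (ty %in% c("VIa", "VIb")) 0 else 180
    dh <- data.frame(residue = 1:4,
                     phi = c(NA, a[1], a[3], NA),
                     psi = c(NA, a[2], a[4], NA),
                     omega = c(NA, 180, om, 180))
    expect_equal(classify_turn(dh, 1)$type, ty)
  }
})

test_that("turn typing tolerates moderate deviation and rejects large", {
  a <- c(-60, 120, 80, 0)
  mk <- function(delta) data.frame(residue = 1:4,
                                   phi = c(NA, a[1] + delta, a[3] + delta, NA),
                                   psi = c(NA, a[2] + delta, a[4] + delta, NA),
                                   omega = c(NA, 180, 180, 180))
  expect_equal(classify_turn(mk(20), 1)$type, "II")
  expect_equal(classify_turn(mk(50), 1)$type, "IV")
  expect_error(classify_turn(mk(0), 0), "out of range")
  dh <- mk(0); dh$phi[2] <- NA
  expect_error(classify_turn(dh, 1), "undefined")
})

test_that("type VI assignment requires the cis peptide bond", {
  a <- c(-60, 120, -90, 0)
  dh <- data.frame(residue = 1:4, phi = c(NA, a[1], a[3], NA),
                   psi = c(NA, a[2], a[4], NA),
                   omega = c(NA, 180, 180, 180))
  expect_false(classify_turn(dh, 1)$type %in% c("VIa", "VIb"))
  dh$omega[3] <- 5
  expect_equal(classify_turn(dh, 1)$type, "VIa")
})

test_that("torsions round-trip through the backbone builder", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 6
    spec <- torsion_spec(n, phi = stats::runif(n, -170, -40),
                         psi = stats::runif(n, -60, 160),
                         omega = sample(c(180, 175, -175, 0), n, TRUE))
    s <- build_backbone(spec)
    tor <- backbone_torsions(s)
    idx <- 2:(n - 1)
    expect_equal(tor$phi[idx], spec$phi[idx], tolerance = 1e-6)
    expect_equal(tor$psi[idx], spec$psi[idx], tolerance = 1e-6)
    expect_equal(tor$omega[idx], spec$omega[idx], tolerance = 1e-6)
  }
})

test_that("mirroring coordinates negates torsions and primes turn types", {
  spec <- torsion_spec(4, phi = c(NA, -60, -60, NA),
                       psi = c(100, -30, 0, NA), omega = 180,
                       code = "A")
  spec$phi <- c(NA, -60, -90, NA); spec$psi <- c(100, -30, 0, NA)
  s <- build_backbone(spec)
  m <- mirror_structure(s)
  ts <- backbone_torsions(s); tm <- backbone_torsions(m)
  idx <- !is.na(ts$phi)
  expect_lt(max(bbpkit:::circ_diff(tm$phi[idx], -ts$phi[idx])), 1e-9)
  jdx <- !is.na(ts$psi)
  expect_lt(max(bbpkit:::circ_diff(tm$psi[jdx], -ts$psi[jdx])), 1e-9)
  # a type-I window on the original classifies I' on the mirror
  spec2 <- torsion_spec(4, phi = c(NA, -60, -90, NA),
                        psi = c(NA, -30, 0, NA), omega = 180)
  s2 <- build_backbone(spec2)
  t_orig <- classify_turn(backbone_torsions(s2), 1)
  t_mirr <- classify_turn(backbone_torsions(mirror_structure(s2)), 1)
  expect_equal(t_orig$type, "I")
  expect_equal(t_mirr$type, "Iprime")
})

test_that("hydrogen bonds are detected inside both cutoffs only", {
  # minimal two-residue geometry: donor N at origin, C(i-1) and CA chosen so
  # the reconstructed H points along +x toward the acceptor O
  at <- function(res, atom, x, y, z)
    data.frame(residue = res, atom = atom, x = x, y = y, z = z)
  base <- rbind(
    at(1, "N", -4, 1, 0), at(1, "CA", -3.0, 1.4, 0),
    at(1, "C", -1.2, -0.8, 0),
    at(2, "N", 0, 0, 0), at(2, "CA", -1.2, 0.8, 0), at(2, "C", 0.6, 1.2, 0))
  near <- rbind(base, at(3, "O", 2.9, 0.15, 0),
                at(3, "CA", 3.9, 0.2, 0), at(3, "N", 3.4, 1, 0),
                at(3, "C", 4.4, 1, 0))
  s <- make_structure(c("A", "A", "A"), near)
  hb <- detect_hbonds(s)
  expect_true(any(hb$donor == 2 & hb$acceptor == 3))
  far <- near; far$x[far$residue == 3 & far$atom == "O"] <- 4.0
  expect_false(any(with(detect_hbonds(make_structure(c("A", "A", "A"), far)),
                        donor == 2 & acceptor == 3)))
})

test_that("an ideal helix shows the i+4 -> i hydrogen-bond ladder", {
  h <- build_ideal_helix(9)
  hb <- detect_hbonds(h)
  for (i in 1:5)
    expect_true(any(hb$donor == i + 4 & hb$acceptor == i),
                info = paste("window", i))
  expect_true(all(hb$distance <= 3.5))
  expect_true(all(hb$angle >= 120))
})

test_that("prolines and N-methylated residues donate no hydrogen bonds", {
  h <- build_ideal_helix(9)
  h$residues$code[6] <- "P"
  hb <- detect_hbonds(h)
  expect_false(any(hb$donor == 6))
})
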
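test_that("elemental formulas follow the cyclization bookkeeping", {
  expect_equal(ef_string(formula_of(parse_bbp("l1 G k2 f P E1 a2"))),
               "C36H52N8O8")
  g27c <- parse_bbp("K2 E1 K w z2 W K1 G", c_term = "amide",
                    thioether = TRUE)
  expect_equal(ef_string(formula_of(g27c)), "C52H72N14O10S")
  # free linear triglycine: 3 x C2H3NO + H2O
  expect_equal(ef_string(formula_of(parse_bbp("G G G"))), "C6H11N3O4")
})

test_that("formula arithmetic is closed and guards underflow", {
  a <- parse_ef("C2H3NO")
  b <- parse_ef("H2O")
  expect_equal(ef_string(a + b), "C2H5NO2")
  expect_equal(ef_string((a + b) - b), "C2H3NO")
  expect_error(a - parse_ef("S"), "underflow")
})

test_that("monoisotopic masses match element sums", {
  expect_equal(monoisotopic_mass(parse_ef("H2O")), 18.0106, tolerance = 1e-4)
  expect_equal(monoisotopic_mass(parse_ef("C36H52N8O8")), 724.3908,
               tolerance = 1e-4)
  expect_equal(monoisotopic_mass(ef()), 0)
  expect_error(monoisotopic_mass(ef(Xx = 1)), "unknown element")
})

test_that("monoisotopic mass is additive over formula addition", {
  set.seed(42)
  for (i in 1:20) {
    f1 <- ef(C = sample(0:30, 1), H = sample(1:60, 1), N = sample(0:10, 1),
             O = sample(0:12, 1), S = sample(0:2, 1))
    f2 <- ef(C = sample(0:30, 1), H = sample(1:60, 1), O = sample(0:12, 1))
    expect_equal(monoisotopic_mass(f1 + f2),
                 monoisotopic_mass(f1) + monoisotopic_mass(f2),
                 tolerance = 1e-9)
  }
})

test_that("adduct m/z values reproduce the printed calc. examples", {
  M <- monoisotopic_mass(parse_ef("C36H52N8O8"))
  expect_equal(adduct_mz(M, "[M+H]+")$mz2, 725.40)
  expect_equal(adduct_mz(M, "[M+Na]+")$mz2, 747.38)
  M2 <- monoisotopic_mass(parse_ef("C82H105N17O21S2"))
  expect_equal(adduct_mz(M2, "[M+2H]2+")$mz2, 864.86)
  expect_error(adduct_mz(M, "[M+Cs]+"), "unsupported adduct")
  expect_error(adduct_mz(-1, "[M+H]+"), "positive")
})

test_that("mz_report composes parsing, formula and adducts", {
  rep10 <- mz_report("l1 G k2 y P E1 a2", c("[M+H]+", "[M+Na]+"))
  expect_equal(rep10$mz_2dp, c(741.39, 763.37))
  rep30 <- mz_report("Me-l1 G k2 f P E1 a2", "[M+H]+")
  expect_equal(rep30$mz_2dp, 739.41)
  empty <- mz_report("G G G", character(0))
  expect_equal(nrow(empty), 0)
})

test_that("all self-consistent printed formulas are reproduced exactly", {
  sq <- load_fixtures("sequences")
  fm <- load_fixtures("formulas_mz")
  tabs <- rbind(sq[, c("id", "notation", "c_term", "thioether",
                       "printed_formula", "formula_consistent")],
                stats::setNames(
                  fm[, c("id", "notation", "c_term", "thioether",
                         "printed_formula", "formula_consistent")],
                  c("id", "notation", "c_term", "thioether",
                    "printed_formula", "formula_consistent")))
  tabs <- tabs[!duplicated(tabs$id), ]
  for (i in which(tabs$formula_consistent)) {
    g <- parse_bbp(tabs$notation[i], c_term = tabs$c_term[i],
                   thioether = tabs$thioether[i])
    expect_equal(ef_string(formula_of(g)), tabs$printed_formula[i],
                 info = tabs$id[i])
  }
})

test_that("every consistent printed calc. m/z is matched within 0.01", {
  sq <- load_fixtures("sequences")
  for (i in which(sq$mz_consistent)) {
    g <- parse_bbp(sq$notation[i], c_term = sq$c_term[i],
                   thioether = sq$thioether[i])
    mz <- adduct_mz(monoisotopic_mass(formula_of(g)), sq$printed_adduct[i])
    expect_lt(abs(mz$mz2 - sq$printed_mz[i]), 0.01 + 1e-9,
              label = paste(sq$id[i], mz$mz2))
  }
  fm <- load_fixtures("formulas_mz")
  for (i in which(fm$mz_consistent)) {
    g <- parse_bbp(fm$notation[i], c_term = fm$c_term[i],
                   thioether = fm$thioether[i])
    mz <- adduct_mz(monoisotopic_mass(formula_of(g)), fm$adduct[i])
    expect_lt(abs(mz$mz2 - fm$mz_printed[i]), 0.01 + 1e-9,
              label = paste(fm$id[i], fm$adduct[i], mz$mz2))
  }
})

test_that("bicyclic formulas differ from the linear chain by two waters", {
  sq <- load_fixtures("sequences")
  double_lactam <- sq[!sq$thioether, ]
  for (i in seq_len(nrow(double_lactam))) {
    g <- parse_bbp(double_lactam$notation[i])
    # strip the closure labels to get the linear precursor
    lin_not <- gsub("[12]", "", double_lactam$notation[i])
    lin <- parse_bbp(lin_not)
    f_cyc <- formula_of(g)
    f_lin <- formula_of(lin)
    expect_equal(ef_string(f_cyc + ef(H = 4, O = 2)), ef_string(f_lin),
                 info = double_lactam$id[i])
  }
  # adding one water back reproduces the printed monocyclic intermediate
  f1mono <- formula_of(parse_bbp("l1 G k f P E1 a"))
  f1 <- formula_of(parse_bbp("l1 G k2 f P E1 a2"))
  expect_equal(ef_string(f1 + ef(H = 2, O = 1)), ef_string(f1mono))
  expect_equal(ef_string(f1mono), "C36H54N8O9")
})
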
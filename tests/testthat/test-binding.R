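test_that("temperature coefficients classify on the stated thresholds", {
  expect_equal(classify_temp_coeff(1.7), "full")
  expect_equal(classify_temp_coeff(8.8), "none")
  expect_equal(classify_temp_coeff(4.0), "partial")  # boundary inclusive
  expect_equal(classify_temp_coeff(7.0), "partial")
  expect_equal(classify_temp_coeff(7.01), "none")
  expect_equal(classify_temp_coeff(-1.0), "full")
  expect_equal(classify_temp_coeff(c(3.9, NA)), c("full", NA))
})

test_that("the printed boldface partition is reproduced exactly", {
  tc <- load_fixtures("temp_coeffs")
  expect_equal(nrow(tc), 63)  # 7 protons x 9 compounds
  tc$class <- classify_temp_coeff(tc$coeff)
  determined <- !is.na(tc$coeff)
  expect_equal(sum(determined), 61)
  # boldface <=> fully H-bonded, plain <=> partial or none
  expect_identical(tc$class[determined] == "full", tc$bold[determined])
  expect_true(all(is.na(tc$class[!determined])))
})

test_that("Gibbs thermodynamics uses R = 1.98 cal/(mol K) and is exact", {
  expect_equal(thermodynamics(1, 0)$dG, 0)
  th <- thermodynamics(1 / 0.80e-6, -5, 298.15)
  expect_equal(th$dG, -8.29, tolerance = 0.005)
  for (Ka in c(1e3, 1e6, 1e9)) {
    th <- thermodynamics(Ka, -7.5, 310)
    expect_equal(th$dG, -7.5 - th$TdS, tolerance = 1e-12)
  }
})

test_that("the ITC isotherm shows the one-site limits", {
  e <- itc_experiment()
  # stoichiometric limit: huge Ka, heats track moles injected then vanish
  iso <- itc_model(1, 1e12, -5, e)
  moles_per_inj <- e$syringe * e$inj[1]
  expect_equal(iso$heat[1] * 1e-6, -5000 * moles_per_inj, tolerance = 0.01)
  expect_lt(abs(iso$heat[15]), abs(iso$heat[1]) / 1e3)
  # total heat equals dH times moles bound at saturation
  expect_equal(iso$Q[15] * 1e-6,
               -5000 * tail(bbpkit:::itc_concentrations(e)$Mt, 1) * e$V0,
               tolerance = 1e-3)
  # vanishing affinity produces vanishing heats
  expect_lt(max(abs(itc_model(1, 1e-9, -5, e)$heat)), 1e-6)
  # the sigmoid midpoint sits near molar ratio n
  for (n in c(0.5, 1, 2)) {
    iso <- itc_model(n, 1e8, -5, e <- itc_experiment(n_inj = 40))
    mid <- iso$molar_ratio[which.min(abs(iso$heat - iso$heat[1] / 2))]
    expect_equal(mid, n, tolerance = 0.15)
  }
  expect_error(itc_model(1, -1, -5), "Ka")
})

test_that("cumulative heats telescope with the displacement correction", {
  e <- itc_experiment()
  iso <- itc_model(1, 1.25e6, -5, e)
  corr <- (e$inj / e$V0) *
    (iso$Q + c(0, head(iso$Q, -1))) / 2
  expect_equal(sum(iso$heat - corr), tail(iso$Q, 1),
               tolerance = 1e-9 * abs(tail(iso$Q, 1)))
})

test_that("the ITC fitter recovers noiseless parameters across a KD grid", {
  e <- itc_experiment()
  for (KD_uM in c(0.01, 0.1, 1, 10, 100)) {
    Ka <- 1 / (KD_uM * 1e-6)
    iso <- itc_model(1, Ka, -5, e)
    fit <- suppressWarnings(fit_itc(iso, e))
    expect_lt(abs(fit$KD * 1e6 - KD_uM) / KD_uM, 1e-3)
    expect_equal(fit$n, 1, tolerance = 1e-3)
    expect_equal(fit$dH, -5, tolerance = 1e-3)
    expect_equal(fit$dG, fit$dH - fit$TdS, tolerance = 1e-12)
  }
})

test_that("flipping the enthalpy sign flips recovered dH only", {
  e <- itc_experiment()
  up <- suppressWarnings(fit_itc(itc_model(1, 1.25e6, 5, e), e))
  dn <- suppressWarnings(fit_itc(itc_model(1, 1.25e6, -5, e), e))
  expect_equal(up$dH, -dn$dH, tolerance = 1e-6)
  expect_equal(up$KD, dn$KD, tolerance = 1e-6)
})

test_that("ITC Monte-Carlo recovery stays within 10% median error", {
  e <- itc_experiment()
  true_KD <- 0.80e-6
  errs <- vapply(1:100, function(seed) {
    iso <- gen_itc(1, 1 / true_KD, -5, e, noise_sd = 0.02, seed = seed)
    fit <- tryCatch(suppressWarnings(fit_itc(iso, e)),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    abs(fit$KD - true_KD) / true_KD
  }, 0)
  expect_lt(stats::median(errs, na.rm = TRUE), 0.10)
})

test_that("the quadratic MST model has the right limits", {
  expect_equal(mst_model(4.5e-6, 1e-12, 4.5e-6), 0.5, tolerance = 1e-4)
  expect_equal(mst_model(0, 1e-9, 1e-6), 0)
  expect_equal(mst_model(1, 1e-9, 1e-6), 1, tolerance = 1e-5)
  expect_equal(mst_model(2e-6, 0, 1e-6), 2 / 3)  # excess-ligand limit
  # quadratic and hyperbolic forms agree within 0.1% at 10 nM protein
  L <- mst_design()$ligand
  fb_quad <- mst_model(L, 10e-9, 4.5e-6)
  fb_hyp <- L / (L + 4.5e-6)
  expect_true(all(abs(fb_quad - fb_hyp) < 1e-3))
  expect_error(mst_model(1e-6, 1e-9, 0), "KD")
})

test_that("the dilution series reproduces the printed endpoints", {
  pre <- dilution_series(500e-6, 2, 15)
  expect_equal(pre[1], 500e-6)
  expect_equal(pre[15] * 1e9, 30.5, tolerance = 0.01)
  post <- dilution_series(500e-6, 2, 15, mix = TRUE)
  expect_equal(post[1] * 1e6, 250)
  expect_equal(post[15] * 1e9, 15.3, tolerance = 0.01)
  expect_equal(dilution_series(7, levels = 1), 7)
})

test_that("the MST fitter recovers noiseless KD across a log grid", {
  d <- mst_design()
  for (KD_uM in c(0.05, 0.5, 4.5, 45, 100)) {
    ser <- gen_mst(KD_uM * 1e-6, d)
    fit <- fit_mst(ser, d$protein)
    expect_lt(abs(fit$KD * 1e6 - KD_uM) / KD_uM, 1e-3)
  }
})

test_that("degenerate MST series are flagged rather than fitted", {
  d <- mst_design()
  flat <- data.frame(ligand = d$ligand, signal = rep(0.5, length(d$ligand)))
  fit <- fit_mst(flat, d$protein)
  expect_false(fit$reliable)
  expect_true(is.na(fit$KD))
  # transition far above the measured range is flagged unreliable
  ser <- gen_mst(5e-2, d)
  fit2 <- fit_mst(ser, d$protein)
  expect_false(fit2$reliable)
})

test_that("MST Monte-Carlo recovery stays within 15% median error", {
  d <- mst_design()
  true_KD <- 4.5e-6
  errs <- vapply(1:100, function(seed) {
    ser <- gen_mst(true_KD, d, noise_sd = 0.05, seed = seed)
    fit <- tryCatch(fit_mst(ser, d$protein), error = function(e) NULL)
    if (is.null(fit) || is.na(fit$KD)) return(NA_real_)
    abs(fit$KD - true_KD) / true_KD
  }, 0)
  expect_lt(stats::median(errs, na.rm = TRUE), 0.15)
})
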
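# Amide-proton temperature-coefficient classification and quantitative
# binding models: one-set-of-sites ITC and 1:1 MST with least-squares fits.

R_GAS_KCAL <- 1.98e-3  # kcal mol^-1 K^-1, as used for Gibbs bookkeeping

#' Classify an amide-proton temperature coefficient
#'
#' Coefficients are -d(delta)/dT in ppb/K. Below 4.0 the proton counts as
#' fully hydrogen bonded, from 4.0 to 7.0 inclusive as partially bonded,
#' above 7.0 as not bonded. Negative coefficients are legal (strongly
#' shielded protons) and classify as full.
#'
#' @param coeff Numeric vector of coefficients (ppb/K); NA passes through.
#' @return Character vector: \code{"full"}, \code{"partial"}, \code{"none"}.
#' @examples
#' classify_temp_coeff(c(1.7, 4.0, 8.8))  # full partial none
#' @export
classify_temp_coeff <- function(coeff) {
  ifelse(is.na(coeff), NA_character_,
         ifelse(coeff < 4.0, "full",
                ifelse(coeff <= 7.0, "partial", "none")))
}

#' ITC experiment protocol
#'
#' Defaults follow a 200 uL cell of 50 uM macromolecule titrated with
#' fifteen 2.5 uL injections of 0.7 mM ligand at 25 C.
#'
#' @param V0_uL Cell volume (uL).
#' @param inj_uL Injection volumes (uL); a scalar is recycled to n_inj.
#' @param n_inj Number of injections.
#' @param syringe_mM Syringe (titrant) concentration (mM).
#' @param cell_uM Initial cell (macromolecule) concentration (uM).
#' @param temp_C Temperature (Celsius).
#' @return List of class \code{bbp_itc_experiment}.
#' @export
itc_experiment <- function(V0_uL = 200, inj_uL = 2.5, n_inj = 15,
                           syringe_mM = 0.7, cell_uM = 50, temp_C = 25) {
  inj <- rep_len(inj_uL, n_inj)
  stopifnot(V0_uL > 0, all(inj > 0), n_inj >= 1, syringe_mM > 0,
            cell_uM > 0)
  structure(list(V0 = V0_uL * 1e-6, inj = inj * 1e-6,
                 syringe = syringe_mM * 1e-3, cell0 = cell_uM * 1e-6,
                 temp_K = temp_C + 273.15),
            class = "bbp_itc_experiment")
}

# Effective cell concentrations after cumulative injected volume dV, with
# the instrument-style displacement correction (each injection expels fully
# mixed solution), or naive dilution.
itc_concentrations <- function(expt, displacement = TRUE) {
  dV <- cumsum(expt$inj)
  if (displacement) {
    f <- dV / (2 * expt$V0)
    Mt <- expt$cell0 * (1 - f) / (1 + f)
    Xt <- expt$syringe * (dV / expt$V0) / (1 + f)
  } else {
    Mt <- expt$cell0 * expt$V0 / (expt$V0 + dV)
    Xt <- expt$syringe * dV / (expt$V0 + dV)
  }
  list(Mt = Mt, Xt = Xt, dV = dV)
}

#' One-set-of-sites ITC isotherm
#'
#' Cumulative binding heat from the single-class quadratic binding equation
#' at the effective post-injection concentrations, differenced per injection
#' with a displaced-volume correction term.
#'
#' @param n Binding sites per macromolecule.
#' @param Ka Association constant (1/M).
#' @param dH Binding enthalpy (kcal/mol).
#' @param expt An \code{\link{itc_experiment}}.
#' @param displacement Use the displacement-corrected effective
#'   concentrations (default) or naive dilution.
#' @return data.frame: injection, molar_ratio, heat (ucal), Q (cumulative,
#'   ucal).
#' @export
itc_model <- function(n, Ka, dH, expt = itc_experiment(),
                      displacement = TRUE) {
  if (Ka <= 0) stop("Ka must be positive")
  if (n <= 0) stop("n must be positive")
  cc <- itc_concentrations(expt, displacement)
  Mt <- cc$Mt; Xt <- cc$Xt
  dH_cal <- dH * 1000  # cal/mol
  r <- Xt / (n * Mt)
  s <- 1 / (n * Ka * Mt)
  theta <- (1 + r + s - sqrt((1 + r + s)^2 - 4 * r)) / 2
  Q <- n * theta * Mt * dH_cal * expt$V0  # cal
  ninj <- length(expt$inj)
  dQ <- numeric(ninj)
  for (i in seq_len(ninj)) {
    Qprev <- if (i == 1) 0 else Q[i - 1]
    corr <- if (displacement)
      (expt$inj[i] / expt$V0) * (Q[i] + Qprev) / 2 else 0
    dQ[i] <- Q[i] - Qprev + corr
  }
  data.frame(injection = seq_len(ninj), molar_ratio = Xt / Mt,
             heat = dQ * 1e6, Q = Q * 1e6)
}

#' Binding thermodynamics from Ka and dH
#'
#' dG = -RT ln Ka with R = 1.98e-3 kcal/(mol K); dS = (dH - dG)/T.
#'
#' @param Ka Association constant (1/M).
#' @param dH Enthalpy (kcal/mol).
#' @param T_K Absolute temperature (K).
#' @return List: dG (kcal/mol), dS (kcal/(mol K)), TdS (kcal/mol).
#' @export
thermodynamics <- function(Ka, dH, T_K = 298.15) {
  stopifnot(Ka > 0, T_K > 0)
  dG <- -R_GAS_KCAL * T_K * log(Ka)
  dS <- (dH - dG) / T_K
  list(dG = dG, dS = dS, TdS = T_K * dS)
}

#' Fit the one-set-of-sites model to an ITC isotherm
#'
#' Least-squares estimation of (n, Ka, dH) with Ka on a log scale, completed
#' with the Gibbs thermodynamics at the experiment temperature. Warns when
#' the Wiseman c-value (n Ka Mt) leaves the informative ~1-1000 window.
#'
#' @param iso data.frame with a \code{heat} column (ucal per injection), as
#'   from \code{\link{itc_model}} or \code{\link{gen_itc}}.
#' @param expt The \code{\link{itc_experiment}} that produced it.
#' @param init Optional named list of starting values (n, Ka, dH).
#' @param displacement Concentration convention, as in \code{itc_model}.
#' @return A \code{bbp_binding_fit}: n, Ka, KD, dH, dG, dS, TdS, T_K,
#'   standard errors, residual norm, convergence info.
#' @export
fit_itc <- function(iso, expt = itc_experiment(), init = NULL,
                    displacement = TRUE) {
  heats <- iso$heat
  if (sum(is.finite(heats)) < 4) stop("need at least 4 informative injections")
  moles1 <- expt$syringe * expt$inj[1]
  dH0 <- if (!is.null(init$dH)) init$dH else heats[1] * 1e-6 / moles1 / 1000
  Ka0 <- if (!is.null(init$Ka)) init$Ka else 10 / expt$cell0
  n0 <- if (!is.null(init$n)) init$n else 1
  fit <- minpack.lm::nlsLM(
    heat ~ itc_model(n, exp(lKa), dH, expt, displacement)$heat,
    data = data.frame(heat = heats),
    start = list(n = n0, lKa = log(Ka0), dH = dH0),
    control = minpack.lm::nls.lm.control(maxiter = 1000))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  Ka <- exp(est[["lKa"]])
  th <- thermodynamics(Ka, est[["dH"]], expt$temp_K)
  cval <- est[["n"]] * Ka * expt$cell0
  if (cval < 1 || cval > 1000)
    warning(sprintf("c-value %.3g outside ~1-1000: KD poorly determined",
                    cval))
  structure(list(n = est[["n"]], Ka = Ka, KD = 1 / Ka, dH = est[["dH"]],
                 dG = th$dG, dS = th$dS, TdS = th$TdS, T_K = expt$temp_K,
                 se = se, c_value = cval,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = fit$convInfo$isConv, fit = fit),
            class = "bbp_binding_fit")
}

#' @export
print.bbp_binding_fit <- function(x, ...) {
  gv <- function(f) if (is.null(x[[f]])) NA_real_ else x[[f]]
  cat(sprintf("<binding fit> n = %.3f, KD = %.4g M, dH = %.3f kcal/mol\n",
              gv("n"), gv("KD"), gv("dH")))
  cat(sprintf("  dG = %.3f kcal/mol at %.2f K\n", gv("dG"), gv("T_K")))
  if (isFALSE(x$reliable)) cat("  flagged unreliable: ", x$reason, "\n")
  invisible(x)
}

#' Fraction of labeled protein bound in a 1:1 equilibrium
#'
#' Exact quadratic solution; the P = 0 limit reduces to the excess-ligand
#' hyperbola L/(L + KD).
#'
#' @param L Total ligand concentration(s) (M).
#' @param P Total labeled protein concentration (M).
#' @param KD Dissociation constant (M).
#' @return Fraction bound in [0, 1].
#' @export
mst_model <- function(L, P, KD) {
  stopifnot(all(L >= 0), P >= 0, KD > 0)
  if (P == 0) return(L / (L + KD))
  s <- P + L + KD
  (s - sqrt(s^2 - 4 * P * L)) / (2 * P)
}

#' Serial dilution series
#'
#' Geometric series top/factor^k for k = 0..levels-1; an optional final 1:1
#' mixing step (as when ligand dilutions are mixed with an equal volume of
#' labeled protein) halves every concentration.
#'
#' @param top Highest concentration.
#' @param factor Dilution factor (> 1).
#' @param levels Number of levels (>= 1).
#' @param mix Apply the 1:1 mixing step.
#' @return Numeric vector, decreasing.
#' @export
dilution_series <- function(top, factor = 2, levels = 15, mix = FALSE) {
  stopifnot(factor > 1, levels >= 1)
  out <- top / factor^(0:(levels - 1))
  if (mix) out <- out / 2
  out
}

#' MST assay design
#'
#' Defaults follow a 10 nM labeled protein and a 2-fold, 15-level ligand
#' series from 500 uM, mixed 1:1 with the protein (final 250 uM down to
#' 15.3 nM).
#'
#' @param protein_nM Labeled protein concentration after mixing (nM).
#' @param top_uM Pre-mixing top ligand concentration (uM).
#' @param factor,levels Dilution series parameters.
#' @param mix Apply the 1:1 mixing step to the ligand series.
#' @return List: ligand (M, decreasing), protein (M).
#' @export
mst_design <- function(protein_nM = 10, top_uM = 500, factor = 2,
                       levels = 15, mix = TRUE) {
  list(ligand = dilution_series(top_uM * 1e-6, factor, levels, mix),
       protein = protein_nM * 1e-9)
}

#' Fit a 1:1 binding model to an MST dose-response series
#'
#' Least squares over (KD, S_free, S_bound) with KD on a log scale. The fit
#' is flagged unreliable when the series shows no transition or the fitted
#' KD falls outside the measured concentration range.
#'
#' @param series data.frame with columns ligand (M) and signal.
#' @param protein Labeled protein concentration (M).
#' @param init Optional starting values (KD, s_free, s_bound).
#' @return A \code{bbp_binding_fit} with elements KD, Ka, s_free, s_bound,
#'   dG at 298.15 K, reliability flag and diagnostics.
#' @export
fit_mst <- function(series, protein = 10e-9, init = NULL) {
  stopifnot(nrow(series) >= 6)
  sig <- series$signal; L <- series$ligand
  amp <- diff(range(sig))
  if (amp < 1e-12 * max(1, max(abs(sig)))) {
    return(structure(list(KD = NA_real_, Ka = NA_real_, reliable = FALSE,
                          reason = "no transition in signal", se = NA),
                     class = "bbp_binding_fit"))
  }
  KD0 <- if (!is.null(init$KD)) init$KD else exp(mean(log(range(L))))
  s_free0 <- if (!is.null(init$s_free)) init$s_free else
    sig[which.min(L)]
  s_bound0 <- if (!is.null(init$s_bound)) init$s_bound else
    sig[which.max(L)]
  fit <- minpack.lm::nlsLM(
    signal ~ s_free + (s_bound - s_free) * mst_model(ligand, protein, exp(lKD)),
    data = data.frame(signal = sig, ligand = L),
    start = list(lKD = log(KD0), s_free = s_free0, s_bound = s_bound0),
    control = minpack.lm::nls.lm.control(maxiter = 1000))
  est <- stats::coef(fit)
  KD <- exp(est[["lKD"]])
  reliable <- KD >= min(L) && KD <= max(L)
  th <- thermodynamics(1 / KD, NA_real_, 298.15)
  structure(list(KD = KD, Ka = 1 / KD, s_free = est[["s_free"]],
                 s_bound = est[["s_bound"]], dG = th$dG,
                 T_K = 298.15, reliable = reliable,
                 reason = if (reliable) "" else "KD outside measured range",
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = fit$convInfo$isConv, fit = fit),
            class = "bbp_binding_fit")
}
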
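#' Photosynthesis model parameters
#'
#' Parameter set for steady-state A-Ci curves after the
#' Farquhar-von Caemmerer-Berry C3 model and a simplified enzyme-limited C4
#' model. Kinetic constants default to the standard tobacco-derived values at
#' 25 degC (Kc = 404 ubar, Ko = 248 mbar, O = 205 mbar, Gamma* = 38.6 ubar).
#' Day respiration Rd is rarely printed with published curves; the default is
#' 0.01 x Vcmax and is declared, not inferred.
#'
#' @param model `"C3"` or `"C4"`.
#' @param vcmax Maximum Rubisco carboxylation rate, umol m-2 s-1
#'   (defaults: 77 for C3, 35 for C4, matching comparable maximum rates).
#' @param jmax Maximum electron transport rate, umol m-2 s-1 (C3 only;
#'   default 144).
#' @param rd Day respiration, umol m-2 s-1.
#' @param kc Michaelis constant of Rubisco for CO2, ubar.
#' @param ko Michaelis constant of Rubisco for O2, mbar.
#' @param o Oxygen partial pressure, mbar.
#' @param gamma_star CO2 compensation point in the absence of Rd, ubar.
#' @param vpmax Maximum PEP carboxylation rate, umol m-2 s-1 (C4 only).
#' @param kp Michaelis constant of PEPC for CO2, ubar (C4 only).
#' @return Object of class `aci_params`.
#' @export
aci_params <- function(model = c("C3", "C4"),
                       vcmax = if (model == "C4") 35 else 77,
                       jmax = 144,
                       rd = 0.01 * vcmax,
                       kc = 404, ko = 248, o = 205, gamma_star = 38.6,
                       vpmax = 120, kp = 80) {
  model <- match.arg(model)
  p <- list(model = model, vcmax = vcmax, jmax = jmax, rd = rd, kc = kc,
            ko = ko, o = o, gamma_star = gamma_star, vpmax = vpmax, kp = kp)
  num <- unlist(p[-1])
  if (any(!is.finite(num)) || any(num <= 0)) {
    c4_abort("all model parameters must be positive", "invalid_spec")
  }
  if (rd >= vcmax) c4_abort("rd must be smaller than vcmax", "invalid_spec")
  structure(p, class = "aci_params")
}

#' Net CO2 assimilation of the C3 model
#'
#' `A = min(Ac, Aj) - Rd` with the Rubisco-limited rate
#' `Ac = Vcmax (Ci - Gamma*) / (Ci + Kc (1 + O/Ko))` and the
#' RuBP-regeneration-limited rate `Aj = J (Ci - Gamma*) / (4 Ci + 8 Gamma*)`
#' at saturating light (`J = Jmax`).
#'
#' @param ci Intercellular CO2 partial pressure, ubar (vectorised).
#' @param p An [aci_params()] with `model = "C3"`.
#' @return data.frame with `ci`, `a` and the `limiting` process.
#' @export
c3_assimilation <- function(ci, p = aci_params("C3")) {
  if (any(ci <= 0)) c4_abort("ci must be positive", "invalid_parameter")
  stopifnot(p$model == "C3")
  ac <- p$vcmax * (ci - p$gamma_star) / (ci + p$kc * (1 + p$o / p$ko))
  aj <- p$jmax * (ci - p$gamma_star) / (4 * ci + 8 * p$gamma_star)
  a <- pmin(ac, aj) - p$rd
  data.frame(ci = ci, a = a,
             limiting = ifelse(ac <= aj, "rubisco", "rubp-regeneration"))
}

#' Net CO2 assimilation of the simplified C4 model
#'
#' Enzyme-limited two-regime form: `A = min(Vp, Vcmax) - Rd` with the PEP
#' carboxylation rate `Vp = Vpmax Ci / (Ci + Kp)`. It reproduces the
#' qualitative C4 contrast (much steeper initial slope, saturation at
#' Vcmax); bundle-sheath leakiness is deliberately omitted.
#'
#' @inheritParams c3_assimilation
#' @param p An [aci_params()] with `model = "C4"`.
#' @return data.frame with `ci`, `a` and the `limiting` process.
#' @export
c4_assimilation <- function(ci, p = aci_params("C4")) {
  if (any(ci < 0)) c4_abort("ci must be non-negative", "invalid_parameter")
  stopifnot(p$model == "C4")
  vp <- p$vpmax * ci / (ci + p$kp)
  a <- pmin(vp, p$vcmax) - p$rd
  data.frame(ci = ci, a = a,
             limiting = ifelse(vp <= p$vcmax, "pep-carboxylation", "rubisco"))
}

# Dispatch on p$model.
assimilation <- function(ci, p) {
  if (p$model == "C3") c3_assimilation(ci, p) else c4_assimilation(ci, p)
}

#' Modeled A-Ci curve over a Ci grid
#'
#' @param ci_grid Vector of Ci values, ubar.
#' @param p An [aci_params()].
#' @return data.frame of class `aci_curve` with `ci`, `a`, `limiting`.
#' @export
model_curve <- function(ci_grid, p) {
  out <- assimilation(sort(ci_grid), p)
  class(out) <- c("aci_curve", "data.frame")
  out
}

#' CO2 compensation point by bracketing bisection
#'
#' Finds the Ci at which net assimilation is zero, to `tol` ubar. For the C3
#' model with Rd = 0 this is exactly Gamma*; with Rd > 0 it matches the
#' algebraic root of `Ac - Rd = 0`.
#'
#' @param p An [aci_params()].
#' @param lower,upper Bracketing interval, ubar.
#' @param tol Absolute tolerance, ubar.
#' @return Compensation point in ubar.
#' @export
compensation_point <- function(p, lower = 1e-4, upper = 200, tol = 1e-3) {
  f <- function(ci) assimilation(ci, p)$a
  lo <- lower; hi <- upper
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    c4_abort("no sign change in the bisection bracket", "no_root")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (flo * fm <= 0) { hi <- mid } else { lo <- mid; flo <- fm }
  }
  (lo + hi) / 2
}

#' Classify observed gas exchange as C3 or C4
#'
#' Computes the RMSE of the observations against each fixed-parameter model
#' curve and returns the better-fitting model; no parameters are fitted.
#'
#' @param obs data.frame with columns `ci` (ubar) and `a` (umol m-2 s-1).
#' @param c3_params,c4_params Model parameter sets.
#' @return List with `verdict` (`"C3"` or `"C4"`), `rmse` (named vector)
#'   and `margin` (RMSE difference).
#' @export
classify_observations <- function(obs, c3_params = aci_params("C3"),
                                  c4_params = aci_params("C4")) {
  if (nrow(obs) < 4) c4_abort("need >= 4 observation points", "insufficient_range")
  if (diff(range(obs$ci)) < 50) {
    c4_abort("ci range too narrow to separate the models", "insufficient_range")
  }
  rmse <- c(
    C3 = sqrt(mean((obs$a - c3_assimilation(obs$ci, c3_params)$a)^2)),
    C4 = sqrt(mean((obs$a - c4_assimilation(obs$ci, c4_params)$a)^2)))
  verdict <- names(rmse)[which.min(rmse)]
  list(verdict = verdict, rmse = rmse, margin = abs(diff(rmse))[[1]])
}

#' Measurement pressures of the reference gas-exchange protocol
#'
#' The CO2 response measurement grid in Pa, converted to ubar
#' (1 Pa = 10 ubar).
#'
#' @return Numeric vector of Ci values in ubar, ascending.
#' @export
default_ci_grid <- function() {
  sort(c(25, 19.4, 16.6, 13.5, 7.6, 4.7, 36.7, 60.4, 140.3) * 10)
}

#' Simulate noisy gas-exchange observations from a model curve
#'
#' @param model `"C3"` or `"C4"`.
#' @param params An [aci_params()]; defaults to the model's defaults.
#' @param ci_grid Ci values in ubar.
#' @param noise_sd Gaussian noise s.d. on A, umol m-2 s-1.
#' @param seed Integer seed.
#' @return data.frame with `ci` and `a`.
#' @export
simulate_aci <- function(model = c("C3", "C4"), params = aci_params(model),
                         ci_grid = default_ci_grid(), noise_sd = 0.5,
                         seed = 1L) {
  model <- match.arg(model)
  if (any(ci_grid <= 0)) c4_abort("ci_grid must be positive", "invalid_spec")
  set.seed(seed)
  curve <- model_curve(ci_grid, params)
  data.frame(ci = curve$ci, a = curve$a + rnorm(nrow(curve), 0, noise_sd))
}
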
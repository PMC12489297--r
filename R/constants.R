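#' Kinetic and respiratory constants for the enzyme-limited C4 model
#'
#' Bundles every fixed parameter used by the forward equations, the curve
#' fits and the quality filters, so that any fit is reproducible from the
#' data plus one constants record. Defaults are the standard literature
#' values for C4 leaves.
#'
#' @param kp25 Michaelis constant of PEP carboxylase for CO2 at 25 degC
#'   (ubar). Default 80.
#' @param ea_kp Activation energy of Kp (kJ mol-1). Default 36.3.
#' @param gas_const Molar gas constant (kJ K-1 mol-1). Default 0.008314.
#' @param rday25 Daytime mitochondrial respiration at 25 degC
#'   (umol CO2 m-2 s-1). Default 1.2.
#' @param q10 Q10 of daytime respiration (unitless). Default 2.
#' @param theta Curvature of the non-rectangular hyperbola (unitless,
#'   in [0, 1]). Default 0.7.
#' @param co2_solubility CO2 solubility (mol bar-1). Stored as metadata;
#'   not used by the default ubar-to-mole-fraction conversion. Default 0.0334.
#' @param rm_fraction Fraction of Rday attributed to the mesophyll, so that
#'   Rm = rm_fraction * Rday. Default 0.5.
#'
#' @return An object of class \code{"kinetic_constants"}: a named list of the
#'   validated parameter values.
#' @examples
#' kc <- kinetic_constants()
#' kp_at_temperature(35, kc)
#' @export
kinetic_constants <- function(kp25 = 80, ea_kp = 36.3, gas_const = 0.008314,
                              rday25 = 1.2, q10 = 2, theta = 0.7,
                              co2_solubility = 0.0334, rm_fraction = 0.5) {
  stopifnot(
    is.numeric(kp25), length(kp25) == 1L, is.finite(kp25), kp25 > 0,
    is.numeric(ea_kp), length(ea_kp) == 1L, is.finite(ea_kp),
    is.numeric(gas_const), length(gas_const) == 1L, gas_const > 0,
    is.numeric(rday25), length(rday25) == 1L, rday25 >= 0,
    is.numeric(q10), length(q10) == 1L, q10 > 0,
    is.numeric(theta), length(theta) == 1L, theta >= 0, theta <= 1,
    is.numeric(co2_solubility), length(co2_solubility) == 1L,
    is.numeric(rm_fraction), length(rm_fraction) == 1L,
    rm_fraction >= 0, rm_fraction <= 1
  )
  structure(
    list(kp25 = kp25, ea_kp = ea_kp, gas_const = gas_const,
         rday25 = rday25, q10 = q10, theta = theta,
         co2_solubility = co2_solubility, rm_fraction = rm_fraction),
    class = "kinetic_constants"
  )
}

#' @export
print.kinetic_constants <- function(x, ...) {
  cat("C4 model constants:\n")
  cat(sprintf("  Kp25      %.4g ubar    Ea(Kp) %.4g kJ/mol\n", x$kp25, x$ea_kp))
  cat(sprintf("  Rday25    %.4g umol/m2/s    Q10 %.4g    Rm = %.2g * Rday\n",
              x$rday25, x$q10, x$rm_fraction))
  cat(sprintf("  theta     %.4g    CO2 solubility %.4g mol/bar\n",
              x$theta, x$co2_solubility))
  invisible(x)
}

#' Read kinetic constants from a key = value config file
#'
#' Plain-text configuration: one `key = value` pair per line, `#` comments
#' allowed. Keys are the argument names of [kinetic_constants()]; keys not
#' present keep their defaults.
#'
#' @param path Path to the config file.
#' @return A \code{"kinetic_constants"} object.
#' @export
read_constants_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!all(grepl("=", lines, fixed = TRUE)))
    stop("config lines must be 'key = value' pairs")
  keys <- trimws(sub("=.*$", "", lines))
  vals <- suppressWarnings(as.numeric(trimws(sub("^[^=]*=", "", lines))))
  if (anyNA(vals)) stop("non-numeric value for key(s): ",
                        paste(keys[is.na(vals)], collapse = ", "))
  known <- names(formals(kinetic_constants))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown constant(s): ", paste(bad, collapse = ", "))
  do.call(kinetic_constants, as.list(stats::setNames(vals, keys)))
}

#' Temperature response of the PEPc Michaelis constant
#'
#' Arrhenius-type adjustment of Kp away from the 25 degC reference:
#' Kp = Kp25 * exp(Ea * (Tleaf - 25) / (298.15 * R * (Tleaf + 273.15))).
#'
#' @param tleaf Leaf temperature (degC); vectorised.
#' @param constants A [kinetic_constants()] object.
#' @return Kp at \code{tleaf}, in ubar.
#' @export
kp_at_temperature <- function(tleaf, constants = kinetic_constants()) {
  if (!is.numeric(tleaf) || any(!is.finite(tleaf)))
    stop("tleaf must be finite numeric")
  if (any(tleaf <= -10 | tleaf >= 60))
    stop("tleaf outside plausible leaf-temperature range (-10, 60) degC")
  constants$kp25 * exp(constants$ea_kp * (tleaf - 25) /
                         (298.15 * constants$gas_const * (tleaf + 273.15)))
}

#' Convert Kp from ubar to a mole fraction
#'
#' Divides the partial-pressure Michaelis constant by total atmospheric
#' pressure so that Kp is commensurate with Ci expressed in umol mol-1.
#'
#' @param kp_ubar Kp in ubar.
#' @param pressure Atmospheric pressure in bar (default 1.013, sea level).
#' @return Kp in umol mol-1.
#' @export
kp_to_mole_fraction <- function(kp_ubar, pressure = 1.013) {
  if (!is.numeric(pressure) || any(!is.finite(pressure)) || any(pressure <= 0))
    stop("pressure must be positive and finite (bar)")
  kp_ubar / pressure
}

#' Temperature response of daytime respiration (Q10)
#'
#' Rday = Rday25 * Q10^((Tleaf - 25) / 10). The mesophyll component used by
#' the initial-slope model is Rm = rm_fraction * Rday.
#'
#' @inheritParams kp_at_temperature
#' @return Rday at \code{tleaf}, in umol CO2 m-2 s-1.
#' @export
rday_at_temperature <- function(tleaf, constants = kinetic_constants()) {
  if (!is.numeric(tleaf) || any(!is.finite(tleaf)))
    stop("tleaf must be finite numeric")
  constants$rday25 * constants$q10 ^ ((tleaf - 25) / 10)
}

#' PEP-carboxylation-limited net assimilation
#'
#' Michaelis-Menten initial-slope model of the C4 A/Ci curve:
#' A = Ci * VpmaxA / (Ci + Kp) - Rm. Valid where assimilation is limited by
#' PEPc activity (low Ci).
#'
#' @param ci Intercellular CO2 (umol mol-1); vectorised, non-negative.
#' @param vpmax Apparent maximal PEPc activity (umol m-2 s-1).
#' @param kp Michaelis constant as a mole fraction (umol mol-1).
#' @param rm Mesophyll daytime respiration (umol m-2 s-1).
#' @return Net assimilation A (umol CO2 m-2 s-1).
#' @export
vp_limited_assimilation <- function(ci, vpmax, kp, rm) {
  if (any(!is.finite(ci)) || any(ci < 0)) stop("ci must be finite and >= 0")
  stopifnot(vpmax >= 0, kp > 0)
  ci * vpmax / (ci + kp) - rm
}

#' Non-rectangular hyperbola for the full A/Ci curve
#'
#' Solves theta*X^2 - (alpha*Ci + Amax)*X + alpha*Ci*Amax = 0 for
#' X = A + Rday, taking the smaller (physical) root, and returns
#' A = X - Rday. Amax is the horizontal asymptote of A + Rday; alpha is the
#' initial slope. At theta = 0 the closed-form rectangular hyperbola
#' X = alpha*Ci*Amax / (alpha*Ci + Amax) is used.
#'
#' @param ci Intercellular CO2 (umol mol-1); vectorised.
#' @param alpha Initial slope (umol m-2 s-1 per umol mol-1), >= 0.
#' @param amax Asymptote of A + Rday (umol m-2 s-1), > 0.
#' @param theta Curvature in [0, 1].
#' @param rday Daytime respiration (umol m-2 s-1).
#' @return Net assimilation A (umol CO2 m-2 s-1).
#' @export
nrh_assimilation <- function(ci, alpha, amax, theta, rday) {
  if (any(!is.finite(ci)) || any(ci < 0)) stop("ci must be finite and >= 0")
  stopifnot(alpha >= 0, amax > 0, theta >= 0, theta <= 1)
  aci <- alpha * ci
  if (theta == 0) {
    denom <- aci + amax
    x <- ifelse(denom > 0, aci * amax / denom, 0)
  } else {
    b <- aci + amax
    disc <- b^2 - 4 * theta * aci * amax
    if (any(disc < -1e-8 * amax^2)) stop("negative discriminant in hyperbola root")
    disc <- pmax(disc, 0)
    # smaller root written without the b - sqrt(disc) cancellation, which
    # loses precision as theta -> 0
    x <- 2 * aci * amax / (b + sqrt(disc))
  }
  x - rday
}

#' Forward A/Ci curve blending the two limitation regimes
#'
#' Forward model used by the synthetic generator: the gross rate is either
#' the hard minimum of the PEPc-limited rate Vp(Ci) = Ci*vpmax/(Ci+kp) and a
#' CO2-saturated ceiling, or a smooth quadratic blend of the two (smaller
#' root of theta_blend*G^2 - (Vp + amax_gross)*G + Vp*amax_gross = 0). Net
#' assimilation is the gross rate minus rday.
#'
#' @param ci Intercellular CO2 (umol mol-1); vectorised.
#' @param vpmax Maximal PEPc activity (umol m-2 s-1).
#' @param amax_gross Gross CO2-saturated rate (umol m-2 s-1).
#' @param kp Kp as a mole fraction (umol mol-1).
#' @param rday Daytime respiration (umol m-2 s-1).
#' @param theta_blend Blending curvature in (0, 1); used by
#'   \code{"quadratic_blend"} only.
#' @param mode \code{"hard_min"} or \code{"quadratic_blend"}.
#' @return Net assimilation A (umol CO2 m-2 s-1).
#' @export
blended_forward_curve <- function(ci, vpmax, amax_gross, kp, rday,
                                  theta_blend = 0.99,
                                  mode = c("hard_min", "quadratic_blend")) {
  mode <- tryCatch(match.arg(mode),
                   error = function(e) stop("unknown blend mode"))
  if (any(!is.finite(ci)) || any(ci < 0)) stop("ci must be finite and >= 0")
  stopifnot(vpmax >= 0, amax_gross > 0, kp > 0)
  vp <- ci * vpmax / (ci + kp)
  g <- if (mode == "hard_min") {
    pmin(vp, amax_gross)
  } else {
    stopifnot(theta_blend > 0, theta_blend < 1)
    b <- vp + amax_gross
    (b - sqrt(pmax(b^2 - 4 * theta_blend * vp * amax_gross, 0))) /
      (2 * theta_blend)
  }
  g - rday
}
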
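#' Entropy / internal-energy decomposition of a permeation free energy
#'
#' In the NVT ensemble dA = -S dT - p dV + mu dN, so at fixed volume and
#' composition the entropy contribution follows from the temperature
#' derivative of the free-energy profile. With profiles at T - dT, T and
#' T + dT the central finite difference gives
#'
#'   -T dS(z) = T / (2 dT) * (A_high(z) - A_low(z))
#'   dU(z)    = A_base(z) + T dS(z)
#'
#' The estimate is exact for profile families linear in T and has O(dT^2)
#' error otherwise. Standard errors propagate in quadrature with the same
#' prefactors.
#'
#' @param pmf_low,pmf_base,pmf_high [pmf_profile]s at T - dT, T and T + dT on
#'   a shared grid; the temperature triplet must be symmetric.
#' @return An object of class `thermo_decomposition` with aligned `dA`,
#'   `minus_TdS` and `dU` curves (`dA = dU + minus_TdS` holds identically).
#' @examples
#' fam <- gen_pmf_family(pmf_spec("neutral"), c(305, 310, 315), seed = 1)
#' td <- decompose_thermo(fam[[1]], fam[[2]], fam[[3]])
#' @export
decompose_thermo <- function(pmf_low, pmf_base, pmf_high) {
  stopifnot(inherits(pmf_low, "pmf_profile"),
            inherits(pmf_base, "pmf_profile"),
            inherits(pmf_high, "pmf_profile"))
  check_same_grid(pmf_low, pmf_base)
  check_same_grid(pmf_base, pmf_high)
  t0 <- pmf_base$temperature
  dt_lo <- t0 - pmf_low$temperature
  dt_hi <- pmf_high$temperature - t0
  if (dt_lo <= 0 || dt_hi <= 0 || abs(dt_lo - dt_hi) > 1e-9) {
    stop("temperatures must form a symmetric triplet T - dT, T, T + dT")
  }
  pref <- t0 / (2 * dt_hi)
  minus_tds <- pref * (pmf_high$value - pmf_low$value)
  du <- pmf_base$value - minus_tds
  se_tds <- pref * sqrt(pmf_high$stderr^2 + pmf_low$stderr^2)
  se_du <- sqrt(pmf_base$stderr^2 + se_tds^2)
  structure(list(z = pmf_base$z, dA = pmf_base$value, minus_TdS = minus_tds,
                 dU = du, base_T = t0, delta_T = dt_hi,
                 stderr = list(dA = pmf_base$stderr, minus_TdS = se_tds,
                               dU = se_du)),
            class = "thermo_decomposition")
}

#' @export
print.thermo_decomposition <- function(x, ...) {
  cat(sprintf(
    "Thermodynamic decomposition at T = %g K (dT = %g K), %d grid points\n",
    x$base_T, x$delta_T, length(x$z)))
  cat(sprintf("  -TdS in [%.2f, %.2f], dU in [%.2f, %.2f] kcal/mol\n",
              min(x$minus_TdS), max(x$minus_TdS), min(x$dU), max(x$dU)))
  invisible(x)
}

#' Entropy-enthalpy compensation regression
#'
#' Ordinary least squares of dU (response) on -TdS (predictor) over the
#' selected grid points. A slope near -1 signals near-perfect compensation;
#' slopes below -1 indicate internal-energy-driven behavior and slopes above
#' -1 an entropy-led pathway.
#'
#' @param decomp a [decompose_thermo] result.
#' @param z_mask logical vector over the grid, or a numeric interval
#'   `c(lo, hi)` in Angstrom; default uses every grid point.
#' @return An object of class `compensation_fit` with `slope`, `intercept`
#'   (kcal/mol), `pearson_r`, `n_points` and `slope_stderr`.
#' @export
compensation_fit <- function(decomp, z_mask = NULL) {
  stopifnot(inherits(decomp, "thermo_decomposition"))
  if (is.null(z_mask)) {
    mask <- rep(TRUE, length(decomp$z))
  } else if (is.logical(z_mask)) {
    stopifnot(length(z_mask) == length(decomp$z))
    mask <- z_mask
  } else {
    stopifnot(is.numeric(z_mask), length(z_mask) == 2L)
    mask <- decomp$z >= z_mask[1L] & decomp$z <= z_mask[2L]
  }
  mask <- mask & is.finite(decomp$dU) & is.finite(decomp$minus_TdS)
  if (sum(mask) < 3L) stop("compensation fit needs at least 3 grid points")
  xx <- decomp$minus_TdS[mask]
  yy <- decomp$dU[mask]
  if (stats::var(xx) == 0) stop("zero variance in -TdS over the mask")
  fit <- stats::lm(yy ~ xx)
  ## an exactly collinear input (perfect compensation) is legitimate here
  co <- suppressWarnings(summary(fit))$coefficients
  structure(list(slope = unname(co["xx", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 pearson_r = stats::cor(xx, yy),
                 n_points = sum(mask),
                 slope_stderr = unname(co["xx", "Std. Error"]),
                 data = data.frame(minus_TdS = xx, dU = yy)),
            class = "compensation_fit")
}

#' @export
print.compensation_fit <- function(x, ...) {
  cat(sprintf(
    "Compensation fit: slope %.3f +/- %.3f, intercept %.3f kcal/mol, r = %.3f (n = %d)\n",
    x$slope, x$slope_stderr, x$intercept, x$pearson_r, x$n_points))
  invisible(x)
}

#' Position-dependent pKa from a thermodynamic cycle
#'
#' Closing the deprotonation cycle between bulk water and membrane depth z
#' with the transfer free energies of the neutral base A and the protonated
#' acid AH+ gives
#'
#'   pKa(z) = pKa_water + (dA_neutral(z) - dA_charged(z)) / (ln(10) R T)
#'
#' with both profiles referenced to bulk water (= 0). Where the neutral form
#' is the more stable of the two, the pKa drops below its water value and
#' the compound deprotonates upon insertion.
#'
#' @param pmf_neutral,pmf_charged [pmf_profile]s on one grid, both referenced
#'   to bulk water.
#' @param pka_water aqueous pKa of the compound.
#' @param temperature Kelvin; defaults to the profiles' temperature.
#' @return An object of class `pka_profile` with `z`, `pka`, `stderr`.
#' @export
pka_profile <- function(pmf_neutral, pmf_charged, pka_water = 9.6,
                        temperature = NULL) {
  stopifnot(inherits(pmf_neutral, "pmf_profile"),
            inherits(pmf_charged, "pmf_profile"))
  check_same_grid(pmf_neutral, pmf_charged)
  if (is.na(pmf_neutral$reference) || is.na(pmf_charged$reference)) {
    stop("both PMFs must be referenced (bulk water) before the pKa cycle")
  }
  if (is.null(temperature)) temperature <- pmf_neutral$temperature
  denom <- log(10) * gas_constant() * temperature
  pka <- pka_water + (pmf_neutral$value - pmf_charged$value) / denom
  se <- sqrt(pmf_neutral$stderr^2 + pmf_charged$stderr^2) / denom
  structure(list(z = pmf_neutral$z, pka = pka, stderr = se,
                 pka_water = pka_water, temperature = temperature),
            class = "pka_profile")
}

#' @export
print.pka_profile <- function(x, ...) {
  cat(sprintf(
    "pKa profile: water pKa %.2f, T = %g K, range [%.2f, %.2f] over %d points\n",
    x$pka_water, x$temperature, min(x$pka, na.rm = TRUE),
    max(x$pka, na.rm = TRUE), length(x$z)))
  invisible(x)
}

#' Locate where a pKa profile crosses a target value
#'
#' Scans the grid for sign changes of `pka(z) - target_pka` and places each
#' crossing by linear interpolation between the flanking nodes. At
#' physiological target pKa 7 the crossings mark the depths where the
#' dominant protonation state switches.
#'
#' @param profile a [pka_profile].
#' @param target_pka crossing level (default 7).
#' @return Numeric vector of crossing positions in Angstrom (possibly empty).
#' @export
find_pka_crossing <- function(profile, target_pka = 7.0) {
  stopifnot(inherits(profile, "pka_profile"))
  d <- profile$pka - target_pka
  z <- profile$z
  out <- z[which(d == 0)]
  s <- which(d[-1] * d[-length(d)] < 0)
  for (i in s) {
    out <- c(out, z[i] + (z[i + 1] - z[i]) * d[i] / (d[i] - d[i + 1]))
  }
  sort(unname(out))
}
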
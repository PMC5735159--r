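#' Potential of mean force (PMF) profile
#'
#' Container for a free-energy profile A(z) of one species at one temperature
#' along the membrane normal z, with the bilayer center at z = 0 and bulk
#' water at large |z|. Values are in kcal/mol on a strictly increasing,
#' uniform z grid (Angstrom).
#'
#' @param z numeric, uniform strictly increasing grid in Angstrom.
#' @param value free energy in kcal/mol; may contain `NA` for unsampled bins.
#' @param stderr per-point standard error (kcal/mol); scalar is recycled.
#' @param temperature temperature in Kelvin.
#' @param species `"neutral"` (conjugate base) or `"charged"` (protonated acid).
#' @param reference descriptor of the zero point, e.g. `"bulk_water"`, or
#'   `NA` for an unreferenced profile.
#' @return An object of class `pmf_profile`.
#' @examples
#' p <- pmf_profile(z = seq(-30, 30, 0.5), value = 0, temperature = 310)
#' @export
pmf_profile <- function(z, value, stderr = 0, temperature,
                        species = c("neutral", "charged"),
                        reference = "bulk_water") {
  species <- match.arg(species)
  z <- as.numeric(z)
  if (length(value) == 1L) value <- rep(as.numeric(value), length(z))
  if (length(stderr) == 1L) stderr <- rep(as.numeric(stderr), length(z))
  if (length(z) < 2L) stop("PMF grid needs at least two points")
  if (length(value) != length(z) || length(stderr) != length(z)) {
    stop("z, value and stderr must have equal length")
  }
  dz <- diff(z)
  if (any(dz <= 0)) stop("z grid must be strictly increasing")
  if (any(abs(dz - dz[1L]) > 1e-6 * dz[1L])) stop("z grid must be uniform")
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  structure(
    list(z = z, value = as.numeric(value), stderr = as.numeric(stderr),
         temperature = as.numeric(temperature), species = species,
         reference = reference),
    class = "pmf_profile"
  )
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf(
    "PMF profile: %s species, T = %g K, %d points on [%g, %g] A (step %g A)\n",
    x$species, x$temperature, length(x$z), min(x$z), max(x$z), x$z[2] - x$z[1]))
  rng <- range(x$value, na.rm = TRUE)
  cat(sprintf("  values in [%.3f, %.3f] kcal/mol, reference: %s\n",
              rng[1], rng[2],
              if (is.na(x$reference)) "none" else x$reference))
  invisible(x)
}

grid_step <- function(pmf) pmf$z[2L] - pmf$z[1L]

#' Symmetrize a PMF about the bilayer center
#'
#' Averages A(z) with A(-z); standard errors are combined in quadrature over
#' each mirror pair. The grid must be symmetric about z = 0.
#'
#' @param pmf a [pmf_profile].
#' @return A symmetrized `pmf_profile`.
#' @export
symmetrize <- function(pmf) {
  stopifnot(inherits(pmf, "pmf_profile"))
  tol <- 1e-6 * grid_step(pmf)
  mirrored <- rev(pmf$z)
  if (any(abs(pmf$z + mirrored) > tol)) {
    stop("grid is not symmetric about z = 0; cannot symmetrize")
  }
  value <- (pmf$value + rev(pmf$value)) / 2
  stderr <- sqrt(pmf$stderr^2 + rev(pmf$stderr)^2) / 2
  out <- pmf
  out$value <- value
  out$stderr <- stderr
  out
}

#' Re-reference a PMF to a zone of the reaction coordinate
#'
#' Subtracts the mean free energy over `reference_zone` so that zone becomes
#' the zero of the profile. The default zone is bulk water: the outermost
#' 5 Angstrom at each end of the grid.
#'
#' @param pmf a [pmf_profile].
#' @param reference_zone either `"bulk"` (default) or a numeric interval
#'   `c(lo, hi)` in Angstrom.
#' @return The shifted `pmf_profile` with its reference descriptor updated.
#' @export
rereference <- function(pmf, reference_zone = "bulk") {
  stopifnot(inherits(pmf, "pmf_profile"))
  mask <- reference_mask(pmf$z, reference_zone)
  if (!any(mask & is.finite(pmf$value))) stop("reference zone selects no finite grid points")
  shift <- mean(pmf$value[mask], na.rm = TRUE)
  out <- pmf
  out$value <- pmf$value - shift
  out$reference <- if (identical(reference_zone, "bulk")) {
    "bulk_water"
  } else {
    sprintf("zone[%g,%g]", reference_zone[1L], reference_zone[2L])
  }
  out
}

reference_mask <- function(z, reference_zone) {
  if (identical(reference_zone, "bulk")) {
    mask <- z <= min(z) + 5 | z >= max(z) - 5
  } else {
    stopifnot(is.numeric(reference_zone), length(reference_zone) == 2L)
    if (reference_zone[1L] > max(z) || reference_zone[2L] < min(z)) {
      stop("reference zone lies outside the grid")
    }
    mask <- z >= reference_zone[1L] & z <= reference_zone[2L]
  }
  if (!any(mask)) stop("reference zone selects no grid points")
  mask
}

check_same_grid <- function(a, b, what = "profiles") {
  if (length(a$z) != length(b$z) || any(abs(a$z - b$z) > 1e-8)) {
    stop(sprintf("%s are not on the same z grid", what))
  }
  invisible(TRUE)
}
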
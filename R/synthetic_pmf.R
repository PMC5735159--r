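#' Specification of a synthetic permeation free-energy surface
#'
#' A PMF spec defines the internal-energy profile U0(z) and entropy profile
#' S0(z) as sums of Gaussian terms, so that the free energy
#' A(z, T) = U0(z) - T * S0(z) is exactly linear in temperature. Both U0 and
#' S0 decay to zero in bulk water (the grid edges), which makes bulk water
#' the natural reference.
#'
#' The two presets emulate the qualitative morphology of a titratable
#' amphiphile in a phosphatidylcholine bilayer at a 310 K base temperature:
#'
#' * `"neutral"`: an interfacial barrier of ~2 kcal/mol near |z| = 22 A and a
#'   central plateau ~1 kcal/mol below bulk water, with the central
#'   stabilisation carried by a favorable entropy term (-T dS < 0).
#' * `"charged"`: a ~2 kcal/mol interfacial well (headgroup binding) near
#'   |z| = 18 A and a high central barrier of ~8 kcal/mol driven by a large
#'   unfavorable internal energy partially offset by favorable entropy.
#'
#' @param species `"neutral"` or `"charged"`; selects the preset when
#'   `features`/`entropy_terms` are not supplied.
#' @param features data.frame with columns `center` (A), `width` (A),
#'   `height` (kcal/mol): Gaussian terms of U0(z). `NULL` rows allowed
#'   (a zero-row frame gives a flat profile).
#' @param entropy_terms data.frame with columns `center`, `width`,
#'   `amplitude` (kcal/mol/K): Gaussian terms of S0(z).
#' @param z_range interval in Angstrom, symmetric about 0.
#' @param symmetric if `TRUE`, every term with `center != 0` is mirrored so
#'   the profile is even in z.
#' @return An object of class `pmf_spec`.
#' @examples
#' sp <- pmf_spec("neutral")
#' fam <- gen_pmf_family(sp, temperatures = c(305, 310, 315), seed = 1)
#' @export
pmf_spec <- function(species = c("neutral", "charged"),
                     features = NULL, entropy_terms = NULL,
                     z_range = c(-40, 40), symmetric = TRUE) {
  species <- match.arg(species)
  stopifnot(length(z_range) == 2L, z_range[1L] < z_range[2L])
  if (abs(z_range[1L] + z_range[2L]) > 1e-9) {
    stop("z_range must be symmetric about 0")
  }
  if (is.null(features) && is.null(entropy_terms)) {
    preset <- pmf_spec_preset(species)
    features <- preset$features
    entropy_terms <- preset$entropy_terms
  }
  if (is.null(features)) features <- data.frame(center = numeric(), width = numeric(), height = numeric())
  if (is.null(entropy_terms)) entropy_terms <- data.frame(center = numeric(), width = numeric(), amplitude = numeric())
  features <- as.data.frame(features)
  entropy_terms <- as.data.frame(entropy_terms)
  stopifnot(all(c("center", "width", "height") %in% names(features)),
            all(c("center", "width", "amplitude") %in% names(entropy_terms)))
  if (nrow(features) && any(features$width <= 0)) stop("feature widths must be positive")
  if (nrow(entropy_terms) && any(entropy_terms$width <= 0)) stop("entropy widths must be positive")
  if (symmetric) {
    features <- mirror_terms(features, "height")
    entropy_terms <- mirror_terms(entropy_terms, "amplitude")
  }
  structure(list(species = species, features = features,
                 entropy_terms = entropy_terms, z_range = as.numeric(z_range),
                 symmetric = symmetric),
            class = "pmf_spec")
}

## preset amplitudes are stated at the 310 K base temperature: the entries
## below give (U0, -T*S0) pairs of (0.5, +1.5) at the neutral barrier,
## (2, -3) at the neutral center, (-3, +1) at the charged interface and
## (11, -3) at the charged center.
pmf_spec_preset <- function(species) {
  if (species == "neutral") {
    list(
      features = data.frame(center = c(22, 0), width = c(3, 8),
                            height = c(0.5, 2.0)),
      entropy_terms = data.frame(center = c(22, 0), width = c(3, 8),
                                 amplitude = c(-1.5, 3.0) / 310)
    )
  } else {
    ## the central barrier is narrow (width 4 A): the protonation-state
    ## switch then falls a few Angstrom off-center, inside the tail region
    list(
      features = data.frame(center = c(18, 0), width = c(3, 4),
                            height = c(-3.0, 11.0)),
      entropy_terms = data.frame(center = c(18, 0), width = c(3, 4),
                                 amplitude = c(-1.0, 3.0) / 310)
    )
  }
}

mirror_terms <- function(df, amp_col) {
  off <- df[df$center != 0, , drop = FALSE]
  if (nrow(off)) {
    off$center <- -off$center
    df <- rbind(df, off)
  }
  df
}

eval_gaussians <- function(z, df, amp_col) {
  out <- numeric(length(z))
  for (i in seq_len(nrow(df))) {
    out <- out + df[[amp_col]][i] *
      exp(-(z - df$center[i])^2 / (2 * df$width[i]^2))
  }
  out
}

#' Evaluate the deterministic parts of a PMF spec
#'
#' @param spec a [pmf_spec].
#' @param z positions in Angstrom.
#' @return `pmf_internal_energy` gives U0(z) in kcal/mol;
#'   `pmf_entropy` gives S0(z) in kcal/(mol K).
#' @export
pmf_internal_energy <- function(spec, z) {
  stopifnot(inherits(spec, "pmf_spec"))
  eval_gaussians(z, spec$features, "height")
}

#' @rdname pmf_internal_energy
#' @export
pmf_entropy <- function(spec, z) {
  stopifnot(inherits(spec, "pmf_spec"))
  eval_gaussians(z, spec$entropy_terms, "amplitude")
}

#' Generate a family of PMF profiles at several temperatures
#'
#' Evaluates A(z, T) = U0(z) - T * S0(z) on a uniform grid for each requested
#' temperature, optionally adding i.i.d. Gaussian noise to emulate sampling
#' error. With `noise_sd = 0` the output is exactly linear in T at every grid
#' point. The per-point `stderr` field is set to `noise_sd`.
#'
#' @param spec a [pmf_spec].
#' @param temperatures temperatures in Kelvin (non-empty).
#' @param grid_step grid spacing in Angstrom.
#' @param noise_sd standard deviation of additive noise, kcal/mol.
#' @param seed integer seed; the generator is a pure function of
#'   `(spec, temperatures, grid_step, noise_sd, seed)`.
#' @return A list of [pmf_profile], one per temperature, all on one grid.
#' @export
gen_pmf_family <- function(spec, temperatures, grid_step = 0.5,
                           noise_sd = 0, seed = 1) {
  stopifnot(inherits(spec, "pmf_spec"))
  if (!length(temperatures)) stop("temperatures must be non-empty")
  stopifnot(grid_step > 0, noise_sd >= 0)
  if (grid_step > diff(spec$z_range)) {
    stop("grid_step exceeds the z range: degenerate grid")
  }
  z <- seq(spec$z_range[1L], spec$z_range[2L], by = grid_step)
  u0 <- pmf_internal_energy(spec, z)
  s0 <- pmf_entropy(spec, z)
  withr::with_seed(seed, {
    lapply(temperatures, function(tt) {
      a <- u0 - tt * s0
      if (noise_sd > 0) a <- a + stats::rnorm(length(z), 0, noise_sd)
      pmf_profile(z, a, stderr = noise_sd, temperature = tt,
                  species = spec$species, reference = "bulk_water")
    })
  })
}
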
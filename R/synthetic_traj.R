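#' Specification of an overdamped Langevin (Brownian dynamics) run
#'
#' Parameters for Euler-Maruyama integration of overdamped motion on a 1-D
#' free-energy surface A(z), with free diffusion in the periodic x-y plane
#' and reflective walls in z at +/- Lz/2. The stationary z distribution is
#' proportional to exp(-A(z)/kT).
#'
#' A drift-stability check is performed at construction time against the PMF
#' it is later paired with (see [gen_langevin_traj]): the deterministic drift
#' per step, beta * D * max|dA/dz| * dt, must stay below the PMF grid
#' spacing.
#'
#' @param diffusion_coefficient D in Angstrom^2/ns.
#' @param timestep integration step in ns.
#' @param n_steps number of stored steps per particle.
#' @param temperature Kelvin.
#' @param seed integer; fully determines the output.
#' @param box numeric length-3 (Lx, Ly, Lz) in Angstrom.
#' @param n_particles number of independent walkers.
#' @param burn_in steps discarded before recording.
#' @param species species label stamped on the trajectory.
#' @return An object of class `langevin_spec`.
#' @export
langevin_spec <- function(diffusion_coefficient = 50, timestep = 2e-4,
                          n_steps = 1000L, temperature = 310, seed = 1,
                          box = c(40, 40, 80), n_particles = 1L,
                          burn_in = 0L, species = "neutral") {
  stopifnot(diffusion_coefficient > 0, timestep > 0, n_steps >= 1,
            temperature > 0, length(box) == 3L, all(box > 0),
            n_particles >= 1, burn_in >= 0)
  structure(list(diffusion_coefficient = diffusion_coefficient,
                 timestep = timestep, n_steps = as.integer(n_steps),
                 temperature = temperature, seed = seed,
                 box = as.numeric(box), n_particles = as.integer(n_particles),
                 burn_in = as.integer(burn_in), species = species),
            class = "langevin_spec")
}

## linear interpolation of the PMF gradient at arbitrary z
pmf_gradient <- function(pmf) {
  z <- pmf$z
  v <- pmf$value
  n <- length(z)
  h <- z[2L] - z[1L]
  g <- numeric(n)
  g[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * h)
  g[1L] <- (v[2L] - v[1L]) / h
  g[n] <- (v[n] - v[n - 1L]) / h
  g
}

reflect_into <- function(z, lo, hi) {
  width <- hi - lo
  out <- (z - lo) %% (2 * width)
  out <- ifelse(out > width, 2 * width - out, out)
  out + lo
}

#' Generate a Boltzmann-consistent Brownian trajectory on a PMF
#'
#' Euler-Maruyama update `z' = z - beta * D * dA/dz * dt + sqrt(2 D dt) * xi`
#' with `xi ~ N(0, 1)`; x and y diffuse freely in the periodic box. In the
#' long run the z marginal converges to exp(-A(z)/kT) restricted to the box,
#' which makes the output a stand-in for an unbiased equilibrium MD run.
#'
#' @param pmf a [pmf_profile] whose grid covers the box z extent.
#' @param spec a [langevin_spec].
#' @return A [trajectory_ensemble] with `spec$n_particles * spec$n_steps`
#'   records.
#' @export
gen_langevin_traj <- function(pmf, spec) {
  stopifnot(inherits(pmf, "pmf_profile"), inherits(spec, "langevin_spec"))
  if (any(!is.finite(pmf$value))) stop("PMF contains non-finite values")
  zlo <- -spec$box[3L] / 2
  zhi <- spec$box[3L] / 2
  if (min(pmf$z) > zlo || max(pmf$z) < zhi) {
    stop("PMF grid does not cover the box z extent")
  }
  beta <- 1 / thermal_energy(spec$temperature)
  dd <- spec$diffusion_coefficient
  dt <- spec$timestep
  grad <- pmf_gradient(pmf)
  drift_max <- beta * dd * max(abs(grad)) * dt
  if (drift_max > grid_step(pmf)) {
    stop(sprintf(
      "unstable integration: drift per step %.3g A exceeds grid spacing %.3g A; reduce timestep",
      drift_max, grid_step(pmf)))
  }
  np <- spec$n_particles
  nst <- spec$n_steps
  sig <- sqrt(2 * dd * dt)
  g <- pmf$z
  h <- grid_step(pmf)
  withr::with_seed(spec$seed, {
    ## start from independent Boltzmann draws to shorten equilibration
    pz <- exp(-beta * (pmf$value - min(pmf$value)))
    pz[g < zlo | g > zhi] <- 0
    z <- sample(g, np, replace = TRUE, prob = pz) +
      stats::runif(np, -h / 2, h / 2)
    z <- reflect_into(z, zlo, zhi)
    x <- stats::runif(np, 0, spec$box[1L])
    y <- stats::runif(np, 0, spec$box[2L])
    total <- spec$burn_in + nst
    zs <- matrix(0, nrow = nst, ncol = np)
    xs <- matrix(0, nrow = nst, ncol = np)
    ys <- matrix(0, nrow = nst, ncol = np)
    bdd <- beta * dd * dt
    for (s in seq_len(total)) {
      i <- findInterval(z, g, all.inside = TRUE)
      w <- (z - g[i]) / h
      f <- grad[i] * (1 - w) + grad[i + 1L] * w
      z <- z - bdd * f + sig * stats::rnorm(np)
      z <- reflect_into(z, zlo, zhi)
      x <- (x + sig * stats::rnorm(np)) %% spec$box[1L]
      y <- (y + sig * stats::rnorm(np)) %% spec$box[2L]
      if (s > spec$burn_in) {
        k <- s - spec$burn_in
        zs[k, ] <- z
        xs[k, ] <- x
        ys[k, ] <- y
      }
    }
  })
  frames <- data.frame(
    time_ns = rep(seq_len(nst) * dt, times = np),
    particle_id = rep(seq_len(np), each = nst),
    species = spec$species,
    x = as.vector(xs), y = as.vector(ys), z = as.vector(zs)
  )
  trajectory_ensemble(frames, spec$box)
}

#' Sample umbrella windows exactly from the biased Boltzmann densities
#'
#' For each window center `z_i` with harmonic force constant `k`, samples are
#' drawn from `p_i(z) proportional to exp(-beta * (A(z) + k/2 (z - z_i)^2))`
#' by inverse-CDF lookup on a refined grid, so the window histograms are
#' exact draws from the analytic biased densities.
#'
#' @param pmf a [pmf_profile], the true underlying surface.
#' @param centers window centers in Angstrom.
#' @param force_const harmonic force constant in kcal/mol/Angstrom^2 (> 0);
#'   scalar or one per window.
#' @param n_per_window samples per window.
#' @param seed integer seed.
#' @param refine CDF grid refinement factor relative to the PMF grid; the
#'   sampled density approaches the analytic biased density as O(refine^-2).
#' @return An [umbrella_window_set]. A warning is issued when the overlap
#'   integral of consecutive biased densities falls below 1% of either mass.
#' @export
gen_umbrella_samples <- function(pmf, centers, force_const, n_per_window,
                                 seed = 1, refine = 48L) {
  stopifnot(inherits(pmf, "pmf_profile"), length(centers) >= 1,
            n_per_window >= 1)
  if (any(force_const <= 0)) stop("force_const must be positive")
  k <- rep_len(force_const, length(centers))
  beta <- 1 / thermal_energy(pmf$temperature)
  zf <- seq(min(pmf$z), max(pmf$z), length.out = refine * length(pmf$z))
  af <- stats::approx(pmf$z, pmf$value, zf)$y
  dens <- lapply(seq_along(centers), function(i) {
    u <- af + 0.5 * k[i] * (zf - centers[i])^2
    p <- exp(-beta * (u - min(u)))
    p / pracma::trapz(zf, p)
  })
  ord <- order(centers)
  for (j in seq_len(length(ord) - 1L)) {
    a <- dens[[ord[j]]]
    b <- dens[[ord[j + 1L]]]
    ov <- pracma::trapz(zf, pmin(a, b))
    if (ov < 0.01) {
      warning(sprintf(
        "windows at %g and %g A barely overlap (overlap integral %.2g)",
        centers[ord[j]], centers[ord[j + 1L]], ov))
    }
  }
  dzf <- diff(zf)
  windows <- withr::with_seed(seed, {
    lapply(seq_along(centers), function(i) {
      p <- dens[[i]]
      ## trapezoid CDF: a rectangle rule would bias every sample by half a
      ## fine-grid step, which WHAM integrates into a spurious linear tilt
      cdf <- c(0, cumsum((p[-1L] + p[-length(p)]) / 2 * dzf))
      cdf <- cdf / cdf[length(cdf)]
      keep <- c(TRUE, diff(cdf) > 0)
      u <- stats::runif(n_per_window)
      s <- stats::approx(cdf[keep], zf[keep], u, rule = 2)$y
      list(center = centers[i], force_const = k[i], samples = s)
    })
  })
  umbrella_window_set(windows, temperature = pmf$temperature)
}
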
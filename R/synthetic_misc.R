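#' Slab layout for synthetic charge snapshots
#'
#' Describes dipolar charge fluctuations in z slabs: large amplitudes for
#' water slabs (high-dielectric, strongly fluctuating local field), small
#' amplitudes for the membrane core. Charges are generated strictly in +/-
#' pairs, so every snapshot is electroneutral; a nonzero `net_charge` entry
#' is rejected.
#'
#' @param z_centers slab center positions in Angstrom.
#' @param amplitudes per-slab charge amplitude in elementary charges.
#' @param n_pairs dipole pairs per slab and frame.
#' @param box box lengths (Lx, Ly, Lz) in Angstrom.
#' @param net_charge per-slab monopole charge; must be all zero.
#' @return An object of class `slab_layout`.
#' @export
slab_layout <- function(z_centers = c(-32, -16, 0, 16, 32),
                        amplitudes = c(7, 2, 1, 2, 7) * 0.2,
                        n_pairs = 40L, box = c(30, 30, 80),
                        net_charge = 0) {
  stopifnot(length(z_centers) == length(amplitudes), all(amplitudes >= 0),
            n_pairs >= 1, length(box) == 3L)
  net_charge <- rep_len(net_charge, length(z_centers))
  if (any(net_charge != 0)) stop("non-neutral slab layout: net_charge must be zero")
  structure(list(z_centers = as.numeric(z_centers),
                 amplitudes = as.numeric(amplitudes),
                 n_pairs = as.integer(n_pairs), box = as.numeric(box)),
            class = "slab_layout")
}

#' Generate electroneutral point-charge snapshots with slab structure
#'
#' Each frame places `n_pairs` +/- charge pairs per slab: pair positions are
#' uniform in x-y and offset from the slab center plane by 2-4 Angstrom in
#' z (either side), keeping a standoff from field probes on that plane; the
#' partner charge sits 1 Angstrom away in a random direction. Charge
#' magnitudes equal the slab amplitude, so the instantaneous dipolar field
#' fluctuation in a slab is proportional to its layout amplitude while the
#' time-mean field vanishes by symmetry.
#'
#' @param n_frames number of snapshots.
#' @param layout a [slab_layout].
#' @param seed integer seed; fixed seed gives identical snapshots.
#' @return List of [charged_snapshot] objects.
#' @export
gen_charge_snapshots <- function(n_frames, layout = slab_layout(), seed = 1) {
  stopifnot(n_frames >= 1, inherits(layout, "slab_layout"))
  withr::with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      pos <- list(); chg <- list()
      for (s in seq_along(layout$z_centers)) {
        m <- layout$n_pairs
        p1 <- cbind(stats::runif(m, 0, layout$box[1L]),
                    stats::runif(m, 0, layout$box[2L]),
                    layout$z_centers[s] +
                      sample(c(-1, 1), m, replace = TRUE) *
                      stats::runif(m, 2, 4))
        u <- matrix(stats::rnorm(3 * m), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        p2 <- p1 + u
        p2[, 1] <- p2[, 1] %% layout$box[1L]
        p2[, 2] <- p2[, 2] %% layout$box[2L]
        q <- layout$amplitudes[s]
        pos[[s]] <- rbind(p1, p2)
        chg[[s]] <- c(rep(q, m), rep(-q, m))
      }
      charged_snapshot(do.call(rbind, pos), unlist(chg), layout$box)
    })
  })
}

#' Generate a synthetic analog descriptor table with planted groups
#'
#' Draws analog records (SASA in Angstrom^2, dipole in Debye, logP) from
#' per-group multivariate normals whose means are separated along the SASA
#' axis by at least 3 pooled standard deviations, so grouping is dominated by
#' molecular size. Within each group SASA and logP are positively correlated
#' by construction. True group labels are retained for recovery scoring.
#'
#' Defaults emulate a 54-compound analog survey in four size classes.
#'
#' @param n_groups number of groups.
#' @param sizes group sizes (default splits 54 records).
#' @param group_means matrix `n_groups x 3` of (sasa, dipole, logp) means.
#' @param covariance 3x3 within-group covariance (shared); the zero matrix
#'   is allowed (degenerate: all members at the group mean), any other
#'   singular covariance is an error.
#' @param seed integer seed.
#' @return data.frame with columns `id`, `sasa`, `dipole`, `logp`,
#'   `true_group`.
#' @export
gen_analog_table <- function(n_groups = 4L, sizes = NULL, group_means = NULL,
                             covariance = NULL, seed = 1) {
  if (is.null(sizes)) {
    base <- 54L %/% n_groups
    sizes <- rep(base, n_groups)
    sizes[seq_len(54L %% n_groups)] <- base + 1L
  }
  stopifnot(length(sizes) == n_groups, all(sizes >= 1))
  if (is.null(group_means)) {
    sasa_means <- 250 + 60 * (seq_len(n_groups) - 1)
    ## logP tracks size but with a weaker group contrast than SASA itself,
    ## so the first principal axis of the table is carried by SASA
    group_means <- cbind(sasa = sasa_means,
                         dipole = c(2, 4.5, 3, 5.5)[((seq_len(n_groups) - 1) %% 4) + 1],
                         logp = 1.2 + 0.008 * (sasa_means - 250))
  }
  group_means <- as.matrix(group_means)
  stopifnot(nrow(group_means) == n_groups, ncol(group_means) == 3L)
  if (is.null(covariance)) {
    sds <- c(12, 0.4, 0.3)
    cc <- diag(sds^2)
    cc[1, 3] <- cc[3, 1] <- 0.6 * sds[1] * sds[3]   # SASA-logP coupling
    covariance <- cc
  }
  covariance <- as.matrix(covariance)
  zero_cov <- all(covariance == 0)
  if (!zero_cov && min(eigen(covariance, symmetric = TRUE,
                             only.values = TRUE)$values) <= 0) {
    stop("singular (non-positive-definite) covariance")
  }
  if (n_groups > 1) {
    pooled_sd <- if (zero_cov) 0 else sqrt(covariance[1, 1])
    gaps <- diff(sort(group_means[, 1]))
    if (pooled_sd > 0 && any(gaps < 3 * pooled_sd)) {
      stop("group SASA means must be separated by at least 3 pooled SD")
    }
  }
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_groups), function(g) {
      xx <- if (zero_cov) {
        matrix(group_means[g, ], nrow = sizes[g], ncol = 3, byrow = TRUE)
      } else {
        MASS::mvrnorm(sizes[g], mu = group_means[g, ], Sigma = covariance)
      }
      data.frame(sasa = xx[, 1], dipole = xx[, 2], logp = xx[, 3],
                 true_group = g)
    })
    out <- do.call(rbind, rows)
    out <- cbind(id = sprintf("analog_%02d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    out
  })
}

#' Generate toy conformers linking molecular dipole to the B...N distance
#'
#' Builds four-site point-charge conformers of a borate-amine scaffold: a
#' fixed background dipole plus a boron/nitrogen pair whose separation d(B,N)
#' is swept across `bn_distance_range`. In the `"neutral"` preset the B...N
#' pair opposes the background dipole, so the molecular dipole decreases as
#' the distance grows; protonating the nitrogen (`"charged"` preset, net
#' charge +1 e) reverses the trend.
#'
#' @param n number of conformers (>= 2).
#' @param bn_distance_range interval of B...N distances in Angstrom.
#' @param charge_model `"neutral"` or `"charged"`.
#' @param seed integer seed (small coordinate jitter).
#' @return List of conformers, each with `coords` (4x3, Angstrom), `charges`
#'   (e), `B_index`, `N_index`, `bn_distance`.
#' @export
gen_conformers <- function(n, bn_distance_range = c(1.5, 5),
                           charge_model = c("neutral", "charged"), seed = 1) {
  if (n < 2) stop("need at least 2 conformers to correlate dipole with distance")
  charge_model <- match.arg(charge_model)
  q <- if (charge_model == "neutral") {
    c(0.6, -0.6, 0.25, -0.25)
  } else {
    c(0.6, -0.6, 0.25, 0.75)   # protonated nitrogen: net +1 e
  }
  d <- seq(bn_distance_range[1L], bn_distance_range[2L], length.out = n)
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      coords <- rbind(c(0, 0, 0), c(-3, 0, 0), c(0.5, 0, 0),
                      c(0.5 + d[i], 0, 0))
      coords[, 2:3] <- coords[, 2:3] + stats::rnorm(8, 0, 0.02)
      list(coords = coords, charges = q, B_index = 3L, N_index = 4L,
           bn_distance = d[i])
    })
  })
}

#' Generate a degrees-of-freedom trajectory with dipole and ring columns
#'
#' Emulates the internal degrees of freedom the entropy argument rests on:
#' molecular dipole vectors with tunable orientational order (isotropic for a
#' freely rotating neutral solute, strongly aligned for a charged one held by
#' headgroup contacts), dipole magnitudes with tunable breadth, and the two
#' ring z coordinates whose difference captures unsynchronized ring
#' insertion at the interface.
#'
#' @param n_frames number of records (one particle).
#' @param z_range interval the center of mass samples uniformly.
#' @param orientation_kappa orientational order parameter: 0 gives isotropic
#'   dipoles (uniform in cos theta); larger values align the dipole with the
#'   membrane normal (cos theta concentrated near 1).
#' @param dipole_mean,dipole_sd mean and SD of |mu| in Debye.
#' @param ring_offset_mean,ring_offset_sd mean/SD of the ring z offset in
#'   Angstrom (positive mean: one ring leads the insertion).
#' @param box box lengths.
#' @param species species label.
#' @param seed integer seed.
#' @return A [trajectory_ensemble] with dipole and ring columns.
#' @export
gen_dof_ensemble <- function(n_frames, z_range = c(-30, 30),
                             orientation_kappa = 0, dipole_mean = 5,
                             dipole_sd = 0.8, ring_offset_mean = 0,
                             ring_offset_sd = 1, box = c(40, 40, 80),
                             species = "neutral", seed = 1) {
  stopifnot(n_frames >= 1, orientation_kappa >= 0, dipole_mean > 0)
  withr::with_seed(seed, {
    z <- stats::runif(n_frames, z_range[1L], z_range[2L])
    ct <- stats::runif(n_frames, -1, 1)
    if (orientation_kappa > 0) {
      ## rejection sampling from the aligning density exp(kappa * cos theta):
      ## the dipole is pulled toward the membrane normal, narrowing the
      ## orientational spread
      for (i in seq_len(n_frames)) {
        repeat {
          u <- stats::runif(1, -1, 1)
          if (stats::runif(1) < exp(orientation_kappa * (u - 1))) break
        }
        ct[i] <- u
      }
    }
    phi <- stats::runif(n_frames, 0, 2 * pi)
    st <- sqrt(pmax(0, 1 - ct^2))
    mu <- pmax(stats::rnorm(n_frames, dipole_mean, dipole_sd), 1e-6)
    off <- stats::rnorm(n_frames, ring_offset_mean, ring_offset_sd)
    frames <- data.frame(
      time_ns = seq_len(n_frames) * 1e-3,
      particle_id = 1L, species = species,
      x = stats::runif(n_frames, 0, box[1L]),
      y = stats::runif(n_frames, 0, box[2L]),
      z = z,
      mu_x = mu * st * cos(phi), mu_y = mu * st * sin(phi), mu_z = mu * ct,
      ring1_z = z + off / 2, ring2_z = z - off / 2)
  })
  trajectory_ensemble(frames, box)
}

#' Synthetic bilayer density profiles
#'
#' Analytic density curves emulating a hydrated phosphatidylcholine bilayer:
#' water rising sigmoidally toward bulk, lipid mirrored, tail density peaked
#' mid-leaflet and depleted at the center, and a phosphate band at the
#' headgroups. Used to exercise region detection without a trajectory.
#'
#' @param z_mid bin midpoints in Angstrom.
#' @param water_half |z| of the water sigmoid half height.
#' @param width sigmoid width in Angstrom.
#' @param bulk_water bulk water density (count/Angstrom^3).
#' @return A [density_profile_set].
#' @export
gen_density_preset <- function(z_mid = seq(-39.5, 39.5, by = 0.5),
                               water_half = 25, width = 2,
                               bulk_water = 0.033) {
  sig <- function(z) 1 / (1 + exp(-(abs(z) - water_half) / width))
  water <- bulk_water * sig(z_mid)
  lipid <- bulk_water * (1 - sig(z_mid))
  tail <- 0.028 * exp(-(abs(z_mid) - 10)^2 / (2 * 4^2))
  phosphate <- 0.002 * exp(-(abs(z_mid) - 20)^2 / (2 * 2^2))
  density_profile_set(z_mid,
                      list(system = water + lipid + tail + phosphate,
                           water = water, lipid = lipid, tail = tail,
                           phosphate = phosphate),
                      bin_width = z_mid[2] - z_mid[1], area = 1600)
}
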
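#' Point-charge snapshot
#'
#' One configuration of point charges in a box periodic in x and y. The
#' configuration must be electroneutral.
#'
#' @param positions n x 3 matrix of positions in Angstrom.
#' @param charges charges in elementary charge units; must sum to zero.
#' @param box box lengths (Lx, Ly, Lz) in Angstrom.
#' @return An object of class `charged_snapshot`.
#' @export
charged_snapshot <- function(positions, charges, box) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3L, nrow(positions) == length(charges),
            length(box) == 3L, all(box > 0))
  if (abs(sum(charges)) > 1e-9) {
    stop("snapshot is not electroneutral (total charge ",
         signif(sum(charges), 3), " e)")
  }
  structure(list(positions = positions, charges = as.numeric(charges),
                 box = as.numeric(box)),
            class = "charged_snapshot")
}

## z component of the Coulomb field at probe points from one snapshot,
## x-y minimum image, real-space cutoff in the x-y distance
field_z_at <- function(snap, probes, cutoff) {
  pos <- snap$positions
  q <- snap$charges
  lx <- snap$box[1L]; ly <- snap$box[2L]
  np <- nrow(probes)
  out <- numeric(np)
  for (p in seq_len(np)) {
    dx <- pos[, 1] - probes[p, 1]
    dy <- pos[, 2] - probes[p, 2]
    dz <- pos[, 3] - probes[p, 3]
    dx <- dx - lx * round(dx / lx)
    dy <- dy - ly * round(dy / ly)
    keep <- (dx * dx + dy * dy) <= cutoff^2
    r2 <- dx[keep]^2 + dy[keep]^2 + dz[keep]^2
    r2[r2 < 1e-12] <- Inf        # probe coincident with a charge
    ## field at the probe points from charge toward probe: E_z = -k q dz / r^3
    out[p] <- -coulomb_constant() * sum(q[keep] * dz[keep] / (r2 * sqrt(r2)))
  }
  out
}

#' Local electric-field oscillation profile across the membrane
#'
#' For every frame, computes the z component of the Coulomb field at each
#' probe point from all charges within an x-y minimum-image cutoff (direct
#' sum, no Ewald), averages probes within each z slab, and summarises the
#' per-slab time series by its mean and standard deviation over frames. The
#' standard deviation is the oscillation amplitude: large in the
#' high-dielectric aqueous phase, small in the low-polarity membrane core,
#' while the time mean stays near zero in every slab.
#'
#' @param snapshots list of [charged_snapshot]s sharing one box.
#' @param probes matrix of probe points (n x 3); default: a 3 x 3 x-y grid at
#'   each slab center.
#' @param slab_width slab thickness in Angstrom.
#' @param cutoff x-y cutoff in Angstrom; must be below half the smallest
#'   lateral box length.
#' @return An object of class `field_profile`: data.frame with `z_slab`,
#'   `mean_field`, `oscillation` (kcal/(mol e Angstrom)) and `n_frames`.
#' @export
local_field_profile <- function(snapshots, probes = NULL, slab_width = 16,
                                cutoff = 10) {
  stopifnot(length(snapshots) >= 1)
  box <- snapshots[[1L]]$box
  for (s in snapshots) {
    stopifnot(inherits(s, "charged_snapshot"))
    if (any(abs(s$box - box) > 1e-9)) stop("snapshots must share one box")
  }
  if (cutoff >= min(box[1:2]) / 2) {
    stop("cutoff must be below half the smallest lateral box length")
  }
  n_slab <- max(1L, floor(box[3L] / slab_width))
  edges <- seq(-box[3L] / 2, box[3L] / 2, length.out = n_slab + 1L)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  if (is.null(probes)) {
    gx <- box[1L] * c(0.25, 0.5, 0.75)
    gy <- box[2L] * c(0.25, 0.5, 0.75)
    probes <- as.matrix(expand.grid(x = gx, y = gy, z = mid))
  }
  probes <- as.matrix(probes)
  slab_of <- findInterval(probes[, 3], edges, rightmost.closed = TRUE,
                          all.inside = TRUE)
  per_frame <- vapply(snapshots, function(s) {
    ez <- field_z_at(s, probes, cutoff)
    vapply(seq_len(n_slab), function(b) mean(ez[slab_of == b]), numeric(1))
  }, numeric(n_slab))
  per_frame <- matrix(per_frame, nrow = n_slab)
  structure(data.frame(z_slab = mid,
                       mean_field = rowMeans(per_frame),
                       oscillation = apply(per_frame, 1, stats::sd),
                       n_frames = length(snapshots)),
            class = c("field_profile", "data.frame"))
}

#' Lateral footprint area of a permeant
#'
#' Projects frames whose z lies in `z_window` onto the x-y plane and counts
#' occupied grid cells: `area = occupied cells * cell^2`. A freely diffusing
#' neutral solute covers the whole cross-section; a tethered charged one
#' covers a restricted patch, the translational-entropy contrast.
#'
#' @param traj a [trajectory_ensemble].
#' @param z_window interval in Angstrom selecting frames by z.
#' @param cell occupancy cell edge in Angstrom.
#' @return Area in Angstrom^2.
#' @export
footprint_area <- function(traj, z_window, cell = 1) {
  stopifnot(inherits(traj, "trajectory_ensemble"), cell > 0,
            length(z_window) == 2L)
  fr <- traj$frames
  sel <- fr$z >= z_window[1L] & fr$z <= z_window[2L]
  if (!any(sel)) stop("no frames with z inside the window")
  ix <- floor((fr$x[sel] %% traj$box[1L]) / cell)
  iy <- floor((fr$y[sel] %% traj$box[2L]) / cell)
  length(unique(paste(ix, iy))) * cell^2
}

dipole_columns <- function(traj) {
  if (!all(c("mu_x", "mu_y", "mu_z") %in% names(traj$frames))) {
    stop("trajectory has no dipole columns (mu_x, mu_y, mu_z)")
  }
  fr <- traj$frames
  cbind(fr$mu_x, fr$mu_y, fr$mu_z)
}

#' Joint orientation histogram of the molecular dipole
#'
#' Bins cos(theta) = mu_z / |mu| (theta the angle between the dipole and the
#' membrane normal) jointly with the z position; each z bin's histogram is
#' normalized to unit mass. Frames with zero dipole magnitude are skipped
#' and counted.
#'
#' @param traj a [trajectory_ensemble] with dipole columns.
#' @param z_bins z bin edges in Angstrom.
#' @param costheta_bins cos(theta) bin edges (default 20 bins from -1 to 1).
#' @return List with `z_edges`, `costheta_edges`, `density` (z bin x cos bin,
#'   rows summing to 1 where populated) and `n_skipped`.
#' @export
orientation_histogram <- function(traj, z_bins,
                                  costheta_bins = seq(-1, 1, length.out = 21)) {
  mu <- dipole_columns(traj)
  mag <- sqrt(rowSums(mu^2))
  ok <- mag > 0
  n_skipped <- sum(!ok)
  ct <- mu[ok, 3] / mag[ok]
  zz <- traj$frames$z[ok]
  zi <- findInterval(zz, z_bins, rightmost.closed = TRUE)
  ci <- findInterval(pmin(pmax(ct, -1), 1), costheta_bins,
                     rightmost.closed = TRUE, all.inside = TRUE)
  keep <- zi >= 1 & zi < length(z_bins)
  tab <- table(factor(zi[keep], levels = seq_len(length(z_bins) - 1L)),
               factor(ci[keep], levels = seq_len(length(costheta_bins) - 1L)))
  dens <- unclass(tab)
  rs <- rowSums(dens)
  dens <- sweep(dens, 1, ifelse(rs > 0, rs, 1), "/")
  list(z_edges = z_bins, costheta_edges = costheta_bins,
       density = dens, n_skipped = n_skipped)
}

#' Per-depth dipole-magnitude statistics
#'
#' Mean, standard deviation and a normalized histogram of |mu| per z bin.
#' The breadth of these distributions tracks conformational flexibility.
#'
#' @param traj a [trajectory_ensemble] with dipole columns.
#' @param z_bins z bin edges in Angstrom.
#' @param mu_breaks histogram breaks for |mu| (Debye); default 30 bins over
#'   the observed range.
#' @return List with `stats` (data.frame z_lo, z_hi, n, mean, sd; empty bins
#'   reported with n = 0 and NA moments) and `histograms` (per-bin normalized
#'   densities).
#' @export
dipole_stats <- function(traj, z_bins, mu_breaks = NULL) {
  mu <- dipole_columns(traj)
  mag <- sqrt(rowSums(mu^2))
  zz <- traj$frames$z
  if (is.null(mu_breaks)) {
    mu_breaks <- seq(min(mag), max(mag), length.out = 31)
    if (mu_breaks[1] == mu_breaks[31]) mu_breaks <- mu_breaks[1] + c(-0.5, 0.5)
  }
  zi <- findInterval(zz, z_bins, rightmost.closed = TRUE)
  nbin <- length(z_bins) - 1L
  stats_df <- data.frame(z_lo = z_bins[-length(z_bins)], z_hi = z_bins[-1],
                         n = 0L, mean = NA_real_, sd = NA_real_)
  hists <- vector("list", nbin)
  for (b in seq_len(nbin)) {
    v <- mag[zi == b]
    stats_df$n[b] <- length(v)
    if (length(v)) {
      stats_df$mean[b] <- mean(v)
      stats_df$sd[b] <- if (length(v) > 1) stats::sd(v) else 0
      h <- graphics::hist(pmin(pmax(v, mu_breaks[1]),
                               mu_breaks[length(mu_breaks)]),
                          breaks = mu_breaks, plot = FALSE)
      hists[[b]] <- h$counts / sum(h$counts)
    }
  }
  list(stats = stats_df, histograms = hists, mu_breaks = mu_breaks)
}

#' Distribution of the ring-insertion offset per depth
#'
#' The offset `dz = ring1_z - ring2_z` between the two phenyl-ring z
#' coordinates is histogrammed per center-of-mass z bin and normalized to
#' unit mass per bin; asymmetric interfacial distributions signal one ring
#' inserting ahead of the other.
#'
#' @param traj a [trajectory_ensemble] with `ring1_z`, `ring2_z` columns.
#' @param z_bins z bin edges in Angstrom.
#' @param dz_breaks histogram breaks for dz; default 30 bins over the range.
#' @return List with `z_edges`, `dz_breaks`, `density` (per-bin rows summing
#'   to 1 where populated) and `n` per bin.
#' @export
delta_z_distribution <- function(traj, z_bins, dz_breaks = NULL) {
  fr <- traj$frames
  if (!all(c("ring1_z", "ring2_z") %in% names(fr))) {
    stop("trajectory has no ring columns (ring1_z, ring2_z)")
  }
  dz <- fr$ring1_z - fr$ring2_z
  if (is.null(dz_breaks)) {
    dz_breaks <- seq(min(dz) - 1e-9, max(dz) + 1e-9, length.out = 31)
  }
  zi <- findInterval(fr$z, z_bins, rightmost.closed = TRUE)
  nbin <- length(z_bins) - 1L
  dens <- matrix(0, nrow = nbin, ncol = length(dz_breaks) - 1L)
  nn <- integer(nbin)
  for (b in seq_len(nbin)) {
    v <- dz[zi == b]
    nn[b] <- length(v)
    if (length(v)) {
      h <- graphics::hist(pmin(pmax(v, dz_breaks[1]),
                               dz_breaks[length(dz_breaks)]),
                          breaks = dz_breaks, plot = FALSE)
      dens[b, ] <- h$counts / sum(h$counts)
    }
  }
  list(z_edges = z_bins, dz_breaks = dz_breaks, density = dens, n = nn)
}

#' Molecular dipole from point charges
#'
#' `mu = sum_i q_i (r_i - r_ref)` converted from e*Angstrom to Debye. For a
#' neutral charge set the dipole is independent of the reference point; for
#' a net-charged set a reference must be supplied (`"com"` uses the
#' unweighted center of the sites).
#'
#' @param coords n x 3 matrix in Angstrom.
#' @param charges charges in e.
#' @param reference `NULL` (neutral systems only), `"com"`, or a length-3
#'   point.
#' @return List with `vector` (Debye) and `magnitude` (Debye).
#' @export
dipole_from_charges <- function(coords, charges, reference = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, nrow(coords) == length(charges))
  net <- sum(charges)
  if (abs(net) > 1e-9) {
    if (is.null(reference)) {
      stop("net-charged system: a reference point is required for the dipole")
    }
  }
  ref <- if (is.null(reference)) {
    c(0, 0, 0)
  } else if (identical(reference, "com")) {
    colMeans(coords)
  } else {
    stopifnot(is.numeric(reference), length(reference) == 3L)
    as.numeric(reference)
  }
  mu <- colSums(charges * sweep(coords, 2, ref)) * ea_to_debye()
  list(vector = mu, magnitude = sqrt(sum(mu^2)))
}
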
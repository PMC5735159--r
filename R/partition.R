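#' Density profile set along the membrane normal
#'
#' Per-species number densities on a common z binning, in count/Angstrom^3.
#' The normalization invariant `sum(density) * area * bin_width = mean count`
#' holds for profiles built by [density_profiles()]; analytic profile sets
#' (e.g. sigmoid models for testing region detection) can be constructed
#' directly.
#'
#' @param z_mid bin midpoints in Angstrom (uniform).
#' @param curves named list of numeric density vectors (conventional names:
#'   `system`, `water`, `lipid`, `tail`, `phosphate`, `drug`).
#' @param bin_width bin width in Angstrom.
#' @param area box x-y cross-section in Angstrom^2.
#' @param n_frames number of frames averaged (1 for analytic sets).
#' @return An object of class `density_profile_set`.
#' @export
density_profile_set <- function(z_mid, curves, bin_width, area, n_frames = 1L) {
  stopifnot(is.numeric(z_mid), length(z_mid) >= 2, is.list(curves),
            length(names(curves)) == length(curves), bin_width > 0, area > 0)
  for (nm in names(curves)) {
    if (length(curves[[nm]]) != length(z_mid)) {
      stop("curve '", nm, "' length does not match the z binning")
    }
    if (any(curves[[nm]] < 0)) stop("densities must be non-negative ('", nm, "')")
  }
  structure(list(z = as.numeric(z_mid), curves = lapply(curves, as.numeric),
                 bin_width = bin_width, area = area,
                 n_frames = as.integer(n_frames)),
            class = "density_profile_set")
}

#' @export
print.density_profile_set <- function(x, ...) {
  cat(sprintf("Density profiles: %d bins (%g A), species: %s, %d frame(s)\n",
              length(x$z), x$bin_width, paste(names(x$curves), collapse = ", "),
              x$n_frames))
  invisible(x)
}

#' Time-averaged number-density profiles from a trajectory
#'
#' Bins particle z coordinates per species and averages over frames; density
#' is mean count per bin divided by the bin volume (x-y area times width).
#'
#' @param traj a [trajectory_ensemble].
#' @param species_selectors named list mapping output curve names to species
#'   labels (default: one curve per species present).
#' @param bin_width bin width in Angstrom.
#' @return A [density_profile_set]. An empty selection yields a zero curve
#'   with a warning.
#' @export
density_profiles <- function(traj, species_selectors = NULL, bin_width = 1) {
  stopifnot(inherits(traj, "trajectory_ensemble"), bin_width > 0)
  fr <- traj$frames
  lz <- traj$box[3L]
  edges <- seq(-lz / 2, lz / 2, by = bin_width)
  if (edges[length(edges)] < lz / 2) edges <- c(edges, lz / 2)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  n_frames <- length(unique(fr$time_ns))
  area <- traj$box[1L] * traj$box[2L]
  if (is.null(species_selectors)) {
    species_selectors <- as.list(unique(fr$species))
    names(species_selectors) <- unlist(species_selectors)
  }
  curves <- lapply(species_selectors, function(sel) {
    zz <- fr$z[fr$species %in% sel]
    if (!length(zz)) {
      warning("species selector matched no particles; returning a zero curve")
      return(numeric(length(mid)))
    }
    idx <- findInterval(zz, edges, rightmost.closed = TRUE, all.inside = TRUE)
    counts <- tabulate(idx, nbins = length(mid))
    counts / n_frames / (area * bin_width)
  })
  density_profile_set(mid, curves, bin_width, area, n_frames)
}

#' Four-region model of a hydrated bilayer
#'
#' Region boundaries measured as |z| outward from the bilayer center:
#' region 1 (bulk water) for |z| > b12, region 2 (headgroups) for
#' b23 < |z| <= b12, region 3 (high-density tails) for b34 < |z| <= b23 and
#' region 4 (low-density tails) for |z| <= b34. For partitioning, regions
#' 2-4 constitute the lipid phase and region 1 the water phase.
#'
#' @param b12,b23,b34 boundaries in Angstrom, `0 < b34 < b23 < b12`.
#' @param per_leaflet optional list with per-leaflet boundary values.
#' @return An object of class `region_model`.
#' @export
region_model <- function(b12, b23, b34, per_leaflet = NULL) {
  stopifnot(0 < b34, b34 < b23, b23 < b12)
  structure(list(b12 = b12, b23 = b23, b34 = b34, per_leaflet = per_leaflet),
            class = "region_model")
}

#' @export
print.region_model <- function(x, ...) {
  cat(sprintf(
    "Four-region model: |z| boundaries 1|2 = %.2f, 2|3 = %.2f, 3|4 = %.2f A\n",
    x$b12, x$b23, x$b34))
  invisible(x)
}

#' Map positions to regions of a [region_model]
#' @param regions a [region_model].
#' @param z positions in Angstrom.
#' @return Integer region indices 1-4.
#' @export
region_of <- function(regions, z) {
  stopifnot(inherits(regions, "region_model"))
  az <- abs(z)
  ifelse(az > regions$b12, 1L,
         ifelse(az > regions$b23, 2L, ifelse(az > regions$b34, 3L, 4L)))
}

## outermost |z| where f crosses zero within one leaflet, by linear interp
outermost_crossing <- function(z, f, leaflet_sign) {
  sel <- which(sign(z) == leaflet_sign | z == 0)
  z <- z[sel]; f <- f[sel]
  if (leaflet_sign < 0) { z <- rev(z); f <- rev(f) }   # order center -> edge
  idx <- which(f[-1] * f[-length(f)] <= 0 & (f[-1] != 0 | f[-length(f)] != 0))
  if (!length(idx)) return(NA_real_)
  i <- max(idx)
  zc <- z[i] + (z[i + 1] - z[i]) * f[i] / (f[i] - f[i + 1])
  abs(zc)
}

#' Detect four-region boundaries from density profiles
#'
#' Implements the rules: the water/headgroup boundary b12 is the outermost
#' |z| where the water and lipid densities are equal; b23 is the outermost
#' |z| where the water density falls below 1% of its bulk-zone mean; b34 is
#' the |z| where the lipid-tail density falls to half its in-leaflet maximum
#' on the way to the bilayer center. Boundaries are found per leaflet and
#' averaged.
#'
#' @param profiles a [density_profile_set] with `water` and `lipid` curves;
#'   b34 uses the `tail` curve when present, else `lipid`.
#' @param water_bulk_zone interval of |z| defining bulk water; default the
#'   outermost 5 Angstrom of the binning.
#' @return A [region_model].
#' @export
detect_regions <- function(profiles, water_bulk_zone = NULL) {
  stopifnot(inherits(profiles, "density_profile_set"))
  cv <- profiles$curves
  if (!all(c("water", "lipid") %in% names(cv))) {
    stop("region detection needs 'water' and 'lipid' density curves")
  }
  z <- profiles$z
  tail_curve <- if ("tail" %in% names(cv)) cv$tail else cv$lipid
  if (is.null(water_bulk_zone)) {
    water_bulk_zone <- c(max(abs(z)) - 5, max(abs(z)))
  }
  bulk_mask <- abs(z) >= water_bulk_zone[1L] & abs(z) <= water_bulk_zone[2L]
  bulk_w <- mean(cv$water[bulk_mask])
  if (!is.finite(bulk_w) || bulk_w <= 0) stop("bulk water density is not positive")
  per <- lapply(c(pos = 1, neg = -1), function(sgn) {
    b12 <- outermost_crossing(z, cv$water - cv$lipid, sgn)
    if (is.na(b12)) stop("water and lipid densities never cross (b12 criterion failed)")
    b23 <- outermost_crossing(z, cv$water - 0.01 * bulk_w, sgn)
    if (is.na(b23)) stop("water density never falls below 1% of bulk (b23 criterion failed)")
    sel <- if (sgn > 0) z >= 0 else z <= 0
    tz <- z[sel]; tc <- tail_curve[sel]
    ipk <- which.max(tc)
    half <- tc[ipk] / 2
    inner <- if (sgn > 0) rev(seq_len(ipk)) else seq(ipk, length(tz))
    tz_in <- tz[inner]; tc_in <- tc[inner]   # ordered peak -> center
    below <- which(tc_in < half)
    if (!length(below)) stop("tail density never falls to half maximum (b34 criterion failed)")
    i <- min(below)
    b34 <- abs(tz_in[i - 1] + (tz_in[i] - tz_in[i - 1]) *
                 (tc_in[i - 1] - half) / (tc_in[i - 1] - tc_in[i]))
    c(b12 = b12, b23 = b23, b34 = b34)
  })
  b <- (per$pos + per$neg) / 2
  region_model(b[["b12"]], b[["b23"]], b[["b34"]], per_leaflet = per)
}

#' Partition coefficient estimates
#'
#' `logp_from_trajectory()` implements the equilibrium definition of logP as
#' the log10 ratio of the compound's concentration in the lipid phase
#' (regions 2-4) to that in the water phase (region 1), accumulated as
#' running frame averages up to each checkpoint, the way a converging MD
#' partition run is monitored. Standard errors come from block averaging
#' (default 10 blocks) of per-block log10 concentration ratios; ensembles
#' with at least `2 * n_blocks` independent walkers are blocked over
#' particles (which are independent by construction), otherwise over time.
#'
#' `logp_from_pmf()` is the equilibrium-consistency oracle: with the PMF
#' referenced to bulk water,
#' `logP = log10[(int_lip e^(-A/kT) dz / L_lip) / (int_wat e^(-A/kT) dz / L_wat)]`
#' by trapezoidal quadrature, with compartment lengths from the region model.
#'
#' @param traj a [trajectory_ensemble].
#' @param regions a [region_model].
#' @param checkpoints times in ns at which running estimates are reported;
#'   default: 5 evenly spaced checkpoints ending at the last frame.
#' @param n_blocks blocks for the standard error.
#' @return An object of class `logp_estimate` with fields `logp`, `stderr`,
#'   `series` (data.frame time_ns, logp, stderr) and `method`.
#' @export
logp_from_trajectory <- function(traj, regions, checkpoints = NULL,
                                 n_blocks = 10L) {
  stopifnot(inherits(traj, "trajectory_ensemble"),
            inherits(regions, "region_model"))
  fr <- traj$frames
  lz <- traj$box[3L]
  if (regions$b12 >= lz / 2) stop("water compartment has zero volume in this box")
  tmax <- max(fr$time_ns)
  if (is.null(checkpoints)) checkpoints <- seq(tmax / 5, tmax, length.out = 5)
  if (max(checkpoints) > tmax + 1e-9) {
    stop("trajectory shorter than the last checkpoint")
  }
  in_lip <- abs(fr$z) <= regions$b12
  l_lip <- 2 * regions$b12
  l_wat <- lz - l_lip
  ratio_of <- function(mask) {
    nl <- sum(in_lip[mask]); nw <- sum(!in_lip[mask])
    if (nl == 0 || nw == 0) return(NA_real_)
    (nl / l_lip) / (nw / l_wat)
  }
  series <- data.frame(time_ns = checkpoints, logp = NA_real_,
                       stderr = NA_real_)
  for (j in seq_along(checkpoints)) {
    mask <- fr$time_ns <= checkpoints[j] + 1e-9
    r <- ratio_of(mask)
    if (is.na(r)) {
      warning(sprintf(
        "empty compartment at checkpoint %g ns; logP reported as missing",
        checkpoints[j]))
      next
    }
    series$logp[j] <- log10(r)
    ## block average within [0, t]: by particle groups when the ensemble has
    ## enough independent walkers, else by time blocks
    pids <- unique(fr$particle_id)
    if (length(pids) >= 2L * n_blocks) {
      grp <- match(fr$particle_id, pids) %% n_blocks + 1L
      bi <- grp[mask]
    } else {
      brks <- seq(0, checkpoints[j] + 1e-9, length.out = n_blocks + 1L)
      bi <- findInterval(fr$time_ns[mask], brks, all.inside = TRUE)
    }
    bl <- vapply(seq_len(n_blocks), function(b) {
      m2 <- which(mask)[bi == b]
      nl <- sum(in_lip[m2]); nw <- sum(!in_lip[m2])
      if (nl == 0 || nw == 0) return(NA_real_)
      log10((nl / l_lip) / (nw / l_wat))
    }, numeric(1))
    bl <- bl[is.finite(bl)]
    if (length(bl) >= 2) series$stderr[j] <- stats::sd(bl) / sqrt(length(bl))
  }
  last <- nrow(series)
  structure(list(logp = series$logp[last], stderr = series$stderr[last],
                 series = series, method = "trajectory"),
            class = "logp_estimate")
}

#' @rdname logp_from_trajectory
#' @param pmf a [pmf_profile] referenced to bulk water.
#' @export
logp_from_pmf <- function(pmf, regions) {
  stopifnot(inherits(pmf, "pmf_profile"), inherits(regions, "region_model"))
  if (is.na(pmf$reference)) stop("PMF must be referenced to bulk water")
  if (regions$b12 > max(pmf$z) || -regions$b12 < min(pmf$z)) {
    stop("lipid region extends outside the PMF grid")
  }
  beta <- 1 / thermal_energy(pmf$temperature)
  zb <- regions$b12
  seg_integral <- function(lo, hi) {
    zz <- sort(unique(c(pmf$z[pmf$z > lo & pmf$z < hi], lo, hi)))
    aa <- stats::approx(pmf$z, pmf$value, zz)$y
    pracma::trapz(zz, exp(-beta * aa))
  }
  i_lip <- seg_integral(-zb, zb)
  i_wat <- seg_integral(min(pmf$z), -zb) + seg_integral(zb, max(pmf$z))
  l_lip <- 2 * zb
  l_wat <- (max(pmf$z) - min(pmf$z)) - l_lip
  lp <- log10((i_lip / l_lip) / (i_wat / l_wat))
  structure(list(logp = lp, stderr = 0,
                 series = data.frame(time_ns = NA_real_, logp = lp,
                                     stderr = 0),
                 method = "pmf_integral"),
            class = "logp_estimate")
}

#' @export
print.logp_estimate <- function(x, ...) {
  cat(sprintf("logP estimate (%s): %.3f", x$method, x$logp))
  if (is.finite(x$stderr) && x$stderr > 0) cat(sprintf(" +/- %.3f", x$stderr))
  cat("\n")
  invisible(x)
}
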
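## deterministic golden-section spiral on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area by the rolling-probe test-point method
#'
#' Shrake-Rupley algorithm: each atom's accessible sphere (radius
#' `r_i + probe_radius`) is covered with a deterministic golden-section
#' spiral of test points; a point is exposed when it lies outside every
#' other atom's accessible sphere. Per-atom area is the exposed fraction
#' times `4 pi (r_i + probe)^2`.
#'
#' @param atom_coords n x 3 matrix in Angstrom.
#' @param radii van der Waals radii in Angstrom (scalar recycled).
#' @param probe_radius probe radius in Angstrom (water: 1.4).
#' @param n_sphere_points test points per atom (>= 100).
#' @return List with `total` (Angstrom^2) and `per_atom`.
#' @examples
#' shrake_rupley_sasa(rbind(c(0, 0, 0)), radii = 1.6)$total # 4*pi*3^2
#' @export
shrake_rupley_sasa <- function(atom_coords, radii, probe_radius = 1.4,
                               n_sphere_points = 960L) {
  atom_coords <- as.matrix(atom_coords)
  n <- nrow(atom_coords)
  stopifnot(ncol(atom_coords) == 3L, n >= 1, n_sphere_points >= 100)
  radii <- rep_len(radii, n)
  if (any(radii <= 0) || probe_radius < 0) stop("radii must be positive")
  sp <- sphere_points(n_sphere_points)
  acc <- radii + probe_radius
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sp * acc[i], 2, atom_coords[i, ], "+")
    exposed <- rep(TRUE, n_sphere_points)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (pts[, 1] - atom_coords[j, 1])^2 +
        (pts[, 2] - atom_coords[j, 2])^2 +
        (pts[, 3] - atom_coords[j, 3])^2
      ## points exactly on a neighbor's accessible sphere count as buried,
      ## so coincident duplicates are fully buried rather than half-exposed
      exposed <- exposed & d2 > acc[j]^2 * (1 + 1e-9)
      if (!any(exposed)) break
    }
    per_atom[i] <- sum(exposed) / n_sphere_points * 4 * pi * acc[i]^2
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Clustering by fast search of density peaks
#'
#' For each point, the local density `rho_i` counts neighbors within the
#' cutoff distance `d_c`, and the separation `delta_i` is the distance to
#' the nearest point of higher density (the global maximum distance for the
#' densest point; ties in rho are broken by index, lower index counting as
#' denser). Cluster centers are the points with the largest
#' `gamma_i = rho_i * delta_i`: either the top `n_centers`, or, when
#' `n_centers` is `NULL`, the points above the largest gap in the sorted
#' gamma sequence (decision-graph auto-selection). Every remaining point
#' inherits, in order of decreasing density, the label of its nearest
#' higher-density neighbor.
#'
#' @param points n x d numeric matrix (standardize features upstream).
#' @param d_c cutoff distance; default: the 2nd percentile of the pairwise
#'   distance distribution.
#' @param n_centers number of clusters, or `NULL` for auto-selection.
#' @return An object of class `cluster_result` with `labels`, `centers`
#'   (indices), `rho`, `delta`, `gamma` and `d_c`.
#' @export
density_peak_cluster <- function(points, d_c = NULL, n_centers = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop("clustering needs at least 2 points")
  dmat <- as.matrix(stats::dist(points))
  if (is.null(d_c)) {
    d_c <- stats::quantile(dmat[lower.tri(dmat)], 0.02, names = FALSE)
    if (d_c <= 0) d_c <- min(dmat[lower.tri(dmat)][dmat[lower.tri(dmat)] > 0],
                             1e-12)
  }
  if (d_c <= 0) stop("d_c must be positive")
  rho <- rowSums(dmat <= d_c) - 1L
  ord <- order(-rho, seq_len(n))          # density order, index-tie-broken
  delta <- numeric(n)
  nn_higher <- integer(n)
  delta[ord[1L]] <- max(dmat[ord[1L], ])
  nn_higher[ord[1L]] <- NA_integer_
  for (k in seq_len(n)[-1L]) {
    i <- ord[k]
    higher <- ord[seq_len(k - 1L)]
    j <- higher[which.min(dmat[i, higher])]
    delta[i] <- dmat[i, j]
    nn_higher[i] <- j
  }
  gamma <- rho * delta
  if (is.null(n_centers)) {
    ## decision graph: centers separate from the bulk by a multiplicative
    ## jump in gamma, so the gap is taken on the ratio scale
    gs <- sort(gamma[gamma > 0], decreasing = TRUE)
    if (n == 2L || length(gs) < 2L || all(gs == gs[1L])) {
      k_sel <- 1L
    } else {
      ratios <- gs[-length(gs)] / gs[-1L]
      k_sel <- which.max(ratios)
    }
  } else {
    stopifnot(n_centers >= 1, n_centers <= n)
    k_sel <- as.integer(n_centers)
  }
  centers <- order(-gamma, seq_len(n))[seq_len(k_sel)]
  labels <- integer(n)
  labels[centers] <- seq_len(k_sel)
  for (k in seq_len(n)) {
    i <- ord[k]
    if (labels[i] > 0L) next
    j <- nn_higher[i]
    labels[i] <- if (is.na(j)) {
      labels[centers[which.min(dmat[i, centers])]]
    } else {
      labels[j]
    }
  }
  structure(list(labels = labels, centers = centers, rho = rho,
                 delta = delta, gamma = gamma, d_c = d_c),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Density-peak clustering: %d points, %d cluster(s), d_c = %.4g\n",
              length(x$labels), length(x$centers), x$d_c))
  print(table(cluster = x$labels))
  invisible(x)
}

#' PCA of analog descriptors
#'
#' Principal component analysis of z-scored features (the descriptors live
#' on incomparable scales), via the correlation matrix. The sign convention
#' makes each loading's largest-magnitude entry positive.
#'
#' @param records data.frame of analog records.
#' @param features feature columns to use.
#' @param k number of components to retain.
#' @return An object of class `pca_result` with `loadings` (p x k,
#'   orthonormal), `scores` (n x k) and `explained` (variance fractions,
#'   nonincreasing).
#' @export
pca_reduce <- function(records, features = c("sasa", "dipole", "logp"),
                       k = 2L) {
  stopifnot(all(features %in% names(records)))
  x <- as.matrix(records[, features])
  if (nrow(x) <= k) stop("need more records than retained components")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance feature(s): ", paste(features[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  load <- sweep(load, 2, flip, "*")
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = load, scores = scores,
                 explained = expl[seq_len(min(k, length(expl)))],
                 explained_all = expl),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA of analog descriptors\n  explained variance fractions:",
      paste(sprintf("%.3f", x$explained), collapse = ", "), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Correlation between molecular size and logP
#'
#' Pearson correlation of SASA against logP with a two-sided t-test p-value,
#' probing whether accessible surface area empirically predicts the
#' partition coefficient across the analog series.
#'
#' @param records data.frame with `sasa` and `logp` columns, n >= 3.
#' @return List with `r`, `p_value`, `n`.
#' @export
volume_logp_correlation <- function(records) {
  stopifnot(all(c("sasa", "logp") %in% names(records)), nrow(records) >= 3)
  if (stats::var(records$sasa) == 0 || stats::var(records$logp) == 0) {
    stop("zero variance in sasa or logp")
  }
  ct <- stats::cor.test(records$sasa, records$logp)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(records))
}
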
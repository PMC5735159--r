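## Independent reference implementations used as oracles.

## Plain O(n^2) density-peak reference: written directly from the algorithm
## definition (cutoff density, min distance to a denser point, top-gamma
## centers, descending-density label inheritance), independent of the
## package implementation.
ref_density_peak <- function(points, d_c, n_centers) {
  points <- as.matrix(points)
  n <- nrow(points)
  dm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dm[i, j] <- sqrt(sum((points[i, ] - points[j, ])^2))
    }
  }
  rho <- integer(n)
  for (i in seq_len(n)) rho[i] <- sum(dm[i, -i] <= d_c)
  ## "denser" = higher rho, ties broken by lower index
  denser_than <- function(i, j) (rho[j] > rho[i]) || (rho[j] == rho[i] && j < i)
  delta <- numeric(n)
  nnh <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ds <- Inf
    for (j in seq_len(n)) {
      if (j != i && denser_than(i, j) && dm[i, j] < ds) {
        ds <- dm[i, j]
        nnh[i] <- j
      }
    }
    delta[i] <- if (is.finite(ds)) ds else max(dm[i, ])
  }
  gamma <- rho * delta
  centers <- order(-gamma, seq_len(n))[seq_len(n_centers)]
  labels <- integer(n)
  labels[centers] <- seq_len(n_centers)
  for (i in order(-rho, seq_len(n))) {
    if (labels[i] == 0L) {
      labels[i] <- if (is.na(nnh[i])) {
        labels[centers[which.min(dm[i, centers])]]
      } else {
        labels[nnh[i]]
      }
    }
  }
  labels
}

## Monte-Carlo SASA oracle: uniform random points on each accessible sphere.
mc_sasa <- function(coords, radii, probe = 1.4, n_points = 1e5, seed = 99) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  radii <- rep_len(radii, n)
  acc <- radii + probe
  withr::with_seed(seed, {
    total <- 0
    for (i in seq_len(n)) {
      v <- matrix(stats::rnorm(3 * n_points), ncol = 3)
      v <- v / sqrt(rowSums(v^2))
      pts <- sweep(v * acc[i], 2, coords[i, ], "+")
      exposed <- rep(TRUE, n_points)
      for (j in seq_len(n)) {
        if (j == i) next
        d2 <- rowSums(sweep(pts, 2, coords[j, ])^2)
        exposed <- exposed & d2 > acc[j]^2
      }
      total <- total + mean(exposed) * 4 * pi * acc[i]^2
    }
    total
  })
}

## Brute-force WHAM for two windows: grid search over the single free window
## constant minimizing the binned negative log-likelihood.
wham_two_window_gridsearch <- function(wset, grid_step, f2_grid) {
  stopifnot(length(wset$windows) == 2L)
  beta <- 1 / memperm::thermal_energy(wset$temperature)
  all_z <- unlist(lapply(wset$windows, `[[`, "samples"))
  lo <- floor(min(all_z) / grid_step) * grid_step
  hi <- ceiling(max(all_z) / grid_step) * grid_step
  edges <- seq(lo, hi, by = grid_step)
  mid <- edges[-length(edges)] + grid_step / 2
  h <- sapply(wset$windows, function(w) {
    tabulate(findInterval(w$samples, edges, rightmost.closed = TRUE,
                          all.inside = TRUE), nbins = length(mid))
  })
  ## Simpson bin-average of the bias factor, as in the estimator under test
  cmat <- sapply(wset$windows, function(w) {
    qw <- c(1, 4, 1) / 6
    qz <- c(-0.5, 0, 0.5) * grid_step
    cb <- 0
    for (q in 1:3) {
      cb <- cb + qw[q] * exp(-beta * 0.5 * w$force_const *
                               (mid + qz[q] - w$center)^2)
    }
    cb
  })
  nsamp <- sapply(wset$windows, function(w) length(w$samples))
  pooled <- rowSums(h)
  occ <- pooled > 0
  nll <- function(f2) {
    g <- beta * c(0, f2)
    d <- as.vector(cmat[occ, ] %*% (nsamp * exp(g)))
    sum(pooled[occ] * log(d)) - sum(nsamp * g)
  }
  vals <- vapply(f2_grid, nll, numeric(1))
  f2_grid[which.min(vals)]
}
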
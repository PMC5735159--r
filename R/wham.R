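#' Set of umbrella-sampling windows
#'
#' @param windows list of windows, each a list with `center` (Angstrom),
#'   `force_const` (kcal/mol/Angstrom^2, 0 allowed for an unbiased window)
#'   and `samples` (numeric z values).
#' @param temperature Kelvin.
#' @return An object of class `umbrella_window_set`.
#' @export
umbrella_window_set <- function(windows, temperature) {
  stopifnot(is.list(windows), length(windows) >= 1, temperature > 0)
  for (w in windows) {
    if (!all(c("center", "force_const", "samples") %in% names(w))) {
      stop("each window needs center, force_const and samples")
    }
    if (!length(w$samples)) stop("every window must be non-empty")
    if (w$force_const < 0) stop("force_const must be >= 0")
  }
  structure(list(windows = windows, temperature = as.numeric(temperature)),
            class = "umbrella_window_set")
}

#' @export
print.umbrella_window_set <- function(x, ...) {
  n <- vapply(x$windows, function(w) length(w$samples), integer(1))
  cat(sprintf("Umbrella window set: %d windows, %d samples total, T = %g K\n",
              length(x$windows), sum(n), x$temperature))
  invisible(x)
}

#' Reconstruct a PMF from umbrella windows by WHAM
#'
#' Binned weighted-histogram analysis: the unbiased probability of bin b is
#' estimated as
#' `p_b = sum_i h_ib / sum_i n_i exp(beta f_i) c_ib`,
#' with `c_ib = exp(-beta k_i/2 (z_b - z_i)^2)` the bias factor and the
#' window constants updated self-consistently from
#' `exp(-beta f_i) = sum_b c_ib p_b` until the largest change in any `f_i`
#' falls below `tol`. The profile is `-kT log p_b`, shifted so the reference
#' zone (default: outermost 5 Angstrom at each end) averages to zero.
#' Per-bin standard errors follow from Poisson counting statistics
#' propagated through the log: `kT / sqrt(pooled counts)`.
#'
#' Bins with zero pooled counts are reported as `NA`, never interpolated.
#'
#' The Poisson errors are per-bin counting errors only; they do not carry
#' the uncertainty of stitching window constants together, which accumulates
#' over long window chains. `stderr_method = "bootstrap"` instead
#' block-bootstraps each window's sample series (10 blocks per window) and
#' repeats the full reconstruction, capturing both contributions.
#'
#' @param wset an [umbrella_window_set].
#' @param grid_step bin width in Angstrom.
#' @param tol convergence tolerance on the window constants, kcal/mol.
#' @param max_iter iteration cap; exceeding it is an error that reports the
#'   residual.
#' @param species species label for the output profile.
#' @param reference_zone passed to [rereference()].
#' @param stderr_method `"poisson"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap replicates.
#' @param boot_seed seed for the bootstrap resampling.
#' @return A [pmf_profile] at the window-set temperature, with the pooled
#'   per-bin counts in `$pooled_counts`.
#' @export
wham_reconstruct <- function(wset, grid_step = 0.5, tol = 1e-7,
                             max_iter = 100000L, species = "neutral",
                             reference_zone = "bulk",
                             stderr_method = c("poisson", "bootstrap"),
                             n_boot = 20L, boot_seed = 1L) {
  stderr_method <- match.arg(stderr_method)
  stopifnot(inherits(wset, "umbrella_window_set"), grid_step > 0, tol > 0)
  check_window_connectivity(wset)
  beta <- 1 / thermal_energy(wset$temperature)
  all_z <- unlist(lapply(wset$windows, `[[`, "samples"))
  lo <- floor(min(all_z) / grid_step) * grid_step
  hi <- ceiling(max(all_z) / grid_step) * grid_step
  edges <- seq(lo, hi, by = grid_step)
  if (length(edges) < 3L) stop("grid_step too coarse for the sampled range")
  mid <- edges[-length(edges)] + grid_step / 2
  nb <- length(mid)
  nw <- length(wset$windows)
  h <- matrix(0, nrow = nb, ncol = nw)       # counts per bin per window
  cmat <- matrix(0, nrow = nb, ncol = nw)    # bias factors
  nsamp <- numeric(nw)
  for (i in seq_len(nw)) {
    w <- wset$windows[[i]]
    idx <- findInterval(w$samples, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    h[, i] <- tabulate(idx, nbins = nb)
    nsamp[i] <- length(w$samples)
    ## bias factor averaged over each bin (Simpson), not taken at the bin
    ## center: the center-point value biases narrow-window reconstructions
    qw <- c(1, 4, 1) / 6
    qz <- c(-0.5, 0, 0.5) * grid_step
    cb <- 0
    for (q in 1:3) {
      cb <- cb + qw[q] *
        exp(-beta * 0.5 * w$force_const * (mid + qz[q] - w$center)^2)
    }
    cmat[, i] <- cb
  }
  pooled <- rowSums(h)
  ## The self-consistent equations are the stationarity conditions of the
  ## convex WHAM log-likelihood in g_i = beta f_i (invariant under a uniform
  ## shift; g_1 pinned to 0). A quasi-Newton solve followed by
  ## self-consistent polishing reaches tight tolerances quickly.
  occ <- pooled > 0
  nll <- function(x) {
    g <- c(0, x)
    d <- as.vector(cmat[occ, , drop = FALSE] %*% (nsamp * exp(g)))
    sum(pooled[occ] * log(d)) - sum(nsamp * g)
  }
  nll_grad <- function(x) {
    g <- c(0, x)
    eg <- nsamp * exp(g)
    d <- as.vector(cmat[occ, , drop = FALSE] %*% eg)
    gr <- eg * as.vector(t(cmat[occ, , drop = FALSE]) %*% (pooled[occ] / d)) - nsamp
    gr[-1L]
  }
  g <- numeric(nw)
  if (nw > 1L) {
    opt <- stats::optim(numeric(nw - 1L), nll, nll_grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    g <- c(0, opt$par)
  }
  f <- g / beta
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    denom <- cmat %*% (nsamp * exp(beta * f))
    p <- pooled / as.vector(denom)
    p[pooled == 0] <- 0
    z_i <- as.vector(t(cmat) %*% p)          # = exp(-beta f_i)
    f_new <- -log(z_i) / beta
    f_new <- f_new - f_new[1L]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kcal/mol)",
                 max_iter, delta))
  }
  p <- p / sum(p)
  a <- ifelse(pooled > 0, -log(p) / beta, NA_real_)
  se <- ifelse(pooled > 0, (1 / beta) / sqrt(pooled), NA_real_)
  prof <- pmf_profile(mid, a - min(a, na.rm = TRUE), stderr = se,
                      temperature = wset$temperature, species = species,
                      reference = NA)
  prof <- rereference(prof, reference_zone)
  prof$pooled_counts <- pooled
  prof$window_constants <- f   # converged window free energies, kcal/mol
  if (stderr_method == "bootstrap") {
    reps <- withr::with_seed(boot_seed, {
      lapply(seq_len(n_boot), function(b) {
        rws <- lapply(wset$windows, function(w) {
          nblk <- 10L
          blocks <- split(w$samples,
                          cut(seq_along(w$samples), nblk, labels = FALSE))
          w$samples <- unlist(blocks[sample.int(nblk, nblk, replace = TRUE)],
                              use.names = FALSE)
          w
        })
        wham_reconstruct(umbrella_window_set(rws, wset$temperature),
                         grid_step = grid_step, tol = tol,
                         max_iter = max_iter, species = species,
                         reference_zone = reference_zone)
      })
    })
    boot_vals <- vapply(reps, function(r) {
      r$value[match(round(prof$z / grid_step), round(r$z / grid_step))]
    }, numeric(length(prof$z)))
    prof$stderr <- apply(boot_vals, 1, stats::sd, na.rm = TRUE)
  }
  prof
}

check_window_connectivity <- function(wset) {
  rng <- t(vapply(wset$windows,
                  function(w) range(w$samples), numeric(2)))
  ord <- order(rng[, 1L])
  cur_hi <- rng[ord[1L], 2L]
  for (j in seq_along(ord)[-1L]) {
    i <- ord[j]
    if (rng[i, 1L] > cur_hi) {
      stop(sprintf(
        "window sample ranges are disconnected: gap between z = %.3g and z = %.3g A",
        cur_hi, rng[i, 1L]))
    }
    cur_hi <- max(cur_hi, rng[i, 2L])
  }
  invisible(TRUE)
}
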
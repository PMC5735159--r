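#' Run the full demonstration pipeline
#'
#' Exercises every stage end to end on synthetic data and writes all
#' intermediate and summary files to `out_dir`: PMF families for both
#' species at 305/310/315 K, an umbrella-sampling run reconstructed by WHAM,
#' the entropy/internal-energy decomposition with its compensation fit, the
#' thermodynamic-cycle pKa profile and its physiological crossing, region
#' detection and both logP estimators on a Brownian trajectory, the field
#' oscillation profile, and the analog survey (clustering, PCA, size-logP
#' correlation). One global seed determines every stage through a fixed
#' splitting rule, so two runs with the same seed produce byte-identical
#' files.
#'
#' Problem sizes are desk-scale on purpose (thousands of umbrella samples,
#' ~2e5 trajectory frames); the summary numbers carry the corresponding
#' statistical error.
#'
#' @param seed integer global seed.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the summary quantities.
#' @export
run_demo_pipeline <- function(seed = 1, out_dir = tempfile("memperm_demo_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  temps <- c(305, 310, 315)

  ## --- free-energy surfaces ------------------------------------------------
  fam_n <- gen_pmf_family(pmf_spec("neutral"), temps, grid_step = 0.5,
                          noise_sd = 0, seed = stage_seed(seed, 1L))
  fam_c <- gen_pmf_family(pmf_spec("charged"), temps, grid_step = 0.5,
                          noise_sd = 0, seed = stage_seed(seed, 2L))
  for (i in seq_along(temps)) {
    write_pmf_tsv(fam_n[[i]], file.path(out_dir, sprintf("pmf_neutral_%dK.tsv", temps[i])))
    write_pmf_tsv(fam_c[[i]], file.path(out_dir, sprintf("pmf_charged_%dK.tsv", temps[i])))
  }

  ## --- umbrella sampling + WHAM -------------------------------------------
  truth <- fam_n[[2L]]
  centers <- seq(-36, 36, by = 1.5)
  wset <- gen_umbrella_samples(truth, centers, force_const = 2.5,
                               n_per_window = 5000,
                               seed = stage_seed(seed, 3L))
  write_windows_tsv(wset, file.path(out_dir, "windows_neutral.tsv"))
  recon <- wham_reconstruct(wset, grid_step = 0.5)
  write_pmf_tsv(recon, file.path(out_dir, "pmf_neutral_wham.tsv"))
  ok <- is.finite(recon$value) & recon$pooled_counts >= 100
  tru_on_grid <- stats::approx(truth$z, truth$value, recon$z[ok])$y
  tru_on_grid <- tru_on_grid - mean(tru_on_grid[reference_mask(recon$z[ok], "bulk")])
  wham_rms <- sqrt(mean((recon$value[ok] - tru_on_grid)^2))

  ## --- decomposition and compensation -------------------------------------
  td <- decompose_thermo(fam_n[[1L]], fam_n[[2L]], fam_n[[3L]])
  utils::write.table(
    data.frame(z = td$z, dA = td$dA, minus_TdS = td$minus_TdS, dU = td$dU),
    file.path(out_dir, "decomposition_neutral.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  comp <- compensation_fit(td, z_mask = c(-30, 30))

  ## --- pKa profile ---------------------------------------------------------
  pka <- pka_profile(fam_n[[2L]], fam_c[[2L]], pka_water = 9.6)
  utils::write.table(data.frame(z = pka$z, pka = pka$pka, stderr = pka$stderr),
                     file.path(out_dir, "pka_profile.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  crossings <- find_pka_crossing(pka, 7)

  ## --- partitioning --------------------------------------------------------
  regions <- detect_regions(gen_density_preset())
  lspec <- langevin_spec(diffusion_coefficient = 100, timestep = 2e-3,
                         n_steps = 500L, temperature = 310,
                         seed = stage_seed(seed, 4L), box = c(40, 40, 80),
                         n_particles = 400L, burn_in = 100L)
  traj <- gen_langevin_traj(truth, lspec)
  lp_tr <- logp_from_trajectory(traj, regions)
  lp_or <- logp_from_pmf(truth, regions)
  utils::write.table(lp_tr$series, file.path(out_dir, "logp_running.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  ## --- field profile -------------------------------------------------------
  snaps <- gen_charge_snapshots(120, slab_layout(), seed = stage_seed(seed, 5L))
  fp <- local_field_profile(snaps)
  utils::write.table(as.data.frame(fp), file.path(out_dir, "field_profile.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  i_wat <- c(1L, nrow(fp))
  i_core <- which.min(abs(fp$z_slab))
  field_ratio <- mean(fp$oscillation[i_wat]) / fp$oscillation[i_core]

  ## --- analog survey -------------------------------------------------------
  analogs <- gen_analog_table(seed = stage_seed(seed, 6L))
  write_analog_csv(analogs, file.path(out_dir, "analogs.csv"))
  feats <- scale(as.matrix(analogs[, c("sasa", "dipole", "logp")]))
  cl <- density_peak_cluster(feats, n_centers = 4)
  pc <- pca_reduce(analogs)
  corr <- volume_logp_correlation(analogs)

  summary <- list(
    wham_rms_kcal = wham_rms,
    compensation_slope = comp$slope,
    pka_center = pka$pka[which.min(abs(pka$z))],
    pka_crossings = crossings,
    logp_trajectory = lp_tr$logp,
    logp_pmf = lp_or$logp,
    field_water_core_ratio = field_ratio,
    n_clusters = length(cl$centers),
    sasa_logp_r = corr$r,
    pc1_top_loading = rownames(pc$loadings)[which.max(abs(pc$loadings[, 1]))]
  )
  fmt_field <- function(v) {
    v <- unlist(v)
    if (is.numeric(v)) v <- signif(v, 6)
    paste(v, collapse = " ")
  }
  writeLines(paste(names(summary), vapply(summary, fmt_field, character(1)),
                   sep = "\t"),
             file.path(out_dir, "summary.tsv"))
  invisible(summary)
}
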
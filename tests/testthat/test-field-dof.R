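test_that("the field from a single charge follows Coulomb's law to 1e-6", {
  ## probe at origin, +1 e charge 5 A above it, partner far below to keep
  ## the snapshot neutral; huge box so no periodic images interfere
  s <- charged_snapshot(rbind(c(100, 100, 5), c(100, 100, -150)),
                        c(1, -1), c(200, 200, 400))
  ez <- memperm:::field_z_at(s, rbind(c(100, 100, 0)), cutoff = 90)
  expected <- -coulomb_constant() * (1 / 25 + 1 / 150^2)
  expect_equal(ez, expected, tolerance = 1e-6)
})

test_that("a mirror-symmetric charge pair cancels at the midpoint probe", {
  s <- charged_snapshot(rbind(c(10, 10, 4), c(10, 10, -4)), c(1, -1),
                        c(40, 40, 40))
  ez <- memperm:::field_z_at(s, rbind(c(10, 10, 0)), cutoff = 15)
  ## both charges push the field the same way here; use a same-sign pair
  s2 <- charged_snapshot(rbind(c(10, 10, 4), c(10, 10, -4), c(30, 30, 0),
                               c(30, 30, 1)),
                         c(1, 1, -1, -1), c(80, 80, 40))
  ez2 <- memperm:::field_z_at(s2, rbind(c(10, 10, 0)), cutoff = 15)
  expect_equal(ez2, 0, tolerance = 1e-9)
  expect_false(abs(ez) < 1e-9)
})

test_that("the field profile is exactly linear in the charges", {
  snaps1 <- gen_charge_snapshots(5, slab_layout(), seed = 3)
  layout2 <- slab_layout(amplitudes = 2 * c(7, 2, 1, 2, 7) * 0.2)
  snaps2 <- gen_charge_snapshots(5, layout2, seed = 3)
  f1 <- local_field_profile(snaps1)
  f2 <- local_field_profile(snaps2)
  expect_equal(f2$mean_field, 2 * f1$mean_field, tolerance = 1e-9)
  expect_equal(f2$oscillation, 2 * f1$oscillation, tolerance = 1e-9)
})

test_that("zero-amplitude layouts produce zero charges and fields", {
  snaps <- gen_charge_snapshots(3, slab_layout(amplitudes = rep(0, 5)),
                                seed = 1)
  expect_true(all(vapply(snaps, function(s) all(s$charges == 0), logical(1))))
  fp <- local_field_profile(snaps)
  expect_true(all(fp$mean_field == 0))
})

test_that("slab snapshots are deterministic in the seed and electroneutral", {
  a <- gen_charge_snapshots(2, slab_layout(), seed = 9)
  b <- gen_charge_snapshots(2, slab_layout(), seed = 9)
  expect_identical(a, b)
  expect_error(slab_layout(net_charge = 1), "non-neutral")
  for (s in a) expect_lt(abs(sum(s$charges)), 1e-9)
})

test_that("water/core oscillation ratio tracks the layout amplitude ratio", {
  fp <- local_field_profile(gen_charge_snapshots(120, slab_layout(), seed = 2))
  core <- which.min(abs(fp$z_slab))
  ratio <- mean(fp$oscillation[c(1, nrow(fp))]) / fp$oscillation[core]
  expect_gt(ratio, 6)
  expect_lt(ratio, 8)
  ## time-mean field is zero within 3 SE in every slab
  se <- fp$oscillation / sqrt(fp$n_frames)
  expect_true(all(abs(fp$mean_field) < 3.5 * se))
})

test_that("footprint area counts occupied cells", {
  tr <- trajectory_ensemble(data.frame(
    time_ns = c(0.01, 0.02), particle_id = 1L, species = "drug",
    x = 5.2, y = 7.8, z = 0), c(40, 40, 80))
  expect_equal(footprint_area(tr, c(-1, 1), cell = 1), 1)
  expect_error(footprint_area(tr, c(10, 20)), "no frames")
})

test_that("uniform xy coverage approaches the full cross-section", {
  n <- 1e5
  tr <- withr::with_seed(4, trajectory_ensemble(data.frame(
    time_ns = seq_len(n) * 1e-3, particle_id = 1L, species = "drug",
    x = runif(n, 0, 40), y = runif(n, 0, 40), z = 0), c(40, 40, 80)))
  a <- footprint_area(tr, c(-1, 1), cell = 2)
  expect_equal(a, 1600, tolerance = 0.02)
})

test_that("slower lateral diffusion shrinks the footprint", {
  pmf <- pmf_profile(seq(-42, 42, 0.5), 0, temperature = 310)
  mk <- function(d) gen_langevin_traj(pmf, langevin_spec(
    diffusion_coefficient = d, timestep = 1e-3, n_steps = 2000L,
    n_particles = 1L, seed = 6))
  a_small <- footprint_area(mk(5), c(-40, 40), cell = 2)
  a_large <- footprint_area(mk(80), c(-40, 40), cell = 2)
  expect_lt(a_small, a_large)
})

test_that("dipoles along +z put all orientation mass at cos(theta) = 1", {
  tr <- gen_dof_ensemble(500, seed = 1)
  tr$frames$mu_x <- 0; tr$frames$mu_y <- 0; tr$frames$mu_z <- 5
  oh <- orientation_histogram(tr, z_bins = c(-40, 0, 40))
  expect_equal(unname(oh$density[, ncol(oh$density)]), c(1, 1))
  expect_equal(rowSums(oh$density), c("1" = 1, "2" = 1))
})

test_that("isotropic dipoles are uniform in cos(theta)", {
  tr <- gen_dof_ensemble(20000, orientation_kappa = 0, seed = 2)
  oh <- orientation_histogram(tr, z_bins = c(-40, 40),
                              costheta_bins = seq(-1, 1, length.out = 11))
  counts <- oh$density[1, ] * 20000
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("an orienting potential narrows the circular spread in the core", {
  free <- gen_dof_ensemble(20000, orientation_kappa = 0, seed = 3)
  held <- gen_dof_ensemble(20000, orientation_kappa = 8, seed = 3)
  v <- function(tr) {
    mu <- cbind(tr$frames$mu_x, tr$frames$mu_y, tr$frames$mu_z)
    ct <- mu[, 3] / sqrt(rowSums(mu^2))
    sel <- abs(tr$frames$z) < 10
    stats::var(ct[sel])
  }
  expect_lt(v(held), v(free))
})

test_that("dipole magnitude statistics recover the generator moments", {
  tr <- gen_dof_ensemble(30000, dipole_mean = 5, dipole_sd = 0.8, seed = 4)
  ds <- dipole_stats(tr, z_bins = seq(-30, 30, 20))
  occ <- ds$stats$n > 1000
  expect_true(all(abs(ds$stats$mean[occ] - 5) < 0.1))
  expect_true(all(abs(ds$stats$sd[occ] - 0.8) < 0.08))
  for (h in ds$histograms[occ]) expect_equal(sum(h), 1, tolerance = 1e-9)
  ## broader preset shows larger per-bin SD than a narrow one
  narrow <- gen_dof_ensemble(30000, dipole_mean = 5, dipole_sd = 0.4, seed = 4)
  dn <- dipole_stats(narrow, z_bins = seq(-30, 30, 20))
  expect_true(all(dn$stats$sd[occ] < ds$stats$sd[occ]))
})

test_that("constant dipole magnitude gives zero spread in every bin", {
  tr <- gen_dof_ensemble(200, seed = 5)
  tr$frames$mu_x <- 0; tr$frames$mu_y <- 3; tr$frames$mu_z <- 4
  ds <- dipole_stats(tr, z_bins = c(-40, 0, 40))
  expect_equal(ds$stats$mean, c(5, 5))
  expect_equal(ds$stats$sd, c(0, 0))
})

test_that("ring offsets are histogrammed per depth with unit mass", {
  tr <- gen_dof_ensemble(1000, ring_offset_mean = 2, ring_offset_sd = 0,
                         seed = 6)
  dz <- delta_z_distribution(tr, z_bins = c(-40, 0, 40))
  for (b in 1:2) {
    expect_equal(sum(dz$density[b, ]), 1, tolerance = 1e-9)
    mids <- (dz$dz_breaks[-1] + dz$dz_breaks[-length(dz$dz_breaks)]) / 2
    expect_equal(sum(dz$density[b, ] * mids), 2, tolerance = 0.1)
  }
  tr2 <- gen_dof_ensemble(100, ring_offset_mean = 0, ring_offset_sd = 0,
                          seed = 7)
  dz2 <- delta_z_distribution(tr2, z_bins = c(-40, 40))
  mids <- (dz2$dz_breaks[-1] + dz2$dz_breaks[-length(dz2$dz_breaks)]) / 2
  expect_equal(sum(dz2$density[1, ] * mids), 0, tolerance = 1e-9)
  tr2$frames$ring1_z <- NULL
  tr3 <- trajectory_ensemble(tr2$frames, tr2$box)
  expect_error(delta_z_distribution(tr3, c(-40, 40)), "ring")
})

test_that("dipole_from_charges converts e*Angstrom to Debye and is translation invariant", {
  d <- dipole_from_charges(rbind(c(0, 0, 0), c(0, 0, 1)), c(1, -1))
  expect_equal(d$magnitude, 4.8032)
  ## neutral systems: invariant under random shifts
  coords <- rbind(c(0, 0, 0), c(1, 2, 0.5), c(-1, 0, 2))
  q <- c(0.4, -0.7, 0.3)
  base <- dipole_from_charges(coords, q)$vector
  for (s in 1:3) {
    shift <- withr::with_seed(s, rnorm(3, 0, 10))
    shifted <- dipole_from_charges(sweep(coords, 2, -shift), q)$vector
    expect_equal(shifted, base, tolerance = 1e-9)
  }
  expect_error(dipole_from_charges(coords, c(1, 0, 0)), "reference")
})

test_that("conformer ensembles reproduce the protonation-dependent dipole trend", {
  for (m in c("neutral", "charged")) {
    cf <- gen_conformers(50, charge_model = m, seed = 4)
    mu <- vapply(cf, function(c) {
      dipole_from_charges(c$coords, c$charges, reference = "com")$magnitude
    }, numeric(1))
    d <- vapply(cf, `[[`, numeric(1), "bn_distance")
    r <- cor(mu, d)
    if (m == "neutral") expect_lt(r, 0) else expect_gt(r, 0)
  }
  expect_error(gen_conformers(1), "at least 2")
})
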
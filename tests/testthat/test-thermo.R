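make_family <- function(species = "neutral", temps = c(305, 310, 315)) {
  gen_pmf_family(pmf_spec(species), temps, seed = 1)
}

test_that("temperature-independent profiles decompose to zero entropy", {
  z <- seq(-10, 10, 0.5)
  mk <- function(tt) pmf_profile(z, sin(z / 3), temperature = tt)
  td <- decompose_thermo(mk(305), mk(310), mk(315))
  expect_equal(td$minus_TdS, rep(0, length(z)))
  expect_equal(td$dU, td$dA)
})

test_that("the central difference is exact for linear-in-T families", {
  s0 <- 0.01
  sp <- pmf_spec(entropy_terms = data.frame(center = 0, width = 6,
                                            amplitude = s0),
                 features = data.frame(center = 0, width = 6, height = 2),
                 z_range = c(-20, 20))
  fam <- gen_pmf_family(sp, c(305, 310, 315), seed = 1)
  td <- decompose_thermo(fam[[1]], fam[[2]], fam[[3]])
  i0 <- which(td$z == 0)
  ## A = U0 - T*S0, so the entropic term is -T*s0 = -3.10 kcal/mol exactly
  expect_equal(td$minus_TdS[i0], -310 * s0, tolerance = 1e-12)
  expect_equal(td$dU[i0], 2, tolerance = 1e-12)
  ## the finite-difference prefactor at the 305/315 K pair is T/(2 dT) = 31
  expect_equal(td$base_T / (2 * td$delta_T), 31)
  ## identity dA = dU + (-T dS) holds at machine precision
  expect_lt(max(abs(td$dA - td$dU - td$minus_TdS)), 1e-12)
})

test_that("non-polynomial-in-T families show O(dT^2) error halving 4x with dT", {
  ## a cubic-in-T profile: central differences are exact for anything up to
  ## quadratic, so the cubic term isolates the O(dT^2) truncation error
  z <- seq(-10, 10, 0.5)
  a_of <- function(tt) pmf_profile(z, exp(-z^2 / 8) * (tt / 310)^3,
                                   temperature = tt)
  exact_tds <- 310 * (3 * 310^2 / 310^3) * exp(-z^2 / 8)
  err <- sapply(c(5, 2.5), function(dt) {
    td <- decompose_thermo(a_of(310 - dt), a_of(310), a_of(310 + dt))
    max(abs(td$minus_TdS - exact_tds))
  })
  expect_equal(err[1] / err[2], 4.0, tolerance = 0.3)
})

test_that("grid and temperature symmetry violations are rejected", {
  z <- seq(-10, 10, 0.5)
  p1 <- pmf_profile(z, 0, temperature = 305)
  p2 <- pmf_profile(z, 0, temperature = 310)
  p3 <- pmf_profile(z, 0, temperature = 314)
  expect_error(decompose_thermo(p1, p2, p3), "symmetric")
  q <- pmf_profile(seq(-10, 10, 1), 0, temperature = 315)
  expect_error(decompose_thermo(p1, p2, q), "grid")
})

test_that("perfect compensation returns slope -1 and r -1", {
  z <- seq(-10, 10, 0.5)
  tds <- sin(z / 2)
  td <- structure(list(z = z, dA = rep(2, length(z)), minus_TdS = tds,
                       dU = 2 - tds, base_T = 310, delta_T = 5,
                       stderr = list()), class = "thermo_decomposition")
  fit <- compensation_fit(td)
  expect_equal(fit$slope, -1)
  expect_equal(fit$pearson_r, -1)
})

test_that("a planted compensation slope is recovered within 0.05", {
  slope <- -0.8
  tds <- seq(-3, 3, length.out = 60)
  noise <- withr::with_seed(11, rnorm(60, 0, 0.1))
  du <- slope * tds + 1 + noise
  td <- structure(list(z = seq_along(tds), dA = du + tds, minus_TdS = tds,
                       dU = du, base_T = 310, delta_T = 5, stderr = list()),
                  class = "thermo_decomposition")
  fit <- compensation_fit(td)
  expect_lt(abs(fit$slope - slope), 0.05)
  expect_error(compensation_fit(td, c(100, 200)), "at least 3")
})

test_that("equal species PMFs leave the pKa at its water value", {
  z <- seq(-10, 10, 0.5)
  pn <- pmf_profile(z, exp(-z^2 / 8), temperature = 310)
  pc <- pmf_profile(z, exp(-z^2 / 8), temperature = 310, species = "charged")
  pk <- pka_profile(pn, pc, pka_water = 9.6)
  expect_equal(pk$pka, rep(9.6, length(z)))
})

test_that("the thermodynamic cycle reproduces the hand-computed interior pKa", {
  ## neutral -1 kcal/mol, charged +8 kcal/mol at the center, water pKa 9.6
  z <- c(-0.5, 0.5)
  pn <- pmf_profile(z, -1, temperature = 310)
  pc <- pmf_profile(z, 8, temperature = 310, species = "charged")
  pk <- pka_profile(pn, pc, pka_water = 9.6, temperature = 310)
  hand <- 9.6 - 9 / (log(10) * 1.9872e-3 * 310)
  expect_equal(pk$pka[1], hand, tolerance = 1e-12)
  expect_equal(pk$pka[1], 3.26, tolerance = 0.01)
})

test_that("favorable charged interfacial binding raises the local pKa", {
  z <- seq(-30, 30, 0.5)
  pn <- pmf_profile(z, rep(0, length(z)), temperature = 310)
  pc <- pmf_profile(z, -2 * exp(-(abs(z) - 18)^2 / 4), temperature = 310,
                    species = "charged")
  pk <- pka_profile(pn, pc, pka_water = 9.6)
  expect_gt(pk$pka[which.min(abs(pk$z - 18))], 9.6)
})

test_that("species swap reflects the pKa shift and deepening the charged PMF lowers pKa", {
  fam_n <- make_family("neutral")[[2]]
  fam_c <- make_family("charged")[[2]]
  pk <- pka_profile(fam_n, fam_c, pka_water = 9.6)
  pk_swap <- pka_profile(fam_c, fam_n, pka_water = 9.6)
  expect_equal(pk$pka - 9.6, -(pk_swap$pka - 9.6), tolerance = 1e-12)
  deeper <- fam_c
  deeper$value <- deeper$value + 1
  pk2 <- pka_profile(fam_n, deeper, pka_water = 9.6)
  expect_true(all(pk2$pka <= pk$pka))
})

test_that("unreferenced or mismatched inputs are rejected", {
  z <- seq(-10, 10, 0.5)
  pn <- pmf_profile(z, 0, temperature = 310)
  bad <- pmf_profile(z, 0, temperature = 310, species = "charged",
                     reference = NA)
  expect_error(pka_profile(pn, bad), "referenced")
  other <- pmf_profile(seq(-10, 10, 1), 0, temperature = 310,
                       species = "charged")
  expect_error(pka_profile(pn, other), "grid")
})

test_that("pKa crossings are located by linear interpolation", {
  zz <- seq(-10, 10, 1)
  const <- structure(list(z = zz, pka = rep(9.6, 21), stderr = rep(0, 21),
                          pka_water = 9.6, temperature = 310),
                     class = "pka_profile")
  expect_length(find_pka_crossing(const, 7), 0)
  pw <- structure(list(z = c(3, 5), pka = c(8, 6), stderr = c(0, 0),
                       pka_water = 9.6, temperature = 310),
                  class = "pka_profile")
  expect_equal(find_pka_crossing(pw, 7), 4.0)
})

test_that("a calibrated profile crosses pKa 7 near |z| = 4", {
  fam_n <- make_family("neutral")[[2]]
  fam_c <- make_family("charged")[[2]]
  pk <- pka_profile(fam_n, fam_c, pka_water = 9.6)
  cr <- find_pka_crossing(pk, 7)
  expect_gt(length(cr), 0)
  expect_lt(min(abs(abs(cr) - 4)), 2.5)
})
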
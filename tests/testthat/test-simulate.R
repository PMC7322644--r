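test_that("cross pedigrees have the designed F2 family and inbreeding structure", {
  des <- cross_design(n_f1_sires = 20, n_f1_dams = 60, n_f2 = 240,
                      half_sib_families = 10, random_families = 10,
                      full_sib_mating_rate = 0.3, seed = 4)
  ped <- generate_cross_pedigree(des)
  expect_s3_class(ped, "pedigree")
  expect_equal(sum(ped$generation == "F2", na.rm = TRUE), 240)

  f <- compute_inbreeding(ped)
  f2 <- f$f[grepl("^F2", f$animal)]
  # forced full-sib matings put some F2 at exactly 0.25; the cohort mean
  # sits between 0 and that ceiling
  expect_true(any(abs(f2 - 0.25) < 1e-12))
  expect_gt(mean(f2), 0)
  expect_true(all(f2 <= 0.25 + 1e-12))

  # generated pedigrees always pass validation on re-entry
  expect_s3_class(as_pedigree(as.data.frame(ped)[sample(nrow(ped)), ]),
                  "pedigree")
})

test_that("without forced full-sib mating and with ample founders, F2 are non-inbred", {
  des <- cross_design(n_p0_per_line = 120, n_f1_sires = 10, n_f1_dams = 20,
                      n_f2 = 60, half_sib_families = 5, random_families = 5,
                      full_sib_mating_rate = 0, seed = 9)
  ped <- generate_cross_pedigree(des)
  f <- compute_inbreeding(ped)
  expect_equal(max(f$f), 0)
})

test_that("infeasible family structures are rejected", {
  expect_error(generate_cross_pedigree(
    cross_design(n_f1_sires = 5, half_sib_families = 10, random_families = 10)),
    "infeasible")
})

test_that("default design reproduces the study-scale structure", {
  des <- cross_design()
  expect_equal(des$n_f1_sires, 49L)
  expect_equal(des$n_f1_dams, 639L)
  expect_equal(des$n_f2, 2626L)
  expect_equal(des$half_sib_families + des$random_families, 49L)
})

test_that("simulated genetic effects have covariance sigma_a2 A and sigma_d2 D", {
  ped <- small_cross(seed = 3, n_f2 = 12)
  rel <- relationship_matrices(ped)
  truth <- simulation_truth(sigma_a2 = 2, sigma_d2 = 1.5, sigma_e2 = 1)
  n <- nrow(ped)
  reps <- 2000
  am <- matrix(0, n, reps)
  dm <- matrix(0, n, reps)
  for (r in seq_len(reps)) {
    eff <- simulate_genetic_effects(ped, rel, truth, seed = 10000 + r)
    am[, r] <- eff$a
    dm[, r] <- eff$d
  }
  Ca <- tcrossprod(am - rowMeans(am)) / (reps - 1)
  Cd <- tcrossprod(dm - rowMeans(dm)) / (reps - 1)
  # max over ~500 entries, each with Monte-Carlo SD ~ var * sqrt(2/reps)
  expect_lt(max(abs(Ca - 2 * rel$A)), 4.5 * 2 * sqrt(2 / reps) * max(diag(rel$A)))
  expect_lt(max(abs(Cd - 1.5 * rel$D)), 4.5 * 1.5 * sqrt(2 / reps) * max(diag(rel$D)))

  # zero variances give identically zero effects
  eff0 <- simulate_genetic_effects(ped, rel,
                                   simulation_truth(sigma_a2 = 0, sigma_d2 = 0),
                                   seed = 1)
  expect_equal(unname(eff0$a), rep(0, n))
  expect_equal(unname(eff0$d), rep(0, n))

  # reproducibility
  e1 <- simulate_genetic_effects(ped, rel, truth, seed = 42)
  e2 <- simulate_genetic_effects(ped, rel, truth, seed = 42)
  expect_identical(e1, e2)
})

test_that("phenotypes decompose exactly into stored latent parts", {
  ped <- small_cross(seed = 5, n_f2 = 40)
  truth <- simulation_truth(mu = 60, beta_f = -2)
  sim <- simulate_phenotypes(ped, truth, seed = 11)
  y <- sim$phenotypes$L
  lat <- sim$latent
  expect_equal(y, 60 - 2 * lat$f + lat$a + lat$d + lat$e)
  expect_equal(nrow(sim$phenotypes), 40)

  # same seed, same dataset
  sim2 <- simulate_phenotypes(ped, truth, seed = 11)
  expect_identical(sim$phenotypes, sim2$phenotypes)
})

test_that("degenerate truths behave linearly", {
  ped <- small_cross(seed = 6, n_f2 = 30)
  # all variance off: every phenotype equals mu
  t0 <- simulation_truth(mu = 55, beta_f = 0, sigma_a2 = 0, sigma_d2 = 0,
                         sigma_e2 = 0)
  sim <- simulate_phenotypes(ped, t0, seed = 2)
  expect_equal(sim$phenotypes$L, rep(55, 30))

  # beta_f = -10: hens at F = 0.25 sit 2.5 units below non-inbred hens
  t1 <- simulation_truth(mu = 0, beta_f = -10, sigma_a2 = 0, sigma_d2 = 0,
                         sigma_e2 = 0)
  sim1 <- simulate_phenotypes(ped, t1, seed = 2)
  f <- sim1$latent$f
  if (any(f == 0.25) && any(f == 0)) {
    expect_equal(mean(sim1$phenotypes$L[f == 0.25]) -
                   mean(sim1$phenotypes$L[f == 0]), -2.5)
  }
})

test_that("sample phenotypic variance matches the variance decomposition", {
  des <- cross_design(n_f1_sires = 30, n_f1_dams = 100, n_f2 = 1500,
                      half_sib_families = 15, random_families = 15, seed = 21)
  ped <- generate_cross_pedigree(des)
  truth <- simulation_truth(mu = 50, beta_f = 0, sigma_a2 = 2, sigma_d2 = 0,
                            sigma_e2 = 1)
  sim <- simulate_phenotypes(ped, truth, seed = 22)
  f <- compute_inbreeding(ped)
  hens <- match(sim$phenotypes$animal, f$animal)
  # expected variance ~ sigma_a2 * mean diag(A) + sigma_e2 (ignoring the
  # family covariance contribution, hence the loose tolerance)
  expected <- 2 * (1 + mean(f$f[hens])) + 1
  expect_equal(var(sim$phenotypes$L), expected, tolerance = 0.2)
})

test_that("bivariate simulation respects the G0 / R0 structure", {
  ped <- small_cross(seed = 8, n_f2 = 500)
  G0 <- matrix(c(2, -1.2, -1.2, 1.5), 2)
  R0 <- matrix(c(1, 0.3, 0.3, 0.8), 2)
  truth <- simulation_truth(mu = c(10, 20), beta_f = 0, G0 = G0, R0 = R0,
                            traits = c("L", "b"))
  sim <- simulate_phenotypes(ped, truth, seed = 31)
  expect_true(all(c("L", "b") %in% names(sim$phenotypes)))
  # latent reconstruction per trait
  expect_equal(sim$phenotypes$L, 10 + sim$latent$a_1 + sim$latent$e_1)
  expect_equal(sim$phenotypes$b, 20 + sim$latent$a_2 + sim$latent$e_2)
  # residual pairs carry the R0 correlation
  expect_equal(cor(sim$latent$e_1, sim$latent$e_2),
               R0[1, 2] / sqrt(R0[1, 1] * R0[2, 2]), tolerance = 0.15)
})

test_that("injected outliers are recorded and removable", {
  ped <- small_cross(seed = 9, n_f2 = 300)
  sim <- simulate_phenotypes(ped, simulation_truth(sigma_d2 = 0), seed = 3)
  # 10 trait SDs: even a record starting 3 SD on the other side stays
  # far outside the 3-SD screen after the shift inflates the sample SD
  out <- inject_outliers(sim, n = 8, magnitude_sd = 10, seed = 7)
  expect_equal(nrow(out$outliers), 8)

  cleaned <- clean_outliers(out$phenotypes, "L", 3)
  expect_true(all(out$outliers$animal %in% attr(cleaned, "removed_animals")))

  # n = 0 leaves the dataset unchanged
  same <- inject_outliers(sim, n = 0)
  expect_identical(same$phenotypes, sim$phenotypes)

  # same seed, same indices
  out2 <- inject_outliers(sim, n = 8, magnitude_sd = 10, seed = 7)
  expect_identical(out$outliers, out2$outliers)
})
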
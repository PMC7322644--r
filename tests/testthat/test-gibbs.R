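test_that("chain bookkeeping: default spec retains 4,800 draws", {
  ch <- chain_spec(500000, 20000, 100)
  expect_identical(ch$retained, 4800L)
  expect_identical(chain_spec(10000, 1000, 7)$retained,
                   as.integer(floor((10000 - 1000) / 7)))
  expect_error(chain_spec(1000, 2000, 10), "burn_in")

  ped <- ped_founders(2)
  rel <- relationship_matrices(ped)
  des <- build_design(ped, data.frame(animal = c("f1", "f2"), L = c(1, 2)), "L")
  expect_error(
    gibbs_univariate(des, rel, model_spec(), chain_spec(5, 4, 10)),
    "zero draws")
})

test_that("a data-free run samples the scaled inverse-chi-square prior", {
  ped <- ped_founders(3)
  rel <- relationship_matrices(ped)
  des <- build_design(ped, data.frame(animal = "f1", L = NA_real_), "L") |>
    suppressMessages()
  expect_length(des$y, 0)
  # nu0 = 1 keeps the chi-square draws inside double range (at the 0.002
  # default roughly half the prior mass lies beyond 1e300, which says
  # something about that prior, not about the sampler)
  nu0 <- 1
  v0 <- 2
  fit <- gibbs_univariate(des, rel,
                          model_spec(include_dominance = TRUE,
                                     prior = prior_spec(v0, nu0)),
                          chain_spec(4000, 0, 1, seed = 31))
  expect_true(fit$prior_only)
  for (col in c("sigma_a2", "sigma_d2", "sigma_e2")) {
    # probability transform: nu0 v0 / sigma2 ~ chisq(nu0), so the
    # transformed draws must look uniform
    u <- stats::pchisq(nu0 * v0 / fit$draws[[col]], df = nu0)
    expect_lt(abs(mean(u) - 0.5), 3 * sqrt(1 / 12 / 4000))
    expect_lt(abs(quantile(u, 0.25) - 0.25), 0.03)
    expect_lt(abs(quantile(u, 0.75) - 0.75), 0.03)
  }
  expect_error(dic(fit), "prior-only")
})

test_that("one founder, one record at known variances gives the conjugate posterior", {
  ped <- ped_founders(1)
  rel <- relationship_matrices(ped)
  des <- build_design(ped, data.frame(animal = "f1", y = 2), "y")
  des$X <- des$X[, 0, drop = FALSE]  # no fixed effects
  mod <- model_spec(include_dominance = FALSE, fix_residual_at = 0.5,
                    fix_additive_at = 2)
  fit <- gibbs_univariate(des, rel, mod, chain_spec(20000, 2000, 1, seed = 5))
  # N(y / se2 / (1/sa2 + 1/se2), 1/(1/sa2 + 1/se2)) = N(1.6, 0.4)
  expect_equal(unname(fit$means$a), 1.6, tolerance = 0.02)
})

test_that("a pinned residual variance is carried through every retained draw", {
  ped <- small_cross(seed = 2, n_f2 = 25)
  sim <- simulate_phenotypes(ped, simulation_truth(), seed = 3)
  fit <- fit_animal_model(sim$phenotypes, ped, "L", dominance = TRUE,
                          fix_residual = 1,
                          chain = chain_spec(1500, 300, 3, seed = 4))
  expect_true(all(fit$draws$sigma_e2 == 1))
})

test_that("location-effect posteriors match the direct mixed-model solution", {
  ped <- small_cross(seed = 3, n_f2 = 20)
  rel <- relationship_matrices(ped)
  truth <- simulation_truth(mu = 10, beta_f = -2, sigma_a2 = 2, sigma_d2 = 1,
                            sigma_e2 = 1)
  sim <- simulate_phenotypes(ped, truth, seed = 4, rel = rel)
  des <- build_design(ped, sim$phenotypes, "L", f = rel$f)
  mod <- model_spec(TRUE, fix_residual_at = 1, fix_additive_at = 2,
                    fix_dominance_at = 1)
  fit <- gibbs_univariate(des, rel, mod, chain_spec(120000, 5000, 5, seed = 6))
  ref <- mme_solution(des, rel, sigma_a2 = 2, sigma_d2 = 1, sigma_e2 = 1)
  expect_equal(unname(fit$means$b), ref$b, tolerance = 0.05)
  expect_lt(max(abs(fit$means$a - ref$a)), 0.05)
  expect_lt(max(abs(fit$means$d - ref$d)), 0.05)
})

test_that("chains are bit-reproducible for a fixed seed", {
  ped <- small_cross(seed = 7, n_f2 = 30)
  sim <- simulate_phenotypes(ped, simulation_truth(), seed = 8)
  rel <- relationship_matrices(ped)
  f1 <- fit_animal_model(sim$phenotypes, ped, "L", rel = rel,
                         chain = chain_spec(1200, 200, 2, seed = 10))
  f2 <- fit_animal_model(sim$phenotypes, ped, "L", rel = rel,
                         chain = chain_spec(1200, 200, 2, seed = 10))
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_animal_model(sim$phenotypes, ped, "L", rel = rel,
                         chain = chain_spec(1200, 200, 2, seed = 11))
  expect_false(identical(f1$draws$sigma_a2, f3$draws$sigma_a2))
})

test_that("the total-variance posterior is invariant to record order", {
  ped <- small_cross(seed = 9, n_f2 = 120)
  sim <- simulate_phenotypes(ped, simulation_truth(), seed = 12)
  rel <- relationship_matrices(ped)
  ch <- chain_spec(12000, 2000, 2, seed = 13)
  f1 <- fit_animal_model(sim$phenotypes, ped, "L", rel = rel, chain = ch)
  set.seed(1)
  perm <- sim$phenotypes[sample(nrow(sim$phenotypes)), ]
  f2 <- fit_animal_model(perm, ped, "L", rel = rel, chain = ch)
  tot1 <- f1$draws$sigma_a2 + f1$draws$sigma_d2 + f1$draws$sigma_e2
  tot2 <- f2$draws$sigma_a2 + f2$draws$sigma_d2 + f2$draws$sigma_e2
  expect_equal(mean(tot1), mean(tot2), tolerance = 0.08 * mean(tot1))
  expect_equal(sd(tot1), sd(tot2), tolerance = 0.25 * sd(tot1))
})

test_that("model deviance matches direct density evaluation", {
  ped <- small_cross(seed = 4, n_f2 = 15)
  sim <- simulate_phenotypes(ped, simulation_truth(), seed = 5)
  des <- build_design(ped, sim$phenotypes, "L")
  n <- length(des$y)

  # exact fit: y equals its mean, unit residual variance
  b0 <- c(0, 0)
  expect_equal(model_deviance(des, b = b0, a = des$y, d = NULL, sigma_e2 = 1),
               n * log(2 * pi))

  # single standard-normal residual of 1: -2 log phi(1)
  d1 <- des
  d1$y <- des$y[1] + 1
  d1$y <- d1$y[1]
  d1$X <- des$X[1, , drop = FALSE]
  d1$Z_a <- d1$Z_d <- des$Z_a[1, , drop = FALSE]
  expect_equal(model_deviance(d1, b = b0, a = des$y[1], sigma_e2 = 1),
               -2 * dnorm(1, log = TRUE))

  # random instance against an independent direct computation
  set.seed(6)
  b <- rnorm(2)
  a <- rnorm(n)
  d <- rnorm(n)
  s2 <- 1.7
  mu <- as.numeric(des$X %*% b) + a + d
  direct <- n * log(2 * pi * s2) + sum((des$y - mu)^2) / s2
  expect_equal(model_deviance(des, b, a, d, s2), direct)

  expect_error(model_deviance(des, b, a, d, -1), "positive")
})

test_that("bivariate sampler: degenerate and null cases", {
  ped <- small_cross(seed = 12, n_f2 = 120)
  rel <- relationship_matrices(ped, dominance = FALSE)

  # the same trait twice: genetic correlation pinned at 1
  sim <- simulate_phenotypes(ped, simulation_truth(sigma_d2 = 0), seed = 14)
  ph <- sim$phenotypes
  ph$L2 <- ph$L
  fit <- fit_bivariate_model(ph, ped, c("L", "L2"), rel = rel,
                             chain = chain_spec(3000, 1000, 2, seed = 15))
  cd <- correlation_draws(fit)
  expect_gt(mean(cd$rg), 0.97)

  # independently simulated traits: posterior rg consistent with zero
  sim1 <- simulate_phenotypes(ped, simulation_truth(sigma_d2 = 0), seed = 16)
  sim2 <- simulate_phenotypes(ped, simulation_truth(sigma_d2 = 0), seed = 17)
  ph2 <- sim1$phenotypes
  ph2$b <- sim2$phenotypes$L
  fit2 <- fit_bivariate_model(ph2, ped, c("L", "b"), rel = rel,
                              chain = chain_spec(8000, 2000, 3, seed = 18))
  cd2 <- correlation_draws(fit2)
  expect_lt(abs(mean(cd2$rg)), 3 * sd(cd2$rg))

  # disjoint animal sets: no residual covariance information
  ph3 <- ph2
  ph3$L[1:60] <- NA
  ph3$b[61:120] <- NA
  expect_error(
    suppressMessages(fit_bivariate_model(ph3, ped, c("L", "b"), rel = rel,
                                         chain = chain_spec(100, 10, 1))),
    "disjoint")
})
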
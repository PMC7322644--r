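#' F2 cross design parameters
#'
#' Describes a two-line F2 cross: two unrelated founder lines, reciprocal
#' line crosses producing the F1, and F2 families organized as half-sib
#' sets (one F1 cock over several F1 hens) plus randomly mated pairs. A
#' controlled proportion of matings is forced to be between F1 full sibs so
#' that F2 inbreeding spans 0 to ~0.25. The defaults reproduce the study
#' population this package targets: 49 F1 sires by 639 F1 dams, 25 half-sib
#' plus 24 randomly mated F2 families, 2,626 F2 hens, F2 inbreeding 0-0.25
#' with mean near 0.079.
#'
#' @param n_p0_per_line P0 founders per line (split ~1:3 into sires:dams).
#' @param n_f1_sires,n_f1_dams F1 breeding cocks and hens.
#' @param n_f2 F2 hens (all phenotyped).
#' @param half_sib_families,random_families Family counts.
#' @param full_sib_mating_rate Probability that an F1 dam is a full sister
#'   of her assigned mate (each such mating yields F2 with F = 0.25).
#' @param seed Integer seed for the mating randomness.
#' @return A `cross_design` list.
#' @export
cross_design <- function(n_p0_per_line = 40, n_f1_sires = 49, n_f1_dams = 639,
                         n_f2 = 2626, half_sib_families = 25,
                         random_families = 24, full_sib_mating_rate = 0.28,
                         seed = 1) {
  stopifnot(n_p0_per_line >= 1, n_f1_sires >= 1, n_f1_dams >= 1, n_f2 >= 1,
            half_sib_families >= 1, random_families >= 1,
            full_sib_mating_rate >= 0, full_sib_mating_rate <= 1)
  structure(list(
    n_p0_per_line = as.integer(n_p0_per_line),
    n_f1_sires = as.integer(n_f1_sires),
    n_f1_dams = as.integer(n_f1_dams),
    n_f2 = as.integer(n_f2),
    half_sib_families = as.integer(half_sib_families),
    random_families = as.integer(random_families),
    full_sib_mating_rate = full_sib_mating_rate,
    seed = as.integer(seed)
  ), class = "cross_design")
}

#' Generate an F2 cross pedigree
#'
#' Builds the three-generation pedigree described by a [cross_design()]:
#' P0 founders in two unrelated lines, F1 from reciprocal line crosses with
#' round-robin parent assignment (so a design with enough P0 founders gives
#' fully unrelated F1), and F2 families per the design. Full-sib matings
#' are created by giving a dam the same P0 parents as her assigned mate.
#'
#' @param design A [cross_design()].
#' @return A `pedigree` with generation labels `P0`, `F1`, `F2`.
#' @export
generate_cross_pedigree <- function(design) {
  stopifnot(inherits(design, "cross_design"))
  set.seed(design$seed)
  n_fam <- design$half_sib_families + design$random_families
  if (n_fam > design$n_f1_sires) {
    stop("infeasible family structure: ", n_fam, " families but only ",
         design$n_f1_sires, " F1 sires")
  }
  if (design$n_f1_dams < n_fam) {
    stop("infeasible family structure: fewer F1 dams than families")
  }

  n_s <- max(1L, as.integer(round(design$n_p0_per_line / 4)))
  n_d <- max(1L, design$n_p0_per_line - n_s)
  p0 <- tibble::tibble(
    animal = c(paste0("A_S", seq_len(n_s)), paste0("A_D", seq_len(n_d)),
               paste0("B_S", seq_len(n_s)), paste0("B_D", seq_len(n_d))),
    sire = NA_character_, dam = NA_character_, generation = "P0"
  )

  # F1 parents: reciprocal directions alternate; round-robin over P0 within
  # a direction, so parents repeat only once the P0 pool is exhausted
  nf1 <- design$n_f1_sires + design$n_f1_dams
  dir_a <- (seq_len(nf1) %% 2L) == 1L            # TRUE: A sire x B dam
  k <- integer(nf1)                              # within-direction index
  k[dir_a] <- seq_len(sum(dir_a))
  k[!dir_a] <- seq_len(sum(!dir_a))
  p0_sire <- ifelse(dir_a,
                    paste0("A_S", (k - 1L) %% n_s + 1L),
                    paste0("B_S", (k - 1L) %% n_s + 1L))
  p0_dam <- ifelse(dir_a,
                   paste0("B_D", (k - 1L) %% n_d + 1L),
                   paste0("A_D", (k - 1L) %% n_d + 1L))
  f1_id <- c(paste0("F1_S", seq_len(design$n_f1_sires)),
             paste0("F1_D", seq_len(design$n_f1_dams)))

  # family structure: which F1 sire each dam is mated to
  fam_sire_pos <- seq_len(n_fam)  # positions within the F1 sire block
  n_dams <- design$n_f1_dams
  n_free <- n_dams - design$random_families
  hs_alloc <- rep(seq_len(design$half_sib_families), length.out = n_free)
  dam_fam <- c(sort(hs_alloc),
               design$half_sib_families + seq_len(design$random_families))
  dam_fam <- sample(dam_fam)  # random assignment of dams to families
  dam_sire_pos <- fam_sire_pos[dam_fam]

  # forced full-sib matings: the dam takes her mate's P0 parents
  forced <- stats::runif(n_dams) < design$full_sib_mating_rate
  dam_rows <- design$n_f1_sires + seq_len(n_dams)
  p0_sire[dam_rows][forced] <- p0_sire[dam_sire_pos[forced]]
  p0_dam[dam_rows][forced] <- p0_dam[dam_sire_pos[forced]]

  f1 <- tibble::tibble(animal = f1_id, sire = p0_sire, dam = p0_dam,
                       generation = "F1")

  # F2: distribute offspring evenly over dams
  counts <- rep(design$n_f2 %/% n_dams, n_dams)
  extra <- design$n_f2 %% n_dams
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  f2 <- tibble::tibble(
    animal = paste0("F2_", formatC(seq_len(design$n_f2), width = 5, flag = "0")),
    sire = rep(f1_id[dam_sire_pos], counts),
    dam = rep(f1_id[dam_rows], counts),
    generation = "F2"
  )

  as_pedigree(dplyr::bind_rows(p0, f1, f2))
}

#' Generative parameters for phenotype simulation
#'
#' The truth used by the simulator and checked by recovery tests. The
#' default variance components are realistic posterior estimates for shell
#' lightness in a blue x white F2 cross (additive 6.19, dominance 2.38,
#' residual 1, on the CIE L* scale), with a mild inbreeding depression of
#' the trait. For bivariate simulation supply 2x2 `G0` and `R0` (additive
#' and residual covariance) and two trait names; dominance is not simulated
#' in the bivariate case.
#'
#' @param mu Trait mean (recycled over traits).
#' @param beta_f Fixed regression of the phenotype on the inbreeding
#'   coefficient (trait units per unit F, F as a proportion).
#' @param sigma_a2,sigma_d2,sigma_e2 Univariate variance components.
#' @param G0,R0 Optional 2x2 additive and residual covariance matrices for
#'   two-trait simulation.
#' @param traits Trait name(s).
#' @param eggs_per_hen Integer range of eggs averaged per hen.
#' @param egg_noise_sd Within-hen per-egg measurement SD. The default 0
#'   makes `sigma_e2` exactly the residual variance the model estimates;
#'   a positive value inflates the apparent residual by about
#'   `egg_noise_sd^2 / mean(eggs)`.
#' @return A `simulation_truth` list.
#' @export
simulation_truth <- function(mu = 60, beta_f = -2, sigma_a2 = 6.19,
                             sigma_d2 = 2.38, sigma_e2 = 1,
                             G0 = NULL, R0 = NULL, traits = "L",
                             eggs_per_hen = c(2L, 3L), egg_noise_sd = 0) {
  stopifnot(sigma_a2 >= 0, sigma_d2 >= 0, sigma_e2 >= 0, egg_noise_sd >= 0)
  bivariate <- !is.null(G0)
  if (bivariate) {
    stopifnot(is.matrix(G0), all(dim(G0) == 2), is.matrix(R0), all(dim(R0) == 2),
              length(traits) == 2)
    stopifnot(min(eigen(G0, symmetric = TRUE, only.values = TRUE)$values) >= -1e-8,
              min(eigen(R0, symmetric = TRUE, only.values = TRUE)$values) >= -1e-8)
  }
  structure(list(
    mu = rep(mu, length.out = length(traits)), beta_f = beta_f,
    sigma_a2 = sigma_a2, sigma_d2 = sigma_d2, sigma_e2 = sigma_e2,
    G0 = G0, R0 = R0, traits = traits,
    eggs_per_hen = as.integer(range(eggs_per_hen)),
    egg_noise_sd = egg_noise_sd, bivariate = bivariate
  ), class = "simulation_truth")
}

# Mendelian-sampling variance factor per animal (fraction of the additive
# base variance): 1 for founders, 0.75 - 0.25 F_known with one known
# parent, 0.5 - 0.25 (F_s + F_d) with both
mendelian_factor <- function(si, di, f) {
  fs <- ifelse(si > 0L, f[pmax(si, 1L)], 0)
  fd <- ifelse(di > 0L, f[pmax(di, 1L)], 0)
  both <- si > 0L & di > 0L
  one <- xor(si > 0L, di > 0L)
  ifelse(both, 0.5 - 0.25 * (fs + fd), ifelse(one, 0.75 - 0.25 * (fs + fd), 1))
}

# core effect simulation; assumes the RNG state is already set
sim_effects_core <- function(ped, rel, truth) {
  p <- check_pedigree(ped)
  n <- p$n
  f <- unname(rel$f)
  v <- mendelian_factor(p$si, p$di, f)

  if (truth$bivariate) {
    Lg <- t(chol(truth$G0 + diag(1e-12, 2)))
    a <- matrix(0, n, 2)
    z <- matrix(rnorm(2L * n), n, 2)
    for (i in seq_len(n)) {
      pa <- c(0, 0)
      if (p$si[i] > 0L) pa <- pa + 0.5 * a[p$si[i], ]
      if (p$di[i] > 0L) pa <- pa + 0.5 * a[p$di[i], ]
      a[i, ] <- pa + sqrt(v[i]) * as.numeric(Lg %*% z[i, ])
    }
    rownames(a) <- p$ids
    return(list(a = a, d = NULL))
  }

  a <- numeric(n)
  z <- rnorm(n)
  sda <- sqrt(truth$sigma_a2)
  for (i in seq_len(n)) {
    pa <- 0
    if (p$si[i] > 0L) pa <- pa + 0.5 * a[p$si[i]]
    if (p$di[i] > 0L) pa <- pa + 0.5 * a[p$di[i]]
    a[i] <- pa + sda * sqrt(v[i]) * z[i]
  }

  d <- numeric(n)
  if (truth$sigma_d2 > 0) {
    if (is.null(rel$D)) stop("relationship_set lacks the dominance matrix")
    ev <- eigen(rel$D, symmetric = TRUE)
    vals <- ev$values
    if (min(vals) < -1e-8) {
      warning("dominance matrix is not positive semi-definite; clamping eigenvalues")
    }
    vals <- pmax(vals, 0)
    d <- as.numeric(ev$vectors %*% (sqrt(truth$sigma_d2 * vals) * rnorm(n)))
  }
  list(a = setNames(a, p$ids), d = setNames(d, p$ids))
}

#' Simulate additive and dominance effects on a pedigree
#'
#' Breeding values are generated by the forward Mendelian-sampling
#' recursion `a_i = 0.5 (a_s + a_d) + m_i` with
#' `m_i ~ N(0, sigma_a2 (0.5 - 0.25 (F_s + F_d)))` (founder variance
#' `sigma_a2`), so that `cov(a) = sigma_a2 A` exactly; dominance deviations
#' are drawn jointly as `N(0, sigma_d2 D)` through an eigen-factorization
#' of D. With a bivariate truth, breeding-value pairs use the
#' Kronecker structure `G0 %x% A`.
#'
#' @param ped A `pedigree`.
#' @param rel Matching [relationship_matrices()] (needs `D` only when
#'   `sigma_d2 > 0`).
#' @param truth A [simulation_truth()].
#' @param seed Integer seed; identical seeds give identical vectors.
#' @return List with `a` (vector, or n x 2 matrix for bivariate truth) and
#'   `d` (vector or `NULL`), named/rownamed by animal id.
#' @export
simulate_genetic_effects <- function(ped, rel, truth, seed) {
  stopifnot(inherits(truth, "simulation_truth"))
  set.seed(seed)
  sim_effects_core(ped, rel, truth)
}

#' Simulate an F2 phenotype dataset
#'
#' Generates per-hen averaged records for the F2 cohort (animals labelled
#' `F2`, or all non-parents when labels are absent): each hen lays `k` eggs
#' (`k` uniform on `truth$eggs_per_hen`), each egg measures
#' `mu + beta_f F + a + d + e_hen + egg noise`, and the recorded phenotype
#' is the egg average. With a bivariate truth the hen-level residual pairs
#' are `N(0, R0)` and two trait columns are produced.
#'
#' @param ped A `pedigree`, typically from [generate_cross_pedigree()].
#' @param truth A [simulation_truth()].
#' @param seed Integer seed.
#' @param rel Optional precomputed [relationship_matrices()] (computed on
#'   the fly otherwise, with the dominance matrix only when needed).
#' @return A `sim_dataset`: list with `pedigree`, `phenotypes` (tibble:
#'   `animal` + one column per trait), `truth`, `latent` (tibble of per-hen
#'   `f`, genetic effects and realized total residual, allowing exact
#'   reconstruction of each record), and `seed`.
#' @export
simulate_phenotypes <- function(ped, truth, seed, rel = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  p <- check_pedigree(ped)
  if (is.null(rel)) {
    rel <- relationship_matrices(ped, dominance = !truth$bivariate && truth$sigma_d2 > 0)
  }
  set.seed(seed)
  eff <- sim_effects_core(ped, rel, truth)

  hens <- if (any(!is.na(p$gen))) {
    which(!is.na(p$gen) & p$gen == p$gen[max(which(!is.na(p$gen)))])
  } else {
    which(!(p$ids %in% c(ped$sire, ped$dam)))
  }
  nh <- length(hens)
  f <- unname(rel$f)[hens]
  kr <- truth$eggs_per_hen
  k <- sample(seq(kr[1], kr[2]), nh, replace = TRUE)
  egg_bar <- if (truth$egg_noise_sd > 0) {
    vapply(k, function(ki) mean(rnorm(ki, 0, truth$egg_noise_sd)), 0)
  } else {
    numeric(nh)
  }

  if (truth$bivariate) {
    Lr <- t(chol(truth$R0 + diag(1e-12, 2)))
    e <- t(Lr %*% matrix(rnorm(2L * nh), 2, nh))
    a <- eff$a[hens, , drop = FALSE]
    y1 <- truth$mu[1] + truth$beta_f * f + a[, 1] + e[, 1] + egg_bar
    y2 <- truth$mu[2] + truth$beta_f * f + a[, 2] + e[, 2] + egg_bar
    phen <- tibble::tibble(animal = p$ids[hens])
    phen[[truth$traits[1]]] <- y1
    phen[[truth$traits[2]]] <- y2
    latent <- tibble::tibble(animal = p$ids[hens], f = f, eggs = k,
                             a_1 = a[, 1], a_2 = a[, 2],
                             e_1 = e[, 1] + egg_bar, e_2 = e[, 2] + egg_bar)
  } else {
    e <- rnorm(nh, 0, sqrt(truth$sigma_e2))
    a <- unname(eff$a[hens])
    d <- unname(eff$d[hens])
    y <- truth$mu[1] + truth$beta_f * f + a + d + e + egg_bar
    phen <- tibble::tibble(animal = p$ids[hens])
    phen[[truth$traits[1]]] <- y
    latent <- tibble::tibble(animal = p$ids[hens], f = f, eggs = k,
                             a = a, d = d, e = e + egg_bar)
  }

  structure(list(pedigree = ped, phenotypes = phen, truth = truth,
                 latent = latent, seed = as.integer(seed)),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", nrow(x$phenotypes), " phenotyped hens, ",
      nrow(x$pedigree), " pedigree animals; traits: ",
      paste(x$truth$traits, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Shift randomly chosen records to create artificial outliers
#'
#' Adds `+/- magnitude_sd` trait standard deviations to `n` randomly chosen
#' records; the affected row indices are recorded in the returned dataset's
#' `outliers` element so cleaning rules can be tested against a known
#' truth.
#'
#' @param dataset A `sim_dataset`.
#' @param n Number of records to contaminate.
#' @param magnitude_sd Shift magnitude in trait SDs.
#' @param seed Integer seed (same seed, same indices).
#' @param trait Trait column to contaminate (default: first trait).
#' @return The modified `sim_dataset` with an `outliers` tibble
#'   (`trait`, `row`, `animal`, `shift`).
#' @export
inject_outliers <- function(dataset, n, magnitude_sd = 5, seed = 1, trait = NULL) {
  stopifnot(inherits(dataset, "sim_dataset"), n >= 0,
            n <= nrow(dataset$phenotypes))
  if (is.null(trait)) trait <- dataset$truth$traits[1]
  if (n == 0) {
    dataset$outliers <- tibble::tibble(trait = character(), row = integer(),
                                       animal = character(), shift = numeric())
    return(dataset)
  }
  set.seed(seed)
  y <- dataset$phenotypes[[trait]]
  rows <- sample(length(y), n)
  shift <- sample(c(-1, 1), n, replace = TRUE) * magnitude_sd * sd(y)
  y[rows] <- y[rows] + shift
  dataset$phenotypes[[trait]] <- y
  dataset$outliers <- tibble::tibble(trait = trait, row = rows,
                                     animal = dataset$phenotypes$animal[rows],
                                     shift = shift)
  dataset
}
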
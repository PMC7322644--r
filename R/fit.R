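#' Fit a univariate animal model to a phenotype table
#'
#' Data-frame-first convenience wrapper around [build_design()] and
#' [gibbs_univariate()]: computes the relationship matrices (unless
#' supplied), assembles the design for one trait, and runs the Gibbs
#' sampler.
#'
#' @param phenotypes Data frame with `animal` and trait columns.
#' @param ped A `pedigree` (or data frame convertible by [as_pedigree()]).
#' @param trait Trait column name.
#' @param dominance Include dominance deviations?
#' @param fix_residual Optional positive value at which the residual
#'   variance is held fixed.
#' @param prior A [prior_spec()].
#' @param chain A [chain_spec()].
#' @param rel Optional precomputed [relationship_matrices()].
#' @return An `animal_model_fit` (see [gibbs_univariate()]).
#' @examples
#' \donttest{
#' ped <- generate_cross_pedigree(cross_design(
#'   n_f1_sires = 10, n_f1_dams = 30, n_f2 = 120,
#'   half_sib_families = 5, random_families = 5, seed = 1))
#' sim <- simulate_phenotypes(ped, simulation_truth(), seed = 2)
#' fit <- fit_animal_model(sim$phenotypes, ped, "L",
#'                         chain = chain_spec(4000, 1000, 3, seed = 3))
#' tidy(fit)
#' }
#' @export
fit_animal_model <- function(phenotypes, ped, trait, dominance = TRUE,
                             fix_residual = NULL, prior = prior_spec(),
                             chain = chain_spec(), rel = NULL) {
  ped <- as_pedigree(ped)
  if (is.null(rel)) rel <- relationship_matrices(ped, dominance = dominance)
  design <- build_design(ped, phenotypes, trait, f = rel$f,
                         include_dominance = dominance)
  model <- model_spec(include_dominance = dominance,
                      fix_residual_at = fix_residual, prior = prior)
  gibbs_univariate(design, rel, model, chain)
}

#' Fit the bivariate additive animal model to two traits
#'
#' @param phenotypes Data frame with `animal` and both trait columns.
#' @param ped A `pedigree`.
#' @param traits Character vector of two trait column names.
#' @param prior A [prior_spec()] (scalar `v0` expands to `v0 * I`). The
#'   default uses `nu0 = 1.002`: for a 2x2 inverse-Wishart the marginal
#'   degrees of freedom of each variance are `nu0 - p + 1`, so this keeps
#'   the conventional 0.002 per-variance prior while avoiding the strong
#'   singularity at perfect correlation that `nu0 = 0.002` has in two
#'   dimensions.
#' @param chain A [chain_spec()].
#' @param rel Optional precomputed [relationship_matrices()] (the dominance
#'   matrix is not needed).
#' @return A `bivariate_model_fit` (see [gibbs_bivariate()]).
#' @export
fit_bivariate_model <- function(phenotypes, ped, traits,
                                prior = prior_spec(v0 = 1, nu0 = 1.002),
                                chain = chain_spec(), rel = NULL) {
  stopifnot(length(traits) == 2L)
  ped <- as_pedigree(ped)
  if (is.null(rel)) rel <- relationship_matrices(ped, dominance = FALSE)
  designs <- lapply(traits, function(tr) {
    build_design(ped, phenotypes, tr, f = rel$f, include_dominance = FALSE)
  })
  gibbs_bivariate(designs, rel, prior = prior, chain = chain)
}
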
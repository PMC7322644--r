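#' Prior specification for variance components
#'
#' Inverse-Wishart prior with scale `v0` and degrees of freedom `nu0`,
#' applied to every free (co)variance component. In one dimension this is
#' exactly a scaled inverse-chi-square(`nu0`, `v0`) distribution; for the
#' bivariate model `v0` may be a 2x2 positive-definite matrix (a scalar is
#' expanded to `v0 * I`). The default (`v0 = 1`, `nu0 = 0.002`) is the
#' weakly informative specification conventional for Bayesian animal
#' models.
#'
#' @param v0 Prior scale: positive scalar or 2x2 positive-definite matrix.
#' @param nu0 Prior degrees of freedom (> 0).
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(v0 = 1, nu0 = 0.002) {
  stopifnot(nu0 > 0)
  if (is.matrix(v0)) {
    stopifnot(nrow(v0) == ncol(v0), all(eigen(v0, symmetric = TRUE, only.values = TRUE)$values > 0))
  } else {
    stopifnot(length(v0) == 1L, v0 > 0)
  }
  structure(list(v0 = v0, nu0 = nu0), class = "prior_spec")
}

#' Chain specification for the Gibbs samplers
#'
#' @param n_iter Total iterations.
#' @param burn_in Iterations discarded before retention begins.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Optional integer seed; chains are bit-reproducible given a
#'   seed and chain spec.
#' @return A `chain_spec` list with the derived `retained` count,
#'   `floor((n_iter - burn_in) / thin)`. The default (500,000 iterations,
#'   20,000 burn-in, thin 100) retains 4,800 draws.
#' @export
chain_spec <- function(n_iter = 500000, burn_in = 20000, thin = 100, seed = NULL) {
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter, thin >= 1)
  structure(list(
    n_iter = as.integer(n_iter),
    burn_in = as.integer(burn_in),
    thin = as.integer(thin),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    retained = as.integer(floor((n_iter - burn_in) / thin))
  ), class = "chain_spec")
}

#' Model specification for the univariate animal model
#'
#' @param include_dominance Include dominance deviations as a second random
#'   effect?
#' @param fix_residual_at Optional positive value at which the residual
#'   variance is held fixed (not updated), as is done when residual and
#'   dominance variances mix poorly; every retained residual draw then
#'   equals this value exactly.
#' @param prior A [prior_spec()] shared by all free variance components.
#' @param fix_additive_at,fix_dominance_at Optional positive values pinning
#'   the additive / dominance variance; intended for validation studies
#'   (e.g. checking location-effect conditionals at known variances).
#' @return A `model_spec` list.
#' @export
model_spec <- function(include_dominance = TRUE, fix_residual_at = NULL,
                       prior = prior_spec(), fix_additive_at = NULL,
                       fix_dominance_at = NULL) {
  for (v in list(fix_residual_at, fix_additive_at, fix_dominance_at)) {
    if (!is.null(v)) stopifnot(is.numeric(v), length(v) == 1L, v > 0)
  }
  stopifnot(inherits(prior, "prior_spec"))
  structure(list(
    include_dominance = isTRUE(include_dominance),
    fix_residual_at = fix_residual_at,
    fix_additive_at = fix_additive_at,
    fix_dominance_at = fix_dominance_at,
    prior = prior
  ), class = "model_spec")
}
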
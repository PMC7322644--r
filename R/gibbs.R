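#' Gibbs sampler for the univariate animal model
#'
#' Samples from the posterior of `y = X b + Z_a a + Z_d d + e` with
#' `a ~ N(0, sigma_a2 A)`, optionally `d ~ N(0, sigma_d2 D)`, and
#' `e ~ N(0, sigma_e2 I)`. Fixed effects get an improper flat prior; each
#' free variance gets the scaled inverse-chi-square prior implied by
#' [prior_spec()] and is updated from its full conditional with
#' `df = nu0 + q` and scale `(u' M^{-1} u + nu0 v0)`, `M` the relevant
#' relationship matrix. Location effects are drawn as a single joint block:
#' with one averaged record per animal the full conditional of the
#' phenotyped animals' effects is diagonal in the eigenbasis of the
#' relationship submatrix, so the sampler works there (unphenotyped
#' animals' effects are marginalized out exactly, which leaves the
#' posterior of all variance components, heritabilities and record-level
#' effects unchanged). The conditional deviance
#' `-2 log N(y | Xb + a + d, sigma_e2 I)` is recorded for every retained
#' draw. Chains are bit-reproducible given `chain$seed`.
#'
#' With zero records the sampler returns draws from the prior.
#'
#' @param design A `design_set` from [build_design()].
#' @param rel A `relationship_set` from [relationship_matrices()] for the
#'   same pedigree.
#' @param model A [model_spec()].
#' @param chain A [chain_spec()].
#' @return An `animal_model_fit`: list with `draws` (tibble of retained
#'   draws: `sigma_a2`, `sigma_d2` when dominance is included, `sigma_e2`,
#'   `deviance`, fixed-effect columns `b_*`), `means` (posterior means of
#'   `b`, record-level `a` and `d`, and `sigma_e2`, used by [dic()]),
#'   `design`, `model`, `chain`, `trait`.
#' @export
gibbs_univariate <- function(design, rel, model = model_spec(), chain = chain_spec()) {
  stopifnot(inherits(design, "design_set"), inherits(model, "model_spec"),
            inherits(chain, "chain_spec"))
  if (chain$retained < 1L) stop("chain spec retains zero draws")
  if (!is.null(chain$seed)) set.seed(chain$seed)

  nu0 <- model$prior$nu0
  v0 <- model$prior$v0
  if (is.matrix(v0)) v0 <- v0[1, 1]
  m <- chain$retained
  n <- length(design$y)
  use_dom <- isTRUE(model$include_dominance)

  if (n == 0L) {
    return(prior_only_fit(model, chain, design, nu0, v0, use_dom))
  }

  idx <- design$animal_index
  if (is.null(rel$A)) stop("relationship_set lacks the additive matrix")
  ea <- eigen(rel$A[idx, idx, drop = FALSE], symmetric = TRUE)
  la <- pmax(ea$values, 1e-10)
  if (use_dom) {
    if (is.null(rel$D)) stop("relationship_set lacks the dominance matrix; rebuild with dominance = TRUE")
    ed <- eigen(rel$D[idx, idx, drop = FALSE], symmetric = TRUE)
    ld <- ed$values
    if (min(ld) < 1e-8) {
      warning("dominance relationship matrix is not positive definite; adding a ridge of 1e-8")
      ld <- ld + 1e-8
    }
    ld <- pmax(ld, 1e-10)
    Ud <- ed$vectors
  } else {
    Ud <- matrix(0, 0, 0)
    ld <- numeric(0)
  }

  X <- drop_collinear(design$X)
  design$X <- X

  # initial values: phenotypic variance split over the free components
  vy <- var(design$y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  k_free <- 1L + use_dom + is.null(model$fix_residual_at)
  init <- vy / k_free
  sa2 <- if (is.null(model$fix_additive_at)) init else model$fix_additive_at
  sd2 <- if (is.null(model$fix_dominance_at)) init else model$fix_dominance_at
  se2 <- if (is.null(model$fix_residual_at)) init else model$fix_residual_at

  res <- gibbs_uni_cpp(
    y = design$y, X = X, Ua = ea$vectors, la = la,
    Ud = if (use_dom) Ud else matrix(0, 0, 0), ld = ld, use_dom = use_dom,
    nu0 = nu0, v0 = v0,
    sa2_init = sa2, sd2_init = sd2, se2_init = se2,
    fix_a = !is.null(model$fix_additive_at),
    fix_d = !is.null(model$fix_dominance_at),
    fix_e = !is.null(model$fix_residual_at),
    n_iter = chain$n_iter, burn = chain$burn_in, thin = chain$thin,
    As = rel$A[idx, idx, drop = FALSE],
    Ds = if (use_dom) rel$D[idx, idx, drop = FALSE] else matrix(0, 0, 0),
    mh_every = 25L
  )

  draws <- tibble::tibble(
    iteration = chain$burn_in + chain$thin * seq_len(m),
    sigma_a2 = as.numeric(res$sigma_a2)
  )
  if (use_dom) draws$sigma_d2 <- as.numeric(res$sigma_d2)
  draws$sigma_e2 <- as.numeric(res$sigma_e2)
  draws$deviance <- as.numeric(res$deviance)
  if (ncol(X) > 0) {
    bd <- res$b
    colnames(bd) <- paste0("b_", colnames(X))
    draws <- dplyr::bind_cols(draws, tibble::as_tibble(bd))
  }

  structure(list(
    draws = draws,
    means = list(
      b = setNames(as.numeric(res$mean_b), colnames(X)),
      a = setNames(as.numeric(res$mean_a), design$record_ids),
      d = if (use_dom) setNames(as.numeric(res$mean_d), design$record_ids) else NULL,
      sigma_e2 = mean(draws$sigma_e2)
    ),
    design = design, model = model, chain = chain,
    trait = design$trait, prior_only = FALSE
  ), class = "animal_model_fit")
}

# prior-only sampling (zero records): each free variance is drawn iid from
# its scaled inverse-chi-square prior
prior_only_fit <- function(model, chain, design, nu0, v0, use_dom) {
  m <- chain$retained
  ric <- function() (nu0 * v0) / rchisq(m, df = nu0)
  draws <- tibble::tibble(
    iteration = chain$burn_in + chain$thin * seq_len(m),
    sigma_a2 = if (is.null(model$fix_additive_at)) ric() else rep(model$fix_additive_at, m)
  )
  if (use_dom) {
    draws$sigma_d2 <- if (is.null(model$fix_dominance_at)) ric() else rep(model$fix_dominance_at, m)
  }
  draws$sigma_e2 <- if (is.null(model$fix_residual_at)) ric() else rep(model$fix_residual_at, m)
  draws$deviance <- NA_real_
  structure(list(
    draws = draws, means = NULL, design = design, model = model,
    chain = chain, trait = design$trait, prior_only = TRUE
  ), class = "animal_model_fit")
}

# drop rank-deficient fixed-effect columns (e.g. a constant inbreeding
# covariate aliased with the intercept)
drop_collinear <- function(X) {
  if (ncol(X) == 0L) return(X)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- colnames(X)[-keep]
    message("dropping collinear fixed-effect column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

#' Gibbs sampler for the bivariate additive animal model
#'
#' Additive-only two-trait model used for genetic and phenotypic
#' correlations: breeding-value pairs have covariance `G0 %x% A`, record
#' residual pairs covariance `R0`, and both 2x2 matrices get conjugate
#' inverse-Wishart updates, `G0 | a ~ IW(nu0 + q, nu0 V0 + S_a)` with
#' `S_a` the A-inverse-weighted cross-product of trait-wise additive
#' effects (computed in the eigenbasis), and analogously for `R0` from the
#' residuals. The fixed-effect design (intercept + inbreeding) is shared by
#' both traits. Records are matched by animal id; the two traits must be
#' measured on overlapping animal sets (disjoint sets leave the residual
#' covariance unidentified and raise an error), and analysis is restricted
#' to the common animals.
#'
#' @param designs List of two `design_set`s over the same pedigree.
#' @param rel A `relationship_set` for that pedigree.
#' @param prior A [prior_spec()]; a scalar `v0` is expanded to `v0 * I`.
#'   The default `nu0 = 1.002` preserves the conventional 0.002 marginal
#'   prior per variance in two dimensions (see [fit_bivariate_model()]).
#' @param chain A [chain_spec()].
#' @return A `bivariate_model_fit`: `draws` (tibble with `G0_11`, `G0_12`,
#'   `G0_22`, `R0_11`, `R0_12`, `R0_22`, `deviance`, `b_*`), `means`
#'   (posterior means of `B`, record-level `a`, `R0`), `traits`, data used.
#' @export
gibbs_bivariate <- function(designs, rel, prior = prior_spec(v0 = 1, nu0 = 1.002),
                            chain = chain_spec()) {
  stopifnot(length(designs) == 2L,
            inherits(designs[[1]], "design_set"), inherits(designs[[2]], "design_set"),
            inherits(prior, "prior_spec"), inherits(chain, "chain_spec"))
  if (chain$retained < 1L) stop("chain spec retains zero draws")
  if (!is.null(chain$seed)) set.seed(chain$seed)

  ids1 <- designs[[1]]$record_ids
  ids2 <- designs[[2]]$record_ids
  common <- intersect(ids1, ids2)
  if (!length(common)) {
    stop("the two traits are measured on disjoint animal sets; ",
         "the residual covariance is not identifiable")
  }
  if (length(common) < max(length(ids1), length(ids2))) {
    message("restricting bivariate analysis to ", length(common),
            " animals with both traits recorded")
  }
  i1 <- match(common, ids1)
  i2 <- match(common, ids2)
  Y <- cbind(designs[[1]]$y[i1], designs[[2]]$y[i2])
  X <- drop_collinear(designs[[1]]$X[i1, , drop = FALSE])
  idx <- designs[[1]]$animal_index[i1]
  traits <- c(designs[[1]]$trait, designs[[2]]$trait)
  n <- nrow(Y)

  ea <- eigen(rel$A[idx, idx, drop = FALSE], symmetric = TRUE)
  la <- pmax(ea$values, 1e-10)

  V0 <- prior$v0
  if (!is.matrix(V0)) V0 <- diag(V0, 2)
  vy <- pmax(apply(Y, 2, var), 1e-8)
  G0i <- diag(vy / 2)
  R0i <- diag(vy / 2)

  res <- gibbs_biv_cpp(Y = Y, X = X, Ua = ea$vectors, la = la,
                       nu0 = prior$nu0, V0 = V0, G0_init = G0i, R0_init = R0i,
                       n_iter = chain$n_iter, burn = chain$burn_in,
                       thin = chain$thin)

  m <- chain$retained
  G <- res$G0
  R <- res$R0
  draws <- tibble::tibble(
    iteration = chain$burn_in + chain$thin * seq_len(m),
    G0_11 = G[, 1], G0_12 = G[, 2], G0_22 = G[, 3],
    R0_11 = R[, 1], R0_12 = R[, 2], R0_22 = R[, 3],
    deviance = as.numeric(res$deviance)
  )
  if (ncol(X) > 0) {
    bd <- res$b
    colnames(bd) <- paste0("b_", rep(traits, each = ncol(X)), "_",
                           rep(colnames(X), 2L))
    draws <- dplyr::bind_cols(draws, tibble::as_tibble(bd))
  }

  structure(list(
    draws = draws,
    means = list(
      B = {
        B <- res$mean_b[seq_len(max(ncol(X), 1L)), , drop = FALSE]
        if (ncol(X) > 0) dimnames(B) <- list(colnames(X), traits)
        B
      },
      a = {
        A <- res$mean_a
        dimnames(A) <- list(common, traits)
        A
      },
      R0 = res$mean_R0
    ),
    Y = Y, X = X, record_ids = common,
    traits = traits, prior = prior, chain = chain
  ), class = "bivariate_model_fit")
}

#' Conditional deviance of the animal model
#'
#' `-2 * sum(log N(y_i | X_i b + a_i + d_i, sigma_e2))`, the deviance
#' conditional on the random effects that the DIC computation uses.
#'
#' @param design A `design_set`.
#' @param b Fixed-effect vector (length `ncol(design$X)`).
#' @param a Additive effects: per record (length `length(y)`) or per
#'   pedigree animal (length `ncol(Z_a)`, mapped through `Z_a`).
#' @param d Dominance deviations (same conventions), or `NULL`.
#' @param sigma_e2 Residual variance (> 0).
#' @return The deviance (scalar).
#' @export
model_deviance <- function(design, b, a, d = NULL, sigma_e2) {
  stopifnot(inherits(design, "design_set"))
  if (sigma_e2 <= 0) stop("sigma_e2 must be positive")
  n <- length(design$y)
  to_rec <- function(u, Z) {
    if (is.null(u)) return(numeric(n))
    if (length(u) == n) return(as.numeric(u))
    if (length(u) == ncol(Z)) return(as.numeric(Z %*% u))
    stop("effect vector has incompatible length")
  }
  mu <- if (ncol(design$X) > 0) as.numeric(design$X %*% b) else numeric(n)
  mu <- mu + to_rec(a, design$Z_a) + to_rec(d, design$Z_d)
  -2 * sum(dnorm(design$y, mean = mu, sd = sqrt(sigma_e2), log = TRUE))
}

#' @export
print.animal_model_fit <- function(x, ...) {
  cat("<animal_model_fit> trait ", x$trait,
      if (x$model$include_dominance) " (additive + dominance)" else " (additive)",
      "; ", nrow(x$draws), " retained draws from ",
      x$chain$n_iter, " iterations\n", sep = "")
  if (!x$prior_only) print(tidy(x))
  invisible(x)
}

#' @export
print.bivariate_model_fit <- function(x, ...) {
  cat("<bivariate_model_fit> traits ", paste(x$traits, collapse = " / "),
      "; ", nrow(x$draws), " retained draws\n", sep = "")
  print(tidy(x))
  invisible(x)
}
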
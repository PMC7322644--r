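#' Per-draw heritabilities from a univariate fit
#'
#' For each retained draw, narrow-sense heritability
#' `h2a = sigma_a2 / (sigma_a2 + sigma_d2 + sigma_e2)` (the dominance term
#' is absent for additive-only fits) and, when dominance is included, the
#' dominance heritability `h2d` with `sigma_d2` in the numerator.
#'
#' @param samples An `animal_model_fit`, or a data frame of draws with
#'   columns `sigma_a2`, `sigma_e2` and optionally `sigma_d2`.
#' @return A tibble with `draw`, `h2a` and (when available) `h2d`.
#' @export
heritability_draws <- function(samples) {
  d <- if (inherits(samples, "animal_model_fit")) samples$draws else tibble::as_tibble(samples)
  stopifnot(all(c("sigma_a2", "sigma_e2") %in% names(d)))
  has_d <- "sigma_d2" %in% names(d)
  tot <- d$sigma_a2 + (if (has_d) d$sigma_d2 else 0) + d$sigma_e2
  out <- tibble::tibble(draw = seq_len(nrow(d)), h2a = d$sigma_a2 / tot)
  if (has_d) out$h2d <- d$sigma_d2 / tot
  out
}

#' Per-draw genetic and phenotypic correlations from a bivariate fit
#'
#' `rg = G0_12 / sqrt(G0_11 G0_22)` and
#' `rp = (G0_12 + R0_12) / sqrt((G0_11 + R0_11)(G0_22 + R0_22))`, evaluated
#' draw by draw.
#'
#' @param samples A `bivariate_model_fit`, or a data frame with the six
#'   `G0_*` / `R0_*` draw columns.
#' @return A tibble with `draw`, `rg`, `rp`.
#' @export
correlation_draws <- function(samples) {
  d <- if (inherits(samples, "bivariate_model_fit")) samples$draws else tibble::as_tibble(samples)
  stopifnot(all(c("G0_11", "G0_12", "G0_22", "R0_11", "R0_12", "R0_22") %in% names(d)))
  tibble::tibble(
    draw = seq_len(nrow(d)),
    rg = d$G0_12 / sqrt(d$G0_11 * d$G0_22),
    rp = (d$G0_12 + d$R0_12) /
      sqrt((d$G0_11 + d$R0_11) * (d$G0_22 + d$R0_22))
  )
}

#' Sample autocorrelation of a chain at a given lag
#'
#' @param draws Numeric vector (a retained, thinned chain).
#' @param lag Non-negative lag, smaller than `length(draws)`.
#' @return The autocorrelation (1 at lag 0). A constant chain returns 0
#'   with a warning.
#' @export
autocorrelation <- function(draws, lag) {
  stopifnot(is.numeric(draws), lag >= 0, lag < length(draws))
  x <- draws - mean(draws)
  denom <- sum(x^2)
  if (denom == 0) {
    warning("constant chain; autocorrelation undefined, returning 0")
    return(0)
  }
  n <- length(x)
  sum(x[seq_len(n - lag)] * x[seq_len(n - lag) + lag]) / denom
}

#' Highest posterior density interval
#'
#' Shortest interval containing a probability `prob` of the draws
#' (standard sorted-sample sweep, as used throughout Bayesian reporting).
#'
#' @param draws Numeric vector of at least 10 draws.
#' @param prob Coverage probability in (0, 1).
#' @return Named numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  stopifnot(prob > 0, prob < 1)
  n <- length(draws)
  if (n < 10L) stop("too few draws for an HPD interval (need >= 10)")
  x <- sort(draws)
  gap <- max(1L, min(n - 1L, round(n * prob)))
  starts <- seq_len(n - gap)
  i <- which.min(x[starts + gap] - x[starts])
  c(lower = x[i], upper = x[i + gap])
}

#' Effective sample size of a chain
#'
#' `n / (1 + 2 * sum(rho_k))`, summing autocorrelations until the first
#' non-positive one; capped at `n`.
#'
#' @param draws Numeric vector.
#' @return Effective number of independent draws.
#' @export
effective_size <- function(draws) {
  n <- length(draws)
  if (n < 3L || sd(draws) == 0) return(n)
  s <- 0
  for (k in seq_len(min(n - 2L, 1000L))) {
    r <- autocorrelation(draws, k)
    if (r <= 0) break
    s <- s + r
  }
  min(n, n / (1 + 2 * s))
}

#' Summarize posterior draws
#'
#' Mean, median, SD, HPD interval and effective sample size per column.
#'
#' @param draws A data frame of draws (non-numeric and bookkeeping columns
#'   are skipped) or a numeric vector.
#' @param prob HPD coverage probability.
#' @return A tibble with one row per parameter: `term`, `mean`, `median`,
#'   `sd`, `hpd_low`, `hpd_high`, `ess`.
#' @export
posterior_summary <- function(draws, prob = 0.95) {
  if (is.numeric(draws) && is.null(dim(draws))) {
    draws <- tibble::tibble(value = draws)
  }
  draws <- tibble::as_tibble(draws)
  keep <- vapply(draws, is.numeric, TRUE) &
    !(names(draws) %in% c("iteration", "draw"))
  purrr::map_dfr(names(draws)[keep], function(nm) {
    x <- draws[[nm]]
    h <- if (sum(is.finite(x)) >= 10) hpd_interval(x[is.finite(x)], prob) else c(NA_real_, NA_real_)
    tibble::tibble(
      term = nm, mean = mean(x), median = median(x), sd = sd(x),
      hpd_low = h[[1]], hpd_high = h[[2]],
      ess = if (all(is.finite(x))) effective_size(x) else NA_real_
    )
  })
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean of the stored
#' per-draw conditional deviance and `pD = Dbar - Dhat`, where `Dhat` is
#' the deviance evaluated at the posterior means of the location effects
#' and the residual (co)variance. Lower is better.
#'
#' @param x An `animal_model_fit` or `bivariate_model_fit`.
#' @param ... Unused.
#' @return One-row tibble: `dic`, `p_d`, `d_bar`, `d_hat`.
#' @export
dic <- function(x, ...) UseMethod("dic")

#' @rdname dic
#' @export
dic.animal_model_fit <- function(x, ...) {
  if (is.null(x$means)) {
    stop("no stored location-effect means (prior-only fit); DIC unavailable")
  }
  d_bar <- mean(x$draws$deviance)
  d_hat <- model_deviance(x$design, b = x$means$b, a = x$means$a,
                          d = x$means$d, sigma_e2 = x$means$sigma_e2)
  tibble::tibble(dic = d_bar + (d_bar - d_hat), p_d = d_bar - d_hat,
                 d_bar = d_bar, d_hat = d_hat)
}

#' @rdname dic
#' @export
dic.bivariate_model_fit <- function(x, ...) {
  d_bar <- mean(x$draws$deviance)
  n <- nrow(x$Y)
  XB <- if (ncol(x$X) > 0) x$X %*% x$means$B else matrix(0, n, 2)
  E <- x$Y - XB - x$means$a
  R0 <- x$means$R0
  R0i <- solve(R0)
  d_hat <- n * (2 * log(2 * pi) + log(det(R0))) + sum(R0i * crossprod(E))
  tibble::tibble(dic = d_bar + (d_bar - d_hat), p_d = d_bar - d_hat,
                 d_bar = d_bar, d_hat = d_hat)
}

#' Tidy posterior summary of a univariate fit
#'
#' Variance components, fixed effects and per-draw heritabilities, one row
#' per parameter in broom style.
#'
#' @param x An `animal_model_fit`.
#' @param prob HPD coverage probability.
#' @param ... Unused.
#' @return A tibble from [posterior_summary()].
#' @method tidy animal_model_fit
#' @export
tidy.animal_model_fit <- function(x, prob = 0.95, ...) {
  d <- dplyr::select(x$draws, -dplyr::any_of("iteration"))
  h <- heritability_draws(x)
  d <- dplyr::bind_cols(d, dplyr::select(h, -"draw"))
  posterior_summary(d, prob = prob)
}

#' @method glance animal_model_fit
#' @export
glance.animal_model_fit <- function(x, ...) {
  dd <- if (x$prior_only) {
    tibble::tibble(dic = NA_real_, p_d = NA_real_)
  } else {
    dic(x)[, c("dic", "p_d")]
  }
  tibble::tibble(
    trait = x$trait,
    model = if (x$model$include_dominance) "dominance" else "additive",
    n_records = length(x$design$y),
    n_draws = nrow(x$draws),
    dic = dd$dic, p_d = dd$p_d
  )
}

#' Tidy posterior summary of a bivariate fit
#'
#' (Co)variance draws plus derived genetic and phenotypic correlations.
#'
#' @param x A `bivariate_model_fit`.
#' @param prob HPD coverage probability.
#' @param ... Unused.
#' @return A tibble from [posterior_summary()].
#' @method tidy bivariate_model_fit
#' @export
tidy.bivariate_model_fit <- function(x, prob = 0.95, ...) {
  d <- dplyr::select(x$draws, -dplyr::any_of("iteration"))
  d <- dplyr::bind_cols(d, dplyr::select(correlation_draws(x), -"draw"))
  posterior_summary(d, prob = prob)
}

#' @method glance bivariate_model_fit
#' @export
glance.bivariate_model_fit <- function(x, ...) {
  cd <- correlation_draws(x)
  tibble::tibble(
    trait_1 = x$traits[1], trait_2 = x$traits[2],
    n_records = nrow(x$Y), n_draws = nrow(x$draws),
    rg = mean(cd$rg), rp = mean(cd$rp),
    dic = dic(x)$dic
  )
}

# shared trace/density plotting over a long draws table
draws_plot <- function(long) {
  tr <- ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "steelblue4") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL, title = "Trace")
  de <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue4", alpha = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density", title = "Posterior density")
  list(trace = tr, density = de)
}

#' Trace or density plot of a fit
#'
#' @param object An `animal_model_fit` or `bivariate_model_fit`.
#' @param type `"trace"` or `"density"`.
#' @param pars Optional subset of draw columns to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot animal_model_fit
#' @export
autoplot.animal_model_fit <- function(object, type = c("trace", "density"),
                                      pars = NULL, ...) {
  type <- match.arg(type)
  d <- dplyr::bind_cols(object$draws,
                        dplyr::select(heritability_draws(object), -"draw"))
  if (is.null(pars)) {
    pars <- intersect(c("sigma_a2", "sigma_d2", "sigma_e2", "h2a", "h2d"),
                      names(d))
  }
  long <- tidyr::pivot_longer(d[, c("iteration", pars)], -"iteration",
                              names_to = "parameter", values_to = "value")
  draws_plot(long)[[type]]
}

#' @rdname autoplot.animal_model_fit
#' @method autoplot bivariate_model_fit
#' @export
autoplot.bivariate_model_fit <- function(object, type = c("trace", "density"),
                                         pars = NULL, ...) {
  type <- match.arg(type)
  d <- dplyr::bind_cols(object$draws,
                        dplyr::select(correlation_draws(object), -"draw"))
  if (is.null(pars)) {
    pars <- c("G0_11", "G0_12", "G0_22", "rg", "rp")
  }
  long <- tidyr::pivot_longer(d[, c("iteration", pars)], -"iteration",
                              names_to = "parameter", values_to = "value")
  draws_plot(long)[[type]]
}
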
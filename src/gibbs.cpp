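// Gibbs samplers for the univariate (additive +/- dominance) and bivariate
// (additive) animal models, in the reduced parameterization: effects of
// unphenotyped animals are marginalized out, and the phenotyped-animal
// effects are sampled jointly in the eigenbasis of the relationship
// submatrix, where the full conditional is diagonal (one record per
// animal). All randomness goes through R's RNG so chains are reproducible
// from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

// Marginal log-posterior of theta = log(variance) given the eigenbasis
// projections z of the data with the corresponding effect integrated out:
// z_i ~ N(0, sig2 * lam_i + other) when the variance scales the effect
// (effect_scale = true), or z_i ~ N(0, other * lam_i + sig2) when it is
// the residual. Prior: scaled inverse chi-square(nu0, v0) on the variance.
static double logpost_logvar(double th, const arma::vec& z2, const arma::vec& lam,
                             double other, bool effect_scale,
                             double nu0, double v0) {
  double s2 = std::exp(th);
  double lp = -0.5 * nu0 * th - 0.5 * nu0 * v0 / s2;
  const int n = z2.n_elem;
  for (int i = 0; i < n; ++i) {
    double vt = effect_scale ? (s2 * lam[i] + other) : (other * lam[i] + s2);
    lp += -0.5 * std::log(vt) - 0.5 * z2[i] / vt;
  }
  return lp;
}

// Slice sampler (stepping out + shrinkage) on log(variance). Drawing the
// variance from this marginal and then the effect from its conditional is
// a joint blocked draw of (variance, effect), which removes the slow
// random walk a centered variance update suffers from when effect and
// residual are weakly separated.
static double slice_logvar(double th0, const arma::vec& z2, const arma::vec& lam,
                           double other, bool effect_scale,
                           double nu0, double v0) {
  const double w = 1.0;
  double f0 = logpost_logvar(th0, z2, lam, other, effect_scale, nu0, v0);
  double logy = f0 + std::log(::unif_rand());
  double L = th0 - w * ::unif_rand();
  double R = L + w;
  int k = 100;
  while (k-- > 0 && logpost_logvar(L, z2, lam, other, effect_scale, nu0, v0) > logy) L -= w;
  k = 100;
  while (k-- > 0 && logpost_logvar(R, z2, lam, other, effect_scale, nu0, v0) > logy) R += w;
  for (int j = 0; j < 200; ++j) {
    double th1 = L + ::unif_rand() * (R - L);
    if (logpost_logvar(th1, z2, lam, other, effect_scale, nu0, v0) > logy) return th1;
    if (th1 < th0) L = th1; else R = th1;
  }
  return th0;
}

// 2x2 Wishart(df, S) via Bartlett decomposition
static arma::mat rwish2(double df, const arma::mat& S) {
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(2, 2, arma::fill::zeros);
  A(0, 0) = std::sqrt(::Rf_rchisq(df));
  A(1, 1) = std::sqrt(::Rf_rchisq(df - 1.0));
  A(1, 0) = ::norm_rand();
  arma::mat LA = L * A;
  return LA * LA.t();
}

// 2x2 inverse-Wishart(scale S, df): Sigma^{-1} ~ Wishart(df, S^{-1})
static arma::mat riw2(double df, const arma::mat& S) {
  return arma::inv_sympd(rwish2(df, arma::inv_sympd(S)));
}

// Exact marginal log-posterior of the variance components with BOTH
// genetic effects integrated out: r ~ N(0, sa2 As + sd2 Ds + se2 I),
// plus the scaled inverse chi-square prior terms (on the log scale) for
// each free component. Used by a periodic Metropolis move that steps
// along the (sa2, sd2, se2) ridge the one-at-a-time updates random-walk
// through. Returns -inf when the covariance is not positive definite.
static double logpost_margvar(const arma::vec& r, const arma::mat& As,
                              const arma::mat& Ds, bool use_dom,
                              double sa2, double sd2, double se2,
                              bool free_a, bool free_d, bool free_e,
                              double nu0, double v0) {
  arma::mat V = sa2 * As;
  if (use_dom) V += sd2 * Ds;
  V.diag() += se2;
  arma::mat L;
  if (!arma::chol(L, V, "lower")) return -std::numeric_limits<double>::infinity();
  arma::vec u = arma::solve(arma::trimatl(L), r);
  double lp = -arma::accu(arma::log(L.diag())) - 0.5 * arma::dot(u, u);
  if (free_a) lp += -0.5 * nu0 * std::log(sa2) - 0.5 * nu0 * v0 / sa2;
  if (use_dom && free_d) lp += -0.5 * nu0 * std::log(sd2) - 0.5 * nu0 * v0 / sd2;
  if (free_e) lp += -0.5 * nu0 * std::log(se2) - 0.5 * nu0 * v0 / se2;
  return lp;
}

// [[Rcpp::export]]
List gibbs_uni_cpp(const arma::vec& y,
                   const arma::mat& X,
                   const arma::mat& Ua, const arma::vec& la,
                   const arma::mat& Ud, const arma::vec& ld,
                   const bool use_dom,
                   const double nu0, const double v0,
                   const double sa2_init, const double sd2_init, const double se2_init,
                   const bool fix_a, const bool fix_d, const bool fix_e,
                   const int n_iter, const int burn, const int thin,
                   const arma::mat& As, const arma::mat& Ds,
                   const int mh_every) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int m = (n_iter - burn) / thin;

  vec b(std::max(p, 1), fill::zeros);
  vec wa(n, fill::zeros), arec(n, fill::zeros);
  vec wd(n, fill::zeros), drec(n, fill::zeros);
  double sa2 = sa2_init, sd2 = sd2_init, se2 = se2_init;

  mat XtXinv, Lx;
  if (p > 0) {
    XtXinv = inv_sympd(X.t() * X);
    Lx = chol(XtXinv, "lower");
  }

  vec out_sa2(m), out_sd2(m), out_se2(m), out_dev(m);
  mat out_b(m, p, fill::zeros);
  vec mean_b(p, fill::zeros), mean_a(n, fill::zeros), mean_d(n, fill::zeros);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // fixed effects: flat prior, conditional normal around the OLS solution
    vec xb(n, fill::zeros);
    if (p > 0) {
      vec r = y - arec - drec;
      vec bhat = XtXinv * (X.t() * r);
      vec z(p);
      for (int k = 0; k < p; ++k) z[k] = ::norm_rand();
      b.head(p) = bhat + std::sqrt(se2) * (Lx * z);
      xb = X * b.head(p);
    }

    // periodic joint Metropolis step on the variance components with the
    // genetic effects integrated out exactly (random-walk on the log
    // scale); the one-at-a-time collapsed updates below then refresh the
    // effects conditionally
    if (mh_every > 0 && use_dom && !fix_a && !fix_d && it % mh_every == 0) {
      vec r = y - xb;
      double cur = logpost_margvar(r, As, Ds, use_dom, sa2, sd2, se2,
                                   true, true, !fix_e, nu0, v0);
      double psa = sa2 * std::exp(0.35 * ::norm_rand());
      double psd = sd2 * std::exp(0.35 * ::norm_rand());
      double pse = fix_e ? se2 : se2 * std::exp(0.35 * ::norm_rand());
      double prop = logpost_margvar(r, As, Ds, use_dom, psa, psd, pse,
                                    true, true, !fix_e, nu0, v0);
      if (std::log(::unif_rand()) < prop - cur) {
        sa2 = psa; sd2 = psd; se2 = pse;
      }
    }

    // additive block: draw (sigma_a2 [, sigma_e2], a) as one blocked
    // update -- the variances from their marginal with a integrated out
    // (the eigenbasis projections are independent
    // N(0, sigma_a2 lam_i + sigma_e2)), then a from its conditional
    {
      vec za = Ua.t() * (y - xb - drec);
      vec za2 = square(za);
      if (!fix_a) sa2 = std::exp(slice_logvar(std::log(sa2), za2, la, se2, true, nu0, v0));
      if (!use_dom && !fix_e) {
        se2 = std::exp(slice_logvar(std::log(se2), za2, la, sa2, false, nu0, v0));
      }
      for (int i = 0; i < n; ++i) {
        double prec = 1.0 / (la[i] * sa2) + 1.0 / se2;
        double mu = za[i] / (se2 * prec);
        wa[i] = mu + ::norm_rand() / std::sqrt(prec);
      }
      arec = Ua * wa;
    }

    // dominance block: same collapsed scheme in the eigenbasis of D_sub;
    // the residual variance is updated here as well (marginally of d),
    // where its confounding with the dominance variance lives
    if (use_dom) {
      vec zd = Ud.t() * (y - xb - arec);
      vec zd2 = square(zd);
      if (!fix_d) sd2 = std::exp(slice_logvar(std::log(sd2), zd2, ld, se2, true, nu0, v0));
      if (!fix_e) se2 = std::exp(slice_logvar(std::log(se2), zd2, ld, sd2, false, nu0, v0));
      for (int i = 0; i < n; ++i) {
        double prec = 1.0 / (ld[i] * sd2) + 1.0 / se2;
        double mu = zd[i] / (se2 * prec);
        wd[i] = mu + ::norm_rand() / std::sqrt(prec);
      }
      drec = Ud * wd;
    }

    vec resid = y - xb - arec - drec;
    double sse = dot(resid, resid);

    if (it > burn && (it - burn) % thin == 0) {
      out_sa2[kept] = sa2;
      out_sd2[kept] = use_dom ? sd2 : NA_REAL;
      out_se2[kept] = se2;
      out_dev[kept] = n * (LOG2PI + std::log(se2)) + sse / se2;
      if (p > 0) out_b.row(kept) = b.head(p).t();
      if (p > 0) mean_b += b.head(p);
      mean_a += arec;
      mean_d += drec;
      ++kept;
    }
  }

  if (kept > 0) {
    mean_b /= kept;
    mean_a /= kept;
    mean_d /= kept;
  }

  return List::create(
    _["sigma_a2"] = out_sa2, _["sigma_d2"] = out_sd2, _["sigma_e2"] = out_se2,
    _["deviance"] = out_dev, _["b"] = out_b,
    _["mean_b"] = mean_b, _["mean_a"] = mean_a, _["mean_d"] = mean_d);
}

// Collapsed bivariate machinery: with breeding values integrated out, the
// eigenbasis projections z_i of Y - XB are independent bivariate normals
// with covariance la_i G0 + R0, so the marginal log-posterior of
// (G0, R0) is O(n). Parameterization for the random walk:
// (log v1, log v2, atanh rho) per matrix, with the Jacobian
// |J| = v1 v2 (1 - rho^2) sqrt(v1 v2) folded into the target.
static void theta_to_cov(const double* t, arma::mat& S) {
  double v1 = std::exp(t[0]), v2 = std::exp(t[1]), rho = std::tanh(t[2]);
  S(0, 0) = v1;
  S(1, 1) = v2;
  S(0, 1) = S(1, 0) = rho * std::sqrt(v1 * v2);
}

static double iw_logdens2(const arma::mat& S, double df, const arma::mat& Psi) {
  double det = S(0, 0) * S(1, 1) - S(0, 1) * S(1, 0);
  arma::mat Si(2, 2);
  Si(0, 0) = S(1, 1) / det; Si(1, 1) = S(0, 0) / det;
  Si(0, 1) = Si(1, 0) = -S(0, 1) / det;
  return -0.5 * (df + 3.0) * std::log(det) - 0.5 * arma::accu(Psi % Si);
}

static double biv_collapsed_lp(const arma::mat& Zc, const arma::vec& la,
                               const double* th, double nu0,
                               const arma::mat& Psi) {
  arma::mat G(2, 2), R(2, 2);
  theta_to_cov(th, G);
  theta_to_cov(th + 3, R);
  const int n = Zc.n_rows;
  double lp = 0.0;
  for (int i = 0; i < n; ++i) {
    double m11 = la[i] * G(0, 0) + R(0, 0);
    double m12 = la[i] * G(0, 1) + R(0, 1);
    double m22 = la[i] * G(1, 1) + R(1, 1);
    double det = m11 * m22 - m12 * m12;
    if (det <= 0.0) return -std::numeric_limits<double>::infinity();
    double z1 = Zc(i, 0), z2 = Zc(i, 1);
    double quad = (m22 * z1 * z1 - 2.0 * m12 * z1 * z2 + m11 * z2 * z2) / det;
    lp += -0.5 * std::log(det) - 0.5 * quad;
  }
  lp += iw_logdens2(G, nu0, Psi) + iw_logdens2(R, nu0, Psi);
  // log-Jacobians of the (log v, log v, atanh rho) parameterization
  for (int k = 0; k < 2; ++k) {
    const double* t = th + 3 * k;
    double rho = std::tanh(t[2]);
    lp += 1.5 * (t[0] + t[1]) + std::log(1.0 - rho * rho);
  }
  return lp;
}

// slice-sample one coordinate of the collapsed (G0, R0) parameterization
static void biv_slice_coord(double* th, int k, const arma::mat& Zc,
                            const arma::vec& la, double nu0,
                            const arma::mat& Psi) {
  const double w = 0.4;
  double x0 = th[k];
  double f0 = biv_collapsed_lp(Zc, la, th, nu0, Psi);
  double logy = f0 + std::log(::unif_rand());
  double L = x0 - w * ::unif_rand();
  double R = L + w;
  int m = 50;
  th[k] = L;
  while (m-- > 0 && biv_collapsed_lp(Zc, la, th, nu0, Psi) > logy) { L -= w; th[k] = L; }
  m = 50;
  th[k] = R;
  while (m-- > 0 && biv_collapsed_lp(Zc, la, th, nu0, Psi) > logy) { R += w; th[k] = R; }
  for (int j = 0; j < 100; ++j) {
    double x1 = L + ::unif_rand() * (R - L);
    th[k] = x1;
    if (biv_collapsed_lp(Zc, la, th, nu0, Psi) > logy) return;
    if (x1 < x0) L = x1; else R = x1;
  }
  th[k] = x0;
}

// [[Rcpp::export]]
List gibbs_biv_cpp(const arma::mat& Y,
                   const arma::mat& X,
                   const arma::mat& Ua, const arma::vec& la,
                   const double nu0, const arma::mat& V0,
                   const arma::mat& G0_init, const arma::mat& R0_init,
                   const int n_iter, const int burn, const int thin) {
  const int n = Y.n_rows;
  const int p = X.n_cols;
  const int m = (n_iter - burn) / thin;

  mat B(std::max(p, 1), 2, fill::zeros);
  mat W(n, 2, fill::zeros), arec(n, 2, fill::zeros);
  mat G0 = G0_init, R0 = R0_init;
  const vec inv_la = 1.0 / la;

  mat XtXinv, Lx;
  if (p > 0) {
    XtXinv = inv_sympd(X.t() * X);
    Lx = chol(XtXinv, "lower");
  }

  mat out_G0(m, 3), out_R0(m, 3), out_B(m, 2 * p, fill::zeros);
  vec out_dev(m);
  mat mean_B(std::max(p, 1), 2, fill::zeros), mean_a(n, 2, fill::zeros);
  mat mean_R0(2, 2, fill::zeros);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // fixed effects: X shared across traits, so the GLS solution is the
    // per-trait OLS solution, with row covariance R0 on the draw
    mat XB(n, 2, fill::zeros);
    if (p > 0) {
      mat r = Y - arec;
      mat Bhat = XtXinv * (X.t() * r);
      mat Z(p, 2);
      for (int k = 0; k < p; ++k)
        for (int t = 0; t < 2; ++t) Z(k, t) = ::norm_rand();
      B.head_rows(p) = Bhat + Lx * Z * chol(R0, "upper");
      XB = X * B.head_rows(p);
    }

    mat Zc = Ua.t() * (Y - XB);  // n x 2

    // collapsed slice-sampling sweep on (G0, R0) with the breeding
    // values integrated out; cheap (O(n) per evaluation) and removes the
    // genetic/residual covariance ridge the conjugate scan random-walks
    // along
    {
      arma::mat Psi = nu0 * V0;
      double th[6] = {
        std::log(G0(0, 0)), std::log(G0(1, 1)),
        std::atanh(std::max(-0.999, std::min(0.999,
          G0(0, 1) / std::sqrt(G0(0, 0) * G0(1, 1))))),
        std::log(R0(0, 0)), std::log(R0(1, 1)),
        std::atanh(std::max(-0.999, std::min(0.999,
          R0(0, 1) / std::sqrt(R0(0, 0) * R0(1, 1)))))
      };
      for (int k = 0; k < 6; ++k) biv_slice_coord(th, k, Zc, la, nu0, Psi);
      theta_to_cov(th, G0);
      theta_to_cov(th + 3, R0);
    }

    // breeding-value pairs, independent across eigen-coordinates
    mat R0inv = inv_sympd(R0);
    mat G0inv = inv_sympd(G0);
    for (int i = 0; i < n; ++i) {
      mat Q = G0inv * inv_la[i] + R0inv;
      double det = Q(0, 0) * Q(1, 1) - Q(0, 1) * Q(1, 0);
      mat Qinv(2, 2);
      Qinv(0, 0) = Q(1, 1) / det;
      Qinv(1, 1) = Q(0, 0) / det;
      Qinv(0, 1) = Qinv(1, 0) = -Q(0, 1) / det;
      vec rhs = R0inv * Zc.row(i).t();
      vec mu = Qinv * rhs;
      mat Lq = chol(Qinv, "lower");
      vec z(2);
      z[0] = ::norm_rand();
      z[1] = ::norm_rand();
      W.row(i) = (mu + Lq * z).t();
    }
    arec = Ua * W;

    // additive covariance: inverse-Wishart full conditional
    mat Sw = W.t() * (W.each_col() % inv_la);
    G0 = riw2(nu0 + n, nu0 * V0 + Sw);

    // residual covariance
    mat E = Y - XB - arec;
    mat SE = E.t() * E;
    R0 = riw2(nu0 + n, nu0 * V0 + SE);

    if (it > burn && (it - burn) % thin == 0) {
      out_G0(kept, 0) = G0(0, 0); out_G0(kept, 1) = G0(0, 1); out_G0(kept, 2) = G0(1, 1);
      out_R0(kept, 0) = R0(0, 0); out_R0(kept, 1) = R0(0, 1); out_R0(kept, 2) = R0(1, 1);
      mat R0i = inv_sympd(R0);
      double ldet = std::log(R0(0, 0) * R0(1, 1) - R0(0, 1) * R0(1, 0));
      out_dev[kept] = n * (2.0 * LOG2PI + ldet) + accu(R0i % SE);
      if (p > 0) {
        for (int t = 0; t < 2; ++t)
          for (int k = 0; k < p; ++k) out_B(kept, t * p + k) = B(k, t);
        mean_B.head_rows(p) += B.head_rows(p);
      }
      mean_a += arec;
      mean_R0 += R0;
      ++kept;
    }
  }

  if (kept > 0) {
    mean_B /= kept;
    mean_a /= kept;
    mean_R0 /= kept;
  }

  return List::create(
    _["G0"] = out_G0, _["R0"] = out_R0, _["b"] = out_B,
    _["deviance"] = out_dev,
    _["mean_b"] = mean_B, _["mean_a"] = mean_a, _["mean_R0"] = mean_R0);
}
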
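// Blocked Gibbs sampler for the bivariate latent-normal hierarchical model:
//   y1_ij = x_ij' b1 + u1_j + e1_ij            (continuous margin)
//   z_ij  = x_ij' b2 + u2_j + e2_ij,  y2_ij = 1{z_ij > 0}   (probit margin)
//   (e1,e2) ~ N(0, Omega_e),  Omega_e[2,2] == 1 for identification
//   (u1,u2) ~ N(0, Omega_u)
// Missing y1 and all z are data-augmented. The sigma2^2 = 1 constraint is
// enforced by parameter expansion: Omega_e is updated unconstrained from its
// conjugate inverse-Wishart full conditional, then the latent scale is
// transformed out of (z, b2, u2, Omega_u).
// Uses R's RNG throughout so results are governed by set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// fast standard-normal CDF via erfc (accurate to ~1e-16, much cheaper than
// R::pnorm inside the hot data-augmentation loop)
static inline double fast_pnorm(double x) {
  return 0.5 * std::erfc(-x * M_SQRT1_2);
}

// fast standard-normal quantile: Acklam's rational approximation polished
// by one Halley step against erfc, giving near machine precision
static inline double fast_qnorm(double p) {
  static const double a[] = {-3.969683028665376e+01, 2.209460984245205e+02,
                             -2.759285104469687e+02, 1.383577518672690e+02,
                             -3.066479806614716e+01, 2.506628277459239e+00};
  static const double b[] = {-5.447609879822406e+01, 1.615858368580409e+02,
                             -1.556989798598866e+02, 6.680131188771972e+01,
                             -1.328068155288572e+01};
  static const double c[] = {-7.784894002430293e-03, -3.223964580411365e-01,
                             -2.400758277161838e+00, -2.549732539343734e+00,
                             4.374664141464968e+00,  2.938163982698783e+00};
  static const double d[] = {7.784695709041462e-03, 3.224671290700398e-01,
                             2.445134137142996e+00, 3.754408661907416e+00};
  double x;
  if (p < 0.02425) {
    double q = std::sqrt(-2.0 * std::log(p));
    x = (((((c[0] * q + c[1]) * q + c[2]) * q + c[3]) * q + c[4]) * q + c[5]) /
        ((((d[0] * q + d[1]) * q + d[2]) * q + d[3]) * q + 1.0);
  } else if (p <= 0.97575) {
    double q = p - 0.5, r = q * q;
    x = (((((a[0] * r + a[1]) * r + a[2]) * r + a[3]) * r + a[4]) * r + a[5]) *
        q /
        (((((b[0] * r + b[1]) * r + b[2]) * r + b[3]) * r + b[4]) * r + 1.0);
  } else {
    double q = std::sqrt(-2.0 * std::log(1.0 - p));
    x = -(((((c[0] * q + c[1]) * q + c[2]) * q + c[3]) * q + c[4]) * q + c[5]) /
        ((((d[0] * q + d[1]) * q + d[2]) * q + d[3]) * q + 1.0);
  }
  // one Halley refinement
  double e = fast_pnorm(x) - p;
  double uu = e * std::sqrt(2.0 * M_PI) * std::exp(0.5 * x * x);
  x = x - uu / (1.0 + 0.5 * x * uu);
  return x;
}

// N(m, s^2) truncated to (0, Inf), by inversion with boundary guards
static inline double rtnorm_pos(double m, double s) {
  double pa = fast_pnorm(-m / s);
  double u = pa + unif_rand() * (1.0 - pa);
  if (u > 1.0 - 1e-15) u = 1.0 - 1e-15;
  double out = m + s * fast_qnorm(u);
  return (out > 0.0) ? out : 1e-10;
}

// N(m, s^2) truncated to (-Inf, 0]
static inline double rtnorm_neg(double m, double s) {
  double pa = fast_pnorm(-m / s);
  double u = unif_rand() * pa;
  if (u < 1e-15) u = 1e-15;
  double out = m + s * fast_qnorm(u);
  return (out <= 0.0) ? out : -1e-10;
}

// 2x2 inverse-Wishart via Bartlett decomposition
static arma::mat rinvwish2(double nu, const arma::mat& S) {
  arma::mat L = arma::chol(arma::inv_sympd(S), "lower");
  arma::mat A(2, 2, arma::fill::zeros);
  A(0, 0) = std::sqrt(R::rchisq(nu));
  A(1, 1) = std::sqrt(R::rchisq(nu - 1.0));
  A(1, 0) = norm_rand();
  arma::mat LA = L * A;
  return arma::inv_sympd(LA * LA.t());
}

// [[Rcpp::export]]
List gibbs_joint_cpp(arma::vec y1, arma::ivec y2, const arma::mat& X,
                     const arma::uvec& study, int n_studies,
                     const arma::uvec& miss1, const arma::uvec& miss2,
                     int n_iter, int n_burn, int thin,
                     double beta_prec, double nu_e, const arma::mat& Se,
                     double nu_u, const arma::mat& Su) {
  const int n = X.n_rows, p = X.n_cols, J = n_studies;

  // state
  arma::vec b1(p, arma::fill::zeros), b2(p, arma::fill::zeros);
  arma::mat u(J, 2, arma::fill::zeros);
  arma::mat Omega_u = 0.5 * arma::eye(2, 2);
  double s11 = 1.0, s12 = 0.0; // Omega_e with s22 fixed at 1
  arma::vec z(n);

  // crude but adequate initial values
  {
    double my = 0.0; int nobs1 = 0;
    for (int i = 0; i < n; ++i) if (!miss1(i)) { my += y1(i); ++nobs1; }
    my = (nobs1 > 0) ? my / nobs1 : 0.0;
    for (int i = 0; i < n; ++i) if (miss1(i)) y1(i) = my;
    b1 = arma::solve(X.t() * X + 1e-8 * arma::eye(p, p), X.t() * y1);
    for (int i = 0; i < n; ++i)
      z(i) = miss2(i) ? 0.0 : (y2(i) == 1 ? 0.5 : -0.5);
  }

  const arma::mat XtX = X.t() * X;
  const int n_keep = (n_iter - n_burn) / thin;
  // columns: b1 (p), b2 (p), sigma1_sq, sigma2_sq, rho, tau1_sq, tau2_sq, phi
  arma::mat draws(n_keep, 2 * p + 6);
  int kept = 0;
  long sign_violations = 0;

  arma::vec mu1(n), mu2(n), e1(n), e2(n);
  arma::ivec nj(J, arma::fill::zeros);
  for (int i = 0; i < n; ++i) nj(study(i))++;

  for (int it = 0; it < n_iter; ++it) {
    // linear predictors
    mu1 = X * b1; mu2 = X * b2;
    for (int i = 0; i < n; ++i) {
      mu1(i) += u(study(i), 0);
      mu2(i) += u(study(i), 1);
    }

    // (1)-(2) latent z given y1, then missing y1 given z
    {
      double det = s11 - s12 * s12;
      double v2 = 1.0 - s12 * s12 / s11, sd2 = std::sqrt(v2);
      double v1 = det, sd1 = std::sqrt(v1); // var(y1 | z) = s11 - s12^2/1
      double k21 = s12 / s11;
      for (int i = 0; i < n; ++i) {
        double cm = mu2(i) + k21 * (y1(i) - mu1(i));
        if (miss2(i))        z(i) = cm + sd2 * norm_rand();
        else if (y2(i) == 1) z(i) = rtnorm_pos(cm, sd2);
        else                 z(i) = rtnorm_neg(cm, sd2);
      }
      for (int i = 0; i < n; ++i) {
        if (miss1(i))
          y1(i) = mu1(i) + s12 * (z(i) - mu2(i)) + sd1 * norm_rand();
      }
    }

    // (3) regression coefficients, both margins jointly
    {
      double det = s11 - s12 * s12;
      double oi11 = 1.0 / det, oi12 = -s12 / det, oi22 = s11 / det;
      arma::vec c1(n), c2(n);
      for (int i = 0; i < n; ++i) {
        c1(i) = y1(i) - u(study(i), 0);
        c2(i) = z(i)  - u(study(i), 1);
      }
      arma::mat P(2 * p, 2 * p);
      P.submat(0, 0, p - 1, p - 1)         = oi11 * XtX;
      P.submat(0, p, p - 1, 2 * p - 1)     = oi12 * XtX;
      P.submat(p, 0, 2 * p - 1, p - 1)     = oi12 * XtX;
      P.submat(p, p, 2 * p - 1, 2 * p - 1) = oi22 * XtX;
      P.diag() += beta_prec;
      arma::vec rhs(2 * p);
      rhs.subvec(0, p - 1)     = X.t() * (oi11 * c1 + oi12 * c2);
      rhs.subvec(p, 2 * p - 1) = X.t() * (oi12 * c1 + oi22 * c2);
      arma::mat L = arma::chol(P, "lower");
      arma::vec w = arma::solve(arma::trimatl(L), rhs);
      arma::vec m = arma::solve(arma::trimatu(L.t()), w);
      arma::vec eps(2 * p);
      for (int k = 0; k < 2 * p; ++k) eps(k) = norm_rand();
      arma::vec b = m + arma::solve(arma::trimatu(L.t()), eps);
      b1 = b.subvec(0, p - 1);
      b2 = b.subvec(p, 2 * p - 1);
    }

    // (4) study random intercepts
    {
      double det = s11 - s12 * s12;
      double oi11 = 1.0 / det, oi12 = -s12 / det, oi22 = s11 / det;
      arma::vec r1 = y1 - X * b1, r2 = z - X * b2;
      arma::mat sums(J, 2, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        sums(study(i), 0) += r1(i);
        sums(study(i), 1) += r2(i);
      }
      arma::mat Oui = arma::inv_sympd(Omega_u);
      for (int j = 0; j < J; ++j) {
        arma::mat Pj = Oui;
        Pj(0, 0) += nj(j) * oi11; Pj(0, 1) += nj(j) * oi12;
        Pj(1, 0) += nj(j) * oi12; Pj(1, 1) += nj(j) * oi22;
        arma::vec rhs(2);
        rhs(0) = oi11 * sums(j, 0) + oi12 * sums(j, 1);
        rhs(1) = oi12 * sums(j, 0) + oi22 * sums(j, 1);
        arma::mat Lj = arma::chol(Pj, "lower");
        arma::vec wj = arma::solve(arma::trimatl(Lj), rhs);
        arma::vec mj = arma::solve(arma::trimatu(Lj.t()), wj);
        arma::vec ej(2); ej(0) = norm_rand(); ej(1) = norm_rand();
        arma::vec uj = mj + arma::solve(arma::trimatu(Lj.t()), ej);
        u(j, 0) = uj(0); u(j, 1) = uj(1);
      }
    }

    // (5) study-level covariance
    {
      arma::mat Supost = Su + u.t() * u;
      Omega_u = rinvwish2(nu_u + J, Supost);
    }

    // (6) individual-level covariance via parameter expansion,
    //     then rescale so Omega_e[2,2] == 1 exactly
    {
      arma::vec xb1 = X * b1, xb2 = X * b2;
      for (int i = 0; i < n; ++i) {
        e1(i) = y1(i) - xb1(i) - u(study(i), 0);
        e2(i) = z(i)  - xb2(i) - u(study(i), 1);
      }
      arma::mat Sp = Se;
      Sp(0, 0) += arma::dot(e1, e1);
      Sp(0, 1) += arma::dot(e1, e2);
      Sp(1, 0) = Sp(0, 1);
      Sp(1, 1) += arma::dot(e2, e2);
      arma::mat Ostar = rinvwish2(nu_e + n, Sp);
      double s = std::sqrt(Ostar(1, 1));
      z /= s;
      b2 /= s;
      u.col(1) /= s;
      Omega_u(0, 1) /= s; Omega_u(1, 0) /= s; Omega_u(1, 1) /= (s * s);
      s11 = Ostar(0, 0);
      s12 = Ostar(0, 1) / s;
    }

    // record
    if (it >= n_burn && ((it - n_burn) % thin) == 0) {
      for (int k = 0; k < p; ++k) draws(kept, k) = b1(k);
      for (int k = 0; k < p; ++k) draws(kept, p + k) = b2(k);
      draws(kept, 2 * p)     = s11;
      draws(kept, 2 * p + 1) = 1.0; // sigma2_sq, identified
      draws(kept, 2 * p + 2) = s12 / std::sqrt(s11);
      draws(kept, 2 * p + 3) = Omega_u(0, 0);
      draws(kept, 2 * p + 4) = Omega_u(1, 1);
      draws(kept, 2 * p + 5) =
        Omega_u(0, 1) / std::sqrt(Omega_u(0, 0) * Omega_u(1, 1));
      for (int i = 0; i < n; ++i) {
        if (!miss2(i)) {
          if ((y2(i) == 1 && z(i) <= 0.0) || (y2(i) == 0 && z(i) > 0.0))
            ++sign_violations;
        }
      }
      ++kept;
    }
  }

  return List::create(_["draws"] = draws,
                      _["sign_violations"] = sign_violations,
                      _["z_final"] = z,
                      _["y1_final"] = y1);
}
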
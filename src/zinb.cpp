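#include <Rcpp.h>
using namespace Rcpp;

// Zero-inflated negative binomial mixed model, marginal negative
// log-likelihood. One scalar random intercept per site; the per-site
// integral over the random effect is evaluated by adaptive Gauss-Hermite
// quadrature (nodes recentred at the site's conditional mode and rescaled
// by the curvature there) or, optionally, by the Laplace approximation.
// The mode search is a damped Newton iteration with analytic first and
// second derivatives of the conditional log-density in u.
//
// Mixture density: P(y=0) = pi + (1-pi) * NB(0 | mu, disp)
//                  P(y=k) = (1-pi) * NB(k | mu, disp),  k > 0
// nb2: size = theta, variance mu(1 + mu/theta)
// nb1: size = mu/alpha, variance mu(1 + alpha)

static inline double log_nb_mu(double y, double mu, double disp, int family) {
  double size = (family == 2) ? disp : mu / disp;
  return R::dnbinom_mu(y, size, mu, 1);
}

// conditional log-likelihood of one site's observations at random effect u,
// plus the random-effect log-density (value only)
static double site_logjoint(double u,
                            const double* eta, const int* y, int n_i,
                            double disp, int family,
                            double lpi, double l1mpi, double sigma) {
  double ll = 0.0;
  for (int j = 0; j < n_i; ++j) {
    double lin = eta[j] + u;
    if (lin > 30.0) lin = 30.0; // guard overflow; mu ~ 1e13 is already absurd
    double mu = std::exp(lin);
    double lnb = log_nb_mu((double)y[j], mu, disp, family);
    if (y[j] == 0) {
      ll += Rf_logspace_add(lpi, l1mpi + lnb);
    } else {
      ll += l1mpi + lnb;
    }
  }
  return ll + R::dnorm(u, 0.0, sigma, 1);
}

// value, d/du and d2/du2 of the site conditional log-joint at u
static void site_logjoint_d(double u,
                            const double* eta, const int* y, int n_i,
                            double disp, int family,
                            double lpi, double l1mpi, double sigma,
                            double& val, double& grad, double& hess) {
  val = 0.0; grad = 0.0; hess = 0.0;
  const double log1pa = (family == 1) ? std::log1p(disp) : 0.0;
  for (int j = 0; j < n_i; ++j) {
    double lin = eta[j] + u;
    if (lin > 30.0) lin = 30.0;
    double mu = std::exp(lin);
    double yj = (double)y[j];
    double lnb, d1, d2;
    if (family == 2) {
      double th = disp;
      lnb = log_nb_mu(yj, mu, th, 2);
      d1 = yj - mu * (yj + th) / (mu + th);
      double r = mu + th;
      d2 = -(yj + th) * th * mu / (r * r);
    } else {
      double s = mu / disp; // NB1 size; ds/du = s
      lnb = log_nb_mu(yj, mu, disp, 1);
      double g = R::digamma(yj + s) - R::digamma(s) - log1pa;
      d1 = s * g;
      d2 = s * g + s * s * (R::trigamma(yj + s) - R::trigamma(s));
    }
    if (y[j] == 0) {
      // log( pi + (1-pi) q ), q = NB(0|mu)
      double lm = Rf_logspace_add(lpi, l1mpi + lnb);
      double w = std::exp(l1mpi + lnb - lm); // (1-pi) q / m, in (0,1)
      val += lm;
      grad += w * d1;
      hess += w * (d2 + d1 * d1) - (w * d1) * (w * d1);
    } else {
      val += l1mpi + lnb;
      grad += d1;
      hess += d2;
    }
  }
  val += R::dnorm(u, 0.0, sigma, 1);
  grad += -u / (sigma * sigma);
  hess += -1.0 / (sigma * sigma);
}

// [[Rcpp::export(name = ".zinb_nll_cpp")]]
double zinb_nll_cpp(NumericVector par, NumericMatrix X, IntegerVector y,
                    NumericVector offset, IntegerVector site, int n_sites,
                    int family, NumericVector gh_nodes,
                    NumericVector gh_weights, int method) {
  // par = c(beta, log_sigma, log_disp, logit_pi); method 1 = AGQ, 0 = Laplace
  const int n = X.nrow(), p = X.ncol();
  const double sigma = std::exp(par[p]);
  const double disp = std::exp(par[p + 1]);
  const double logit_pi = par[p + 2];
  const double l1mpi = -Rf_log1pexp(logit_pi);  // log(1 - pi)
  const double lpi = logit_pi + l1mpi;          // log(pi)

  std::vector<double> eta(n);
  for (int i = 0; i < n; ++i) {
    double e = offset[i];
    for (int k = 0; k < p; ++k) e += X(i, k) * par[k];
    eta[i] = e;
  }

  // observations are sorted by site; find each site's slice
  std::vector<int> start(n_sites + 1, 0);
  for (int i = 0; i < n; ++i) start[site[i] + 1]++;
  for (int s = 0; s < n_sites; ++s) start[s + 1] += start[s];

  const int nq = gh_nodes.size();
  double nll = 0.0;

  for (int s = 0; s < n_sites; ++s) {
    const int a = start[s], n_i = start[s + 1] - start[s];
    const double* eta_s = eta.data() + a;
    const int* y_s = &y[a];

    // damped Newton for the conditional mode of the joint density
    double u = 0.0, f0, g, h;
    site_logjoint_d(u, eta_s, y_s, n_i, disp, family, lpi, l1mpi, sigma,
                    f0, g, h);
    for (int it = 0; it < 50; ++it) {
      double hh = (h < -1e-10 && R_finite(h)) ? h : -1.0 / (sigma * sigma);
      double step = -g / hh;
      double cap = 3.0 * sigma + 1.0;
      if (step > cap) step = cap;
      if (step < -cap) step = -cap;
      double u_new = u + step;
      double f_new, g_new, h_new;
      site_logjoint_d(u_new, eta_s, y_s, n_i, disp, family, lpi, l1mpi,
                      sigma, f_new, g_new, h_new);
      int half = 0;
      while (f_new < f0 && half < 20) {
        u_new = 0.5 * (u + u_new);
        site_logjoint_d(u_new, eta_s, y_s, n_i, disp, family, lpi, l1mpi,
                        sigma, f_new, g_new, h_new);
        ++half;
      }
      double moved = std::fabs(u_new - u);
      u = u_new; f0 = f_new; g = g_new; h = h_new;
      if (moved < 1e-9 || std::fabs(g) < 1e-10) break;
    }
    double tau = (h < 0 && R_finite(h)) ? 1.0 / std::sqrt(-h) : sigma;

    double log_Li;
    if (method == 0) { // Laplace
      log_Li = f0 + 0.5 * std::log(2.0 * M_PI) + std::log(tau);
    } else { // adaptive Gauss-Hermite
      const double sq2tau = M_SQRT2 * tau;
      double lmax = R_NegInf;
      std::vector<double> terms(nq);
      for (int q = 0; q < nq; ++q) {
        double uq = u + sq2tau * gh_nodes[q];
        double t = std::log(gh_weights[q]) + gh_nodes[q] * gh_nodes[q] +
          site_logjoint(uq, eta_s, y_s, n_i, disp, family,
                        lpi, l1mpi, sigma);
        terms[q] = t;
        if (t > lmax) lmax = t;
      }
      double acc = 0.0;
      for (int q = 0; q < nq; ++q) acc += std::exp(terms[q] - lmax);
      log_Li = lmax + std::log(acc) + std::log(sq2tau);
    }
    if (!R_finite(log_Li)) return 1e10; // flag for the optimizer
    nll -= log_Li;
  }
  return nll;
}
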
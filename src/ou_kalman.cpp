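#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Matrix exponential of a real 2x2 via Cayley-Hamilton: with m = tr(M)/2 and
// disc = m^2 - det(M), exp(M) = e^m (cosh(d) I + sinh(d)/d (M - m I)) where
// d = sqrt(disc); trigonometric branch for disc < 0, series near disc = 0.
static mat expm2(const mat &M) {
  const double m = 0.5 * (M(0, 0) + M(1, 1));
  const double det = M(0, 0) * M(1, 1) - M(0, 1) * M(1, 0);
  const double disc = m * m - det;
  // ec = e^m cosh(d), es = e^m sinh(d)/d, formed from e^(m +/- d) so that
  // large |m| (long gaps) cannot overflow the hyperbolic terms
  double ec, es;
  if (disc > 1e-10) {
    const double d = std::sqrt(disc);
    const double ep = std::exp(m + d), en = std::exp(m - d);
    ec = 0.5 * (ep + en);
    es = 0.5 * (ep - en) / d;
  } else if (disc < -1e-10) {
    const double d = std::sqrt(-disc);
    const double em = std::exp(m);
    ec = em * std::cos(d);
    es = em * std::sin(d) / d;
  } else {  // cosh(d) = 1 + disc/2 + O(disc^2), sinh(d)/d = 1 + disc/6 + ...
    const double em = std::exp(m);
    ec = em * (1.0 + 0.5 * disc * (1.0 + disc / 12.0));
    es = em * (1.0 + disc / 6.0 * (1.0 + disc / 20.0));
  }
  mat E(2, 2);
  E(0, 0) = ec + es * (M(0, 0) - m);
  E(0, 1) = es * M(0, 1);
  E(1, 0) = es * M(1, 0);
  E(1, 1) = ec + es * (M(1, 1) - m);
  return E;
}

// Stationary covariance G solving A G + G A' + Q = 0 (Q symmetric PSD),
// written out as a 3x3 linear system in (g11, g12, g22).
static mat lyap2(const mat &A, const mat &Q) {
  mat C(3, 3);
  C(0, 0) = 2 * A(0, 0); C(0, 1) = 2 * A(0, 1); C(0, 2) = 0;
  C(1, 0) = A(1, 0);     C(1, 1) = A(0, 0) + A(1, 1); C(1, 2) = A(0, 1);
  C(2, 0) = 0;           C(2, 1) = 2 * A(1, 0); C(2, 2) = 2 * A(1, 1);
  vec rhs = {-Q(0, 0), -Q(0, 1), -Q(1, 1)};
  vec g;
  mat G(2, 2);
  if (!solve(g, C, rhs, solve_opts::no_approx)) {
    G.fill(datum::nan);
    return G;
  }
  G(0, 0) = g(0); G(0, 1) = g(1); G(1, 0) = g(1); G(1, 1) = g(2);
  return G;
}

static bool stationary2(const mat &A) {
  // Routh-Hurwitz for 2x2: both eigenvalue real parts negative iff tr < 0, det > 0
  return (A(0, 0) + A(1, 1) < 0) && (A(0, 0) * A(1, 1) - A(0, 1) * A(1, 0) > 0);
}

// Core continuous-discrete Kalman filter log-likelihood. y is T x 2 with NaN
// for missing components; times in hours, strictly increasing.
static double kalman_core(const vec &times, const mat &y, const mat &A,
                          const vec &b, const mat &Sigma, const vec &tau,
                          const vec &meas_var, const bool diffuse) {
  const uword T = times.n_elem;
  const mat Q = Sigma * Sigma.t();
  const mat G = lyap2(A, Q);
  if (!G.is_finite() || G(0, 0) <= 0 || G(1, 1) <= 0) return -datum::inf;
  vec mu;
  if (!solve(mu, A, -b, solve_opts::no_approx)) return -datum::inf;

  vec m = mu;
  mat P = G;
  if (diffuse) {
    m.zeros();
    P = 1e7 * eye(2, 2);
  }

  const double LOG2PI = 1.8378770664093453;
  double ll = 0.0;

  for (uword t = 0; t < T; ++t) {
    if (t > 0) {
      const double delta = times(t) - times(t - 1);
      const mat Ad = expm2(A * delta);
      m = mu + Ad * (m - mu);
      P = Ad * P * Ad.t() + (G - Ad * G * Ad.t());
      P = 0.5 * (P + P.t());
    }
    const bool o0 = std::isfinite(y(t, 0)), o1 = std::isfinite(y(t, 1));
    if (!o0 && !o1) continue;
    if (o0 && o1) {
      vec innov = {y(t, 0) - m(0) - tau(0), y(t, 1) - m(1) - tau(1)};
      mat S = P;
      S(0, 0) += meas_var(0);
      S(1, 1) += meas_var(1);
      const double dS = S(0, 0) * S(1, 1) - S(0, 1) * S(1, 0);
      if (dS <= 0) return -datum::inf;
      mat Sinv(2, 2);
      Sinv(0, 0) = S(1, 1) / dS; Sinv(1, 1) = S(0, 0) / dS;
      Sinv(0, 1) = -S(0, 1) / dS; Sinv(1, 0) = -S(1, 0) / dS;
      ll += -LOG2PI - 0.5 * std::log(dS) -
            0.5 * as_scalar(innov.t() * Sinv * innov);
      const mat K = P * Sinv;
      m += K * innov;
      P = P - K * P;
      P = 0.5 * (P + P.t());
    } else {
      const uword i = o0 ? 0 : 1;
      const double innov = y(t, i) - m(i) - tau(i);
      const double S = P(i, i) + meas_var(i);
      if (S <= 0) return -datum::inf;
      ll += -0.5 * (LOG2PI + std::log(S) + innov * innov / S);
      const vec K = P.col(i) / S;
      m += K * innov;
      P = P - K * P.row(i);
      P = 0.5 * (P + P.t());
    }
  }
  return ll;
}

// [[Rcpp::export]]
double kalman_loglik_cpp(const arma::vec &times, const arma::mat &y,
                         const arma::mat &A, const arma::vec &b,
                         const arma::mat &Sigma, const arma::vec &tau,
                         const arma::vec &meas_var, const bool diffuse) {
  if (!stationary2(A)) Rcpp::stop("drift matrix is not stationary");
  return kalman_core(times, y, A, b, Sigma, tau, meas_var, diffuse);
}

// [[Rcpp::export]]
arma::mat expm2_cpp(const arma::mat &M) { return expm2(M); }

static double softplus(const double x) {
  return x > 30 ? x : std::log1p(std::exp(x));
}

// Log-likelihood for one person parameterized on the unconstrained sampling
// scale: theta = (th_a11, th_a22, a12, a21, th_d1, th_d2, tau1, tau2) with
// diagonal drift entries -softplus(th_a) and diffusion SDs softplus(th_d);
// meas_theta are softplus-scale shared measurement SDs. Returns -Inf for
// non-stationary drift (rejected by the sampler).
// [[Rcpp::export]]
double theta_loglik_cpp(const arma::vec &times, const arma::mat &y,
                        const arma::vec &theta, const arma::vec &meas_theta) {
  mat A(2, 2);
  A(0, 0) = -softplus(theta(0));
  A(1, 1) = -softplus(theta(1));
  A(0, 1) = theta(2);
  A(1, 0) = theta(3);
  if (!stationary2(A)) return -datum::inf;
  mat Sigma(2, 2, fill::zeros);
  Sigma(0, 0) = softplus(theta(4));
  Sigma(1, 1) = softplus(theta(5));
  vec tau = {theta(6), theta(7)};
  vec b(2, fill::zeros);
  vec mv = {std::pow(softplus(meas_theta(0)), 2),
            std::pow(softplus(meas_theta(1)), 2)};
  return kalman_core(times, y, A, b, Sigma, tau, mv, false);
}
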
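// Overlapping group-lasso Cox regression, solved on the latent-effect
// expanded design by accelerated proximal gradient (FISTA) with
// backtracking line search and warm-started lambda path.
// Breslow handling of ties throughout.  Rows must be pre-sorted by
// ascending observed time.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Negative Breslow log partial likelihood and its gradient in eta.
// tie_first / tie_last are 0-based indices of each row's tie-group span.
static double cox_negloglik_grad(const vec& eta, const vec& delta,
                                 const uvec& tie_first,
                                 const uvec& tie_last, vec& grad_eta) {
  const int n = eta.n_elem;
  const double M = eta.max();
  vec w = exp(eta - M);
  // s0(i) = sum_{l >= i} w(l)
  vec s0(n);
  double acc = 0.0;
  for (int i = n - 1; i >= 0; --i) { acc += w(i); s0(i) = acc; }
  double f = 0.0;
  // per-row hazard increment delta_i / S0(at its event time)
  vec inc(n, fill::zeros);
  for (int i = 0; i < n; ++i) {
    if (delta(i) == 1.0) {
      const double s = s0(tie_first(i));
      f += std::log(s) + M - eta(i);
      inc(i) = 1.0 / s;
    }
  }
  vec cuminc(n);
  acc = 0.0;
  for (int i = 0; i < n; ++i) { acc += inc(i); cuminc(i) = acc; }
  // cumulative hazard of subject i sums increments of all rows with
  // t_l <= t_i, i.e. through the end of i's tie group
  grad_eta.set_size(n);
  for (int i = 0; i < n; ++i)
    grad_eta(i) = -delta(i) + w(i) * cuminc(tie_last(i));
  return f;
}

// group proximal map; groups index penalized columns only
static void prox_groups(vec& b, int nunpen, const uvec& grp_start,
                        const uvec& grp_end, const vec& grp_mult,
                        double thr) {
  for (uword g = 0; g < grp_start.n_elem; ++g) {
    const uword a = nunpen + grp_start(g), z = nunpen + grp_end(g);
    double nrm = norm(b.subvec(a, z), 2);
    const double t = thr * grp_mult(g);
    if (nrm <= t) {
      b.subvec(a, z).zeros();
    } else {
      b.subvec(a, z) *= (1.0 - t / nrm);
    }
  }
}

static double penalty_value(const vec& b, int nunpen, const uvec& grp_start,
                            const uvec& grp_end, const vec& grp_mult,
                            double lam) {
  double pen = 0.0;
  for (uword g = 0; g < grp_start.n_elem; ++g)
    pen += grp_mult(g) *
      norm(b.subvec(nunpen + grp_start(g), nunpen + grp_end(g)), 2);
  return lam * pen;
}

// [[Rcpp::export(name = ".grplasso_cox_path")]]
Rcpp::List grplasso_cox_path(const arma::mat& X, const arma::vec& delta,
                             const arma::uvec& tie_first,
                             const arma::uvec& tie_last, int nunpen,
                             const arma::uvec& grp_start,
                             const arma::uvec& grp_end,
                             const arma::vec& grp_mult,
                             arma::vec lambda, int nlambda,
                             double lambda_min_ratio, int max_iter,
                             double tol) {
  const int n = X.n_rows, m = X.n_cols;
  const double ninv = 1.0 / n;
  vec beta(m, fill::zeros), grad_eta(n);

  // converge the unpenalized block alone (penalized part held at zero)
  // by plain gradient descent with backtracking
  {
    double step = 1.0;
    vec eta = X.cols(0, nunpen > 0 ? nunpen - 1 : 0) *
              beta.subvec(0, nunpen > 0 ? nunpen - 1 : 0);
    if (nunpen > 0) {
      for (int it = 0; it < 200; ++it) {
        vec eta_full = X * beta;
        double f = cox_negloglik_grad(eta_full, delta, tie_first,
                                      tie_last, grad_eta) * ninv;
        vec g = (X.cols(0, nunpen - 1).t() * grad_eta) * ninv;
        if (norm(g, 2) < 1e-9) break;
        for (int bt = 0; bt < 60; ++bt) {
          vec bnew = beta.subvec(0, nunpen - 1) - step * g;
          vec bfull = beta; bfull.subvec(0, nunpen - 1) = bnew;
          vec dummy;
          double fnew = cox_negloglik_grad(X * bfull, delta, tie_first,
                                           tie_last, dummy) * ninv;
          if (fnew <= f - 0.5 * step * dot(g, g) + 1e-14) {
            beta.subvec(0, nunpen - 1) = bnew;
            step *= 1.5;
            break;
          }
          step *= 0.5;
        }
      }
    }
  }

  // gradient at the null fit gives lambda_max
  vec eta = X * beta;
  cox_negloglik_grad(eta, delta, tie_first, tie_last, grad_eta);
  vec g_full = (X.t() * grad_eta) * ninv;
  double lam_max = 0.0;
  for (uword g = 0; g < grp_start.n_elem; ++g) {
    double nrm = norm(g_full.subvec(nunpen + grp_start(g),
                                    nunpen + grp_end(g)), 2) / grp_mult(g);
    if (nrm > lam_max) lam_max = nrm;
  }
  if (lambda.n_elem == 0) {
    lambda.set_size(nlambda);
    const double llmax = std::log(lam_max),
                 llmin = std::log(lam_max * lambda_min_ratio);
    for (int k = 0; k < nlambda; ++k)
      lambda(k) = std::exp(llmax + (llmin - llmax) * k / (nlambda - 1.0));
  }

  mat betas(m, lambda.n_elem, fill::zeros);
  ivec iters(lambda.n_elem, fill::zeros);
  double step = 1.0;

  for (uword k = 0; k < lambda.n_elem; ++k) {
    const double lam = lambda(k);
    vec b = beta, b_prev = beta, y = beta;
    double tk = 1.0;
    double obj_prev = datum::inf;
    int it = 0;
    for (; it < max_iter; ++it) {
      vec eta_y = X * y;
      double fy = cox_negloglik_grad(eta_y, delta, tie_first, tie_last,
                                     grad_eta) * ninv;
      vec g = (X.t() * grad_eta) * ninv;
      vec b_new;
      double fnew = 0.0;
      for (int bt = 0; bt < 60; ++bt) {
        b_new = y - step * g;
        prox_groups(b_new, nunpen, grp_start, grp_end, grp_mult,
                    step * lam);
        vec d = b_new - y;
        vec dummy;
        fnew = cox_negloglik_grad(X * b_new, delta, tie_first, tie_last,
                                  dummy) * ninv;
        if (fnew <= fy + dot(g, d) + 0.5 * dot(d, d) / step + 1e-14)
          break;
        step *= 0.5;
      }
      double t_next = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * tk * tk));
      y = b_new + ((tk - 1.0) / t_next) * (b_new - b);
      double obj = fnew + penalty_value(b_new, nunpen, grp_start,
                                        grp_end, grp_mult, lam);
      if (obj > obj_prev + 1e-14) {      // adaptive restart
        y = b_new;
        t_next = 1.0;
      }
      double chg = norm(b_new - b, "inf");
      b_prev = b; b = b_new; tk = t_next;
      if (chg < tol * std::max(1.0, norm(b, "inf")) &&
          std::fabs(obj_prev - obj) <
            tol * std::max(1.0, std::fabs(obj)))
        { obj_prev = obj; break; }
      obj_prev = obj;
      step *= 1.1;                       // gentle step recovery
    }
    beta = b;
    betas.col(k) = b;
    iters(k) = it;
  }
  return Rcpp::List::create(Rcpp::Named("beta") = betas,
                            Rcpp::Named("lambda") = lambda,
                            Rcpp::Named("lambda_max") = lam_max,
                            Rcpp::Named("iters") = iters);
}

// [[Rcpp::export(name = ".cox_negloglik")]]
double cox_negloglik(const arma::vec& eta, const arma::vec& delta,
                     const arma::uvec& tie_first,
                     const arma::uvec& tie_last) {
  vec dummy;
  return cox_negloglik_grad(eta, delta, tie_first, tie_last, dummy);
}
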
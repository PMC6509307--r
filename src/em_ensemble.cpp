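// Euler-Maruyama ensemble simulator for the correlated-noise firing-rate
// network. The update for each realization (row of x) is
//   x <- x + (dt/tau) * (-x + mu~(t) + G F(x)) + (sqrt(dt)/tau) * s~(t) (L z)
// with z iid standard normal and L L' = Cr. Uses R's RNG (norm_rand) so
// results are reproducible through set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat sigmoid_cols(const arma::mat& x,
                                     const arma::rowvec& x_rev,
                                     const arma::rowvec& x_sp) {
  arma::mat z = x;
  z.each_row() -= x_rev;
  z.each_row() /= x_sp;
  return 0.5 * (1.0 + arma::tanh(z));
}

// [[Rcpp::export(name = ".em_ensemble_cpp")]]
List em_ensemble_cpp(arma::mat x, const arma::vec& tau, const arma::mat& G,
                     const arma::mat& L, const arma::vec& x_rev,
                     const arma::vec& x_sp, const arma::mat& mu_path,
                     const arma::mat& sigma_path, double dt,
                     const arma::ivec& rec_state, int group_size) {
  const arma::uword n_real = x.n_rows, N = x.n_cols;
  const int n_steps = mu_path.n_rows;
  const arma::uword n_out = rec_state.n_elem;
  const arma::uword n_groups = n_real / group_size;
  const arma::uword P = N * (N - 1) / 2;
  if (n_real % group_size != 0)
    stop("n_realizations must be a multiple of group_size");

  const arma::rowvec xr = x_rev.t(), xs = x_sp.t();
  const arma::rowvec dt_tau = dt / tau.t();
  const arma::rowvec sdt_tau = std::sqrt(dt) / tau.t();
  const arma::mat Gt = G.t(), Lt = L.t();

  arma::mat sum_x(n_out, N, arma::fill::zeros), sum_F(n_out, N, arma::fill::zeros);
  arma::cube sum_xx(N, N, n_out, arma::fill::zeros),
             sum_FF(N, N, n_out, arma::fill::zeros);
  arma::uword Pc = P > 0 ? P : 1;
  arma::cube gmean_x(n_groups, N, n_out), gvar_x(n_groups, N, n_out),
             gmean_F(n_groups, N, n_out), gvar_F(n_groups, N, n_out),
             gcov_x(n_groups, Pc, n_out, arma::fill::zeros),
             gcov_F(n_groups, Pc, n_out, arma::fill::zeros);

  auto record = [&](arma::uword idx) {
    arma::mat Fx = sigmoid_cols(x, xr, xs);
    sum_x.row(idx) = arma::sum(x, 0);
    sum_F.row(idx) = arma::sum(Fx, 0);
    sum_xx.slice(idx) = x.t() * x;
    sum_FF.slice(idx) = Fx.t() * Fx;
    for (arma::uword g = 0; g < n_groups; ++g) {
      arma::uword r0 = g * group_size, r1 = r0 + group_size - 1;
      const arma::mat Xg = x.rows(r0, r1);
      const arma::mat Fg = Fx.rows(r0, r1);
      arma::rowvec mx = arma::mean(Xg, 0), mf = arma::mean(Fg, 0);
      arma::mat Cx = Xg.t() * Xg / group_size - mx.t() * mx;
      arma::mat Cf = Fg.t() * Fg / group_size - mf.t() * mf;
      gmean_x.slice(idx).row(g) = mx;
      gmean_F.slice(idx).row(g) = mf;
      gvar_x.slice(idx).row(g) = Cx.diag().t();
      gvar_F.slice(idx).row(g) = Cf.diag().t();
      arma::uword q = 0;
      for (arma::uword k = 1; k < N; ++k)
        for (arma::uword j = 0; j < k; ++j, ++q) {
          gcov_x.slice(idx)(g, q) = Cx(j, k);
          gcov_F.slice(idx)(g, q) = Cf(j, k);
        }
    }
  };

  RNGScope scope;
  arma::mat Z(n_real, N);
  arma::uword rec_i = 0;
  for (int s = 0; s <= n_steps; ++s) {
    while (rec_i < n_out && rec_state[rec_i] == s) {
      record(rec_i);
      ++rec_i;
    }
    if (s == n_steps) break;
    arma::mat Fx = sigmoid_cols(x, xr, xs);
    arma::mat drift = -x + Fx * Gt;
    drift.each_row() += mu_path.row(s);
    drift.each_row() %= dt_tau;
    for (arma::uword i = 0; i < Z.n_elem; ++i) Z[i] = norm_rand();
    arma::mat W = Z * Lt;
    W.each_row() %= sigma_path.row(s) % sdt_tau;
    x += drift + W;
    if (s % 100 == 0 && !x.is_finite()) {
      arma::uvec bad = arma::find_nonfinite(x);
      stop("non-finite trajectory at step %d (realization %d)", s,
           (int)(bad(0) % n_real) + 1);
    }
  }
  if (!x.is_finite()) stop("non-finite trajectory at final step");

  return List::create(
    _["sum_x"] = sum_x, _["sum_F"] = sum_F,
    _["sum_xx"] = sum_xx, _["sum_FF"] = sum_FF,
    _["gmean_x"] = gmean_x, _["gvar_x"] = gvar_x, _["gcov_x"] = gcov_x,
    _["gmean_F"] = gmean_F, _["gvar_F"] = gvar_F, _["gcov_F"] = gcov_F);
}
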
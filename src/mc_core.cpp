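#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sequential per-layer Monte-Carlo rejection fit of the retained fractions.
//
// One replicate = one perturbed realisation of every measured quantity
// (rows of the input matrices / vectors). Within a replicate, layers are
// fitted top-down; the accepted draw's drainage trajectory becomes the
// input series of the layer below. Chlorine is at steady state throughout,
// so the layer's mobile Cl pool equals its Cl input and the 36Cl absorption
// in "mobile" mode is alpha * [(1-X) I36_t + Z S36_{t-1}] with
// alpha = A_cl / I_cl.
//
// Selection modes for the layer's X draw:
//   first  — uniform candidates until one is accepted (plain rejection);
//   lowest — evaluate max_tries uniform candidates, cluster the accepted
//            ones by the X-gap rule, keep one uniform draw from the lowest
//            contiguous cluster (the acceptance region can be disjoint: a
//            low-X and a high-X solution branch both reproduce the
//            observed stock; measured fluxes favour weak retention).
//
// All random numbers come from R's RNG, so results are reproducible under
// set.seed().

static inline double simulate_stock(const std::vector<double>& I, double S0,
                                    double X, double Z, int stock_idx) {
  double S = S0;
  for (int t = 1; t <= stock_idx; ++t)
    S = (1.0 - Z) * S + X * I[t];
  return S;
}

// [[Rcpp::export]]
List mc_fit_core(NumericMatrix s36_obs,   // n x K perturbed observed stocks
                 NumericMatrix tol_abs,   // n x K absolute acceptance widths
                 NumericMatrix t_r,       // n x K Cl residence times
                 NumericMatrix alpha,     // n x K absorption/input ratios
                 NumericMatrix i_cl,      // n x K Cl input cascade
                 NumericVector bg36,      // n background 36Cl rainfall flux
                 NumericVector lam36,     // n litterfall/rainfall ratio, 36Cl
                 NumericVector r_cl,      // n Cl rainfall flux
                 NumericVector shape_t,   // T pulse multiplier series (t0 = 1)
                 int stock_idx,           // 0-based index of the stock year
                 int max_tries,
                 bool rainfall_mode,
                 bool lowest_mode,
                 double gap_threshold) {
  const int n = s36_obs.nrow();
  const int K = s36_obs.ncol();
  const int T = shape_t.size();
  if (stock_idx < 1 || stock_idx >= T)
    stop("stock year index out of range");

  NumericMatrix x_out(n, K), s_sim(n, K), nearest(n, K);
  IntegerMatrix tries_out(n, K), infeas(n, K);
  std::fill(x_out.begin(), x_out.end(), NA_REAL);
  std::fill(s_sim.begin(), s_sim.end(), NA_REAL);
  std::fill(nearest.begin(), nearest.end(), NA_REAL);
  long clamp_count = 0;

  std::vector<double> I_cur(T), D_buf(T);
  std::vector<std::pair<double, double> > acc;  // (X, simulated stock)

  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < T; ++t)
      I_cur[t] = bg36[i] * shape_t[t] * (1.0 + lam36[i]);

    for (int k = 0; k < K; ++k) {
      const double Tr = t_r(i, k);
      const double al = alpha(i, k);
      if (!(Tr > 0.0)) break;  // degenerate replicate: leave layers NA
      const double S0 = I_cur[0] * Tr;  // pre-bomb steady state
      const double obs = s36_obs(i, k);
      const double tol = tol_abs(i, k);

      bool found = false;
      double best = R_PosInf, x_acc = NA_REAL, s_acc = NA_REAL;
      int tries = 0, nif = 0;
      if (!lowest_mode) {
        while (tries < max_tries) {
          ++tries;
          const double X = unif_rand();
          const double Z = X / Tr;
          if (Z > 1.0) { ++nif; continue; }  // stock over-turns in one step
          const double S = simulate_stock(I_cur, S0, X, Z, stock_idx);
          const double miss = std::fabs(S - obs);
          if (miss < best) best = miss;
          if (miss <= tol) { found = true; x_acc = X; s_acc = S; break; }
        }
      } else {
        acc.clear();
        for (tries = 0; tries < max_tries; ++tries) {
          const double X = unif_rand();
          const double Z = X / Tr;
          if (Z > 1.0) { ++nif; continue; }
          const double S = simulate_stock(I_cur, S0, X, Z, stock_idx);
          const double miss = std::fabs(S - obs);
          if (miss < best) best = miss;
          if (miss <= tol) acc.push_back(std::make_pair(X, S));
        }
        if (!acc.empty()) {
          std::sort(acc.begin(), acc.end());
          // lowest contiguous cluster under the X-gap rule
          size_t hi = acc.size();
          for (size_t j = 1; j < acc.size(); ++j) {
            if (acc[j].first - acc[j - 1].first > gap_threshold) {
              hi = j;
              break;
            }
          }
          const size_t pick = (size_t)std::floor(unif_rand() * (double)hi);
          const size_t j = pick >= hi ? hi - 1 : pick;
          found = true;
          x_acc = acc[j].first;
          s_acc = acc[j].second;
        }
      }
      tries_out(i, k) = tries;
      infeas(i, k) = nif;
      nearest(i, k) = best;
      if (!found) break;  // no accepted upstream draw: stop this replicate

      x_out(i, k) = x_acc;
      s_sim(i, k) = s_acc;
      if (k == K - 1) break;

      // drainage trajectory of the accepted draw feeds the next layer
      const double Z = x_acc / Tr;
      double S = S0;
      for (int t = 0; t < T; ++t) {
        const double mobile = (1.0 - x_acc) * I_cur[t] + Z * S;
        double A36;
        if (rainfall_mode) {
          A36 = al * i_cl(i, k) * (bg36[i] * shape_t[t] / r_cl[i]);
        } else {
          A36 = al * mobile;
        }
        double D = mobile - A36;
        if (D < 0.0) { D = 0.0; ++clamp_count; }
        if (t > 0) S = (1.0 - Z) * S + x_acc * I_cur[t];
        D_buf[t] = D;
      }
      std::copy(D_buf.begin(), D_buf.end(), I_cur.begin());
    }
  }

  IntegerVector accept_n(K);
  for (int k = 0; k < K; ++k) {
    int c = 0;
    for (int i = 0; i < n; ++i)
      if (!NumericVector::is_na(x_out(i, k))) ++c;
    accept_n[k] = c;
  }

  return List::create(
    _["x"] = x_out, _["s_sim"] = s_sim, _["tries"] = tries_out,
    _["infeasible"] = infeas, _["nearest_miss"] = nearest,
    _["accept_n"] = accept_n, _["clamp_count"] = (double)clamp_count);
}
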
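#include <Rcpp.h>
using namespace Rcpp;

// Condition / racer order everywhere: C, M, O, CO, MO, CM.
// Each double-feature condition is a 3-racer race.
static const int RACE[3][3] = {
  {0, 2, 3},  // CO: C, O, CO
  {1, 2, 4},  // MO: M, O, MO
  {0, 1, 5}   // CM: C, M, CM
};

// survivor S(k, i) = sum_{j >= i} p(k, j); caller supplies storage [3][N+1]
static void survivors(const NumericMatrix& probs, const int* members,
                      std::vector<std::vector<double> >& S, int N) {
  for (int k = 0; k < 3; ++k) {
    S[k][N] = 0.0;
    const int r = members[k];
    for (int i = N - 1; i >= 0; --i) S[k][i] = S[k][i + 1] + probs(r, i);
  }
}

// [[Rcpp::export]]
double cpp_nll(NumericMatrix probs, NumericMatrix counts, double prob_floor) {
  const int N = probs.ncol();
  double nll = 0.0;
  for (int c = 0; c < 3; ++c)       // single conditions
    for (int i = 0; i < N; ++i)
      if (counts(c, i) > 0)
        nll -= counts(c, i) * std::log(std::max(probs(c, i), prob_floor));
  std::vector<std::vector<double> > S(3, std::vector<double>(N + 1));
  for (int r = 0; r < 3; ++r) {     // races
    survivors(probs, RACE[r], S, N);
    for (int i = 0; i < N; ++i) {
      const double n = counts(3 + r, i);
      if (n > 0) {
        double q = S[0][i] * S[1][i] * S[2][i]
                 - S[0][i + 1] * S[1][i + 1] * S[2][i + 1];
        nll -= n * std::log(std::max(q, prob_floor));
      }
    }
  }
  return nll;
}

// One EM sweep: expected bin occupancies for every racer, then renormalise
// the free racers. Latent variables are the racers' individual bins given
// the observed winning bin of each race.
static void em_sweep(NumericMatrix& probs, const NumericMatrix& counts,
                     const LogicalVector& free_racer, NumericMatrix& occ) {
  const int N = probs.ncol();
  std::fill(occ.begin(), occ.end(), 0.0);
  for (int c = 0; c < 3; ++c)
    for (int i = 0; i < N; ++i) occ(c, i) += counts(c, i);
  std::vector<std::vector<double> > S(3, std::vector<double>(N + 1));
  for (int r = 0; r < 3; ++r) {
    bool any = false;
    for (int i = 0; i < N; ++i) if (counts(3 + r, i) > 0) { any = true; break; }
    if (!any) continue;
    survivors(probs, RACE[r], S, N);
    for (int ki = 0; ki < 3; ++ki) {
      const int k = RACE[r][ki];
      const int o1 = (ki == 0) ? 1 : 0;
      const int o2 = (ki == 2) ? 1 : 2;
      for (int i = 0; i < N; ++i) {
        const double n = counts(3 + r, i);
        if (n <= 0) continue;
        const double q = S[0][i] * S[1][i] * S[2][i]
                       - S[0][i + 1] * S[1][i + 1] * S[2][i + 1];
        const double denom = std::max(q, 1e-300);
        const double Tk  = S[o1][i] * S[o2][i];
        const double Tk1 = S[o1][i + 1] * S[o2][i + 1];
        // racer k in the winning bin itself (others at or after i)
        occ(k, i) += n * probs(k, i) * Tk / denom;
        // racer k strictly later than the winning bin
        const double f = n * (Tk - Tk1) / denom;
        if (f != 0.0)
          for (int j = i + 1; j < N; ++j) occ(k, j) += f * probs(k, j);
      }
    }
  }
  for (int k = 0; k < 6; ++k) {
    if (!free_racer[k]) continue;
    double tot = 0.0;
    for (int i = 0; i < N; ++i) tot += occ(k, i);
    if (tot > 0)
      for (int i = 0; i < N; ++i) probs(k, i) = occ(k, i) / tot;
  }
}

// [[Rcpp::export]]
List cpp_em_fit(NumericMatrix counts, NumericMatrix init,
                LogicalVector free_racer, int max_iter, double tol,
                double prob_floor) {
  if (counts.nrow() != 6 || init.nrow() != 6 || counts.ncol() != init.ncol())
    stop("counts and init must both be 6 x N");
  NumericMatrix probs = clone(init);
  NumericMatrix occ(6, probs.ncol());
  double last = cpp_nll(probs, counts, prob_floor);
  double cur = last;
  bool converged = false;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    em_sweep(probs, counts, free_racer, occ);
    cur = cpp_nll(probs, counts, prob_floor);
    if (last - cur < tol) { converged = true; ++iter; break; }
    last = cur;
  }
  return List::create(_["probs"] = probs, _["nll"] = cur,
                      _["converged"] = converged, _["n_iter"] = iter);
}
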
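#include <Rcpp.h>
using namespace Rcpp;

// One meiosis over a multi-chromosome cM map: writes the gamete into `out`.
// Crossover count per chromosome is Poisson(map length in Morgans), positions
// uniform on the cM interval (Haldane, no interference).
static void meiosis(const IntegerMatrix &hap, int hA, int hB,
                    const NumericVector &cm,
                    const IntegerVector &chr_start, const IntegerVector &chr_end,
                    double mu, IntegerVector &out) {
  int nchr = chr_start.size();
  for (int c = 0; c < nchr; ++c) {
    int s = chr_start[c], e = chr_end[c];
    double lo = cm[s], hi = cm[e];
    double L = (hi - lo) / 100.0;
    int k = (int) R::rpois(L);
    std::vector<double> xo(k);
    for (int i = 0; i < k; ++i) xo[i] = lo + R::unif_rand() * (hi - lo);
    std::sort(xo.begin(), xo.end());
    int phase = (R::unif_rand() < 0.5) ? 0 : 1;  // 0 -> hA first
    int xi = 0;
    for (int j = s; j <= e; ++j) {
      while (xi < k && xo[xi] < cm[j]) { phase = 1 - phase; ++xi; }
      out[j] = phase == 0 ? hap(hA, j) : hap(hB, j);
    }
  }
  if (mu > 0) {
    int m = cm.size();
    int nmut = (int) R::rbinom((double) m, mu);
    for (int i = 0; i < nmut; ++i) {
      int j = (int) floor(R::unif_rand() * m);
      if (j >= m) j = m - 1;
      out[j] = 1 - out[j];
    }
  }
}

// Discrete-generation Wright-Fisher with recombination and recurrent mutation.
// hap: (2*Ne) x m matrix of 0/1 haplotypes, rows 2i, 2i+1 belong to diploid i.
// [[Rcpp::export]]
IntegerMatrix cpp_wf_evolve(IntegerMatrix hap, NumericVector cm,
                            IntegerVector chr_start, IntegerVector chr_end,
                            int n_gen, double mu) {
  int H = hap.nrow(), m = hap.ncol();
  int Ne = H / 2;
  IntegerMatrix cur = clone(hap);
  IntegerMatrix nxt(H, m);
  IntegerVector gam(m);
  for (int g = 0; g < n_gen; ++g) {
    for (int h = 0; h < H; ++h) {
      int par = (int) floor(R::unif_rand() * Ne);
      if (par >= Ne) par = Ne - 1;
      meiosis(cur, 2 * par, 2 * par + 1, cm, chr_start, chr_end, mu, gam);
      for (int j = 0; j < m; ++j) nxt(h, j) = gam[j];
    }
    std::swap(cur, nxt);
  }
  return cur;
}

// Gametes from chosen parents: one row per requested gamete (parent indices 1-based
// diploid ids into hap rows 2i, 2i+1). Used to drop half-sib offspring.
// [[Rcpp::export]]
IntegerMatrix cpp_gametes(IntegerMatrix hap, IntegerVector parent,
                          NumericVector cm, IntegerVector chr_start,
                          IntegerVector chr_end, double mu) {
  int n = parent.size(), m = hap.ncol();
  IntegerMatrix out(n, m);
  IntegerVector gam(m);
  for (int i = 0; i < n; ++i) {
    int p = parent[i] - 1;
    meiosis(hap, 2 * p, 2 * p + 1, cm, chr_start, chr_end, mu, gam);
    for (int j = 0; j < m; ++j) out(i, j) = gam[j];
  }
  return out;
}

// Single-site Gibbs sampler for BayesA: y = mu + X u + Z v + e with
// u_j ~ N(0, s2u_j), s2u_j ~ scaled-inv-chisq(nu, S), e ~ N(0, I s2e),
// optional polygenic v ~ N(0, A s2v) passed via the non-zero triplets of A-inverse.
// X must be column-centred by the caller. record_of: for each polygenic level,
// the 1-based row of y it belongs to, or 0 if the level has no record.
// [[Rcpp::export]]
List cpp_bayesa(NumericVector y, NumericMatrix X, double nu, double S,
                int n_iter, int burn_in, int thin,
                bool polygenic, IntegerVector ai_i, IntegerVector ai_j,
                NumericVector ai_x, IntegerVector record_of) {
  int n = y.size(), m = X.ncol();
  std::vector<double> xx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0; for (int i = 0; i < n; ++i) { double v = X(i, j); s += v * v; }
    xx[j] = s;
  }
  double vy = 0, my = 0;
  for (int i = 0; i < n; ++i) my += y[i];
  my /= n;
  for (int i = 0; i < n; ++i) vy += (y[i] - my) * (y[i] - my);
  vy /= (n - 1);

  double mu = my, s2e = vy / 2.0;
  std::vector<double> u(m, 0.0), s2u(m, S > 0 ? S : vy / (2.0 * m));
  NumericVector e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  int q = polygenic ? record_of.size() : 0;
  std::vector<double> v(q, 0.0), aidiag(q, 0.0);
  // CSR-ish storage of off-diagonal A-inverse entries per row
  std::vector< std::vector< std::pair<int, double> > > aoff(q);
  double s2v = polygenic ? vy / 4.0 : 0.0;
  if (polygenic) {
    int nz = ai_i.size();
    for (int k = 0; k < nz; ++k) {
      int r = ai_i[k] - 1, c = ai_j[k] - 1;
      if (r == c) aidiag[r] += ai_x[k];
      else aoff[r].push_back(std::make_pair(c, ai_x[k]));
    }
  }

  std::vector<double> u_sum(m, 0.0), s2u_sum(m, 0.0), v_sum(q, 0.0);
  double mu_sum = 0;
  std::vector<double> s2e_draws;
  int n_keep = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept (flat prior)
    double em = 0; for (int i = 0; i < n; ++i) em += e[i];
    em = em / n + mu;
    double mun = R::rnorm(em, sqrt(s2e / n));
    double dmu = mu - mun;
    for (int i = 0; i < n; ++i) e[i] += dmu;
    mu = mun;

    // SNP effects and their variances
    for (int j = 0; j < m; ++j) {
      if (xx[j] <= 0) { u[j] = 0; continue; }
      double rhs = 0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      rhs += xx[j] * u[j];
      double C = xx[j] + s2e / s2u[j];
      double un = R::rnorm(rhs / C, sqrt(s2e / C));
      double d = u[j] - un;
      if (d != 0) for (int i = 0; i < n; ++i) e[i] += X(i, j) * d;
      u[j] = un;
      s2u[j] = (nu * S + un * un) / R::rchisq(nu + 1.0);
    }

    if (polygenic) {
      for (int l = 0; l < q; ++l) {
        double off = 0;
        for (size_t k = 0; k < aoff[l].size(); ++k)
          off += aoff[l][k].second * v[aoff[l][k].first];
        double prec = aidiag[l] / s2v, rhs = -off / s2v;
        int rec = record_of[l];
        if (rec > 0) {
          int i = rec - 1;
          prec += 1.0 / s2e;
          rhs += (e[i] + v[l]) / s2e;
        }
        double vn = R::rnorm(rhs / prec, sqrt(1.0 / prec));
        if (rec > 0) e[rec - 1] += v[l] - vn;
        v[l] = vn;
      }
      double vav = 0;
      for (int l = 0; l < q; ++l) {
        double r = aidiag[l] * v[l];
        for (size_t k = 0; k < aoff[l].size(); ++k)
          r += aoff[l][k].second * v[aoff[l][k].first];
        vav += v[l] * r;
      }
      if (q > 2) s2v = vav / R::rchisq((double)(q - 2));
    }

    double sse = 0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = sse / R::rchisq((double)(n - 2));
    if (!R_finite(s2e) || s2e <= 0) stop("residual variance diverged");

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      ++n_keep;
      mu_sum += mu;
      for (int j = 0; j < m; ++j) { u_sum[j] += u[j]; s2u_sum[j] += s2u[j]; }
      for (int l = 0; l < q; ++l) v_sum[l] += v[l];
      s2e_draws.push_back(s2e);
    }
  }

  NumericVector uh(m), s2uh(m), vh(q);
  for (int j = 0; j < m; ++j) { uh[j] = u_sum[j] / n_keep; s2uh[j] = s2u_sum[j] / n_keep; }
  for (int l = 0; l < q; ++l) vh[l] = v_sum[l] / n_keep;
  return List::create(_["mu"] = mu_sum / n_keep, _["u_hat"] = uh,
                      _["s2u_hat"] = s2uh, _["v_hat"] = vh,
                      _["s2e_draws"] = NumericVector(s2e_draws.begin(), s2e_draws.end()),
                      _["n_keep"] = n_keep);
}
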
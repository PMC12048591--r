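// Event-driven cis-trans coevolution core.
//
// Between trans-mutation events the cis-genotypic value of every gene
// evolves under a fixed origin-fixation transition matrix; propagation uses
// cached binary powers of T so an interval of dt steps costs O(log dt)
// vector-matrix products. When every gene shares one architecture and the
// full distribution is retained after events (the default), all genes have
// identical distributions at all times and a single shared distribution is
// tracked, with per-gene genotypes sampled only at events.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Model {
  int l;
  double Ne, mu01, mu10;
  double alpha, gamma0, gamma1, C, eps, sigma, lambda, P0_opt;
  double Q_opt, sigma_Q;
};

// Kimura diploid fixation probability, expm1-accurate, underflow-guarded.
double kimura(double Ne, double s) {
  if (std::fabs(s) < 1e-300) return 1.0 / (2.0 * Ne);
  double b = -4.0 * Ne * s;
  if (b > 700.0) {
    return std::exp(2.0 * s * (2.0 * Ne - 1.0)) * (-std::expm1(2.0 * s));
  }
  return std::expm1(-2.0 * s) / std::expm1(b);
}

// Log fitness over v = 0..l for a deleterious editing-type event at trans
// value Q: Gaussian stabilizing selection on ln P0 plus toxicity on P1.
std::vector<double> log_fitness(const Model& m, double Q) {
  std::vector<double> lw(m.l + 1);
  for (int v = 0; v <= m.l; ++v) {
    double vhat = (m.l == 0) ? 0.0 : (double)v / m.l;
    double beta = Q * (m.C * vhat + m.eps);
    double P0 = m.alpha / (beta + m.gamma0);
    double P1 = m.alpha * beta / (m.gamma1 * (beta + m.gamma0));
    double d = std::log(P0) - std::log(m.P0_opt);
    lw[v] = -(d * d) / (2.0 * m.sigma * m.sigma) - m.lambda * P1;
  }
  return lw;
}

// Row-major (l+1)^2 origin-fixation transition matrix at trans value Q.
void build_T(const Model& m, double Q, std::vector<double>& T) {
  int n = m.l + 1;
  std::fill(T.begin(), T.end(), 0.0);
  std::vector<double> lw = log_fitness(m, Q);
  for (int v = 0; v < m.l; ++v) {
    double s_up = std::exp(lw[v + 1] - lw[v]) - 1.0;
    double s_dn = std::exp(lw[v] - lw[v + 1]) - 1.0;
    T[v * n + (v + 1)] = 2.0 * (m.l - v) * m.Ne * m.mu01 * kimura(m.Ne, s_up);
    T[(v + 1) * n + v] = 2.0 * (v + 1) * m.Ne * m.mu10 * kimura(m.Ne, s_dn);
  }
  for (int v = 0; v < n; ++v) {
    double off = 0.0;
    for (int j = 0; j < n; ++j)
      if (j != v) off += T[v * n + j];
    if (off > 1.0) stop("transition mass exceeds 1 (validity violated)");
    T[v * n + v] = 1.0 - off;
  }
}

void mat_square(const std::vector<double>& A, std::vector<double>& out,
                int n) {
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double acc = 0.0;
      for (int k = 0; k < n; ++k) acc += A[i * n + k] * A[k * n + j];
      out[i * n + j] = acc;
    }
}

struct PowerCache {
  int n;
  std::vector<std::vector<double>> pw;  // pw[k] = T^(2^k)
  void rebuild(const std::vector<double>& T, int nbits) {
    n = (int)std::sqrt((double)T.size() + 0.5);
    pw.assign(nbits, std::vector<double>(n * n));
    pw[0] = T;
    for (int k = 1; k < nbits; ++k) mat_square(pw[k - 1], pw[k], n);
  }
  // dist <- dist %*% T^dt, renormalized
  void advance(std::vector<double>& dist, double dt) const {
    std::vector<double> tmp(n);
    int k = 0;
    long long t = (long long)dt;
    while (t > 0) {
      if (t & 1LL) {
        const std::vector<double>& P = pw[k];
        for (int j = 0; j < n; ++j) {
          double acc = 0.0;
          for (int i = 0; i < n; ++i) acc += dist[i] * P[i * n + j];
          tmp[j] = acc;
        }
        dist = tmp;
      }
      t >>= 1;
      ++k;
    }
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      if (dist[i] < 0.0) dist[i] = 0.0;
      s += dist[i];
    }
    if (std::fabs(s - 1.0) > 1e-12)
      for (int i = 0; i < n; ++i) dist[i] /= s;
  }
};

int sample_categorical(const std::vector<double>& p) {
  double u = R::unif_rand();
  double acc = 0.0;
  int n = (int)p.size();
  for (int i = 0; i < n; ++i) {
    acc += p[i];
    if (u <= acc) return i;
  }
  return n - 1;
}

double log_trans_fitness(const Model& m, double Q) {
  if (!std::isfinite(m.sigma_Q)) return 0.0;
  double d = std::log(Q) - std::log(m.Q_opt);
  return -(d * d) / (2.0 * m.sigma_Q * m.sigma_Q);
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_editing_transition_matrix(
    int l, double Ne, double mu01, double mu10, double alpha, double gamma0,
    double gamma1, double C, double eps, double sigma, double lambda,
    double P0_opt, double Q) {
  Model m{l, Ne, mu01, mu10, alpha, gamma0, gamma1, C, eps,
          sigma, lambda, P0_opt, 1.0, R_PosInf};
  int n = l + 1;
  std::vector<double> T(n * n);
  build_T(m, Q, T);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) out(i, j) = T[i * n + j];
  return out;
}

// [[Rcpp::export]]
List cpp_simulate_lineage(int l, int v0, int n_genes, double Ne, double mu01,
                          double mu10, double alpha, double gamma0,
                          double gamma1, double C, double eps, double sigma,
                          double lambda, double P0_opt, double Q0,
                          double Q_opt, double sigma_Q, double S_Q, double L,
                          NumericVector event_times, bool collapse) {
  Model m{l, Ne, mu01, mu10, alpha, gamma0, gamma1, C, eps,
          sigma, lambda, P0_opt, Q_opt, sigma_Q};
  int n = l + 1;
  int nbits = 1;
  while (std::pow(2.0, nbits) < L + 1.0) ++nbits;

  std::vector<double> T(n * n);
  double Q = Q0;
  build_T(m, Q, T);
  PowerCache cache;
  cache.rebuild(T, nbits);

  std::vector<double> shared(n, 0.0);
  shared[v0] = 1.0;
  std::vector<std::vector<double>> gdist;
  if (collapse) gdist.assign(n_genes, shared);

  std::vector<int> vs(n_genes);
  int n_proposed = 0, n_fixed = 0;
  double tprev = 0.0;
  int mev = event_times.size();

  for (int e = 0; e < mev; ++e) {
    double te = event_times[e];
    double dt = te - tprev;
    tprev = te;
    if (collapse) {
      for (int g = 0; g < n_genes; ++g) cache.advance(gdist[g], dt);
    } else {
      cache.advance(shared, dt);
    }

    double delta = R::norm_rand() * S_Q;
    double Qm = Q * std::exp(delta);
    std::vector<double> lwA = log_fitness(m, Q);
    std::vector<double> lwM = log_fitness(m, Qm);
    double sumA = log_trans_fitness(m, Q);
    double sumM = log_trans_fitness(m, Qm);
    for (int g = 0; g < n_genes; ++g) {
      int v = sample_categorical(collapse ? gdist[g] : shared);
      vs[g] = v;
      sumA += lwA[v];
      sumM += lwM[v];
    }
    double s = std::exp(sumM - sumA) - 1.0;
    ++n_proposed;
    if (R::unif_rand() < kimura(Ne, s)) {
      Q = Qm;
      ++n_fixed;
      build_T(m, Q, T);
      cache.rebuild(T, nbits);
    }
    if (collapse) {
      for (int g = 0; g < n_genes; ++g) {
        std::fill(gdist[g].begin(), gdist[g].end(), 0.0);
        gdist[g][vs[g]] = 1.0;
      }
    }
  }

  double dt = L - tprev;
  if (collapse) {
    for (int g = 0; g < n_genes; ++g) cache.advance(gdist[g], dt);
  } else {
    cache.advance(shared, dt);
  }

  IntegerVector v_final(n_genes);
  NumericVector P1(n_genes);
  for (int g = 0; g < n_genes; ++g) {
    int v = sample_categorical(collapse ? gdist[g] : shared);
    v_final[g] = v;
    double vhat = (l == 0) ? 0.0 : (double)v / l;
    double beta = Q * (C * vhat + eps);
    P1[g] = alpha * beta / (gamma1 * (beta + gamma0));
  }

  NumericVector dist_out(n);
  if (collapse) {
    for (int g = 0; g < n_genes; ++g)
      for (int i = 0; i < n; ++i) dist_out[i] += gdist[g][i] / n_genes;
  } else {
    for (int i = 0; i < n; ++i) dist_out[i] = shared[i];
  }

  return List::create(
      _["Q_final"] = Q, _["v_final"] = v_final, _["P1"] = P1,
      _["dist_final"] = dist_out, _["n_proposed"] = n_proposed,
      _["n_fixed"] = n_fixed);
}
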
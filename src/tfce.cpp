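// Threshold-free cluster enhancement over a labels x time grid.
// Spatiotemporal connectivity = label adjacency (same time sample) plus
// +/- 1 time sample (same label). Enhancement: for each sample s,
// TFCE(s) = sum over thresholds h = dh, 2dh, ..., <= max(stat) of
// extent(cluster(s, h))^E * h^H * dh, where the cluster at height h is the
// connected suprathreshold (stat >= h) component containing s.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::vector<std::vector<int> > AdjList;

static AdjList build_adj(const List &adj) {
  int L = adj.size();
  AdjList out(L);
  for (int l = 0; l < L; ++l) {
    IntegerVector nb = adj[l];
    out[l].reserve(nb.size());
    for (int k = 0; k < nb.size(); ++k) out[l].push_back(nb[k] - 1);
  }
  return out;
}

// One enhancement pass; stat and out are length L*T, node id = l + t*L.
static void tfce_pass(const double *stat, int L, int T, const AdjList &ladj,
                      double E, double H, double dh, double hmax,
                      double *out, std::vector<int> &mark,
                      std::vector<int> &stack, std::vector<int> &members) {
  const int n = L * T;
  std::fill(out, out + n, 0.0);
  if (hmax <= 0 || dh <= 0) return;
  int nsteps = (int)std::floor(hmax / dh + 1e-9);
  std::fill(mark.begin(), mark.end(), -1);
  for (int k = 1; k <= nsteps; ++k) {
    double h = dh * k;
    double hH = std::pow(h, H) * dh;
    for (int s = 0; s < n; ++s) {
      if (stat[s] < h || mark[s] == k) continue;
      // BFS the component containing s
      members.clear();
      stack.clear();
      stack.push_back(s);
      mark[s] = k;
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        members.push_back(v);
        int l = v % L, t = v / L;
        const std::vector<int> &nb = ladj[l];
        for (size_t q = 0; q < nb.size(); ++q) {
          int w = nb[q] + t * L;
          if (mark[w] != k && stat[w] >= h) { mark[w] = k; stack.push_back(w); }
        }
        if (t > 0) {
          int w = v - L;
          if (mark[w] != k && stat[w] >= h) { mark[w] = k; stack.push_back(w); }
        }
        if (t + 1 < T) {
          int w = v + L;
          if (mark[w] != k && stat[w] >= h) { mark[w] = k; stack.push_back(w); }
        }
      }
      double add = std::pow((double)members.size(), E) * hH;
      for (size_t q = 0; q < members.size(); ++q) out[members[q]] += add;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix tfce_enhance_cpp(NumericMatrix stat, List adj, double E,
                               double H, double dh) {
  int L = stat.nrow(), T = stat.ncol();
  AdjList ladj = build_adj(adj);
  double hmax = 0.0;
  for (int i = 0; i < L * T; ++i) hmax = std::max(hmax, stat[i]);
  NumericMatrix out(L, T);
  std::vector<int> mark(L * T), stack, members;
  tfce_pass(stat.begin(), L, T, ladj, E, H, dh, hmax, out.begin(), mark,
            stack, members);
  return out;
}

// Pooled two-sample |t| (or t^2) per grid sample; data is n x (L*T)
// column-major, grp01 a 0/1 assignment. Writes into stat (length L*T).
static void tmap(const double *data, int nsub, int S, const int *grp01,
                 bool useF, double *stat) {
  int n0 = 0, n1 = 0;
  for (int i = 0; i < nsub; ++i) (grp01[i] ? n1 : n0)++;
  double inv = 1.0 / n0 + 1.0 / n1;
  for (int s = 0; s < S; ++s) {
    const double *col = data + (size_t)s * nsub;
    double s0 = 0, s1 = 0, q0 = 0, q1 = 0;
    for (int i = 0; i < nsub; ++i) {
      double v = col[i];
      if (grp01[i]) { s1 += v; q1 += v * v; } else { s0 += v; q0 += v * v; }
    }
    double m0 = s0 / n0, m1 = s1 / n1;
    double ss = (q0 - n0 * m0 * m0) + (q1 - n1 * m1 * m1);
    double sp2 = ss / (n0 + n1 - 2);
    double t = 0.0;
    if (sp2 > 0) t = (m0 - m1) / std::sqrt(sp2 * inv);
    stat[s] = useF ? t * t : std::fabs(t);
  }
}

// [[Rcpp::export]]
List tfce_perm_cpp(NumericMatrix data, IntegerVector grp,
                   IntegerMatrix perm_grp, List adj, int L, int T,
                   double E, double H, double dh, bool useF) {
  int nsub = data.nrow();
  int S = L * T;
  if (data.ncol() != S) stop("data has wrong number of samples");
  AdjList ladj = build_adj(adj);
  std::vector<double> stat(S), enh(S);
  std::vector<int> mark(S), stack, members, g(nsub);

  for (int i = 0; i < nsub; ++i) g[i] = grp[i];
  tmap(data.begin(), nsub, S, g.data(), useF, stat.data());
  double hmax_obs = 0.0;
  for (int s = 0; s < S; ++s) hmax_obs = std::max(hmax_obs, stat[s]);
  double step = dh > 0 ? dh : hmax_obs / 50.0;

  NumericMatrix obs_stat(L, T), obs_tfce(L, T);
  std::copy(stat.begin(), stat.end(), obs_stat.begin());
  tfce_pass(stat.data(), L, T, ladj, E, H, step, hmax_obs, enh.data(), mark,
            stack, members);
  std::copy(enh.begin(), enh.end(), obs_tfce.begin());

  int nperm = perm_grp.nrow();
  std::vector<int> exceed(S, 0);
  NumericVector max_null(nperm);
  for (int p = 0; p < nperm; ++p) {
    for (int i = 0; i < nsub; ++i) g[i] = perm_grp(p, i);
    tmap(data.begin(), nsub, S, g.data(), useF, stat.data());
    double hmax = 0.0;
    for (int s = 0; s < S; ++s) hmax = std::max(hmax, stat[s]);
    tfce_pass(stat.data(), L, T, ladj, E, H, step, hmax, enh.data(), mark,
              stack, members);
    double mx = 0.0;
    for (int s = 0; s < S; ++s) mx = std::max(mx, enh[s]);
    max_null[p] = mx;
    for (int s = 0; s < S; ++s)
      if (mx >= obs_tfce[s]) exceed[s]++;
    Rcpp::checkUserInterrupt();
  }
  NumericMatrix pmat(L, T);
  for (int s = 0; s < S; ++s)
    pmat[s] = (1.0 + exceed[s]) / (nperm + 1.0);
  return List::create(_["stat"] = obs_stat, _["tfce"] = obs_tfce,
                      _["p"] = pmat, _["max_null"] = max_null,
                      _["dh"] = step);
}
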
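#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Spatiotemporal connected components of supra-threshold points.
// Points (channel c, time t) and (c', t) are linked iff c' is a
// neighbouring channel; (c, t) and (c, t +/- 1) are linked along time.
// Positive and negative supra-threshold points never merge.

static void flood(const double* t, int nch, int nt,
                  const std::vector< std::vector<int> >& nb,
                  double thr, int sign, std::vector<int>& label,
                  int start, int id) {
  std::vector<int> stack;
  stack.push_back(start);
  label[start] = id;
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    int c = p % nch, tt = p / nch;
    // temporal neighbours
    for (int dt = -1; dt <= 1; dt += 2) {
      int t2 = tt + dt;
      if (t2 < 0 || t2 >= nt) continue;
      int q = c + nch * t2;
      if (label[q] == 0 && sign * t[q] > thr) {
        label[q] = id; stack.push_back(q);
      }
    }
    // spatial neighbours at the same sample
    const std::vector<int>& nbc = nb[c];
    for (size_t j = 0; j < nbc.size(); ++j) {
      int q = nbc[j] + nch * tt;
      if (label[q] == 0 && sign * t[q] > thr) {
        label[q] = id; stack.push_back(q);
      }
    }
  }
}

static std::vector< std::vector<int> > adj_to_nb(const LogicalMatrix& adj) {
  int nch = adj.nrow();
  std::vector< std::vector<int> > nb(nch);
  for (int i = 0; i < nch; ++i)
    for (int j = 0; j < nch; ++j)
      if (adj(i, j)) nb[i].push_back(j);
  return nb;
}

// Label clusters of one polarity (sign = +1 or -1) in a channels x time
// t map. Returns an integer matrix of cluster ids (0 = sub-threshold).
// [[Rcpp::export]]
IntegerMatrix cluster_label_cpp(NumericMatrix tmat, LogicalMatrix adj,
                                double thr, int sign) {
  int nch = tmat.nrow(), nt = tmat.ncol();
  std::vector< std::vector<int> > nb = adj_to_nb(adj);
  std::vector<int> label(nch * nt, 0);
  const double* t = REAL(tmat);
  int id = 0;
  for (int p = 0; p < nch * nt; ++p) {
    if (label[p] == 0 && sign * t[p] > thr) {
      ++id;
      flood(t, nch, nt, nb, thr, sign, label, p, id);
    }
  }
  IntegerMatrix out(nch, nt);
  for (int p = 0; p < nch * nt; ++p) out[p] = label[p];
  return out;
}

// Maximum positive and most extreme negative cluster mass for each of S
// permutation t maps (columns of tmats, each a flattened nch x nt map,
// so tmats is (nch*nt) x S). Column 1 of the result: max positive-
// cluster mass (0 when none); column 2: minimum negative-cluster mass.
// [[Rcpp::export]]
NumericMatrix perm_max_mass_cpp(NumericMatrix tmats, int nch, int nt,
                                LogicalMatrix adj, double thr) {
  int S = tmats.ncol();
  int P = nch * nt;
  if (tmats.nrow() != P) stop("tmats must be (nch*nt) x S");
  std::vector< std::vector<int> > nb = adj_to_nb(adj);
  NumericMatrix out(S, 2);
  std::vector<double> t(P);
  std::vector<int> label(P);
  const double* base = REAL(tmats);
  for (int s = 0; s < S; ++s) {
    std::copy(base + (size_t)s * P, base + (size_t)(s + 1) * P, t.begin());
    for (int signv = 0; signv < 2; ++signv) {
      int sign = signv == 0 ? 1 : -1;
      std::fill(label.begin(), label.end(), 0);
      int id = 0;
      std::vector<double> mass;
      for (int p = 0; p < P; ++p) {
        if (label[p] == 0 && sign * t[p] > thr) {
          ++id;
          flood(t.data(), nch, nt, nb, thr, sign, label, p, id);
          mass.push_back(0.0);
        }
      }
      for (int p = 0; p < P; ++p)
        if (label[p] > 0) mass[label[p] - 1] += t[p];
      double best = 0.0;
      for (size_t k = 0; k < mass.size(); ++k) {
        if (sign > 0) { if (mass[k] > best) best = mass[k]; }
        else          { if (mass[k] < best) best = mass[k]; }
      }
      out(s, signv) = best;
    }
  }
  return out;
}
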
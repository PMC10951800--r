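#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Coordinates are handled internally as 0-based column-major offsets; the R
// layer converts to 1-based array indices. Lexicographic tie-breaking ranks
// voxels row-major, i.e. the first array axis is the most significant.

static void decode_coords(int l, const std::vector<int> &d, int nd, int *out) {
  for (int k = 0; k < nd; ++k) {
    out[k] = l % d[k];
    l /= d[k];
  }
}

static long long fold_lex(const int *coords, const std::vector<int> &d, int nd) {
  long long r = 0;
  for (int k = 0; k < nd; ++k) r = r * d[k] + coords[k];
  return r;
}

static std::vector<std::vector<int> > make_offsets(int nd, bool full) {
  std::vector<std::vector<int> > offsets;
  std::vector<int> cur(nd, -1);
  for (;;) {
    bool all_zero = true;
    int nonzero = 0;
    for (int k = 0; k < nd; ++k) {
      if (cur[k] != 0) { all_zero = false; ++nonzero; }
    }
    if (!all_zero && (full || nonzero == 1)) offsets.push_back(cur);
    int k = 0;
    while (k < nd && cur[k] == 1) { cur[k] = -1; ++k; }
    if (k == nd) break;
    ++cur[k];
  }
  return offsets;
}

struct UnionFind {
  std::vector<int> parent, rank_;
  UnionFind(int n) : parent(n, -1), rank_(n, 0) {}
  int find(int a) {
    int r = a;
    while (parent[r] != r) r = parent[r];
    while (parent[a] != r) { int nxt = parent[a]; parent[a] = r; a = nxt; }
    return r;
  }
};

// Total order of voxels: decreasing intensity, ties by lexicographic
// (row-major) coordinate. Returns 1-based linear indices.
// [[Rcpp::export]]
IntegerVector cpp_filtration_order(NumericVector x, IntegerVector dims) {
  int n = x.size();
  int nd = dims.size();
  std::vector<int> d(dims.begin(), dims.end());
  std::vector<long long> lex(n);
  int coords[8];
  for (int i = 0; i < n; ++i) {
    decode_coords(i, d, nd, coords);
    lex[i] = fold_lex(coords, d, nd);
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] > x[b];
    return lex[a] < lex[b];
  });
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = idx[i] + 1;
  return out;
}

// Persistence sweep over the superlevel-set filtration of an n-D image.
// Voxels are visited in decreasing intensity; a voxel with no assigned
// neighbour seeds a component (a local maximum becomes its root); otherwise
// it may attach to the brightest-rooted neighbouring component when the gap
// to that root is at most tau, triggering root-gap-gated merges of the other
// neighbouring components. Components whose root is dimmer than tau are
// discarded as background. Labels are 1..K by decreasing root intensity.
// [[Rcpp::export]]
List cpp_segment(NumericVector x, IntegerVector dims, double tau, bool full_conn) {
  int n = x.size();
  int nd = dims.size();
  if (nd < 1 || nd > 6) stop("unsupported array dimensionality");
  std::vector<int> d(dims.begin(), dims.end());
  std::vector<double> xv(x.begin(), x.end());
  const double *xp = xv.data();
  std::vector<long long> lex(n);
  int coords[8];
  for (int i = 0; i < n; ++i) {
    decode_coords(i, d, nd, coords);
    lex[i] = fold_lex(coords, d, nd);
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (xp[a] != xp[b]) return xp[a] > xp[b];
    return lex[a] < lex[b];
  });

  std::vector<std::vector<int> > offsets = make_offsets(nd, full_conn);
  int noff = offsets.size();
  // flattened per-offset coordinate deltas and linear deltas
  std::vector<int> odelta(noff * nd);
  std::vector<int> olin(noff);
  for (int o = 0; o < noff; ++o) {
    int lin = 0, stride = 1;
    for (int k = 0; k < nd; ++k) {
      odelta[o * nd + k] = offsets[o][k];
      lin += offsets[o][k] * stride;
      stride *= d[k];
    }
    olin[o] = lin;
  }

  UnionFind uf(n);
  // root metadata lives at the set representative
  std::vector<double> rootI(n, 0.0);
  std::vector<long long> rootLex(n, 0);
  std::vector<int> rootIdx(n, -1);
  std::vector<char> assigned(n, 0);
  std::vector<int> setOf(n, -1); // initial set link per voxel

  std::vector<int> nbr_reps;
  nbr_reps.reserve(32);

  for (int step = 0; step < n; ++step) {
    int v = order[step];
    double Iv = xp[v];
    decode_coords(v, d, nd, coords);
    bool interior = true;
    for (int k = 0; k < nd; ++k)
      if (coords[k] == 0 || coords[k] == d[k] - 1) { interior = false; break; }
    nbr_reps.clear();
    for (int o = 0; o < noff; ++o) {
      if (!interior) {
        bool ok = true;
        for (int k = 0; k < nd; ++k) {
          int c = coords[k] + odelta[o * nd + k];
          if (c < 0 || c >= d[k]) { ok = false; break; }
        }
        if (!ok) continue;
      }
      int u = v + olin[o];
      if (!assigned[u]) continue;
      int rep = uf.find(setOf[u]);
      bool seen = false;
      for (size_t j = 0; j < nbr_reps.size(); ++j)
        if (nbr_reps[j] == rep) { seen = true; break; }
      if (!seen) nbr_reps.push_back(rep);
    }

    if (nbr_reps.empty()) {
      // local maximum in sweep order: seed a new component rooted at v
      uf.parent[v] = v;
      setOf[v] = v;
      rootI[v] = Iv;
      rootLex[v] = lex[v];
      rootIdx[v] = v;
      assigned[v] = 1;
      continue;
    }

    // brightest-rooted neighbouring component, ties to lex-smaller root
    int cstar = nbr_reps[0];
    for (size_t j = 1; j < nbr_reps.size(); ++j) {
      int c = nbr_reps[j];
      if (rootI[c] > rootI[cstar] ||
          (rootI[c] == rootI[cstar] && rootLex[c] < rootLex[cstar]))
        cstar = c;
    }

    if (rootI[cstar] - Iv <= tau) {
      setOf[v] = cstar;
      assigned[v] = 1;
      for (size_t j = 0; j < nbr_reps.size(); ++j) {
        int c = nbr_reps[j];
        if (c == cstar) continue;
        if (std::fabs(rootI[cstar] - rootI[c]) <= tau) {
          // union by rank, keeping cstar's root metadata
          int a = uf.find(cstar), b = uf.find(c);
          if (a == b) continue;
          double ri = rootI[a]; long long rl = rootLex[a]; int rx = rootIdx[a];
          int winner;
          if (uf.rank_[a] < uf.rank_[b]) { uf.parent[a] = b; winner = b; }
          else if (uf.rank_[a] > uf.rank_[b]) { uf.parent[b] = a; winner = a; }
          else { uf.parent[b] = a; ++uf.rank_[a]; winner = a; }
          rootI[winner] = ri; rootLex[winner] = rl; rootIdx[winner] = rx;
          cstar = winner;
        }
      }
    }
    // else: v stays background; no merge occurs at v
  }

  // collect surviving components (root intensity >= tau)
  std::vector<int> repOf(n, 0);
  std::vector<int> reps;
  std::vector<int> compOf(n, -1); // rep voxel -> compact id
  for (int i = 0; i < n; ++i) {
    if (!assigned[i]) continue;
    int rep = uf.find(setOf[i]);
    repOf[i] = rep;
    if (compOf[rep] == -1 && rootI[rep] >= tau) {
      compOf[rep] = 0; // mark
      reps.push_back(rep);
    }
  }
  std::sort(reps.begin(), reps.end(), [&](int a, int b) {
    if (rootI[a] != rootI[b]) return rootI[a] > rootI[b];
    return rootLex[a] < rootLex[b];
  });
  int K = reps.size();
  for (int k = 0; k < K; ++k) compOf[reps[k]] = k + 1;

  IntegerVector labels(n, 0);
  IntegerVector size(K, 0);
  for (int i = 0; i < n; ++i) {
    if (!assigned[i]) continue;
    int rep = repOf[i];
    if (rootI[rep] < tau) continue;
    int id = compOf[rep];
    labels[i] = id;
    ++size[id - 1];
  }
  IntegerVector root_index(K);
  NumericVector root_intensity(K);
  for (int k = 0; k < K; ++k) {
    root_index[k] = rootIdx[reps[k]] + 1;
    root_intensity[k] = rootI[reps[k]];
  }
  return List::create(_["labels"] = labels,
                      _["root_index"] = root_index,
                      _["root_intensity"] = root_intensity,
                      _["size"] = size);
}

static void blur_axis(std::vector<double> &src, std::vector<double> &dst,
                      const std::vector<int> &d, int axis, double sigma) {
  int nd = d.size();
  int len = d[axis];
  int n = src.size();
  int radius = (int)std::ceil(4.0 * sigma);
  if (radius < 1) radius = 1;
  std::vector<double> w(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    w[i + radius] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += w[i + radius];
  }
  for (size_t i = 0; i < w.size(); ++i) w[i] /= s;

  int stride = 1;
  for (int k = 0; k < axis; ++k) stride *= d[k];
  int block = stride * len;
  int nouter = n / block;
  for (int outer = 0; outer < nouter; ++outer) {
    for (int inner = 0; inner < stride; ++inner) {
      int base = outer * block + inner;
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int jj = -radius; jj <= radius; ++jj) {
          int j = i + jj;
          // symmetric (mirror) boundary: ...2 1 0 | 0 1 2...
          while (j < 0 || j >= len) {
            if (j < 0) j = -j - 1;
            if (j >= len) j = 2 * len - j - 1;
          }
          acc += w[jj + radius] * src[base + j * stride];
        }
        dst[base + i * stride] = acc;
      }
    }
  }
  (void)nd;
}

// Separable Gaussian smoothing with mirror boundary; sigmas is per-axis
// (0 skips the axis, so videos can be smoothed laterally only).
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector x, IntegerVector dims,
                                NumericVector sigmas) {
  std::vector<int> d(dims.begin(), dims.end());
  std::vector<double> a(x.begin(), x.end());
  std::vector<double> b(a.size());
  for (int axis = 0; axis < (int)d.size(); ++axis) {
    double s = sigmas[axis];
    if (s > 0) {
      blur_axis(a, b, d, axis, s);
      a.swap(b);
    }
  }
  NumericVector out(a.begin(), a.end());
  return out;
}

// Binary dilation by an axis-aligned box of half-widths hw (separable
// running OR); used to build the windowed evaluation domain.
// [[Rcpp::export]]
LogicalVector cpp_box_dilate(LogicalVector mask, IntegerVector dims,
                             IntegerVector hw) {
  std::vector<int> d(dims.begin(), dims.end());
  int n = mask.size();
  std::vector<char> a(n), b(n);
  for (int i = 0; i < n; ++i) a[i] = mask[i] ? 1 : 0;
  for (int axis = 0; axis < (int)d.size(); ++axis) {
    int w = hw[axis];
    if (w <= 0) continue;
    int len = d[axis];
    int stride = 1;
    for (int k = 0; k < axis; ++k) stride *= d[k];
    int block = stride * len;
    int nouter = n / block;
    std::vector<int> pre(len + 1);
    for (int outer = 0; outer < nouter; ++outer) {
      for (int inner = 0; inner < stride; ++inner) {
        int base = outer * block + inner;
        pre[0] = 0;
        for (int i = 0; i < len; ++i)
          pre[i + 1] = pre[i] + (a[base + i * stride] ? 1 : 0);
        for (int i = 0; i < len; ++i) {
          int lo = i - w; if (lo < 0) lo = 0;
          int hi = i + w; if (hi > len - 1) hi = len - 1;
          b[base + i * stride] = (pre[hi + 1] - pre[lo]) > 0;
        }
      }
    }
    a.swap(b);
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = a[i] != 0;
  return out;
}
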
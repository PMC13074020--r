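// Double-precision margin evaluation and exact Shapley attributions for
// gradient-boosted tree ensembles (the polynomial-time path algorithm).
// Split routing replicates the learner's float32 comparisons so leaf
// membership is bit-compatible; accumulation is done in doubles so the
// additive decomposition base + sum(phi) reproduces the margin to
// near machine precision.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Tree {
  std::vector<int> feat, yes, no, miss;
  std::vector<double> split, value, cover;
};

static std::vector<Tree> convertTrees(const List& trees) {
  std::vector<Tree> out(trees.size());
  for (R_xlen_t t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    out[t].feat  = as<std::vector<int> >(tr["feature"]);
    out[t].yes   = as<std::vector<int> >(tr["yes"]);
    out[t].no    = as<std::vector<int> >(tr["no"]);
    out[t].miss  = as<std::vector<int> >(tr["missing"]);
    out[t].split = as<std::vector<double> >(tr["split"]);
    out[t].value = as<std::vector<double> >(tr["value"]);
    out[t].cover = as<std::vector<double> >(tr["cover"]);
  }
  return out;
}

// next node under the learner's routing rule: missing -> default child,
// otherwise float32 comparison x < split
static inline int route(const Tree& tr, int node, double x) {
  if (ISNAN(x)) return tr.miss[node];
  return ((float)x < (float)tr.split[node]) ? tr.yes[node] : tr.no[node];
}

// [[Rcpp::export]]
NumericVector treeMarginsCpp(List trees, NumericMatrix X, double base) {
  std::vector<Tree> T = convertTrees(trees);
  int n = X.nrow();
  NumericVector out(n, base);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (size_t t = 0; t < T.size(); ++t) {
      const Tree& tr = T[t];
      int node = 0;
      while (tr.feat[node] >= 0)
        node = route(tr, node, X(i, tr.feat[node]));
      s += tr.value[node];
    }
    out[i] += s;
  }
  return out;
}

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extendPath(PathElement* path, unsigned depth, double pz,
                       double po, int pi) {
  path[depth].feature_index = pi;
  path[depth].zero_fraction = pz;
  path[depth].one_fraction = po;
  path[depth].pweight = (depth == 0 ? 1.0 : 0.0);
  for (int i = depth - 1; i >= 0; --i) {
    path[i + 1].pweight += po * path[i].pweight * (i + 1) /
      static_cast<double>(depth + 1);
    path[i].pweight = pz * path[i].pweight * (depth - i) /
      static_cast<double>(depth + 1);
  }
}

static void unwindPath(PathElement* path, unsigned depth, unsigned index) {
  const double po = path[index].one_fraction;
  const double pz = path[index].zero_fraction;
  double next_one = path[depth].pweight;
  for (int i = depth - 1; i >= 0; --i) {
    if (po != 0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one * (depth + 1) /
        static_cast<double>((i + 1) * po);
      next_one = tmp - path[i].pweight * pz * (depth - i) /
        static_cast<double>(depth + 1);
    } else {
      path[i].pweight = (path[i].pweight * (depth + 1)) /
        static_cast<double>(pz * (depth - i));
    }
  }
  for (unsigned i = index; i < depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

static double unwoundPathSum(const PathElement* path, unsigned depth,
                             unsigned index) {
  const double po = path[index].one_fraction;
  const double pz = path[index].zero_fraction;
  double next_one = path[depth].pweight;
  double total = 0;
  if (po != 0) {
    for (int i = depth - 1; i >= 0; --i) {
      const double tmp = next_one / static_cast<double>((i + 1) * po);
      total += tmp;
      next_one = path[i].pweight - tmp * pz * (depth - i);
    }
  } else {
    for (int i = depth - 1; i >= 0; --i)
      total += path[i].pweight / (pz * (depth - i));
  }
  return total * (depth + 1);
}

static void shapRecurse(const Tree& tr, const NumericMatrix& X, int row,
                        double* phi, int node, unsigned depth,
                        PathElement* parent_path, double pz, double po,
                        int pi) {
  PathElement* path = parent_path + depth + 1;
  std::copy(parent_path, parent_path + depth + 1, path);
  extendPath(path, depth, pz, po, pi);

  if (tr.feat[node] < 0) {                 // leaf
    for (unsigned i = 1; i <= depth; ++i) {
      const double w = unwoundPathSum(path, depth, i);
      const PathElement& el = path[i];
      phi[el.feature_index] += w * (el.one_fraction - el.zero_fraction) *
        tr.value[node];
    }
    return;
  }
  const int f = tr.feat[node];
  const int hot = route(tr, node, X(row, f));
  const int cold = (hot == tr.yes[node]) ? tr.no[node] : tr.yes[node];
  const double w = tr.cover[node];
  const double hot_zero = tr.cover[hot] / w;
  const double cold_zero = tr.cover[cold] / w;
  double iz = 1.0, io = 1.0;

  unsigned index = 0;
  for (; index <= depth; ++index)
    if (path[index].feature_index == f) break;
  if (index != depth + 1) {
    iz = path[index].zero_fraction;
    io = path[index].one_fraction;
    unwindPath(path, depth, index);
    depth -= 1;
  }
  shapRecurse(tr, X, row, phi, hot, depth + 1, path, hot_zero * iz, io, f);
  shapRecurse(tr, X, row, phi, cold, depth + 1, path, cold_zero * iz, 0, f);
}

static unsigned treeDepth(const Tree& tr, int node) {
  if (tr.feat[node] < 0) return 1;
  unsigned l = treeDepth(tr, tr.yes[node]);
  unsigned r = treeDepth(tr, tr.no[node]);
  return 1 + (l > r ? l : r);
}

// [[Rcpp::export]]
NumericMatrix treeShapCpp(List trees, NumericMatrix X, double base) {
  std::vector<Tree> T = convertTrees(trees);
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix phi(n, p + 1);

  double bias = base;
  unsigned maxd = 0;
  for (size_t t = 0; t < T.size(); ++t) {
    const Tree& tr = T[t];
    double ev = 0, cv = 0;
    for (size_t j = 0; j < tr.feat.size(); ++j) {
      if (tr.feat[j] < 0) { ev += tr.value[j] * tr.cover[j]; cv += tr.cover[j]; }
    }
    bias += ev / cv;
    unsigned d = treeDepth(tr, 0);
    if (d > maxd) maxd = d;
  }
  std::vector<PathElement> scratch((maxd + 2) * (maxd + 3) / 2);
  std::vector<double> rowphi(p);

  for (int i = 0; i < n; ++i) {
    std::fill(rowphi.begin(), rowphi.end(), 0.0);
    for (size_t t = 0; t < T.size(); ++t) {
      const Tree& tr = T[t];
      if (tr.feat[0] < 0) continue;        // single-leaf tree: all in bias
      shapRecurse(tr, X, i, rowphi.data(), 0, 0, scratch.data(), 1, 1, -1);
    }
    for (int j = 0; j < p; ++j) phi(i, j) = rowphi[j];
    phi(i, p) = bias;
  }
  return phi;
}
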
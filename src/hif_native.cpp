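#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

// Label connected components of a binary mask (connectivity 8 or 4).
// Returns an integer matrix; labels are provisional (insertion order),
// relabelling by component size happens on the R side.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(c * nr + r);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            if (connectivity == 4 && dr != 0 && dc != 0) continue;
            int r2 = cr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(r2, c2) && lab(r2, c2) == 0) {
              lab(r2, c2) = next;
              stack.push_back(c2 * nr + r2);
            }
          }
        }
      }
    }
  }
  return lab;
}

namespace {

struct PointGrid {
  double cell;
  std::unordered_map<int64_t, std::vector<int>> buckets;
  const NumericVector &px, &py;
  PointGrid(const NumericVector &x, const NumericVector &y, double cell_size)
      : cell(cell_size), px(x), py(y) {
    for (int i = 0; i < x.size(); ++i) buckets[key(x[i], y[i])].push_back(i);
  }
  int64_t key(double x, double y) const {
    int64_t gx = (int64_t)std::floor(x / cell);
    int64_t gy = (int64_t)std::floor(y / cell);
    return gx * 2000003LL + gy;
  }
  // true if any stored point lies within radius r of (x, y)
  bool has_within(double x, double y, double r) const {
    const double r2 = r * r;
    int64_t gx = (int64_t)std::floor(x / cell);
    int64_t gy = (int64_t)std::floor(y / cell);
    int span = (int)std::ceil(r / cell);
    for (int64_t ix = gx - span; ix <= gx + span; ++ix) {
      for (int64_t iy = gy - span; iy <= gy + span; ++iy) {
        auto it = buckets.find(ix * 2000003LL + iy);
        if (it == buckets.end()) continue;
        for (int j : it->second) {
          double dx = px[j] - x, dy = py[j] - y;
          if (dx * dx + dy * dy <= r2) return true;
        }
      }
    }
    return false;
  }
};

} // namespace

// For each query point, whether any reference point lies within radius r
// (Euclidean, same units as the coordinates).
// [[Rcpp::export]]
LogicalVector cpp_has_neighbor(NumericVector qx, NumericVector qy,
                               NumericVector px, NumericVector py, double r) {
  LogicalVector out(qx.size());
  if (px.size() == 0) return out;
  PointGrid grid(px, py, std::max(r, 1e-9));
  for (int i = 0; i < qx.size(); ++i) out[i] = grid.has_within(qx[i], qy[i], r);
  return out;
}

// Nearest reference index (1-based) and distance per query point; brute force,
// intended for modest numbers of reference centers (cluster exemplars,
// interface samples).
// [[Rcpp::export]]
List cpp_nearest_index(NumericVector qx, NumericVector qy,
                       NumericVector cx, NumericVector cy) {
  const int nq = qx.size(), k = cx.size();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    int bj = NA_INTEGER;
    for (int j = 0; j < k; ++j) {
      double dx = qx[i] - cx[j], dy = qy[i] - cy[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; bj = j + 1; }
    }
    idx[i] = bj;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// ----------------------------------------------------------------------------
// Birch clustering feature (CF) tree.
//
// Incremental construction with a subcluster radius threshold and a node
// branching factor; no global reclustering step, so the leaf subclusters are
// the final clusters and their centroids are the exemplars. Points are
// inserted in input order, which makes the tree deterministic for a fixed
// point sequence.
// ----------------------------------------------------------------------------

namespace {

struct CF {
  double n = 0, lx = 0, ly = 0, ss = 0; // count, linear sums, sum of squares
  void add(double x, double y) { n += 1; lx += x; ly += y; ss += x * x + y * y; }
  void merge(const CF &o) { n += o.n; lx += o.lx; ly += o.ly; ss += o.ss; }
  double cx() const { return lx / n; }
  double cy() const { return ly / n; }
  // root-mean-square distance of members to the subcluster centroid
  double radius() const {
    double v = ss / n - (cx() * cx() + cy() * cy());
    return v > 0 ? std::sqrt(v) : 0.0;
  }
  double dist2(double x, double y) const {
    double dx = cx() - x, dy = cy() - y;
    return dx * dx + dy * dy;
  }
};

struct BirchNode {
  bool leaf = true;
  std::vector<CF> cfs;
  std::vector<int> child; // child node ids, parallel to cfs (internal only)
};

struct BirchTree {
  double threshold;
  int branching;
  std::vector<BirchNode> nodes;
  int root;

  BirchTree(double thr, int b) : threshold(thr), branching(b) {
    nodes.emplace_back();
    root = 0;
  }

  int nearest_entry(const BirchNode &nd, double x, double y) const {
    int best = -1;
    double bd = R_PosInf;
    for (size_t i = 0; i < nd.cfs.size(); ++i) {
      double d = nd.cfs[i].dist2(x, y);
      if (d < bd) { bd = d; best = (int)i; }
    }
    return best;
  }

  // split entries of node id into two nodes seeded by the farthest pair;
  // returns the id of the new sibling, and the two summary CFs
  int split(int id, CF &cf_keep, CF &cf_new) {
    BirchNode &nd = nodes[id];
    size_t m = nd.cfs.size();
    size_t s1 = 0, s2 = 1;
    double far = -1;
    for (size_t i = 0; i < m; ++i)
      for (size_t j = i + 1; j < m; ++j) {
        double d = nd.cfs[i].dist2(nd.cfs[j].cx(), nd.cfs[j].cy());
        if (d > far) { far = d; s1 = i; s2 = j; }
      }
    BirchNode keep, fresh;
    keep.leaf = fresh.leaf = nd.leaf;
    cf_keep = CF(); cf_new = CF();
    for (size_t i = 0; i < m; ++i) {
      double d1 = nd.cfs[s1].dist2(nd.cfs[i].cx(), nd.cfs[i].cy());
      double d2 = nd.cfs[s2].dist2(nd.cfs[i].cx(), nd.cfs[i].cy());
      bool to_keep = (i == s1) || (i != s2 && d1 <= d2);
      if (to_keep) {
        keep.cfs.push_back(nd.cfs[i]);
        if (!nd.leaf) keep.child.push_back(nd.child[i]);
        cf_keep.merge(nd.cfs[i]);
      } else {
        fresh.cfs.push_back(nd.cfs[i]);
        if (!nd.leaf) fresh.child.push_back(nd.child[i]);
        cf_new.merge(nd.cfs[i]);
      }
    }
    nodes[id] = keep;
    nodes.push_back(fresh);
    return (int)nodes.size() - 1;
  }

  // insert into subtree rooted at id; returns true if the node split,
  // in which case sibling/cf_keep/cf_new describe the split
  bool insert(int id, double x, double y, int &sibling, CF &cf_keep, CF &cf_new) {
    BirchNode &nd = nodes[id];
    if (nd.leaf) {
      if (nd.cfs.empty()) {
        CF e; e.add(x, y);
        nd.cfs.push_back(e);
        return false;
      }
      int j = nearest_entry(nd, x, y);
      CF merged = nd.cfs[j];
      merged.add(x, y);
      if (merged.radius() <= threshold) {
        nd.cfs[j] = merged;
        return false;
      }
      CF e; e.add(x, y);
      nd.cfs.push_back(e);
      if ((int)nd.cfs.size() <= branching) return false;
      sibling = split(id, cf_keep, cf_new);
      return true;
    }
    int j = nearest_entry(nd, x, y);
    int child_id = nd.child[j];
    int sib;
    CF ck, cn;
    bool child_split = insert(child_id, x, y, sib, ck, cn);
    BirchNode &nd2 = nodes[id]; // re-borrow: nodes may have reallocated
    if (!child_split) {
      nd2.cfs[j].add(x, y);
      return false;
    }
    nd2.cfs[j] = ck;
    nd2.cfs.insert(nd2.cfs.begin() + j + 1, cn);
    nd2.child.insert(nd2.child.begin() + j + 1, sib);
    if ((int)nd2.cfs.size() <= branching) return false;
    sibling = split(id, cf_keep, cf_new);
    return true;
  }

  void add_point(double x, double y) {
    int sib;
    CF ck, cn;
    if (insert(root, x, y, sib, ck, cn)) {
      BirchNode nr;
      nr.leaf = false;
      nr.cfs = {ck, cn};
      nr.child = {root, sib};
      nodes.push_back(nr);
      root = (int)nodes.size() - 1;
    }
  }

  void collect_leaves(int id, std::vector<CF> &out) const {
    const BirchNode &nd = nodes[id];
    if (nd.leaf) {
      for (const CF &e : nd.cfs) out.push_back(e);
    } else {
      for (int ch : nd.child) collect_leaves(ch, out);
    }
  }
};

} // namespace

// Sparse-group-lasso proximal operator: elementwise soft-threshold at `a`,
// then per-group shrinkage at b * sqrt(p_g). gidx is 1-based group index per
// feature, ngroups the number of groups.
// [[Rcpp::export]]
NumericVector cpp_sgl_prox(NumericVector v, IntegerVector gidx, int ngroups,
                           double a, double b) {
  const int p = v.size();
  NumericVector z(p);
  std::vector<double> norm2(ngroups, 0.0);
  std::vector<int> gsize(ngroups, 0);
  for (int j = 0; j < p; ++j) {
    double s = std::fabs(v[j]) - a;
    z[j] = s > 0 ? (v[j] > 0 ? s : -s) : 0.0;
    norm2[gidx[j] - 1] += z[j] * z[j];
    gsize[gidx[j] - 1] += 1;
  }
  std::vector<double> shrink(ngroups);
  for (int g = 0; g < ngroups; ++g) {
    double nrm = std::sqrt(norm2[g]);
    double f = nrm > 0 ? 1.0 - b * std::sqrt((double)gsize[g]) / nrm : 0.0;
    shrink[g] = f > 0 ? f : 0.0;
  }
  for (int j = 0; j < p; ++j) z[j] *= shrink[gidx[j] - 1];
  return z;
}

// Sparse-group-lasso penalty value.
// [[Rcpp::export]]
double cpp_sgl_penalty(NumericVector beta, IntegerVector gidx, int ngroups,
                       double lambda, double alpha) {
  std::vector<double> norm2(ngroups, 0.0);
  std::vector<int> gsize(ngroups, 0);
  double l1 = 0.0;
  for (int j = 0; j < beta.size(); ++j) {
    norm2[gidx[j] - 1] += beta[j] * beta[j];
    gsize[gidx[j] - 1] += 1;
    l1 += std::fabs(beta[j]);
  }
  double gsum = 0.0;
  for (int g = 0; g < ngroups; ++g)
    gsum += std::sqrt((double)gsize[g]) * std::sqrt(norm2[g]);
  return lambda * ((1.0 - alpha) * gsum + alpha * l1);
}

// Mean logistic deviance sum((1-y)*eta + log(1+exp(-eta)))/n, numerically
// stable for large |eta|.
// [[Rcpp::export]]
double cpp_logistic_dev(NumericVector eta, NumericVector y) {
  double s = 0.0;
  for (int i = 0; i < eta.size(); ++i) {
    double u = -eta[i];
    double l1e = u > 0 ? u + std::log1p(std::exp(-u)) : std::log1p(std::exp(u));
    s += (1.0 - y[i]) * eta[i] + l1e;
  }
  return s / eta.size();
}

// Birch CF-tree leaf subcluster exemplars (centroids) for a 2-D point set.
// [[Rcpp::export]]
NumericMatrix cpp_birch_exemplars(NumericVector x, NumericVector y,
                                  double threshold, int branching) {
  BirchTree tree(threshold, branching);
  for (int i = 0; i < x.size(); ++i) tree.add_point(x[i], y[i]);
  std::vector<CF> leaves;
  tree.collect_leaves(tree.root, leaves);
  NumericMatrix out(leaves.size(), 3);
  for (size_t i = 0; i < leaves.size(); ++i) {
    out(i, 0) = leaves[i].cx();
    out(i, 1) = leaves[i].cy();
    out(i, 2) = leaves[i].n;
  }
  colnames(out) = CharacterVector::create("x", "y", "n");
  return out;
}
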
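#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Static 3-d tree for nearest-neighbour correspondence search during ICP,
// Hausdorff distances and calcification capture queries.  Median split on
// the widest dimension; ties in distance resolve to the lowest point index
// so that pairings are deterministic and match a brute-force scan.

namespace {

struct Node {
  int left, right;    // child node ids, -1 if leaf
  int begin, end;     // index range into perm for leaves
  int axis;
  double split;
};

struct KdTree {
  const double *pts;  // column-major m x 3
  int m;
  std::vector<int> perm;
  std::vector<Node> nodes;

  double coord(int i, int ax) const { return pts[i + ax * (size_t)m]; }

  int build(int begin, int end) {
    Node nd;
    nd.begin = begin;
    nd.end = end;
    nd.left = nd.right = -1;
    nd.axis = 0;
    nd.split = 0.0;
    int id = (int)nodes.size();
    nodes.push_back(nd);
    if (end - begin <= 16) return id;

    double lo[3], hi[3];
    for (int ax = 0; ax < 3; ++ax) {
      lo[ax] = R_PosInf;
      hi[ax] = R_NegInf;
    }
    for (int k = begin; k < end; ++k) {
      for (int ax = 0; ax < 3; ++ax) {
        double v = coord(perm[k], ax);
        if (v < lo[ax]) lo[ax] = v;
        if (v > hi[ax]) hi[ax] = v;
      }
    }
    int axis = 0;
    double w = hi[0] - lo[0];
    for (int ax = 1; ax < 3; ++ax)
      if (hi[ax] - lo[ax] > w) { w = hi[ax] - lo[ax]; axis = ax; }
    if (w <= 0.0) return id;  // all points coincide; stay a leaf

    int mid = begin + (end - begin) / 2;
    const double *p = pts;
    int mm = m;
    std::nth_element(perm.begin() + begin, perm.begin() + mid,
                     perm.begin() + end, [p, mm, axis](int a, int b) {
                       return p[a + axis * (size_t)mm] <
                              p[b + axis * (size_t)mm];
                     });
    double split = coord(perm[mid], axis);
    int l = build(begin, mid);
    int r = build(mid, end);
    nodes[id].axis = axis;
    nodes[id].split = split;
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

  // k best neighbours of q, kept sorted by (distance, index)
  void search(int nid, const double *q, int k, std::vector<double> &bd,
              std::vector<int> &bi) const {
    const Node &nd = nodes[nid];
    if (nd.left < 0) {
      for (int t = nd.begin; t < nd.end; ++t) {
        int i = perm[t];
        double dx = coord(i, 0) - q[0];
        double dy = coord(i, 1) - q[1];
        double dz = coord(i, 2) - q[2];
        double d2 = dx * dx + dy * dy + dz * dz;
        int nb = (int)bd.size();
        if (nb == k && (d2 > bd[nb - 1] ||
                        (d2 == bd[nb - 1] && i + 1 >= bi[nb - 1])))
          continue;
        int pos = nb;
        while (pos > 0 &&
               (d2 < bd[pos - 1] || (d2 == bd[pos - 1] && i + 1 < bi[pos - 1])))
          --pos;
        bd.insert(bd.begin() + pos, d2);
        bi.insert(bi.begin() + pos, i + 1);
        if ((int)bd.size() > k) { bd.pop_back(); bi.pop_back(); }
      }
      return;
    }
    double diff = q[nd.axis] - nd.split;
    int first = diff < 0.0 ? nd.left : nd.right;
    int second = diff < 0.0 ? nd.right : nd.left;
    search(first, q, k, bd, bi);
    if ((int)bd.size() < k || diff * diff <= bd.back())
      search(second, q, k, bd, bi);
  }
};

}  // namespace

// [[Rcpp::export(name = ".kd_nearest")]]
Rcpp::List kd_nearest(Rcpp::NumericMatrix data, Rcpp::NumericMatrix query,
                      int k = 1) {
  int m = data.nrow(), nq = query.nrow();
  if (m < 1) Rcpp::stop("empty reference cloud");
  if (data.ncol() != 3 || query.ncol() != 3)
    Rcpp::stop("point matrices must have 3 columns");
  if (k < 1 || k > m) Rcpp::stop("k out of range");

  KdTree tree;
  tree.pts = data.begin();
  tree.m = m;
  tree.perm.resize(m);
  for (int i = 0; i < m; ++i) tree.perm[i] = i;
  tree.nodes.reserve(2 * m / 8 + 8);
  tree.build(0, m);

  Rcpp::IntegerMatrix idx(nq, k);
  Rcpp::NumericMatrix dist(nq, k);
  std::vector<double> bd;
  std::vector<int> bi;
  for (int j = 0; j < nq; ++j) {
    double q[3] = {query(j, 0), query(j, 1), query(j, 2)};
    bd.clear();
    bi.clear();
    tree.search(0, q, k, bd, bi);
    for (int t = 0; t < k; ++t) {
      idx(j, t) = bi[t];
      dist(j, t) = std::sqrt(bd[t]);
    }
  }
  return Rcpp::List::create(Rcpp::Named("index") = idx,
                            Rcpp::Named("distance") = dist);
}
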
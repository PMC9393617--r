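// Geometry kernels: incremental 3D convex hull volume, locally-Delaunay
// greedy surface triangulation, and moving-least-squares smoothing.
#include <RcppArmadillo.h>
#include <map>
#include <array>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct Face {
  int a, b, c;
  double nx, ny, nz, d; // outward unit normal, plane offset (n.x = d)
  bool alive;
};

static inline void face_plane(const arma::mat& P, Face& f, const arma::rowvec& inside) {
  arma::rowvec u = P.row(f.b) - P.row(f.a);
  arma::rowvec v = P.row(f.c) - P.row(f.a);
  arma::rowvec n = arma::cross(u, v);
  double nn = arma::norm(n);
  if (nn < 1e-300) nn = 1e-300;
  n /= nn;
  double d = arma::dot(n, P.row(f.a));
  if (arma::dot(n, inside) - d > 0) { // flip so the interior point is below
    std::swap(f.b, f.c);
    n = -n; d = -d;
  }
  f.nx = n(0); f.ny = n(1); f.nz = n(2); f.d = d;
}

// Exact-on-vertices convex hull volume via randomized incremental insertion.
// Returns volume (0 for degenerate/coplanar input, with flag = 1).
// [[Rcpp::export]]
List cpp_convex_hull_volume(const arma::mat& P0) {
  int n = P0.n_rows;
  if (n < 4) return List::create(_["volume"] = 0.0, _["degenerate"] = true);
  arma::mat P = P0;
  double diag = arma::norm(arma::max(P, 0) - arma::min(P, 0));
  if (diag <= 0) return List::create(_["volume"] = 0.0, _["degenerate"] = true);
  double eps = 1e-10 * diag;

  // initial tetrahedron from extreme points
  arma::uword i0 = P.col(0).index_min(), i1 = P.col(0).index_max();
  if (arma::norm(P.row(i0) - P.row(i1)) < eps) {
    i0 = P.col(1).index_min(); i1 = P.col(1).index_max();
    if (arma::norm(P.row(i0) - P.row(i1)) < eps) {
      i0 = P.col(2).index_min(); i1 = P.col(2).index_max();
    }
  }
  arma::rowvec a = P.row(i0), b = P.row(i1);
  double best = -1; int i2 = -1;
  arma::rowvec ab = b - a; double abn = arma::norm(ab);
  for (int i = 0; i < n; ++i) {
    arma::rowvec d = arma::cross(P.row(i) - a, ab);
    double h = arma::norm(d) / abn;
    if (h > best) { best = h; i2 = i; }
  }
  if (best < eps) return List::create(_["volume"] = 0.0, _["degenerate"] = true);
  arma::rowvec nrm = arma::cross(ab, P.row(i2) - a);
  nrm /= arma::norm(nrm);
  best = -1; int i3 = -1;
  for (int i = 0; i < n; ++i) {
    double h = std::abs(arma::dot(nrm, P.row(i) - a));
    if (h > best) { best = h; i3 = i; }
  }
  if (best < eps) return List::create(_["volume"] = 0.0, _["degenerate"] = true);

  arma::rowvec inside = (P.row(i0) + P.row(i1) + P.row(i2) + P.row(i3)) / 4.0;
  std::vector<Face> faces;
  int v0 = i0, v1 = i1, v2 = i2, v3 = i3;
  int quads[4][3] = {{v0, v1, v2}, {v0, v1, v3}, {v0, v2, v3}, {v1, v2, v3}};
  for (auto& q : quads) {
    Face f{q[0], q[1], q[2], 0, 0, 0, 0, true};
    face_plane(P, f, inside);
    faces.push_back(f);
  }

  for (int i = 0; i < n; ++i) {
    if (i == v0 || i == v1 || i == v2 || i == v3) continue;
    // find faces visible from point i
    std::vector<int> vis;
    for (size_t k = 0; k < faces.size(); ++k) {
      if (!faces[k].alive) continue;
      const Face& f = faces[k];
      if (f.nx * P(i, 0) + f.ny * P(i, 1) + f.nz * P(i, 2) - f.d > eps) vis.push_back(k);
    }
    if (vis.empty()) continue;
    // horizon = edges of visible faces not shared with another visible face
    std::map<std::pair<int, int>, int> edge_cnt;
    for (int k : vis) {
      const Face& f = faces[k];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (auto& ed : e) {
        int lo = std::min(ed[0], ed[1]), hi = std::max(ed[0], ed[1]);
        edge_cnt[{lo, hi}]++;
      }
    }
    for (int k : vis) faces[k].alive = false;
    for (auto& kv : edge_cnt) {
      if (kv.second != 1) continue;
      Face f{kv.first.first, kv.first.second, i, 0, 0, 0, 0, true};
      face_plane(P, f, inside);
      faces.push_back(f);
    }
  }

  double vol = 0.0;
  for (const Face& f : faces) {
    if (!f.alive) continue;
    arma::rowvec pa = P.row(f.a) - inside, pb = P.row(f.b) - inside, pc = P.row(f.c) - inside;
    vol += arma::dot(pa, arma::cross(pb, pc)) / 6.0;
  }
  return List::create(_["volume"] = std::abs(vol), _["degenerate"] = false);
}

// Greedy surface triangulation: for each point, project its k nearest
// neighbors onto the local tangent plane (PCA), keep triangles incident to
// the point that satisfy the empty-circumcircle test among the neighbors,
// cap edge lengths, and retain triangles confirmed by at least `min_stars`
// of their three vertex stars.
// [[Rcpp::export]]
IntegerMatrix cpp_local_star_mesh(const arma::mat& P, const IntegerMatrix& knn,
                                  double max_edge, int min_stars = 2) {
  int n = P.n_rows, k = knn.ncol();
  double cap2 = max_edge * max_edge;
  std::map<std::array<int, 3>, int> cnt;
  arma::mat C(3, 3);

  for (int i = 0; i < n; ++i) {
    std::vector<int> nb;
    nb.reserve(k);
    for (int j = 0; j < k; ++j) {
      int id = knn(i, j) - 1;
      if (id >= 0 && id != i) nb.push_back(id);
    }
    int m = nb.size();
    if (m < 2) continue;
    // local tangent plane from the neighborhood covariance
    arma::mat Q(m + 1, 3);
    Q.row(0) = P.row(i);
    for (int j = 0; j < m; ++j) Q.row(j + 1) = P.row(nb[j]);
    arma::rowvec mu = arma::mean(Q, 0);
    Q.each_row() -= mu;
    C = Q.t() * Q;
    arma::vec eval; arma::mat evec;
    arma::eig_sym(eval, evec, C);
    arma::mat B = evec.cols(1, 2); // two largest eigenvectors
    arma::mat uv = Q * B;          // row 0 is point i
    double u0 = uv(0, 0), v0 = uv(0, 1);

    for (int a = 1; a <= m - 1; ++a) {
      for (int b = a + 1; b <= m; ++b) {
        double ua = uv(a, 0), va = uv(a, 1), ub = uv(b, 0), vb = uv(b, 1);
        double D = 2.0 * (u0 * (va - vb) + ua * (vb - v0) + ub * (v0 - va));
        if (std::abs(D) < 1e-12) continue;
        double s0 = u0 * u0 + v0 * v0, sa = ua * ua + va * va, sb = ub * ub + vb * vb;
        double cx = (s0 * (va - vb) + sa * (vb - v0) + sb * (v0 - va)) / D;
        double cy = (s0 * (ub - ua) + sa * (u0 - ub) + sb * (ua - u0)) / D;
        double r2 = (u0 - cx) * (u0 - cx) + (v0 - cy) * (v0 - cy);
        bool empty = true;
        for (int c = 1; c <= m; ++c) {
          if (c == a || c == b) continue;
          double dx = uv(c, 0) - cx, dy = uv(c, 1) - cy;
          if (dx * dx + dy * dy < r2 * (1.0 - 1e-9)) { empty = false; break; }
        }
        if (!empty) continue;
        int ia = nb[a - 1], ib = nb[b - 1];
        double e1 = arma::accu(arma::square(P.row(i) - P.row(ia)));
        double e2 = arma::accu(arma::square(P.row(i) - P.row(ib)));
        double e3 = arma::accu(arma::square(P.row(ia) - P.row(ib)));
        if (e1 > cap2 || e2 > cap2 || e3 > cap2) continue;
        std::array<int, 3> key{i, ia, ib};
        std::sort(key.begin(), key.end());
        cnt[key]++;
      }
    }
  }

  std::vector<std::array<int, 3>> keep;
  for (auto& kv : cnt) if (kv.second >= min_stars) keep.push_back(kv.first);
  IntegerMatrix out(keep.size(), 3);
  for (size_t r = 0; r < keep.size(); ++r) {
    out(r, 0) = keep[r][0] + 1; out(r, 1) = keep[r][1] + 1; out(r, 2) = keep[r][2] + 1;
  }
  return out;
}

// Moving-least-squares smoothing: each point is projected onto a bivariate
// polynomial surface of the given order fitted (Gaussian-weighted) to its
// radius neighborhood over the local PCA tangent plane. Neighborhoods too
// small for the polynomial fall back to the fitted plane; counted.
// A point whose neighborhood is not sheet-like is flagged when
// sqrt(lambda_min / lambda_mid) of the weighted covariance exceeds
// `max_thickness_ratio`: a flat blade has near-zero thickness relative to
// its width, a stem tube does not.
// [[Rcpp::export]]
List cpp_mls_smooth(const arma::mat& P, const IntegerMatrix& knn,
                    const arma::mat& knn_dist, double radius, int order,
                    double max_thickness_ratio = 0.0) {
  int n = P.n_rows, k = knn.ncol();
  int ncoef = (order + 1) * (order + 2) / 2;
  double h = radius / 2.0;
  arma::mat out = P;
  LogicalVector keep(n, true);
  int starved = 0;
  arma::mat C(3, 3);

  for (int i = 0; i < n; ++i) {
    std::vector<int> nb;
    std::vector<double> nd;
    for (int j = 0; j < k; ++j) {
      int id = knn(i, j) - 1;
      double d = knn_dist(i, j);
      if (id >= 0 && d <= radius) { nb.push_back(id); nd.push_back(d); }
    }
    int m = nb.size();
    if (m < 4) { starved++; continue; } // keep the original point
    arma::mat Q(m, 3);
    arma::vec w(m);
    for (int j = 0; j < m; ++j) {
      Q.row(j) = P.row(nb[j]);
      w(j) = std::exp(-(nd[j] * nd[j]) / (h * h));
    }
    arma::rowvec mu = (w.t() * Q) / arma::accu(w);
    arma::mat Qc = Q.each_row() - mu;
    C = Qc.t() * arma::diagmat(w) * Qc;
    arma::vec eval; arma::mat evec;
    arma::eig_sym(eval, evec, C);
    if (max_thickness_ratio > 0 && eval(1) > 0 &&
        std::sqrt(std::max(eval(0), 0.0) / eval(1)) > max_thickness_ratio) {
      keep[i] = false;
      continue;
    }
    arma::vec nrm = evec.col(0);
    arma::mat B = evec.cols(1, 2);
    arma::vec uu = Qc * B.col(0), vv = Qc * B.col(1);
    arma::vec ww = Qc * nrm;
    int ord = order;
    if (m < ncoef + 2) { ord = 1; starved++; }
    int nc = (ord + 1) * (ord + 2) / 2;
    arma::mat A(m, nc);
    double sc = (h > 0) ? h : 1.0;
    int col = 0;
    for (int tot = 0; tot <= ord; ++tot) {
      for (int pu = tot; pu >= 0; --pu) {
        int pv = tot - pu;
        for (int j = 0; j < m; ++j) {
          A(j, col) = std::pow(uu(j) / sc, pu) * std::pow(vv(j) / sc, pv);
        }
        col++;
      }
    }
    arma::mat Aw = A.each_col() % arma::sqrt(w);
    arma::vec bw = ww % arma::sqrt(w);
    arma::mat AtA = Aw.t() * Aw;
    AtA.diag() += 1e-10 * arma::trace(AtA) / nc;
    arma::vec coef;
    bool ok = arma::solve(coef, AtA, Aw.t() * bw, arma::solve_opts::no_approx);
    if (!ok) { starved++; continue; }
    // evaluate the surface at the point's own (u, v)
    arma::rowvec pc = P.row(i) - mu;
    double pu0 = arma::dot(pc, B.col(0)) / sc, pv0 = arma::dot(pc, B.col(1)) / sc;
    double f = 0; col = 0;
    for (int tot = 0; tot <= ord; ++tot) {
      for (int pu = tot; pu >= 0; --pu) {
        int pv = tot - pu;
        f += coef(col) * std::pow(pu0, pu) * std::pow(pv0, pv);
        col++;
      }
    }
    arma::rowvec proj = mu + (pu0 * sc) * B.col(0).t() + (pv0 * sc) * B.col(1).t() + f * nrm.t();
    out.row(i) = proj;
  }
  return List::create(_["points"] = out, _["starved"] = starved,
                      _["keep"] = keep);
}
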
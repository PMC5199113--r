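// Co-rotational linear-elastic tetrahedral FEM kernels.
//
// The solver models the head-and-neck body as a homogeneous isotropic
// linear-elastic continuum; per-element rotations are extracted by polar
// decomposition of the deformation gradient and the element stiffness is
// warped as R K R^T ("stiffness warping"), which keeps the formulation
// valid for large rotations at small strains.  Landmark constraints are
// zero-rest-length springs f = k (target - x) attached at barycentric
// points; the spring energy is exactly quadratic in the nodal
// displacements, so only the elastic part needs Newton iteration (done in
// R, see R/fem.R).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// 6x6 isotropic elasticity matrix (Voigt, engineering shear)
static arma::mat66 iso_D(double lambda, double mu) {
  arma::mat66 D(arma::fill::zeros);
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) D(i, j) = lambda;
    D(i, i) += 2.0 * mu;
    D(i + 3, i + 3) = mu;
  }
  return D;
}

// element stiffness (12x12) of a linear tetrahedron; also returns volume
static arma::mat tet_stiffness(const arma::mat33 &M, double lambda,
                               double mu, double &vol) {
  vol = arma::det(M) / 6.0;
  arma::mat33 Minv = arma::inv(M);
  // rows of Minv are gradients of barycentric coords 1..3; coord 0 = -sum
  arma::mat grad(3, 4);
  grad.col(0) = -arma::sum(Minv, 0).t();
  for (int c = 0; c < 3; ++c) grad.col(c + 1) = Minv.row(c).t();
  arma::mat B(6, 12, arma::fill::zeros);
  for (int n = 0; n < 4; ++n) {
    double gx = grad(0, n), gy = grad(1, n), gz = grad(2, n);
    int c = 3 * n;
    B(0, c) = gx;  B(1, c + 1) = gy;  B(2, c + 2) = gz;
    B(3, c) = gy;  B(3, c + 1) = gx;
    B(4, c + 1) = gz;  B(4, c + 2) = gy;
    B(5, c) = gz;  B(5, c + 2) = gx;
  }
  return vol * B.t() * iso_D(lambda, mu) * B;
}

struct ElemCache {
  std::vector<arma::mat> K;       // 12x12 per element
  std::vector<arma::mat33> Minv;  // inverse rest edge matrix
  arma::umat tets;                // 4 x m, 0-based
  int n_nodes;
};

static ElemCache build_cache(const arma::mat &nodes, const arma::imat &tets,
                             double lambda, double mu) {
  ElemCache ec;
  int m = tets.n_rows;
  ec.K.resize(m);
  ec.Minv.resize(m);
  ec.tets.set_size(4, m);
  ec.n_nodes = nodes.n_rows;
  for (int e = 0; e < m; ++e) {
    arma::uvec idx(4);
    for (int a = 0; a < 4; ++a) idx(a) = (arma::uword)(tets(e, a) - 1);
    ec.tets.col(e) = idx;
    arma::mat33 M;
    for (int c = 0; c < 3; ++c)
      M.col(c) = (nodes.row(idx(c + 1)) - nodes.row(idx(0))).t();
    double vol;
    ec.K[e] = tet_stiffness(M, lambda, mu, vol);
    if (vol <= 0) stop("tetrahedron %d has non-positive volume", e + 1);
    ec.Minv[e] = arma::inv(M);
  }
  return ec;
}

// polar rotation of deformation gradient F via SVD with reflection guard
static arma::mat33 polar_rotation(const arma::mat33 &F) {
  arma::mat33 U, V;
  arma::vec3 s;
  arma::svd(U, s, V, F);
  arma::mat33 R = U * V.t();
  if (arma::det(R) < 0) {
    U.col(2) *= -1.0;
    R = U * V.t();
  }
  return R;
}

// Assemble the elastic tangent (as triplets), internal force, strain
// energy and inverted-element count at displacement u.
// nodes: n x 3 (rest, mm); tets: m x 4 (1-based); u: n x 3 (mm)
// corotational: extract per-element rotations (TRUE) or fix R = I (FALSE)
// want_K: skip triplet assembly when only forces/energy are needed
// [[Rcpp::export(name = ".fem_system")]]
List fem_system(const arma::mat &nodes, const arma::imat &tets,
                double lambda, double mu, const arma::mat &u,
                bool corotational, bool want_K) {
  ElemCache ec = build_cache(nodes, tets, lambda, mu);
  int m = ec.tets.n_cols, n = ec.n_nodes;
  arma::vec fint(3 * n, arma::fill::zeros);
  double energy = 0.0;
  int n_inverted = 0;

  int nnz = want_K ? m * 144 : 0;
  IntegerVector ti(nnz), tj(nnz);
  NumericVector tx(nnz);
  int pos = 0;

  arma::mat Rbig(12, 12, arma::fill::eye);
  for (int e = 0; e < m; ++e) {
    arma::uvec idx = ec.tets.col(e);
    arma::mat33 Md;
    for (int c = 0; c < 3; ++c) {
      arma::rowvec3 edge =
          (nodes.row(idx(c + 1)) + u.row(idx(c + 1))) -
          (nodes.row(idx(0)) + u.row(idx(0)));
      Md.col(c) = edge.t();
    }
    arma::mat33 F = Md * ec.Minv[e];
    if (arma::det(F) <= 0) ++n_inverted;
    arma::mat33 R = corotational ? polar_rotation(F)
                                 : arma::mat33(arma::fill::eye);
    for (int a = 0; a < 4; ++a)
      Rbig.submat(3 * a, 3 * a, 3 * a + 2, 3 * a + 2) = R;

    // d = R^T x_def - x_rest (rigid part annihilated by K's nullspace)
    arma::vec d(12);
    for (int a = 0; a < 4; ++a) {
      arma::vec3 xd = (nodes.row(idx(a)) + u.row(idx(a))).t();
      arma::vec3 x0 = nodes.row(idx(a)).t();
      d.subvec(3 * a, 3 * a + 2) = R.t() * xd - x0;
    }
    arma::vec fe = Rbig * (ec.K[e] * d);
    energy += 0.5 * arma::dot(d, ec.K[e] * d);
    for (int a = 0; a < 4; ++a)
      fint.subvec(3 * idx(a), 3 * idx(a) + 2) += fe.subvec(3 * a, 3 * a + 2);

    if (want_K) {
      arma::mat Kw = Rbig * ec.K[e] * Rbig.t();
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b)
          for (int r = 0; r < 3; ++r)
            for (int c = 0; c < 3; ++c) {
              ti[pos] = 3 * idx(a) + r + 1;
              tj[pos] = 3 * idx(b) + c + 1;
              tx[pos] = Kw(3 * a + r, 3 * b + c);
              ++pos;
            }
    }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx,
                      _["fint"] = fint, _["energy"] = energy,
                      _["n_inverted"] = n_inverted);
}

// Locate query points in a tetrahedral mesh.
// Returns 1-based tet index, barycentric coords (clamped for exterior
// points), exterior flag and reconstruction distance.
// [[Rcpp::export(name = ".locate_points")]]
List locate_points(const arma::mat &points, const arma::mat &nodes,
                   const arma::imat &tets) {
  int m = tets.n_rows, np = points.n_rows;
  if (m == 0) stop("empty mesh");
  std::vector<arma::mat33> Minv(m);
  arma::mat x0(m, 3), lo(m, 3), hi(m, 3), cent(m, 3);
  for (int e = 0; e < m; ++e) {
    arma::mat33 M;
    arma::rowvec3 p0 = nodes.row(tets(e, 0) - 1);
    lo.row(e) = p0; hi.row(e) = p0;
    cent.row(e) = p0;
    for (int c = 0; c < 3; ++c) {
      arma::rowvec3 pc = nodes.row(tets(e, c + 1) - 1);
      M.col(c) = (pc - p0).t();
      lo.row(e) = arma::min(lo.row(e), pc);
      hi.row(e) = arma::max(hi.row(e), pc);
      cent.row(e) += pc;
    }
    cent.row(e) /= 4.0;
    Minv[e] = arma::inv(M);
    x0.row(e) = p0;
  }
  const double eps = 1e-9;
  IntegerVector tet_idx(np);
  LogicalVector exterior(np);
  NumericVector dist(np);
  NumericMatrix bary(np, 4);

  for (int p = 0; p < np; ++p) {
    arma::rowvec3 q = points.row(p);
    int found = -1;
    for (int e = 0; e < m; ++e) {
      if (q(0) < lo(e, 0) - eps || q(0) > hi(e, 0) + eps ||
          q(1) < lo(e, 1) - eps || q(1) > hi(e, 1) + eps ||
          q(2) < lo(e, 2) - eps || q(2) > hi(e, 2) + eps)
        continue;
      arma::vec3 b123 = Minv[e] * (q - x0.row(e)).t();
      double b0 = 1.0 - arma::sum(b123);
      if (b0 >= -eps && b123(0) >= -eps && b123(1) >= -eps &&
          b123(2) >= -eps) {
        found = e;
        bary(p, 0) = b0;
        for (int c = 0; c < 3; ++c) bary(p, c + 1) = b123(c);
        break;
      }
    }
    if (found >= 0) {
      tet_idx[p] = found + 1;
      exterior[p] = false;
      dist[p] = 0.0;
    } else {
      // exterior: nearest tet by clamped-barycentric reconstruction
      double best = R_PosInf;
      int best_e = 0;
      arma::vec4 best_b;
      for (int e = 0; e < m; ++e) {
        // cheap reject on centroid distance vs current best + tet radius
        double cd = arma::norm(q - cent.row(e));
        double rad = arma::norm(hi.row(e) - lo.row(e));
        if (cd - rad > best) continue;
        arma::vec3 b123 = Minv[e] * (q - x0.row(e)).t();
        arma::vec4 b;
        b(0) = 1.0 - arma::sum(b123);
        for (int c = 0; c < 3; ++c) b(c + 1) = b123(c);
        b.transform([](double v) { return v < 0 ? 0.0 : v; });
        double s = arma::sum(b);
        if (s <= 0) continue;
        b /= s;
        arma::rowvec3 rec(arma::fill::zeros);
        for (int a = 0; a < 4; ++a)
          rec += b(a) * nodes.row(tets(e, a) - 1);
        double d2 = arma::norm(q - rec);
        if (d2 < best) { best = d2; best_e = e; best_b = b; }
      }
      tet_idx[p] = best_e + 1;
      exterior[p] = true;
      dist[p] = best;
      for (int a = 0; a < 4; ++a) bary(p, a) = best_b(a);
    }
  }
  return List::create(_["tet"] = tet_idx, _["bary"] = bary,
                      _["exterior"] = exterior, _["dist"] = dist);
}
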
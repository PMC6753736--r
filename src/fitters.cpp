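// Levenberg-Marquardt cores of the two per-image fits: physical camera
// resection (9 parameters) and perspective-n-point module pose (6
// parameters).  Called once per simulated exposure, hence compiled.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat rodrigues_cpp(const vec& w) {
  double th = norm(w);
  if (th < 1e-14) return eye(3, 3);
  vec k = w / th;
  mat K = {{0, -k(2), k(1)}, {k(2), 0, -k(0)}, {-k(1), k(0), 0}};
  return eye(3, 3) + std::sin(th) * K + (1.0 - std::cos(th)) * (K * K);
}

// residuals of the camera model; returns false if a marker has non-positive
// depth
static bool cam_resid(const mat& X, const mat& uv, const mat& R,
                      const vec& C, double f, const vec& pp,
                      vec& r, mat& Xc) {
  Xc = (X.each_row() - C.t()) * R.t();
  if (any(Xc.col(2) <= 0)) return false;
  vec u = f * Xc.col(0) / Xc.col(2) + pp(0);
  vec v = f * Xc.col(1) / Xc.col(2) + pp(1);
  r = join_cols(uv.col(0) - u, uv.col(1) - v);
  return true;
}

// [[Rcpp::export]]
Rcpp::List resect_lm(const arma::mat& X, const arma::mat& uv,
                     const arma::mat& R0, const arma::vec& C0, double f0,
                     int max_iter, double tol) {
  const uword n = X.n_rows;
  mat R = R0;
  vec C = C0;
  double f = f0;
  vec pp = zeros(2);
  vec r;
  mat Xc;
  if (!cam_resid(X, uv, R, C, f, pp, r, Xc))
    Rcpp::stop("camera resection failed: markers behind the source");
  double cost = dot(r, r);
  double lambda = 1e-8;
  bool done = false;
  for (int it = 0; it < max_iter && !done && cost > 1e-28; ++it) {
    vec un = Xc.col(0) / Xc.col(2), vn = Xc.col(1) / Xc.col(2);
    vec aa = f / Xc.col(2);
    mat Du = join_rows(aa, zeros(n), -aa % un);
    mat Dv = join_rows(zeros(n), aa, -aa % vn);
    // w' S(x) = (w x x)'
    auto crossmat = [&](const mat& W) {
      return join_rows(W.col(1) % Xc.col(2) - W.col(2) % Xc.col(1),
                       W.col(2) % Xc.col(0) - W.col(0) % Xc.col(2),
                       W.col(0) % Xc.col(1) - W.col(1) % Xc.col(0));
    };
    mat Ju = join_rows(-crossmat(Du), -Du * R, un, join_rows(ones(n), zeros(n)));
    mat Jv = join_rows(-crossmat(Dv), -Dv * R, vn, join_rows(zeros(n), ones(n)));
    mat J = join_cols(Ju, Jv);
    vec g = J.t() * r;
    mat H = J.t() * J;
    bool improved = false;
    for (int t = 0; t < 10; ++t) {
      vec step;
      bool ok = solve(step, H + lambda * eye(9, 9), g, solve_opts::no_approx);
      if (ok) {
        mat Rn = rodrigues_cpp(step.subvec(0, 2)) * R;
        vec Cn = C + step.subvec(3, 5);
        double fn = f + step(6);
        vec ppn = pp + step.subvec(7, 8);
        vec rn;
        mat Xcn;
        if (fn > 0 && cam_resid(X, uv, Rn, Cn, fn, ppn, rn, Xcn)) {
          double cn = dot(rn, rn);
          if (cn < cost) {
            double rel = (cost - cn) / std::max(cost, 1e-300);
            R = Rn; C = Cn; f = fn; pp = ppn; r = rn; Xc = Xcn; cost = cn;
            lambda = std::max(lambda / 5.0, 1e-12);
            improved = true;
            if (rel < tol) done = true;
            break;
          }
        }
      }
      lambda *= 10.0;
    }
    if (!improved) break;
  }
  // re-orthonormalize, preserving the frame's handedness
  mat U, V;
  vec s;
  svd(U, s, V, R);
  R = U * V.t();
  return Rcpp::List::create(Rcpp::Named("R") = R, Rcpp::Named("C") = C,
                            Rcpp::Named("f") = f, Rcpp::Named("pp") = pp,
                            Rcpp::Named("cost") = cost);
}

static void pnp_resid(const mat& M, const mat& uv, const mat& P,
                      const mat& R, const vec& t,
                      vec& r, mat& Xr, vec& z, vec& u, vec& v) {
  Xr = M * R.t();
  Xr.each_row() += t.t();
  z = Xr * P.row(2).cols(0, 2).t() + P(2, 3);
  u = (Xr * P.row(0).cols(0, 2).t() + P(0, 3)) / z;
  v = (Xr * P.row(1).cols(0, 2).t() + P(1, 3)) / z;
  r = join_cols(uv.col(0) - u, uv.col(1) - v);
}

// [[Rcpp::export]]
Rcpp::List pnp_lm(const arma::mat& M, const arma::mat& uv,
                  const arma::mat& P, const arma::mat& R0,
                  const arma::vec& t0, int max_iter, double tol) {
  const uword m = M.n_rows;
  mat R = R0;
  vec t = t0;
  vec r, z, u, v;
  mat Xr;
  pnp_resid(M, uv, P, R, t, r, Xr, z, u, v);
  double cost = dot(r, r);
  double lambda = 1e-8;
  bool done = false;
  rowvec p1 = P.row(0).cols(0, 2), p2 = P.row(1).cols(0, 2),
         p3 = P.row(2).cols(0, 2);
  for (int it = 0; it < max_iter && !done && cost > 1e-28; ++it) {
    mat V1 = Xr.each_row() - t.t();
    mat A1 = (repmat(p1, m, 1) - u * p3);
    A1.each_col() /= z;
    mat A2 = (repmat(p2, m, 1) - v * p3);
    A2.each_col() /= z;
    auto crossmat = [&](const mat& W) {
      return join_rows(W.col(1) % V1.col(2) - W.col(2) % V1.col(1),
                       W.col(2) % V1.col(0) - W.col(0) % V1.col(2),
                       W.col(0) % V1.col(1) - W.col(1) % V1.col(0));
    };
    mat J = join_cols(join_rows(-crossmat(A1), A1),
                      join_rows(-crossmat(A2), A2));
    vec g = J.t() * r;
    mat H = J.t() * J;
    bool improved = false;
    for (int tr = 0; tr < 10; ++tr) {
      vec step;
      bool ok = solve(step, H + lambda * eye(6, 6), g, solve_opts::no_approx);
      if (ok) {
        mat Rn = rodrigues_cpp(step.subvec(0, 2)) * R;
        vec tn = t + step.subvec(3, 5);
        vec rn, zn, un, vn;
        mat Xrn;
        pnp_resid(M, uv, P, Rn, tn, rn, Xrn, zn, un, vn);
        double cn = dot(rn, rn);
        if (cn < cost) {
          double rel = (cost - cn) / std::max(cost, 1e-300);
          R = Rn; t = tn; r = rn; Xr = Xrn; z = zn; u = un; v = vn;
          cost = cn;
          lambda = std::max(lambda / 5.0, 1e-12);
          improved = true;
          if (rel < tol) done = true;
          break;
        }
      }
      lambda *= 10.0;
    }
    if (!improved) break;
  }
  mat U, Vv;
  vec s;
  svd(U, s, Vv, R);
  mat Rout = U * Vv.t();
  if (det(Rout) < 0) Rout = U * diagmat(vec{1, 1, -1}) * Vv.t();
  mat pos = M * Rout.t();
  pos.each_row() += t.t();
  return Rcpp::List::create(Rcpp::Named("R") = Rout, Rcpp::Named("t") = t,
                            Rcpp::Named("positions") = pos,
                            Rcpp::Named("rms") = std::sqrt(cost / (2.0 * m)));
}
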
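// Least-squares rigid (proper) transforms between point sets.
// Hot path of pose reconstruction: one small Procrustes fit per frame per
// cluster, so thousands to millions of 3x3 SVDs per analysis.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Kabsch solution for R, t minimising sum ||R p + t - q||^2.
// P, Q are M x 3 with rows as points. Returns false on SVD failure.
static bool kabsch(const mat& P, const mat& Q, mat& R, vec& t, double& rms) {
  const rowvec cp = mean(P, 0);
  const rowvec cq = mean(Q, 0);
  const mat Pc = P.each_row() - cp;
  const mat Qc = Q.each_row() - cq;

  mat U, V;
  vec s;
  if (!svd(U, s, V, Pc.t() * Qc)) return false;

  mat D = eye<mat>(3, 3);
  // Reflection correction keeps det(R) = +1.
  if (det(V * U.t()) < 0) D(2, 2) = -1.0;
  R = V * D * U.t();
  t = cq.t() - R * cp.t();

  const mat E = (R * Pc.t()).t() - Qc;
  rms = std::sqrt(accu(E % E) / P.n_rows);
  return true;
}

// [[Rcpp::export]]
Rcpp::List cpp_rigid_fit(const arma::mat& P, const arma::mat& Q) {
  mat R;
  vec t;
  double rms = 0.0;
  if (!kabsch(P, Q, R, t, rms)) Rcpp::stop("SVD failed in rigid fit");
  return Rcpp::List::create(Rcpp::Named("rotation") = R,
                            Rcpp::Named("translation") = t,
                            Rcpp::Named("rms") = rms);
}

// Per-frame fits of one marker cluster. `ref` is M x 3 body-frame offsets,
// `obs` is an M x 3 x N cube of observed lab positions.
// [[Rcpp::export]]
Rcpp::List cpp_rigid_fit_series(const arma::mat& ref, const arma::cube& obs) {
  const uword N = obs.n_slices;
  cube Rout(3, 3, N);
  mat tout(N, 3);
  vec rms(N);
  mat R;
  vec t;
  double e;
  for (uword i = 0; i < N; ++i) {
    if (!kabsch(ref, obs.slice(i), R, t, e))
      Rcpp::stop("SVD failed in rigid fit at frame %d", (int)(i + 1));
    Rout.slice(i) = R;
    tout.row(i) = t.t();
    rms(i) = e;
  }
  return Rcpp::List::create(Rcpp::Named("rotations") = Rout,
                            Rcpp::Named("origins") = tout,
                            Rcpp::Named("rms") = rms);
}

// Relative pose series moving-in-fixed from two cluster fits.
// [[Rcpp::export]]
Rcpp::List cpp_relative_pose_series(const arma::mat& ref_fixed,
                                    const arma::cube& obs_fixed,
                                    const arma::mat& ref_moving,
                                    const arma::cube& obs_moving) {
  const uword N = obs_fixed.n_slices;
  if (obs_moving.n_slices != N) Rcpp::stop("cluster frame counts differ");
  cube Rout(3, 3, N);
  mat Oout(N, 3);
  vec rms_f(N), rms_m(N);
  mat Rf, Rm;
  vec tf, tm;
  double ef, em;
  for (uword i = 0; i < N; ++i) {
    if (!kabsch(ref_fixed, obs_fixed.slice(i), Rf, tf, ef) ||
        !kabsch(ref_moving, obs_moving.slice(i), Rm, tm, em))
      Rcpp::stop("SVD failed in rigid fit at frame %d", (int)(i + 1));
    // moving-in-fixed: x_fixed = Rf^T (x_lab - tf)
    Rout.slice(i) = Rf.t() * Rm;
    Oout.row(i) = (Rf.t() * (tm - tf)).t();
    rms_f(i) = ef;
    rms_m(i) = em;
  }
  return Rcpp::List::create(Rcpp::Named("rotations") = Rout,
                            Rcpp::Named("origins") = Oout,
                            Rcpp::Named("rms_fixed") = rms_f,
                            Rcpp::Named("rms_moving") = rms_m);
}
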
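// Per-pixel Lu-Chipman polar decomposition kernel.
//
// Mirrors the pure-R lc_decompose() exactly (the test suite cross-checks
// the two paths on random physical matrices); compiled because a tissue
// microarray field of view has 1e5-1e6 foreground pixels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double clamp1(double x, long long& n_clamped) {
  if (x > 1.0) { ++n_clamped; return 1.0; }
  if (x < -1.0) { ++n_clamped; return -1.0; }
  return x;
}

// [[Rcpp::export]]
List decompose_image_cpp(NumericVector elements, LogicalMatrix mask,
                         double delta_cutoff) {
  IntegerVector dims = elements.attr("dim");
  if (dims.size() != 4 || dims[2] != 4 || dims[3] != 4)
    stop("elements must be a h x w x 4 x 4 array");
  const int h = dims[0], w = dims[1];
  const R_xlen_t plane = (R_xlen_t)h * w;

  NumericMatrix delta(h, w), theta(h, w), Rmap(h, w), Delta(h, w), D(h, w),
      psi(h, w);
  LogicalMatrix valid(h, w);
  std::fill(delta.begin(), delta.end(), NA_REAL);
  std::fill(theta.begin(), theta.end(), NA_REAL);
  std::fill(Rmap.begin(), Rmap.end(), NA_REAL);
  std::fill(Delta.begin(), Delta.end(), NA_REAL);
  std::fill(D.begin(), D.end(), NA_REAL);
  std::fill(psi.begin(), psi.end(), NA_REAL);
  long long n_clamped = 0;

  arma::mat44 M, MD, Mp, MDelta, MR;
  arma::mat33 mp, G, A, B, mdelta, bLR;

  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (!mask(r, c)) continue;
      const R_xlen_t base = (R_xlen_t)r + (R_xlen_t)c * h;
      bool finite = true;
      for (int j = 0; j < 4 && finite; ++j)
        for (int i = 0; i < 4; ++i) {
          double v = elements[base + plane * (i + 4 * j)];
          if (!std::isfinite(v)) { finite = false; break; }
          M(i, j) = v;
        }
      if (!finite || M(0, 0) <= 0.0) continue;
      M /= M(0, 0);

      // diattenuator
      arma::vec3 Dv = {M(0, 1), M(0, 2), M(0, 3)};
      double d = arma::norm(Dv);
      if (d >= 1.0 - 1e-9) continue;  // ideal polarizer, flagged invalid
      if (d < 1e-14) {
        Mp = M;
        MD.eye();
      } else {
        arma::vec3 dh = Dv / d;
        double a = std::sqrt(1.0 - d * d);
        arma::mat33 mD = a * arma::eye(3, 3) + (1.0 - a) * (dh * dh.t());
        MD.eye();
        for (int i = 0; i < 3; ++i) {
          MD(0, i + 1) = Dv(i);
          MD(i + 1, 0) = Dv(i);
          for (int j = 0; j < 3; ++j) MD(i + 1, j + 1) = mD(i, j);
        }
        arma::mat44 MDinv;
        if (!arma::inv(MDinv, MD)) continue;
        Mp = M * MDinv;
      }

      // depolarizer
      mp = Mp.submat(1, 1, 3, 3);
      G = mp * mp.t();
      arma::vec3 ev;
      arma::mat33 evec;
      if (!arma::eig_sym(ev, evec, arma::symmatu(G))) continue;
      ev = arma::clamp(ev, 0.0, arma::datum::inf);
      const double l1 = ev(2), l2 = ev(1), l3 = ev(0);  // descending
      A = G + (std::sqrt(l1 * l2) + std::sqrt(l2 * l3) + std::sqrt(l3 * l1)) *
                  arma::eye(3, 3);
      B = (std::sqrt(l1) + std::sqrt(l2) + std::sqrt(l3)) * G +
          std::sqrt(l1 * l2 * l3) * arma::eye(3, 3);
      if (!arma::solve(mdelta, A, B)) continue;
      if (arma::det(mp) < 0) mdelta = -mdelta;
      MDelta.eye();
      for (int i = 0; i < 3; ++i) {
        MDelta(i + 1, 0) = Mp(i + 1, 0);
        for (int j = 0; j < 3; ++j) MDelta(i + 1, j + 1) = mdelta(i, j);
      }
      arma::mat44 MDeltaInv;
      if (!arma::inv(MDeltaInv, MDelta)) continue;
      if (std::abs(arma::det(MDelta)) < 1e-12) continue;
      MR = MDeltaInv * Mp;

      // scalar parameters
      double de = std::acos(clamp1(
          std::sqrt(std::pow(MR(1, 1) + MR(2, 2), 2.0) +
                    std::pow(MR(2, 1) - MR(1, 2), 2.0)) - 1.0,
          n_clamped));
      double Rtot = std::acos(clamp1(arma::trace(MR) / 2.0 - 1.0, n_clamped));
      double ps = 0.5 * std::atan2(MR(1, 2) - MR(2, 1), MR(1, 1) + MR(2, 2));

      delta(r, c) = de;
      Rmap(r, c) = Rtot;
      psi(r, c) = ps;
      D(r, c) = d;
      double tr = std::abs(mdelta(0, 0)) + std::abs(mdelta(1, 1)) +
                  std::abs(mdelta(2, 2));
      double dep = 1.0 - tr / 3.0;
      Delta(r, c) = std::min(1.0, std::max(0.0, dep));
      valid(r, c) = true;

      if (de > delta_cutoff) {
        // linear factor M_LR = M_R * M_CR(psi)^-1; only its 3x3 block needed
        double c2 = std::cos(2.0 * ps), s2 = std::sin(2.0 * ps);
        arma::mat33 crInv = {{c2, -s2, 0.0}, {s2, c2, 0.0}, {0.0, 0.0, 1.0}};
        bLR = MR.submat(1, 1, 3, 3) * crInv;
        double s = 2.0 * std::sin(de);
        double r1 = (bLR(1, 2) - bLR(2, 1)) / s;
        double r2 = (bLR(2, 0) - bLR(0, 2)) / s;
        double th = 0.5 * std::atan2(r2, r1);
        if (th < 0) th += arma::datum::pi;
        theta(r, c) = th;
      }
    }
  }

  return List::create(_["delta"] = delta, _["theta"] = theta,
                      _["R"] = Rmap, _["Delta"] = Delta, _["D"] = D,
                      _["psi"] = psi, _["valid"] = valid,
                      _["n_clamped"] = (double)n_clamped);
}
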
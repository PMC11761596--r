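// Compiled core of the four-layer motion model.
//
// The per-frame pipeline (frame differencing -> ON/OFF split -> spatial
// denoising -> lateral inhibition -> divisive tanh normalization ->
// centre-surround contrast -> T4/T5 correlators -> LPTC convergence -> LPi
// opponency) is a long chain of small-kernel convolutions and elementwise
// maps over the full visual field.  Benchmarks run the model over hundreds
// of 500x250x100 sequences, so the sequence loop lives here; the R level
// keeps an equivalent per-stage reference implementation that the test
// suite checks against this engine to 1e-10.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

// Centred 2-D kernel application (correlation form: out(r,c) =
// sum_{u,v} X(r+u, c+v) K(u+hr, v+hc)) with replicate-edge padding.
// All model kernels are symmetric, so correlation equals convolution.
// [[Rcpp::export]]
arma::mat cpp_conv2_replicate(const arma::mat& X, const arma::mat& K) {
  const int H = X.n_rows, W = X.n_cols;
  const int hr = (K.n_rows - 1) / 2, hc = (K.n_cols - 1) / 2;
  mat out(H, W, arma::fill::zeros);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double acc = 0.0;
      for (int v = -hc; v <= hc; ++v) {
        int cc = c + v;
        cc = cc < 0 ? 0 : (cc >= W ? W - 1 : cc);
        for (int u = -hr; u <= hr; ++u) {
          int rr = r + u;
          rr = rr < 0 ? 0 : (rr >= H ? H - 1 : rr);
          acc += X(rr, cc) * K(u + hr, v + hc);
        }
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// Separable centred kernel with replicate padding; k is the 1-D profile
// applied along rows then columns (outer-product kernel).  The interior is
// a straight (auto-vectorizable) loop; only the kernel-halfwidth edge bands
// use clamped indices.
static void sepconv_replicate(const mat& X, const vec& k, mat& tmp,
                              mat& out) {
  const int H = X.n_rows, W = X.n_cols;
  const int n = static_cast<int>(k.n_elem), hw = (n - 1) / 2;
  tmp.zeros();
  for (int c = 0; c < W; ++c) {
    const double* xc = X.colptr(c);
    double* tc = tmp.colptr(c);
    for (int i = 0; i < n; ++i) {
      const int off = i - hw;
      const double ki = k(i);
      const int r0 = std::max(0, -off), r1 = std::min(H, H - off);
      for (int r = 0; r < r0; ++r) tc[r] += ki * xc[0];
      for (int r = r0; r < r1; ++r) tc[r] += ki * xc[r + off];
      for (int r = r1; r < H; ++r) tc[r] += ki * xc[H - 1];
    }
  }
  out.zeros();
  for (int i = 0; i < n; ++i) {
    const int off = i - hw;
    const double ki = k(i);
    for (int c = 0; c < W; ++c) {
      int cc = c + off;
      cc = cc < 0 ? 0 : (cc >= W ? W - 1 : cc);
      out.col(c) += ki * tmp.col(cc);
    }
  }
}

// 8-neighbour ring mean (3x3 kernel of 1/8 with zero centre), replicate pad.
static void ring8(const mat& X, const vec& box, mat& tmp, mat& scratch,
                  mat& out) {
  sepconv_replicate(X, box, tmp, scratch);  // 3x3 box mean (1/9 weights)
  out = (scratch * 9.0 - X) / 8.0;
}

static inline double pow_rect(double v, double g) {
  if (v <= 0.0) return 0.0;
  return g == 0.5 ? std::sqrt(v) : (g == 1.0 ? v : std::pow(v, g));
}

// Fused T4/T5 correlation, LPTC convergence and LPi opponency for one
// opponent axis.  For the vertical axis the preferred/null shifts are
// (-sd, +sd) rows; for the horizontal axis (+sd, -sd) columns.  Out-of-
// field shifted samples are zeros.  Returns sum[LPTC_P - LPTC_N]+ -
// sum[LPTC_N - LPTC_P]+ over all pixels.
static double opponent_sum(const mat& Non, const mat& NdOn, const mat& Noff,
                           const mat& NdOff, const mat& Con, const mat& Coff,
                           int sd, bool vertical, double g1, double g2) {
  const int H = Non.n_rows, W = Non.n_cols;
  double pos = 0.0, neg = 0.0;
  for (int c = 0; c < W; ++c) {
    const double* on = Non.colptr(c);
    const double* don = NdOn.colptr(c);
    const double* off = Noff.colptr(c);
    const double* doff = NdOff.colptr(c);
    const double* co = Con.colptr(c);
    const double* cf = Coff.colptr(c);
    const double* on_p;   // preferred-shift source columns (horizontal axis)
    const double* don_p;
    const double* off_p;
    const double* doff_p;
    const double* on_n;
    const double* don_n;
    const double* off_n;
    const double* doff_n;
    bool have_p = true, have_n = true;
    if (!vertical) {
      have_p = c + sd < W;   // rightward (preferred) samples x + sd
      have_n = c - sd >= 0;  // leftward (null) samples x - sd
      if (have_p) {
        on_p = Non.colptr(c + sd);
        don_p = NdOn.colptr(c + sd);
        off_p = Noff.colptr(c + sd);
        doff_p = NdOff.colptr(c + sd);
      }
      if (have_n) {
        on_n = Non.colptr(c - sd);
        don_n = NdOn.colptr(c - sd);
        off_n = Noff.colptr(c - sd);
        doff_n = NdOff.colptr(c - sd);
      }
    }
    for (int r = 0; r < H; ++r) {
      double t4p, t5p, t4n, t5n;
      if (vertical) {
        // up: samples y - sd; down: samples y + sd
        const bool up_ok = r - sd >= 0, dn_ok = r + sd < H;
        t4p = (up_ok ? on[r - sd] : 0.0) * don[r] -
              on[r] * (up_ok ? don[r - sd] : 0.0);
        t5p = (up_ok ? off[r - sd] : 0.0) * doff[r] -
              off[r] * (up_ok ? doff[r - sd] : 0.0);
        t4n = (dn_ok ? on[r + sd] : 0.0) * don[r] -
              on[r] * (dn_ok ? don[r + sd] : 0.0);
        t5n = (dn_ok ? off[r + sd] : 0.0) * doff[r] -
              off[r] * (dn_ok ? doff[r + sd] : 0.0);
      } else {
        t4p = (have_p ? on_p[r] : 0.0) * don[r] -
              on[r] * (have_p ? don_p[r] : 0.0);
        t5p = (have_p ? off_p[r] : 0.0) * doff[r] -
              off[r] * (have_p ? doff_p[r] : 0.0);
        t4n = (have_n ? on_n[r] : 0.0) * don[r] -
              on[r] * (have_n ? don_n[r] : 0.0);
        t5n = (have_n ? off_n[r] : 0.0) * doff[r] -
              off[r] * (have_n ? doff_n[r] : 0.0);
      }
      double lp, ln;
      if (g1 == 0.5 && g2 == 0.5) {  // reference exponents: branchless sqrt
        lp = std::sqrt(std::max(t4p - co[r], 0.0)) +
             std::sqrt(std::max(t5p - cf[r], 0.0));
        ln = std::sqrt(std::max(t4n - co[r], 0.0)) +
             std::sqrt(std::max(t5n - cf[r], 0.0));
      } else {
        lp = pow_rect(t4p - co[r], g1) + pow_rect(t5p - cf[r], g2);
        ln = pow_rect(t4n - co[r], g1) + pow_rect(t5n - cf[r], g2);
      }
      const double d = lp - ln;
      pos += std::max(d, 0.0);
      neg += std::max(-d, 0.0);
    }
  }
  return pos - neg;
}

// Full model run over one sequence.  frames: H x W x T cube of luminance
// values; par: flat list of model parameters (see R model_params()).
// Returns per-frame VS/HS (NA for the first frame, which has no luminance
// change) plus the index of the first frame with a defined delayed signal.
// [[Rcpp::export]]
List cpp_run_sequence(const arma::cube& frames, const List& par) {
  const int H = frames.n_rows, W = frames.n_cols, T = frames.n_slices;
  const double delta_c = par["delta_c"];
  const double thr = par["iso_threshold"];
  const double li_w = par["li_weight"];
  const bool li_on = par["li_enabled"];
  const bool denoise_on = par["denoise_enabled"];
  const double psi = par["psi"];
  const double sigma = par["sigma"];
  const int khw = par["kernel_halfwidth"];
  const int sd = par["sd"];
  const int delay = par["delay_frames"];
  const double g1 = par["gamma1"], g2 = par["gamma2"];
  const bool contrast_on = par["contrast_enabled"];
  const bool knorm = par["normalize_kernel"];

  // 1-D Gaussian profile; outer product reproduces the truncated 2-D
  // kernel.  Unit-sum renormalization makes a uniform field its own
  // surround estimate; the raw analytic truncation is kept as an option.
  vec gk(2 * khw + 1);
  for (int i = -khw; i <= khw; ++i)
    gk(i + khw) = std::exp(-(double)(i * i) / (2.0 * sigma * sigma));
  if (knorm)
    gk /= arma::accu(gk);
  else
    gk /= std::sqrt(2.0 * arma::datum::pi * sigma * sigma);

  const vec box3 = vec({1.0, 1.0, 1.0}) / 3.0;

  NumericVector vs(T, NA_REAL), hs(T, NA_REAL);

  mat tmp(H, W), scratch(H, W), ringbuf(H, W);
  mat DN[2], S[2], N[2], C[2], dn_prev[2];
  for (int p = 0; p < 2; ++p) {
    DN[p].set_size(H, W);
    S[p].set_size(H, W);
    N[p].set_size(H, W);
    C[p].zeros(H, W);
    dn_prev[p].zeros(H, W);
  }
  // delayed normalized signals: ring buffer of the last `delay` map pairs
  std::vector<mat> hist(2 * delay, mat(H, W, arma::fill::zeros));
  int steps = 0;  // completed frame-difference steps

  for (int t = 1; t < T; ++t) {
    const mat P = frames.slice(t) - frames.slice(t - 1);

    for (int p = 0; p < 2; ++p) {
      // lamina: ON/OFF half-wave rectification (OFF sign-inverted)
      mat& DNp = DN[p];
      if (p == 0) {
        DNp = arma::clamp(P, 0.0, arma::datum::inf);
      } else {
        DNp = arma::clamp(-P, 0.0, arma::datum::inf);
      }

      // lamina: cluster passing coefficient + threshold comparison
      if (denoise_on) {
        sepconv_replicate(DNp, box3, tmp, scratch);  // 3x3 mean excitation
        const double m = scratch.max();
        if (m <= 0.0) {
          DNp.zeros();
        } else {
          const double inv = 1.0 / (delta_c + m);
          DNp %= scratch * inv;
          DNp.transform([thr](double v) { return v < thr ? 0.0 : v; });
        }
      }

      // lamina: lateral inhibition by the one-step-delayed surround
      if (li_on) {
        ring8(dn_prev[p], box3, tmp, scratch, ringbuf);
        S[p] = DNp - li_w * ringbuf;
        S[p].transform([](double v) { return v > 0.0 ? v : 0.0; });
      } else {
        S[p] = DNp;
      }
      dn_prev[p] = DNp;

      // medulla: divisive tanh contrast normalization
      sepconv_replicate(S[p], gk, tmp, scratch);
      scratch += psi;
      N[p] = S[p] / scratch;
      N[p].transform([](double v) { return std::tanh(v); });

      // medulla: centre-surround contrast pathways
      if (contrast_on) {
        ring8(N[p], box3, tmp, scratch, ringbuf);
        C[p] = N[p] - ringbuf;
      }
    }

    // lobula complex: correlators, LPTC convergence, LPi opponency
    mat& NdOn = hist[2 * (steps % delay)];
    mat& NdOff = hist[2 * (steps % delay) + 1];
    vs[t] = opponent_sum(N[0], NdOn, N[1], NdOff, C[0], C[1], sd, true,
                         g1, g2);
    hs[t] = opponent_sum(N[0], NdOn, N[1], NdOff, C[0], C[1], sd, false,
                         g1, g2);
    NdOn = N[0];
    NdOff = N[1];
    ++steps;
  }

  return List::create(_["vs"] = vs, _["hs"] = hs,
                      _["first_evaluated"] = delay + 2);
}
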
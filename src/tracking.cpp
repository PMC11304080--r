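#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Pyramidal Lucas-Kanade sparse optical flow over a grayscale frame stack.
// Coordinates are 0-based (row, col) doubles; the R wrapper shifts to 1-based.

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Bilinear sample with replicated borders.
static inline double bilinear(const NumericMatrix &M, double r, double c) {
  const int nr = M.nrow(), nc = M.ncol();
  r = clampd(r, 0.0, nr - 1.0);
  c = clampd(c, 0.0, nc - 1.0);
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  int r1 = r0 + 1 < nr ? r0 + 1 : r0;
  int c1 = c0 + 1 < nc ? c0 + 1 : c0;
  double fr = r - r0, fc = c - c0;
  return (1 - fr) * ((1 - fc) * M(r0, c0) + fc * M(r0, c1)) +
         fr * ((1 - fc) * M(r1, c0) + fc * M(r1, c1));
}

// 5-tap binomial blur [1 4 6 4 1]/16, separable, replicate borders.
static NumericMatrix blur5(const NumericMatrix &src) {
  const int nr = src.nrow(), nc = src.ncol();
  static const double k[5] = {1.0 / 16, 4.0 / 16, 6.0 / 16, 4.0 / 16, 1.0 / 16};
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double s = 0;
      for (int t = -2; t <= 2; ++t) {
        int jj = j + t;
        jj = jj < 0 ? 0 : (jj >= nc ? nc - 1 : jj);
        s += k[t + 2] * src(i, jj);
      }
      tmp(i, j) = s;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0;
      for (int t = -2; t <= 2; ++t) {
        int ii = i + t;
        ii = ii < 0 ? 0 : (ii >= nr ? nr - 1 : ii);
        s += k[t + 2] * tmp(ii, j);
      }
      out(i, j) = s;
    }
  return out;
}

static NumericMatrix pyr_down(const NumericMatrix &src) {
  NumericMatrix b = blur5(src);
  const int nr = (src.nrow() + 1) / 2, nc = (src.ncol() + 1) / 2;
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) out(i, j) = b(2 * i, 2 * j);
  return out;
}

static std::vector<NumericMatrix> build_pyramid(const NumericMatrix &base,
                                                int levels) {
  std::vector<NumericMatrix> pyr;
  pyr.push_back(base);
  for (int l = 1; l < levels; ++l) {
    const NumericMatrix &prev = pyr.back();
    if (prev.nrow() < 8 || prev.ncol() < 8) break;
    pyr.push_back(pyr_down(prev));
  }
  return pyr;
}

// Central-difference gradients (rows -> gr, cols -> gc), replicate borders.
static void gradients(const NumericMatrix &M, NumericMatrix &gr,
                      NumericMatrix &gc) {
  const int nr = M.nrow(), nc = M.ncol();
  gr = NumericMatrix(nr, nc);
  gc = NumericMatrix(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      int ip = i + 1 < nr ? i + 1 : i, im = i > 0 ? i - 1 : i;
      int jp = j + 1 < nc ? j + 1 : j, jm = j > 0 ? j - 1 : j;
      gr(i, j) = (M(ip, j) - M(im, j)) / (ip - im > 0 ? (double)(ip - im) : 1.0);
      gc(i, j) = (M(i, jp) - M(i, jm)) / (jp - jm > 0 ? (double)(jp - jm) : 1.0);
    }
}

// Iterative LK refinement of one point across one pyramid pair, using
// symmetric (averaged reference/target) window gradients, which suppresses
// the sub-pixel interpolation bias of the one-sided scheme.
// Returns displacement (dr, dc) at base resolution; ok = false on failure.
static bool track_point(const std::vector<NumericMatrix> &pyrI,
                        const std::vector<NumericMatrix> &grI,
                        const std::vector<NumericMatrix> &gcI,
                        const std::vector<NumericMatrix> &pyrJ,
                        const std::vector<NumericMatrix> &grJ,
                        const std::vector<NumericMatrix> &gcJ, double pr,
                        double pc, double dr0, double dc0, int win_half,
                        int max_iter, double eps, double &dr, double &dc) {
  const int nlev = (int)pyrI.size();
  // warm start: inject the initial displacement guess at the coarsest level
  const double top_scale = std::pow(2.0, nlev - 1);
  double gr_ = dr0 / top_scale, gc_ = dc0 / top_scale;
  const int wsz = 2 * win_half + 1, npx = wsz * wsz;
  std::vector<double> iw(npx), ixw(npx), iyw(npx);
  for (int L = nlev - 1; L >= 0; --L) {
    const double scale = std::pow(2.0, L);
    const double plr = pr / scale, plc = pc / scale;
    const NumericMatrix &I = pyrI[L];
    // window samples of I and its gradients (fixed for this level)
    int idx = 0;
    for (int a = -win_half; a <= win_half; ++a)
      for (int b = -win_half; b <= win_half; ++b, ++idx) {
        double rr = plr + a, cc = plc + b;
        iw[idx] = bilinear(I, rr, cc);
        ixw[idx] = bilinear(grI[L], rr, cc);
        iyw[idx] = bilinear(gcI[L], rr, cc);
      }
    double vr = 0, vc = 0;
    for (int it = 0; it < max_iter; ++it) {
      double G11 = 0, G12 = 0, G22 = 0, b1 = 0, b2 = 0;
      idx = 0;
      for (int a = -win_half; a <= win_half; ++a)
        for (int b = -win_half; b <= win_half; ++b, ++idx) {
          double jr = plr + gr_ + vr + a, jc = plc + gc_ + vc + b;
          double dI = iw[idx] - bilinear(pyrJ[L], jr, jc);
          double gx = 0.5 * (ixw[idx] + bilinear(grJ[L], jr, jc));
          double gy = 0.5 * (iyw[idx] + bilinear(gcJ[L], jr, jc));
          G11 += gx * gx;
          G12 += gx * gy;
          G22 += gy * gy;
          b1 += dI * gx;
          b2 += dI * gy;
        }
      const double det = G11 * G22 - G12 * G12;
      if (det < 1e-12 || (G11 + G22) < 1e-10) return false;
      double nr_ = (G22 * b1 - G12 * b2) / det;
      double nc_ = (G11 * b2 - G12 * b1) / det;
      vr += nr_;
      vc += nc_;
      if (std::sqrt(nr_ * nr_ + nc_ * nc_) < eps) break;
    }
    if (L > 0) {
      gr_ = 2.0 * (gr_ + vr);
      gc_ = 2.0 * (gc_ + vc);
    } else {
      gr_ += vr;
      gc_ += vc;
    }
  }
  dr = gr_;
  dc = gc_;
  return std::isfinite(dr) && std::isfinite(dc);
}

//' @noRd
// [[Rcpp::export(name = ".lk_track_stack")]]
List lk_track_stack(NumericVector frames, NumericMatrix pts, int levels,
                    int win_half, int max_iter, double eps) {
  IntegerVector dm = frames.attr("dim");
  if (dm.size() != 3) stop("frames must be a rows x cols x n array");
  const int nr = dm[0], nc = dm[1], nf = dm[2];
  const int m = pts.nrow();
  if (nf < 2) stop("need at least 2 frames");

  // positions [marker, frame, (row, col)], 0-based
  NumericVector pos(Dimension(m, nf, 2));
  LogicalVector valid(m, true);
  for (int k = 0; k < m; ++k) {
    pos[k + 0 * m] = pts(k, 0);
    pos[k + (size_t)nf * m + 0 * m] = pts(k, 1);
  }
  auto setpos = [&](int k, int t, double r, double c) {
    pos[(size_t)k + (size_t)t * m] = r;
    pos[(size_t)k + (size_t)t * m + (size_t)nf * m] = c;
  };
  auto getpos = [&](int k, int t, double &r, double &c) {
    r = pos[(size_t)k + (size_t)t * m];
    c = pos[(size_t)k + (size_t)t * m + (size_t)nf * m];
  };

  // reference-anchored tracking: every frame is matched against the frame-1
  // template (no frame-to-frame error accumulation), warm-started from the
  // previous frame's displacement so per-step increments stay small
  NumericMatrix tmpl(nr, nc);
  for (int i = 0; i < nr * nc; ++i) tmpl[i] = frames[i];
  std::vector<NumericMatrix> pyrT = build_pyramid(tmpl, levels);
  std::vector<NumericMatrix> grT(pyrT.size()), gcT(pyrT.size());
  for (size_t l = 0; l < pyrT.size(); ++l) gradients(pyrT[l], grT[l], gcT[l]);

  for (int t = 1; t < nf; ++t) {
    NumericMatrix nxt(nr, nc);
    const size_t off = (size_t)t * nr * nc;
    for (int i = 0; i < nr * nc; ++i) nxt[i] = frames[off + i];
    std::vector<NumericMatrix> pyrNext = build_pyramid(nxt, levels);
    std::vector<NumericMatrix> grNext(pyrNext.size()), gcNext(pyrNext.size());
    for (size_t l = 0; l < pyrNext.size(); ++l)
      gradients(pyrNext[l], grNext[l], gcNext[l]);

    for (int k = 0; k < m; ++k) {
      double pr, pc, p0r, p0c;
      getpos(k, t - 1, pr, pc);
      getpos(k, 0, p0r, p0c);
      if (!valid[k]) {
        setpos(k, t, pr, pc);
        continue;
      }
      double dr = 0, dc = 0;
      bool ok = track_point(pyrT, grT, gcT, pyrNext, grNext, gcNext, p0r, p0c,
                            pr - p0r, pc - p0c, win_half, max_iter, eps, dr,
                            dc);
      double qr = p0r + dr, qc = p0c + dc;
      // a marker whose integration window leaves the image is untrackable
      if (!ok || qr < win_half || qr > nr - 1.0 - win_half ||
          qc < win_half || qc > nc - 1.0 - win_half) {
        valid[k] = false;
        setpos(k, t, pr, pc);
      } else {
        setpos(k, t, qr, qc);
      }
    }
  }
  return List::create(_["pos"] = pos, _["valid"] = valid);
}
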
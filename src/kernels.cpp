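#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected-component labeling on a binary mask with 4- or 8-connectivity.
// Labels are assigned in column-major scan order starting at 1.
// [[Rcpp::export]]
IntegerMatrix cc_label(const LogicalMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc2 = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int rr = cr + dr8[k], ccn = cc2 + dc8[k];
          if (rr < 0 || rr >= nr || ccn < 0 || ccn >= nc) continue;
          if (mask(rr, ccn) && lab(rr, ccn) == 0) {
            lab(rr, ccn) = next;
            stack.push_back(rr + ccn * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Sliding-window gray-level co-occurrence statistics.
// q: quantized image with integer levels in [0, levels-1]; halfw: window
// half-width; offsets: k x 2 integer matrix of (dr, dc) displacements.
// The GLCM is made symmetric, normalized per offset, and averaged over
// offsets that contribute at least one pair. Returns five maps.
// [[Rcpp::export]]
List glcm_stat_maps(const IntegerMatrix& q, int levels, int halfw,
                    const IntegerMatrix& offsets) {
  const int nr = q.nrow(), nc = q.ncol(), noff = offsets.nrow();
  NumericMatrix contrast(nr, nc), correlation(nr, nc), energy(nr, nc),
      homogeneity(nr, nc), entropy(nr, nc);
  const int ncell = levels * levels;
  std::vector<int> glcm(ncell);
  std::vector<double> acc(ncell);
  const int* qp = q.begin();
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      std::fill(acc.begin(), acc.end(), 0.0);
      int used = 0;
      const int r0 = std::max(0, r - halfw), r1 = std::min(nr - 1, r + halfw);
      const int c0 = std::max(0, c - halfw), c1 = std::min(nc - 1, c + halfw);
      for (int o = 0; o < noff; ++o) {
        const int dr = offsets(o, 0), dc = offsets(o, 1);
        std::fill(glcm.begin(), glcm.end(), 0);
        int tot = 0;
        const int ccA = std::max(c0, c0 - dc), ccB = std::min(c1, c1 - dc);
        const int rrA = std::max(r0, r0 - dr), rrB = std::min(r1, r1 - dr);
        for (int cc2 = ccA; cc2 <= ccB; ++cc2) {
          const int* colA = qp + (size_t)cc2 * nr;
          const int* colB = qp + (size_t)(cc2 + dc) * nr + dr;
          for (int rr = rrA; rr <= rrB; ++rr) {
            const int a = colA[rr], b = colB[rr];
            ++glcm[a + b * levels];
            ++glcm[b + a * levels];
            tot += 2;
          }
        }
        if (tot > 0) {
          const double inv = 1.0 / tot;
          for (int i = 0; i < ncell; ++i)
            if (glcm[i]) acc[i] += glcm[i] * inv;
          ++used;
        }
      }
      if (used == 0) { // window too small for any offset: leave zeros, energy 1
        energy(r, c) = 1.0;
        homogeneity(r, c) = 1.0;
        continue;
      }
      double con = 0, ene = 0, hom = 0, ent = 0;
      double mi = 0, mj = 0, si = 0, sj = 0, sij = 0;
      const double invu = 1.0 / used;
      for (int j = 0; j < levels; ++j) {
        for (int i = 0; i < levels; ++i) {
          const double p = acc[i + j * levels] * invu;
          if (p <= 0) continue;
          const int d = i - j;
          con += p * d * d;
          ene += p * p;
          hom += p / (1.0 + d * d);
          ent -= p * std::log2(p);
          mi += p * i;
          mj += p * j;
          si += p * i * i;
          sj += p * j * j;
          sij += p * i * j;
        }
      }
      const double vi = si - mi * mi, vj = sj - mj * mj;
      contrast(r, c) = con;
      energy(r, c) = ene;
      homogeneity(r, c) = hom;
      entropy(r, c) = ent;
      correlation(r, c) = (vi > 1e-12 && vj > 1e-12)
                              ? (sij - mi * mj) / std::sqrt(vi * vj)
                              : 0.0;
    }
  }
  return List::create(_["contrast"] = contrast, _["correlation"] = correlation,
                      _["energy"] = energy, _["homogeneity"] = homogeneity,
                      _["entropy"] = entropy);
}

// Local Shannon entropy (bits) of the windowed intensity histogram.
// Bin edges are equal-width over [lo, hi]; values are clamped into range.
// [[Rcpp::export]]
NumericMatrix entropy_map_cpp(const NumericMatrix& x, int halfw, int bins,
                              double lo, double hi) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  const double span = (hi > lo) ? (hi - lo) : 1.0;
  std::vector<double> hist(bins);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      std::fill(hist.begin(), hist.end(), 0.0);
      const int r0 = std::max(0, r - halfw), r1 = std::min(nr - 1, r + halfw);
      const int c0 = std::max(0, c - halfw), c1 = std::min(nc - 1, c + halfw);
      double n = 0;
      for (int cc2 = c0; cc2 <= c1; ++cc2) {
        for (int rr = r0; rr <= r1; ++rr) {
          int b = (int)std::floor((x(rr, cc2) - lo) / span * bins);
          if (b < 0) b = 0;
          if (b >= bins) b = bins - 1;
          hist[b] += 1.0;
          n += 1.0;
        }
      }
      double ent = 0;
      for (int b = 0; b < bins; ++b) {
        if (hist[b] > 0) {
          const double p = hist[b] / n;
          ent -= p * std::log2(p);
        }
      }
      out(r, c) = ent;
    }
  }
  return out;
}

// Stick tensor voting. Each pixel whose ridge strength exceeds
// rel_thresh * max(strength) casts orientation-aligned votes with Gaussian
// radial decay (scale sigma, radius 3*sigma) and cos^4 angular attenuation
// between the vote direction and the displacement. Returns the (lambda1 -
// lambda2) saliency of the accumulated second-order tensor.
// [[Rcpp::export]]
NumericMatrix tensor_vote_cpp(const NumericMatrix& strength,
                              const NumericMatrix& orient, double sigma,
                              double rel_thresh) {
  const int nr = strength.nrow(), nc = strength.ncol();
  NumericMatrix txx(nr, nc), txy(nr, nc), tyy(nr, nc);
  const int rad = (int)std::ceil(3.0 * sigma);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double smax = 0;
  for (int i = 0; i < nr * nc; ++i)
    if (strength[i] > smax) smax = strength[i];
  const double thr = rel_thresh * smax;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const double s = strength(r, c);
      if (s <= thr || s <= 0) continue;
      const double phi = orient(r, c);
      // unit vector along the ridge (x = column direction, y = row direction)
      const double tx = std::cos(phi), ty = std::sin(phi);
      const double vxx = tx * tx, vxy = tx * ty, vyy = ty * ty;
      const int r0 = std::max(0, r - rad), r1 = std::min(nr - 1, r + rad);
      const int c0 = std::max(0, c - rad), c1 = std::min(nc - 1, c + rad);
      for (int cc2 = c0; cc2 <= c1; ++cc2) {
        const double dx = (double)(cc2 - c);
        for (int rr = r0; rr <= r1; ++rr) {
          const double dy = (double)(rr - r);
          const double d2 = dx * dx + dy * dy;
          if (d2 > (double)rad * rad) continue;
          double w;
          if (d2 == 0) {
            w = 1.0;
          } else {
            const double dot = (dx * tx + dy * ty);
            const double c2 = dot * dot / d2; // cos^2 of angle to ridge dir
            w = std::exp(-d2 * inv2s2) * c2 * c2;
          }
          const double ws = w * s;
          txx(rr, cc2) += ws * vxx;
          txy(rr, cc2) += ws * vxy;
          tyy(rr, cc2) += ws * vyy;
        }
      }
    }
  }
  NumericMatrix sal(nr, nc);
  for (int i = 0; i < nr * nc; ++i) {
    const double a = txx[i] - tyy[i], b = txy[i];
    sal[i] = std::sqrt(a * a + 4.0 * b * b);
  }
  return sal;
}
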
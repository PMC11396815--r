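#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Offsets (drow, dcol) for the four standard GLCM directions at distance 1.
// Symmetric counting makes the sign of the offset irrelevant.
static const int DIR_DR[4] = {0, -1, -1, -1}; // 0, 45, 90, 135 degrees
static const int DIR_DC[4] = {1,  1,  0, -1};

struct TexStats {
  double mea, var, hom, con, dis, ent, sec, cor;
};

// Compute the eight GLCM statistics for one window and one direction from the
// ordered symmetric pair list (labels are 1-based gray levels). `n` is the
// number of ordered pairs; returns false when the direction yields no pairs.
static bool stats_from_pairs(const int *ii, const int *jj, int n, TexStats &s) {
  if (n == 0) return false;
  double p = 1.0 / n;
  double mea = 0.0;
  for (int k = 0; k < n; ++k) mea += ii[k];
  mea *= p;
  double var = 0.0, hom = 0.0, con = 0.0, dis = 0.0, cov = 0.0;
  for (int k = 0; k < n; ++k) {
    double di = ii[k] - mea, dj = jj[k] - mea;
    double d = ii[k] - jj[k];
    var += di * di;
    cov += di * dj;
    hom += 1.0 / (1.0 + d * d);
    con += d * d;
    dis += std::fabs(d);
  }
  var *= p; cov *= p; hom *= p; con *= p; dis *= p;
  // entropy and second moment need cell probabilities: aggregate duplicates
  double ent = 0.0, sec = 0.0;
  bool seen[24];
  for (int k = 0; k < n; ++k) seen[k] = false;
  for (int k = 0; k < n; ++k) {
    if (seen[k]) continue;
    int cnt = 1;
    for (int m = k + 1; m < n; ++m) {
      if (!seen[m] && ii[m] == ii[k] && jj[m] == jj[k]) { seen[m] = true; ++cnt; }
    }
    double pc = (double)cnt / n;
    sec += pc * pc;
    ent -= pc * std::log(pc);
  }
  s.mea = mea; s.var = var; s.hom = hom; s.con = con;
  s.dis = dis; s.ent = ent; s.sec = sec;
  s.cor = (var > 0.0) ? cov / var : 0.0; // degenerate marginal: sentinel 0
  return true;
}

//' @name texture_images_cpp
//' @title Sliding 3x3 GLCM texture images (internal)
//' @description For every interior pixel compute the eight GLCM statistics in
//'   each of the four directions at distance 1 over the 3x3 window centred on
//'   the pixel, then average the four directional values. Border pixels are NA.
//' @param q integer matrix of quantized gray levels (0-based)
//' @return list of eight numeric matrices (Mea, Var, Hom, Con, Dis, Ent, Sec, Cor)
//' @keywords internal
// [[Rcpp::export]]
List texture_images_cpp(IntegerMatrix q) {
  int nr = q.nrow(), nc = q.ncol();
  if (nr < 3 || nc < 3) stop("raster must be at least 3x3");
  NumericMatrix out[8];
  for (int f = 0; f < 8; ++f) out[f] = NumericMatrix(nr, nc);
  for (int f = 0; f < 8; ++f)
    std::fill(out[f].begin(), out[f].end(), NA_REAL);

  int ii[24], jj[24];
  for (int r = 1; r < nr - 1; ++r) {
    for (int c = 1; c < nc - 1; ++c) {
      double acc[8] = {0, 0, 0, 0, 0, 0, 0, 0};
      int ndir = 0;
      for (int d = 0; d < 4; ++d) {
        int dr = DIR_DR[d], dc = DIR_DC[d];
        int n = 0;
        for (int wr = r - 1; wr <= r + 1; ++wr) {
          for (int wc = c - 1; wc <= c + 1; ++wc) {
            int pr = wr + dr, pc = wc + dc;
            if (pr < r - 1 || pr > r + 1 || pc < c - 1 || pc > c + 1) continue;
            int a = q(wr, wc) + 1, b = q(pr, pc) + 1;
            ii[n] = a; jj[n] = b; ++n; // ordered pair
            ii[n] = b; jj[n] = a; ++n; // symmetric counterpart
          }
        }
        TexStats s;
        if (stats_from_pairs(ii, jj, n, s)) {
          acc[0] += s.mea; acc[1] += s.var; acc[2] += s.hom; acc[3] += s.con;
          acc[4] += s.dis; acc[5] += s.ent; acc[6] += s.sec; acc[7] += s.cor;
          ++ndir;
        }
      }
      if (ndir > 0)
        for (int f = 0; f < 8; ++f) out[f](r, c) = acc[f] / ndir;
    }
  }
  return List::create(
    _["Mea"] = out[0], _["Var"] = out[1], _["Hom"] = out[2], _["Con"] = out[3],
    _["Dis"] = out[4], _["Ent"] = out[5], _["Sec"] = out[6], _["Cor"] = out[7]);
}

//' @name glcm_counts_cpp
//' @title Symmetric GLCM pair counts for one window (internal)
//' @param q integer matrix of quantized gray levels (0-based)
//' @param levels number of gray levels G
//' @param drow,dcol pixel offset of the direction
//' @return G x G matrix of raw symmetric pair counts
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix glcm_counts_cpp(IntegerMatrix q, int levels, int drow, int dcol) {
  int nr = q.nrow(), nc = q.ncol();
  NumericMatrix cnt(levels, levels);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int pr = r + drow, pc = c + dcol;
      if (pr < 0 || pr >= nr || pc < 0 || pc >= nc) continue;
      int a = q(r, c), b = q(pr, pc);
      if (a < 0 || a >= levels || b < 0 || b >= levels)
        stop("gray level outside [0, levels-1]");
      cnt(a, b) += 1.0;
      cnt(b, a) += 1.0;
    }
  }
  return cnt;
}
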
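// Numerical core for radiomics feature extraction.
//
// Conventions shared with the R layer:
//  * volumes are column-major 3D arrays (dims = c(d1, d2, d3)), voxel
//    indices are 1-based at the R boundary;
//  * discretized gray levels are 1..nlevels, 0 marks out-of-mask voxels;
//  * GLCM logarithms are base 2 with 0*log(0) == 0;
//  * the shape mesh is a marching-tetrahedra isosurface (level 0.5, linear
//    interpolation) of the mask anti-aliased with a Gaussian of sigma 0.8
//    voxels; masks too small/thin for the smoothed field to reach 0.5 fall
//    back to the exact voxel-boundary mesh.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static const double ISO_LEVEL = 0.5;
static const double SMOOTH_SIGMA = 0.8;
static const int SMOOTH_RADIUS = 3;

// ---------------------------------------------------------------- utilities

static inline double log2_safe(double p) { return p > 0.0 ? std::log2(p) : 0.0; }

// type-7 (linear interpolation) quantile of a sorted vector
static double quantile7(const std::vector<double>& s, double p) {
  const int n = (int)s.size();
  if (n == 1) return s[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= n - 1) return s[n - 1];
  return s[lo] + (h - lo) * (s[lo + 1] - s[lo]);
}

// eigenvalues of a symmetric 3x3 matrix, descending
static void eigen_sym3(const double a[3][3], double eig[3]) {
  const double p1 = a[0][1] * a[0][1] + a[0][2] * a[0][2] + a[1][2] * a[1][2];
  if (p1 == 0.0) {
    eig[0] = a[0][0]; eig[1] = a[1][1]; eig[2] = a[2][2];
  } else {
    const double q = (a[0][0] + a[1][1] + a[2][2]) / 3.0;
    const double p2 = (a[0][0] - q) * (a[0][0] - q) + (a[1][1] - q) * (a[1][1] - q) +
                      (a[2][2] - q) * (a[2][2] - q) + 2.0 * p1;
    const double p = std::sqrt(p2 / 6.0);
    double b[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) b[i][j] = (a[i][j] - (i == j ? q : 0.0)) / p;
    double detb = b[0][0] * (b[1][1] * b[2][2] - b[1][2] * b[2][1]) -
                  b[0][1] * (b[1][0] * b[2][2] - b[1][2] * b[2][0]) +
                  b[0][2] * (b[1][0] * b[2][1] - b[1][1] * b[2][0]);
    double r = detb / 2.0;
    r = std::max(-1.0, std::min(1.0, r));
    const double phi = std::acos(r) / 3.0;
    eig[0] = q + 2.0 * p * std::cos(phi);
    eig[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    eig[1] = 3.0 * q - eig[0] - eig[2];
  }
  std::sort(eig, eig + 3, std::greater<double>());
  for (int i = 0; i < 3; ++i)
    if (eig[i] < 0.0 && eig[i] > -1e-12) eig[i] = 0.0;
}

// ---------------------------------------------------------- discretization

// mode 0: fixed bin count (value = count), per-ROI min/max edges
// mode 1: fixed bin width (value = width), edges anchored at 0
static void discretize_core(const std::vector<double>& x, int mode, double value,
                            std::vector<int>& bins, int& nlevels) {
  const int n = (int)x.size();
  bins.resize(n);
  double mn = x[0], mx = x[0];
  for (int i = 1; i < n; ++i) { mn = std::min(mn, x[i]); mx = std::max(mx, x[i]); }
  if (mode == 0) {
    const int nb = (int)value;
    if (mx <= mn) { std::fill(bins.begin(), bins.end(), 1); nlevels = nb; return; }
    const double w = (mx - mn) / nb;
    for (int i = 0; i < n; ++i) {
      int b = 1 + (int)std::floor((x[i] - mn) / w);
      bins[i] = std::min(b, nb);
    }
    nlevels = nb;
  } else {
    const double w = value;
    const long shift = (long)std::floor(mn / w);
    int top = 1;
    for (int i = 0; i < n; ++i) {
      int b = (int)((long)std::floor(x[i] / w) - shift) + 1;
      bins[i] = b;
      top = std::max(top, b);
    }
    nlevels = top;
  }
}

// [[Rcpp::export(name = ".cpp_discretize")]]
IntegerVector cpp_discretize(NumericVector x, int mode, double value) {
  std::vector<double> xs(x.begin(), x.end());
  std::vector<int> bins;
  int nlevels;
  discretize_core(xs, mode, value, bins, nlevels);
  IntegerVector out(bins.begin(), bins.end());
  out.attr("nlevels") = nlevels;
  return out;
}

// ------------------------------------------------------------- first order

static void first_order_core(const std::vector<double>& x, const std::vector<int>& bins,
                             int nlevels, double voxvol, double out[18]) {
  const int n = (int)x.size();
  double sum = 0.0, energy = 0.0;
  double mn = x[0], mx = x[0];
  for (int i = 0; i < n; ++i) {
    sum += x[i];
    energy += x[i] * x[i];
    mn = std::min(mn, x[i]);
    mx = std::max(mx, x[i]);
  }
  const double mean = sum / n;
  double m2 = 0.0, m3 = 0.0, m4 = 0.0, mad = 0.0;
  for (int i = 0; i < n; ++i) {
    const double d = x[i] - mean;
    m2 += d * d; m3 += d * d * d; m4 += d * d * d * d;
    mad += std::fabs(d);
  }
  m2 /= n; m3 /= n; m4 /= n; mad /= n;
  const double skew = m2 > 0.0 ? m3 / std::pow(m2, 1.5) : 0.0;
  const double kurt = m2 > 0.0 ? m4 / (m2 * m2) : 0.0;

  std::vector<double> s(x);
  std::sort(s.begin(), s.end());
  const double p10 = quantile7(s, 0.10), p25 = quantile7(s, 0.25),
               p50 = quantile7(s, 0.50), p75 = quantile7(s, 0.75),
               p90 = quantile7(s, 0.90);

  // robust MAD: values within [P10, P90]
  double rsum = 0.0; int rn = 0;
  for (int i = 0; i < n; ++i)
    if (x[i] >= p10 && x[i] <= p90) { rsum += x[i]; ++rn; }
  double rmad = 0.0;
  if (rn > 0) {
    const double rmean = rsum / rn;
    for (int i = 0; i < n; ++i)
      if (x[i] >= p10 && x[i] <= p90) rmad += std::fabs(x[i] - rmean);
    rmad /= rn;
  }

  // discretized histogram entropy / uniformity
  std::vector<double> hist(nlevels, 0.0);
  for (int i = 0; i < n; ++i) hist[bins[i] - 1] += 1.0;
  double entropy = 0.0, uniformity = 0.0;
  for (int k = 0; k < nlevels; ++k) {
    const double p = hist[k] / n;
    if (p > 0.0) { entropy -= p * std::log2(p); uniformity += p * p; }
  }

  out[0] = p10;                       // 10Percentile
  out[1] = p90;                       // 90Percentile
  out[2] = energy;                    // Energy
  out[3] = entropy;                   // Entropy
  out[4] = p75 - p25;                 // InterquartileRange
  out[5] = kurt;                      // Kurtosis
  out[6] = mx;                        // Maximum
  out[7] = mad;                       // MeanAbsoluteDeviation
  out[8] = mean;                      // Mean
  out[9] = p50;                       // Median
  out[10] = mn;                       // Minimum
  out[11] = mx - mn;                  // Range
  out[12] = rmad;                     // RobustMeanAbsoluteDeviation
  out[13] = std::sqrt(energy / n);    // RootMeanSquared
  out[14] = skew;                     // Skewness
  out[15] = voxvol * energy;          // TotalEnergy
  out[16] = uniformity;               // Uniformity
  out[17] = m2;                       // Variance (population)
}

// [[Rcpp::export(name = ".cpp_first_order")]]
NumericVector cpp_first_order(NumericVector x, IntegerVector bins, int nlevels,
                              double voxvol) {
  std::vector<double> xs(x.begin(), x.end());
  std::vector<int> bs(bins.begin(), bins.end());
  double out[18];
  first_order_core(xs, bs, nlevels, voxvol, out);
  return NumericVector(out, out + 18);
}

// -------------------------------------------------------------------- GLCM

// 22 features from one co-occurrence count matrix (ng x ng, column-major);
// counts are symmetrized and normalized here.
static void glcm_feats_core(std::vector<double>& cnt, int ng, double out[22]) {
  double tot = 0.0;
  for (int k = 0; k < ng * ng; ++k) tot += cnt[k];
  for (int k = 0; k < ng * ng; ++k) cnt[k] /= tot;

  std::vector<double> px(ng, 0.0), psum(2 * ng - 1, 0.0), pdiff(ng, 0.0);
  for (int j = 0; j < ng; ++j)
    for (int i = 0; i < ng; ++i) {
      const double p = cnt[i + ng * j];
      px[i] += p;
      psum[i + j] += p;           // i + j in 2..2ng  -> index (i+1)+(j+1)-2
      pdiff[std::abs(i - j)] += p;
    }

  double mu = 0.0;
  for (int i = 0; i < ng; ++i) mu += (i + 1) * px[i];
  double sig2 = 0.0;
  for (int i = 0; i < ng; ++i) sig2 += (i + 1 - mu) * (i + 1 - mu) * px[i];

  double autoc = 0.0, prom = 0.0, shade = 0.0, tend = 0.0, contrast = 0.0;
  double jenergy = 0.0, jentropy = 0.0, idm = 0.0, idmn = 0.0, id = 0.0, idn = 0.0;
  double invvar = 0.0, maxp = 0.0, sumsq = 0.0, hxy1 = 0.0, hxy2 = 0.0;
  for (int j = 0; j < ng; ++j)
    for (int i = 0; i < ng; ++i) {
      const double p = cnt[i + ng * j];
      const double gi = i + 1, gj = j + 1;
      const double spread = gi + gj - 2.0 * mu;
      const double d = gi - gj, ad = std::fabs(d);
      if (p > 0.0) {
        autoc += p * gi * gj;
        prom += p * spread * spread * spread * spread;
        shade += p * spread * spread * spread;
        tend += p * spread * spread;
        contrast += p * d * d;
        jenergy += p * p;
        jentropy -= p * std::log2(p);
        idm += p / (1.0 + d * d);
        idmn += p / (1.0 + d * d / (double)(ng * ng));
        id += p / (1.0 + ad);
        idn += p / (1.0 + ad / ng);
        if (i != j) invvar += p / (d * d);
        maxp = std::max(maxp, p);
        sumsq += p * (gi - mu) * (gi - mu);
        hxy1 -= p * log2_safe(px[i] * px[j]);
      }
      const double pp = px[i] * px[j];
      if (pp > 0.0) hxy2 -= pp * std::log2(pp);
    }

  double hx = 0.0;
  for (int i = 0; i < ng; ++i) hx -= px[i] > 0.0 ? px[i] * std::log2(px[i]) : 0.0;

  double davg = 0.0;
  for (int k = 0; k < ng; ++k) davg += k * pdiff[k];
  double dent = 0.0, dvar = 0.0;
  for (int k = 0; k < ng; ++k) {
    dent -= pdiff[k] > 0.0 ? pdiff[k] * std::log2(pdiff[k]) : 0.0;
    dvar += pdiff[k] * (k - davg) * (k - davg);
  }
  double sent = 0.0;
  for (int k = 0; k < 2 * ng - 1; ++k)
    sent -= psum[k] > 0.0 ? psum[k] * std::log2(psum[k]) : 0.0;

  const double corr = sig2 > 0.0 ? (autoc - mu * mu) / sig2 : 1.0;
  const double imc1 = hx > 0.0 ? (jentropy - hxy1) / hx : 0.0;
  double imc2 = 1.0 - std::exp(-2.0 * (hxy2 - jentropy));
  imc2 = imc2 < 0.0 ? 0.0 : std::sqrt(imc2);
  imc2 = std::min(imc2, 1.0);

  out[0] = autoc;      // Autocorrelation
  out[1] = mu;         // JointAverage
  out[2] = prom;       // ClusterProminence
  out[3] = shade;      // ClusterShade
  out[4] = tend;       // ClusterTendency
  out[5] = contrast;   // Contrast
  out[6] = corr;       // Correlation
  out[7] = davg;       // DifferenceAverage
  out[8] = dent;       // DifferenceEntropy
  out[9] = dvar;       // DifferenceVariance
  out[10] = jenergy;   // JointEnergy
  out[11] = jentropy;  // JointEntropy
  out[12] = imc1;      // Imc1
  out[13] = imc2;      // Imc2
  out[14] = idm;       // Idm
  out[15] = idmn;      // Idmn
  out[16] = id;        // Id
  out[17] = idn;       // Idn
  out[18] = invvar;    // InverseVariance
  out[19] = maxp;      // MaximumProbability
  out[20] = sent;      // SumEntropy
  out[21] = sumsq;     // SumSquares
}

// per-direction features from a labeled (0 = outside) gray-level volume
static NumericMatrix glcm_dir_features(const std::vector<int>& bins, const int d[3],
                                       int ng, const IntegerMatrix& dirs,
                                       bool symmetric) {
  const int ndir = dirs.nrow();
  NumericMatrix out(22, ndir);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> cnt(ng * ng);
  for (int dd = 0; dd < ndir; ++dd) {
    const int ox = dirs(dd, 0), oy = dirs(dd, 1), oz = dirs(dd, 2);
    std::fill(cnt.begin(), cnt.end(), 0.0);
    long npairs = 0;
    for (int z = 0; z < d[2]; ++z) {
      const int z2 = z + oz;
      if (z2 < 0 || z2 >= d[2]) continue;
      for (int y = 0; y < d[1]; ++y) {
        const int y2 = y + oy;
        if (y2 < 0 || y2 >= d[1]) continue;
        for (int x = 0; x < d[0]; ++x) {
          const int x2 = x + ox;
          if (x2 < 0 || x2 >= d[0]) continue;
          const int b1 = bins[x + d[0] * (y + d[1] * z)];
          if (b1 == 0) continue;
          const int b2 = bins[x2 + d[0] * (y2 + d[1] * z2)];
          if (b2 == 0) continue;
          cnt[(b1 - 1) + ng * (b2 - 1)] += 1.0;
          if (symmetric) cnt[(b2 - 1) + ng * (b1 - 1)] += 1.0;
          ++npairs;
        }
      }
    }
    if (npairs == 0) continue;
    double f[22];
    glcm_feats_core(cnt, ng, f);
    for (int k = 0; k < 22; ++k) out(k, dd) = f[k];
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_glcm_features")]]
NumericMatrix cpp_glcm_features(IntegerVector bins, IntegerVector dims, int nlevels,
                                IntegerMatrix dirs, bool symmetric) {
  std::vector<int> b(bins.begin(), bins.end());
  int d[3] = {dims[0], dims[1], dims[2]};
  return glcm_dir_features(b, d, nlevels, dirs, symmetric);
}

// -------------------------------------------------------------------- mesh

struct MeshAccum {
  double area = 0.0, vol6 = 0.0;
  std::vector<double> vx, vy, vz;  // deduplicated vertices (physical units)
  std::unordered_set<long long> seen;
  void add_vertex(double x, double y, double z, const double sp[3]) {
    const long long qx = (long long)std::llround(x * 4096.0);
    const long long qy = (long long)std::llround(y * 4096.0);
    const long long qz = (long long)std::llround(z * 4096.0);
    const long long key = (qx & 0x1FFFFF) | ((qy & 0x1FFFFF) << 21) | ((qz & 0x1FFFFF) << 42);
    if (seen.insert(key).second) {
      vx.push_back(x * sp[0]);
      vy.push_back(y * sp[1]);
      vz.push_back(z * sp[2]);
    }
  }
  // triangle in voxel coordinates, ref = point inside the surface
  void add_triangle(const double a[3], const double b[3], const double c[3],
                    const double ref[3], const double sp[3]) {
    double pa[3], pb[3], pc[3], pr[3];
    for (int k = 0; k < 3; ++k) {
      pa[k] = a[k] * sp[k]; pb[k] = b[k] * sp[k]; pc[k] = c[k] * sp[k];
      pr[k] = ref[k] * sp[k];
    }
    double u[3], v[3], nrm[3];
    for (int k = 0; k < 3; ++k) { u[k] = pb[k] - pa[k]; v[k] = pc[k] - pa[k]; }
    nrm[0] = u[1] * v[2] - u[2] * v[1];
    nrm[1] = u[2] * v[0] - u[0] * v[2];
    nrm[2] = u[0] * v[1] - u[1] * v[0];
    double cen[3], dot = 0.0;
    for (int k = 0; k < 3; ++k) {
      cen[k] = (pa[k] + pb[k] + pc[k]) / 3.0;
      dot += nrm[k] * (cen[k] - pr[k]);
    }
    const double* t1 = pb; const double* t2 = pc;
    if (dot < 0.0) { t1 = pc; t2 = pb; for (int k = 0; k < 3; ++k) nrm[k] = -nrm[k]; }
    area += 0.5 * std::sqrt(nrm[0] * nrm[0] + nrm[1] * nrm[1] + nrm[2] * nrm[2]);
    // signed volume of tetra (origin, pa, t1, t2), outward orientation
    vol6 += pa[0] * (t1[1] * t2[2] - t1[2] * t2[1]) -
            pa[1] * (t1[0] * t2[2] - t1[2] * t2[0]) +
            pa[2] * (t1[0] * t2[1] - t1[1] * t2[0]);
    add_vertex(a[0], a[1], a[2], sp);
    add_vertex(b[0], b[1], b[2], sp);
    add_vertex(c[0], c[1], c[2], sp);
  }
};

// Kuhn 6-tetrahedra decomposition of the unit cube: corner offsets per tet
static const int TET_CORNERS[6][4][3] = {
  {{0,0,0},{1,0,0},{1,1,0},{1,1,1}},
  {{0,0,0},{1,0,0},{1,0,1},{1,1,1}},
  {{0,0,0},{0,1,0},{1,1,0},{1,1,1}},
  {{0,0,0},{0,1,0},{0,1,1},{1,1,1}},
  {{0,0,0},{0,0,1},{1,0,1},{1,1,1}},
  {{0,0,0},{0,0,1},{0,1,1},{1,1,1}},
};

static void interp_point(const double p1[3], double v1, const double p2[3], double v2,
                         double out[3]) {
  const double t = (ISO_LEVEL - v1) / (v2 - v1);
  for (int k = 0; k < 3; ++k) out[k] = p1[k] + t * (p2[k] - p1[k]);
}

// marching tetrahedra over a smoothed field; cn = cropped dims
static void march_field(const std::vector<double>& f, const int cn[3],
                        const double sp[3], MeshAccum& acc) {
  const long sx = 1, sy = cn[0], sz = (long)cn[0] * cn[1];
  for (int z = 0; z + 1 < cn[2]; ++z)
    for (int y = 0; y + 1 < cn[1]; ++y)
      for (int x = 0; x + 1 < cn[0]; ++x) {
        double cv[2][2][2];
        bool anyin = false, anyout = false;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const double v = f[(x + dx) * sx + (y + dy) * sy + (z + dz) * sz];
              cv[dx][dy][dz] = v;
              if (v > ISO_LEVEL) anyin = true; else anyout = true;
            }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          double pts[4][3], vals[4];
          int ins[4], outs[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            const int* off = TET_CORNERS[t][c];
            pts[c][0] = x + off[0]; pts[c][1] = y + off[1]; pts[c][2] = z + off[2];
            vals[c] = cv[off[0]][off[1]][off[2]];
            if (vals[c] > ISO_LEVEL) ins[ni++] = c; else outs[no++] = c;
          }
          if (ni == 0 || ni == 4) continue;
          double ref[3] = {0, 0, 0};
          for (int k = 0; k < ni; ++k)
            for (int d = 0; d < 3; ++d) ref[d] += pts[ins[k]][d] / ni;
          if (ni == 1) {
            double a[3], b[3], c[3];
            interp_point(pts[ins[0]], vals[ins[0]], pts[outs[0]], vals[outs[0]], a);
            interp_point(pts[ins[0]], vals[ins[0]], pts[outs[1]], vals[outs[1]], b);
            interp_point(pts[ins[0]], vals[ins[0]], pts[outs[2]], vals[outs[2]], c);
            acc.add_triangle(a, b, c, ref, sp);
          } else if (ni == 3) {
            double a[3], b[3], c[3];
            interp_point(pts[ins[0]], vals[ins[0]], pts[outs[0]], vals[outs[0]], a);
            interp_point(pts[ins[1]], vals[ins[1]], pts[outs[0]], vals[outs[0]], b);
            interp_point(pts[ins[2]], vals[ins[2]], pts[outs[0]], vals[outs[0]], c);
            acc.add_triangle(a, b, c, ref, sp);
          } else {  // 2 in / 2 out: quad split into two triangles
            double a[3], b[3], c[3], d[3];
            interp_point(pts[ins[0]], vals[ins[0]], pts[outs[0]], vals[outs[0]], a);
            interp_point(pts[ins[0]], vals[ins[0]], pts[outs[1]], vals[outs[1]], b);
            interp_point(pts[ins[1]], vals[ins[1]], pts[outs[1]], vals[outs[1]], c);
            interp_point(pts[ins[1]], vals[ins[1]], pts[outs[0]], vals[outs[0]], d);
            acc.add_triangle(a, b, c, ref, sp);
            acc.add_triangle(a, c, d, ref, sp);
          }
        }
      }
}

// voxel-boundary mesh fallback for masks the smoothed field cannot resolve
static void voxel_mesh(const std::vector<char>& m, const int cn[3], const double sp[3],
                       MeshAccum& acc) {
  const long sy = cn[0], sz = (long)cn[0] * cn[1];
  const double face[3] = {sp[1] * sp[2], sp[0] * sp[2], sp[0] * sp[1]};
  const int nb[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  for (int z = 0; z < cn[2]; ++z)
    for (int y = 0; y < cn[1]; ++y)
      for (int x = 0; x < cn[0]; ++x) {
        if (!m[x + y * sy + z * sz]) continue;
        bool surface = false;
        for (int k = 0; k < 6; ++k) {
          const int x2 = x + nb[k][0], y2 = y + nb[k][1], z2 = z + nb[k][2];
          const bool inside = x2 >= 0 && x2 < cn[0] && y2 >= 0 && y2 < cn[1] &&
                              z2 >= 0 && z2 < cn[2] && m[x2 + y2 * sy + z2 * sz];
          if (!inside) {
            acc.area += face[k / 2];
            surface = true;
          }
        }
        acc.vol6 += 6.0 * sp[0] * sp[1] * sp[2];
        if (surface)
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx)
                acc.add_vertex(x + dx - 0.5, y + dy - 0.5, z + dz - 0.5, sp);
      }
}

// separable Gaussian smoothing of a 0/1 field (zero boundary)
static void gauss_smooth(std::vector<double>& f, const int cn[3]) {
  double w[SMOOTH_RADIUS + 1];
  double tot = 0.0;
  for (int k = 0; k <= SMOOTH_RADIUS; ++k) {
    w[k] = std::exp(-0.5 * k * k / (SMOOTH_SIGMA * SMOOTH_SIGMA));
    tot += (k == 0 ? 1.0 : 2.0) * w[k];
  }
  for (int k = 0; k <= SMOOTH_RADIUS; ++k) w[k] /= tot;
  const long stride[3] = {1, cn[0], (long)cn[0] * cn[1]};
  std::vector<double> tmp(f.size());
  for (int ax = 0; ax < 3; ++ax) {
    const long s = stride[ax];
    const int n = cn[ax];
    for (int z = 0; z < cn[2]; ++z)
      for (int y = 0; y < cn[1]; ++y)
        for (int x = 0; x < cn[0]; ++x) {
          const long idx = x + (long)cn[0] * (y + (long)cn[1] * z);
          const int pos = ax == 0 ? x : (ax == 1 ? y : z);
          double acc = w[0] * f[idx];
          for (int k = 1; k <= SMOOTH_RADIUS; ++k) {
            if (pos - k >= 0) acc += w[k] * f[idx - k * s];
            if (pos + k < n) acc += w[k] * f[idx + k * s];
          }
          tmp[idx] = acc;
        }
    f.swap(tmp);
  }
}

// Largest pairwise (weighted) squared distance over a vertex cloud.
// Exact branch-and-bound: vertices are binned into a coarse spatial grid,
// cell pairs are processed in decreasing order of a valid upper bound and
// skipped once the bound cannot beat the current best, so only pairs of
// near-antipodal cells are ever enumerated. Weights in {0, 1} select the
// coordinates that enter the distance (projection-plane diameters).
static double max_pair_dist_sq(const std::vector<double>& vx,
                               const std::vector<double>& vy,
                               const std::vector<double>& vz,
                               int wx, int wy, int wz) {
  const long n = (long)vx.size();
  if (n < 2) return 0.0;
  const double w[3] = {(double)wx, (double)wy, (double)wz};
  const std::vector<double>* vv[3] = {&vx, &vy, &vz};

  auto pair_d2 = [&](long i, long j) {
    double s = 0.0;
    for (int k = 0; k < 3; ++k) {
      if (w[k] == 0.0) continue;
      const double d = (*vv[k])[i] - (*vv[k])[j];
      s += d * d;
    }
    return s;
  };

  if (n <= 96) {
    double best = 0.0;
    for (long i = 0; i < n; ++i)
      for (long j = i + 1; j < n; ++j) best = std::max(best, pair_d2(i, j));
    return best;
  }

  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = hi[k] = (*vv[k])[0];
    for (long i = 1; i < n; ++i) {
      lo[k] = std::min(lo[k], (*vv[k])[i]);
      hi[k] = std::max(hi[k], (*vv[k])[i]);
    }
  }
  const int G = 8;
  double csize[3];
  for (int k = 0; k < 3; ++k)
    csize[k] = std::max((hi[k] - lo[k]) / G, 1e-9);
  auto cell_of = [&](long i) {
    int c[3];
    for (int k = 0; k < 3; ++k)
      c[k] = std::min(G - 1, (int)(((*vv[k])[i] - lo[k]) / csize[k]));
    return c[0] + G * (c[1] + G * c[2]);
  };
  struct Cell {
    std::vector<long> pts;
    double lo[3], hi[3];
  };
  std::vector<Cell> cells(G * G * G);
  for (long i = 0; i < n; ++i) {
    Cell& c = cells[cell_of(i)];
    if (c.pts.empty())
      for (int k = 0; k < 3; ++k) { c.lo[k] = c.hi[k] = (*vv[k])[i]; }
    else
      for (int k = 0; k < 3; ++k) {
        c.lo[k] = std::min(c.lo[k], (*vv[k])[i]);
        c.hi[k] = std::max(c.hi[k], (*vv[k])[i]);
      }
    c.pts.push_back(i);
  }
  std::vector<int> occ;
  for (int c = 0; c < G * G * G; ++c)
    if (!cells[c].pts.empty()) occ.push_back(c);

  auto cell_bound = [&](const Cell& a, const Cell& b) {
    double s = 0.0;
    for (int k = 0; k < 3; ++k) {
      if (w[k] == 0.0) continue;
      const double gap = std::max(a.hi[k] - b.lo[k], b.hi[k] - a.lo[k]);
      if (gap > 0.0) s += gap * gap;
    }
    return s;
  };

  // lower bound from one farthest-point sweep
  long far = 1;
  double best = 0.0;
  for (long i = 1; i < n; ++i) {
    const double q = pair_d2(0, i);
    if (q > best) { best = q; far = i; }
  }
  for (long i = 0; i < n; ++i) best = std::max(best, pair_d2(far, i));

  struct Job { double bound; int a, b; };
  std::vector<Job> jobs;
  for (size_t ai = 0; ai < occ.size(); ++ai)
    for (size_t bi = ai; bi < occ.size(); ++bi) {
      const double bd = cell_bound(cells[occ[ai]], cells[occ[bi]]);
      if (bd > best) jobs.push_back({bd, occ[ai], occ[bi]});
    }
  std::sort(jobs.begin(), jobs.end(),
            [](const Job& x, const Job& y) { return x.bound > y.bound; });
  for (const Job& jb : jobs) {
    if (jb.bound <= best) break;
    const std::vector<long>& pa = cells[jb.a].pts;
    const std::vector<long>& pb = cells[jb.b].pts;
    if (jb.a == jb.b) {
      for (size_t i = 0; i < pa.size(); ++i)
        for (size_t j = i + 1; j < pa.size(); ++j)
          best = std::max(best, pair_d2(pa[i], pa[j]));
    } else {
      for (size_t i = 0; i < pa.size(); ++i)
        for (size_t j = 0; j < pb.size(); ++j)
          best = std::max(best, pair_d2(pa[i], pb[j]));
    }
  }
  return best;
}

struct ShapeResult { double out[14]; };

// idx: 0-based voxel linear indices (column-major) of the mask
static ShapeResult shape_core(const std::vector<long>& idx, const int dims[3],
                              const double sp[3]) {
  const long n = (long)idx.size();
  const double voxvol = sp[0] * sp[1] * sp[2];

  // voxel coordinates and bounding box
  std::vector<int> xs(n), ys(n), zs(n);
  int lo[3] = {dims[0], dims[1], dims[2]}, hi[3] = {0, 0, 0};
  for (long i = 0; i < n; ++i) {
    const long v = idx[i];
    xs[i] = (int)(v % dims[0]);
    ys[i] = (int)((v / dims[0]) % dims[1]);
    zs[i] = (int)(v / ((long)dims[0] * dims[1]));
    lo[0] = std::min(lo[0], xs[i]); hi[0] = std::max(hi[0], xs[i]);
    lo[1] = std::min(lo[1], ys[i]); hi[1] = std::max(hi[1], ys[i]);
    lo[2] = std::min(lo[2], zs[i]); hi[2] = std::max(hi[2], zs[i]);
  }

  // population covariance of physical voxel-center coordinates
  double mean[3] = {0, 0, 0};
  for (long i = 0; i < n; ++i) {
    mean[0] += xs[i] * sp[0]; mean[1] += ys[i] * sp[1]; mean[2] += zs[i] * sp[2];
  }
  for (int k = 0; k < 3; ++k) mean[k] /= n;
  double cov[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  for (long i = 0; i < n; ++i) {
    const double d[3] = {xs[i] * sp[0] - mean[0], ys[i] * sp[1] - mean[1],
                         zs[i] * sp[2] - mean[2]};
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) cov[a][b] += d[a] * d[b];
  }
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) cov[a][b] /= n;
  double eig[3];
  eigen_sym3(cov, eig);
  const double major = 4.0 * std::sqrt(std::max(eig[0], 0.0));
  const double minor = 4.0 * std::sqrt(std::max(eig[1], 0.0));
  const double least = 4.0 * std::sqrt(std::max(eig[2], 0.0));
  const double elong = eig[0] > 0.0 ? std::sqrt(std::max(eig[1], 0.0) / eig[0]) : 0.0;
  const double flat = eig[0] > 0.0 ? std::sqrt(std::max(eig[2], 0.0) / eig[0]) : 0.0;

  // cropped mask with margin for smoothing + marching
  const int PAD = SMOOTH_RADIUS + 1;
  int cn[3];
  for (int k = 0; k < 3; ++k) cn[k] = hi[k] - lo[k] + 1 + 2 * PAD;
  std::vector<char> mask((long)cn[0] * cn[1] * cn[2], 0);
  std::vector<double> field((long)cn[0] * cn[1] * cn[2], 0.0);
  for (long i = 0; i < n; ++i) {
    const long p = (xs[i] - lo[0] + PAD) +
                   (long)cn[0] * ((ys[i] - lo[1] + PAD) +
                                  (long)cn[1] * (zs[i] - lo[2] + PAD));
    mask[p] = 1;
    field[p] = 1.0;
  }
  gauss_smooth(field, cn);
  bool resolved = false;
  for (long p = 0; p < (long)field.size() && !resolved; ++p)
    if (mask[p] && field[p] > ISO_LEVEL) resolved = true;

  MeshAccum acc;
  if (resolved) march_field(field, cn, sp, acc);
  else voxel_mesh(mask, cn, sp, acc);

  const double mesh_volume = std::fabs(acc.vol6) / 6.0;
  const double surf = acc.area;
  const double spher =
      surf > 0.0 ? std::cbrt(36.0 * M_PI * mesh_volume * mesh_volume) / surf : 0.0;

  // maximum diameters over surface vertices (exact, grid-pruned)
  const double d3 = max_pair_dist_sq(acc.vx, acc.vy, acc.vz, 1, 1, 1);
  const double dslice = max_pair_dist_sq(acc.vx, acc.vy, acc.vz, 1, 1, 0);
  const double dcol = max_pair_dist_sq(acc.vx, acc.vy, acc.vz, 0, 1, 1);
  const double drow = max_pair_dist_sq(acc.vx, acc.vy, acc.vz, 1, 0, 1);

  ShapeResult r;
  r.out[0] = elong;                           // Elongation
  r.out[1] = flat;                            // Flatness
  r.out[2] = least;                           // LeastAxisLength
  r.out[3] = major;                           // MajorAxisLength
  r.out[4] = std::sqrt(dcol);                 // Maximum2DDiameterColumn
  r.out[5] = std::sqrt(drow);                 // Maximum2DDiameterRow
  r.out[6] = std::sqrt(dslice);               // Maximum2DDiameterSlice
  r.out[7] = std::sqrt(d3);                   // Maximum3DDiameter
  r.out[8] = mesh_volume;                     // MeshVolume
  r.out[9] = minor;                           // MinorAxisLength
  r.out[10] = spher;                          // Sphericity
  r.out[11] = surf;                           // SurfaceArea
  r.out[12] = mesh_volume > 0.0 ? surf / mesh_volume : 0.0;  // SurfaceVolumeRatio
  r.out[13] = n * voxvol;                     // VoxelVolume
  return r;
}

// [[Rcpp::export(name = ".cpp_shape_features")]]
NumericVector cpp_shape_features(IntegerVector idx1, IntegerVector dims,
                                 NumericVector spacing) {
  std::vector<long> idx(idx1.size());
  for (R_xlen_t i = 0; i < idx1.size(); ++i) idx[i] = (long)idx1[i] - 1;
  int d[3] = {dims[0], dims[1], dims[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  ShapeResult r = shape_core(idx, d, sp);
  return NumericVector(r.out, r.out + 14);
}

// --------------------------------------------------- batched patient extract

// maps: named list of numeric vectors (full volumes, same dims)
// rois: list of 1-based integer voxel index vectors
// returns: numeric vector, sequence-major, then ROI, then the 54 features
// (18 first-order, 14 shape, 22 GLCM averaged over directions with pairs)
// [[Rcpp::export(name = ".cpp_extract_patient")]]
NumericVector cpp_extract_patient(List maps, List rois, IntegerVector dims,
                                  NumericVector spacing, int disc_mode,
                                  double disc_value, IntegerMatrix dirs,
                                  bool symmetric) {
  const int nseq = maps.size(), nroi = rois.size();
  const int d[3] = {dims[0], dims[1], dims[2]};
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  const double voxvol = sp[0] * sp[1] * sp[2];
  NumericVector out((R_xlen_t)nseq * nroi * 54);

  // per-ROI precomputation: indices, bbox, shape features
  std::vector<std::vector<long>> roi_idx(nroi);
  std::vector<ShapeResult> shapes(nroi);
  std::vector<std::array<int, 6>> bboxes(nroi);
  for (int r = 0; r < nroi; ++r) {
    IntegerVector iv = rois[r];
    std::vector<long>& ix = roi_idx[r];
    ix.resize(iv.size());
    int lo[3] = {d[0], d[1], d[2]}, hi[3] = {0, 0, 0};
    for (R_xlen_t i = 0; i < iv.size(); ++i) {
      const long v = (long)iv[i] - 1;
      ix[i] = v;
      const int x = (int)(v % d[0]);
      const int y = (int)((v / d[0]) % d[1]);
      const int z = (int)(v / ((long)d[0] * d[1]));
      lo[0] = std::min(lo[0], x); hi[0] = std::max(hi[0], x);
      lo[1] = std::min(lo[1], y); hi[1] = std::max(hi[1], y);
      lo[2] = std::min(lo[2], z); hi[2] = std::max(hi[2], z);
    }
    shapes[r] = shape_core(ix, d, sp);
    bboxes[r] = {lo[0], hi[0], lo[1], hi[1], lo[2], hi[2]};
  }

  std::vector<double> vals;
  std::vector<int> bins;
  for (int s = 0; s < nseq; ++s) {
    NumericVector map = maps[s];
    for (int r = 0; r < nroi; ++r) {
      const std::vector<long>& ix = roi_idx[r];
      const long n = (long)ix.size();
      vals.resize(n);
      for (long i = 0; i < n; ++i) vals[i] = map[ix[i]];
      int nlevels;
      discretize_core(vals, disc_mode, disc_value, bins, nlevels);

      double fo[18];
      first_order_core(vals, bins, nlevels, voxvol, fo);

      // cropped gray-level volume for the GLCM
      const std::array<int, 6>& bb = bboxes[r];
      const int cn[3] = {bb[1] - bb[0] + 1, bb[3] - bb[2] + 1, bb[5] - bb[4] + 1};
      std::vector<int> crop((long)cn[0] * cn[1] * cn[2], 0);
      for (long i = 0; i < n; ++i) {
        const long v = ix[i];
        const int x = (int)(v % d[0]) - bb[0];
        const int y = (int)((v / d[0]) % d[1]) - bb[2];
        const int z = (int)(v / ((long)d[0] * d[1])) - bb[4];
        crop[x + (long)cn[0] * (y + (long)cn[1] * z)] = bins[i];
      }
      NumericMatrix gf = glcm_dir_features(crop, cn, nlevels, dirs, symmetric);
      double gl[22];
      bool any_dir = false;
      for (int dd = 0; dd < gf.ncol(); ++dd)
        if (!NumericVector::is_na(gf(0, dd))) any_dir = true;
      if (any_dir) {
        for (int k = 0; k < 22; ++k) {
          double acc = 0.0;
          int nd = 0;
          for (int dd = 0; dd < gf.ncol(); ++dd)
            if (!NumericVector::is_na(gf(k, dd))) { acc += gf(k, dd); ++nd; }
          gl[k] = acc / nd;
        }
      } else {
        // degenerate-ROI policy: an ROI with no voxel pairs (isolated
        // voxel) takes the constant-image limit, i.e. a single
        // self-co-occurrence at its own gray level
        std::vector<double> cnt((long)nlevels * nlevels, 0.0);
        const int b = bins[0];
        cnt[(b - 1) + (long)nlevels * (b - 1)] = 1.0;
        glcm_feats_core(cnt, nlevels, gl);
      }

      const R_xlen_t base = ((R_xlen_t)s * nroi + r) * 54;
      for (int k = 0; k < 18; ++k) out[base + k] = fo[k];
      for (int k = 0; k < 14; ++k) out[base + 18 + k] = shapes[r].out[k];
      for (int k = 0; k < 22; ++k) out[base + 32 + k] = gl[k];
    }
  }
  return out;
}

// ------------------------------------------------- LASSO coordinate descent

// Cyclic coordinate descent for (1/2n)||y - X b||^2 + lambda ||b||_1,
// cold-started from b = 0. X columns are expected pre-standardized and y
// centered (the R wrapper handles both). Stops when the largest absolute
// coefficient change in a full pass drops below tol, or at max_iter
// passes; in the near-unpenalized p >> n regime the iteration cap is what
// keeps the otherwise ill-posed limit deterministic and stable.
// [[Rcpp::export(name = ".cpp_lasso_cd")]]
List cpp_lasso_cd(NumericMatrix X, NumericVector y, double lambda, double tol,
                  int max_iter) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> b(p, 0.0), r(y.begin(), y.end()), d(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    d[j] = s / n;
  }
  bool converged = false;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    double max_delta = 0.0;
    for (int j = 0; j < p; ++j) {
      if (d[j] == 0.0) continue;
      double rho = 0.0;
      for (int i = 0; i < n; ++i) rho += X(i, j) * r[i];
      const double z = rho / n + d[j] * b[j];
      double bn = 0.0;
      if (z > lambda) bn = (z - lambda) / d[j];
      else if (z < -lambda) bn = (z + lambda) / d[j];
      const double delta = bn - b[j];
      if (delta != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= X(i, j) * delta;
        b[j] = bn;
      }
      max_delta = std::max(max_delta, std::fabs(delta));
    }
    if (max_delta < tol) { converged = true; ++iter; break; }
  }
  return List::create(_["beta"] = NumericVector(b.begin(), b.end()),
                      _["iterations"] = iter, _["converged"] = converged);
}
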
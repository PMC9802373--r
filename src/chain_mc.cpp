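// Monte Carlo engine for a discretized, self-avoiding twistable wormlike
// chain held at fixed linking number under tension.
//
// Geometry conventions:
//   - beads 0..N-1, segment s joins beads s and s+1, all segment lengths a
//   - beads 0 and 1 are fixed (bottom tangent clamped along +z); the top
//     tangent is kept along +z by a stiff harmonic alignment energy
//   - twist is implicit: E_twist = (2 pi^2 C / L) (dLk - Wr)^2 in kBT
//   - writhe uses the open-chain convention with both termini extended to
//     long vertical rays; pairwise contributions use the exact closed-form
//     Gauss integral for straight segment pairs
//
// Moves: crankshaft rotations of an interior subchain about the axis through
// its end beads, and pivot rotations of a short top tail about a random axis
// through its base bead. Both are rigid rotations about an axis containing a
// fixed bead, so the rotated segment set is rigid and self-distances are
// preserved; excluded volume is checked by sub-stepped bead sweeps plus an
// exact segment-segment check of the final position, and any move with
// |dWr| > 0.5 is rejected as a strand-passage sentinel.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstring>
#include <cmath>
using namespace Rcpp;

static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void vcross(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double clamp1(double x) {
  return x > 1.0 ? 1.0 : (x < -1.0 ? -1.0 : x);
}

// Exact Gauss-integral writhe contribution of the ordered segment pair
// (p1->p2, q1->q2); returns Omega/(4 pi) with sign, so that
// Wr = 2 * sum over unordered non-adjacent pairs.
static double wr_pair(const double* p1, const double* p2,
                      const double* q1, const double* q2) {
  double r12[3], r34[3], r13[3], r14[3], r23[3], r24[3];
  for (int d = 0; d < 3; ++d) {
    r12[d] = p2[d] - p1[d];
    r34[d] = q2[d] - q1[d];
    r13[d] = q1[d] - p1[d];
    r14[d] = q2[d] - p1[d];
    r23[d] = q1[d] - p2[d];
    r24[d] = q2[d] - p2[d];
  }
  // area of the spherical quadrilateral spanned by the unit vectors to the
  // four endpoint combinations (two triangles, van Oosterom-Strackee)
  const double eps = 1e-14;
  double a[3], b[3], c[3], d[3];
  double la = std::sqrt(vdot(r13, r13)), lb = std::sqrt(vdot(r14, r14));
  double lc = std::sqrt(vdot(r24, r24)), ld = std::sqrt(vdot(r23, r23));
  if (la < eps || lb < eps || lc < eps || ld < eps) return 0.0;
  for (int k = 0; k < 3; ++k) {
    a[k] = r13[k] / la;
    b[k] = r14[k] / lb;
    c[k] = r24[k] / lc;
    d[k] = r23[k] / ld;
  }
  double cx[3];
  vcross(b, c, cx);
  double om = 2.0 * std::atan2(vdot(a, cx),
                               1.0 + vdot(a, b) + vdot(b, c) + vdot(a, c));
  vcross(c, d, cx);
  om += 2.0 * std::atan2(vdot(a, cx),
                         1.0 + vdot(a, c) + vdot(c, d) + vdot(a, d));
  double cr[3];
  vcross(r34, r12, cr);
  double sg = vdot(cr, r13);
  double sign = (sg > 0.0) - (sg < 0.0);
  return std::fabs(om) * sign / (4.0 * M_PI);
}

// segment endpoints, with s = -1 the bottom ray and s = N-1 the top ray
static inline void seg_ends(const double* X, int N, double ray_len, int s,
                            double* p1, double* p2) {
  if (s == -1) {
    p1[0] = X[0]; p1[1] = X[1]; p1[2] = X[2] - ray_len;
    p2[0] = X[0]; p2[1] = X[1]; p2[2] = X[2];
  } else if (s == N - 1) {
    const double* t = X + 3 * (N - 1);
    p1[0] = t[0]; p1[1] = t[1]; p1[2] = t[2];
    p2[0] = t[0]; p2[1] = t[1]; p2[2] = t[2] + ray_len;
  } else {
    const double* u = X + 3 * s;
    const double* v = X + 3 * (s + 1);
    p1[0] = u[0]; p1[1] = u[1]; p1[2] = u[2];
    p2[0] = v[0]; p2[1] = v[1]; p2[2] = v[2];
  }
}

static inline bool seg_adjacent(int s, int t, int N) {
  // rays are adjacent only to the chain segment they touch
  if (s > t) std::swap(s, t);
  if (s == -1) return t == 0;
  if (t == N - 1) return s == N - 2;
  return (t - s) <= 1;
}

// writhe of the full open chain with vertical closure rays
static double full_writhe(const double* X, int N, double ray_len) {
  double sum = 0.0;
  double p1[3], p2[3], q1[3], q2[3];
  for (int s = -1; s <= N - 2; ++s) {
    seg_ends(X, N, ray_len, s, p1, p2);
    for (int t = s + 1; t <= N - 1; ++t) {
      if (seg_adjacent(s, t, N)) continue;
      seg_ends(X, N, ray_len, t, q1, q2);
      sum += wr_pair(p1, p2, q1, q2);
    }
  }
  return 2.0 * sum;
}

// sum of pair contributions between the affected segment set
// A = chain segments [aLo..aHi] (+ the top ray if a_top) and its complement.
// Distant chain-chain pairs use midpoint quadrature of the Gauss integrand
// (the integrand decays as 1/r^2, so the far-field error is O((a/r)^2) of an
// already tiny contribution); near pairs and every pair involving a closure
// ray use the exact closed form. The full writhe is refreshed exactly at
// every sampling point.
static double wr_far2_for(double a) {
  // keep the midpoint-rule error small relative to the pair contribution
  double r = 5.0 * a;
  if (r < 18.0) r = 18.0;
  return r * r;
}

static double cross_sum(const double* X, int N, double ray_len,
                        int aLo, int aHi, bool a_top, double far2) {
  static std::vector<double> mid, tan_;
  int ns = N - 1;  // chain segments
  mid.resize(3 * ns);
  tan_.resize(3 * ns);
  for (int s = 0; s < ns; ++s) {
    for (int d = 0; d < 3; ++d) {
      double u = X[3 * s + d], v = X[3 * (s + 1) + d];
      mid[3 * s + d] = 0.5 * (u + v);
      tan_[3 * s + d] = v - u;
    }
  }
  double sum = 0.0;
  double p1[3], p2[3], q1[3], q2[3];
  for (int s = aLo; s <= aHi; ++s) {
    seg_ends(X, N, ray_len, s, p1, p2);
    const double* ms = &mid[3 * s];
    const double* ts = &tan_[3 * s];
    for (int t = -1; t <= N - 1; ++t) {
      if (t >= aLo && t <= aHi) continue;
      if (a_top && t == N - 1) continue;
      if (seg_adjacent(s, t, N)) continue;
      if (t >= 0 && t <= N - 2) {
        const double* mt = &mid[3 * t];
        double r[3] = {ms[0] - mt[0], ms[1] - mt[1], ms[2] - mt[2]};
        double d2 = vdot(r, r);
        if (d2 > far2) {
          const double* tt = &tan_[3 * t];
          double cx[3];
          vcross(ts, tt, cx);
          sum += vdot(cx, r) / (4.0 * M_PI * d2 * std::sqrt(d2));
          continue;
        }
      }
      seg_ends(X, N, ray_len, t, q1, q2);
      sum += wr_pair(p1, p2, q1, q2);
    }
  }
  if (a_top) {
    seg_ends(X, N, ray_len, N - 1, p1, p2);
    for (int t = -1; t <= aLo - 1; ++t) {
      if (seg_adjacent(N - 1, t, N)) continue;
      seg_ends(X, N, ray_len, t, q1, q2);
      sum += wr_pair(p1, p2, q1, q2);
    }
  }
  return sum;
}

// top ray against chain segments [sLo..sHi] (used for pivot moves, where the
// rotated chain segments are rigid but the vertical ray is not)
static double topray_vs(const double* X, int N, double ray_len,
                        int sLo, int sHi) {
  double sum = 0.0;
  double p1[3], p2[3], q1[3], q2[3];
  seg_ends(X, N, ray_len, N - 1, p1, p2);
  for (int t = sLo; t <= sHi; ++t) {
    if (seg_adjacent(N - 1, t, N)) continue;
    seg_ends(X, N, ray_len, t, q1, q2);
    sum += wr_pair(p1, p2, q1, q2);
  }
  return sum;
}

// squared minimal distance between segments p1-p2 and q1-q2 (Ericson)
static double segseg_d2(const double* p1, const double* p2,
                        const double* q1, const double* q2) {
  double d1[3], d2[3], r[3];
  for (int d = 0; d < 3; ++d) {
    d1[d] = p2[d] - p1[d];
    d2[d] = q2[d] - q1[d];
    r[d] = p1[d] - q1[d];
  }
  double a = vdot(d1, d1), e = vdot(d2, d2), f = vdot(d2, r);
  double c = vdot(d1, r), b = vdot(d1, d2);
  double denom = a * e - b * b;
  double s = 0.0, t = 0.0;
  if (denom > 1e-12) {
    s = (b * f - c * e) / denom;
    s = s < 0.0 ? 0.0 : (s > 1.0 ? 1.0 : s);
  }
  t = e > 1e-12 ? (b * s + f) / e : 0.0;
  if (t < 0.0) {
    t = 0.0;
    s = -c / a;
  } else if (t > 1.0) {
    t = 1.0;
    s = (b - c) / a;
  }
  s = s < 0.0 ? 0.0 : (s > 1.0 ? 1.0 : s);
  double dd = 0.0;
  for (int d = 0; d < 3; ++d) {
    double diff = (p1[d] + s * d1[d]) - (q1[d] + t * d2[d]);
    dd += diff * diff;
  }
  return dd;
}

static double point_seg_d2(const double* p, const double* q1,
                           const double* q2) {
  double d[3], r[3];
  for (int k = 0; k < 3; ++k) {
    d[k] = q2[k] - q1[k];
    r[k] = p[k] - q1[k];
  }
  double e = vdot(d, d);
  double t = e > 1e-12 ? vdot(r, d) / e : 0.0;
  t = t < 0.0 ? 0.0 : (t > 1.0 ? 1.0 : t);
  double dd = 0.0;
  for (int k = 0; k < 3; ++k) {
    double diff = r[k] - t * d[k];
    dd += diff * diff;
  }
  return dd;
}

static inline void rodrigues(const double* p, const double* O, const double* u,
                             double cth, double sth, double* out) {
  double v[3] = {p[0] - O[0], p[1] - O[1], p[2] - O[2]};
  double cr[3];
  vcross(u, v, cr);
  double du = vdot(u, v);
  for (int d = 0; d < 3; ++d) {
    out[d] = O[d] + v[d] * cth + cr[d] * sth + u[d] * du * (1.0 - cth);
  }
}

// plectoneme labels: a bead is plectonemic if some bead at contour
// separation > min_sep lies within r_thresh; smoothed by 5-bead majority
static void plect_labels(const double* X, int N, double a,
                         double min_sep, double r_thresh, int* lab) {
  int sep_beads = (int)std::ceil(min_sep / a);
  double r2 = r_thresh * r_thresh;
  std::vector<int> raw(N, 0);
  for (int i = 0; i < N; ++i) {
    for (int j = i + sep_beads + 1; j < N; ++j) {
      double dx = X[3 * i] - X[3 * j];
      double dy = X[3 * i + 1] - X[3 * j + 1];
      double dz = X[3 * i + 2] - X[3 * j + 2];
      if (dx * dx + dy * dy + dz * dz < r2) {
        raw[i] = 1;
        raw[j] = 1;
      }
    }
  }
  for (int i = 0; i < N; ++i) {
    int lo = i - 2 < 0 ? 0 : i - 2;
    int hi = i + 2 >= N ? N - 1 : i + 2;
    int cnt = 0, tot = hi - lo + 1;
    for (int k = lo; k <= hi; ++k) cnt += raw[k];
    lab[i] = (2 * cnt > tot) ? 1 : (2 * cnt < tot ? 0 : raw[i]);
  }
}

static double plect_length(const int* lab, int N, double a) {
  double lp = 0.0;
  for (int s = 0; s < N - 1; ++s) lp += 0.5 * a * (lab[s] + lab[s + 1]);
  return lp;
}

// writhe of a closed polygon (rows of X are the vertices, closed last->first)
static double closed_writhe(const double* X, int M) {
  double sum = 0.0;
  for (int s = 0; s < M; ++s) {
    const double* p1 = X + 3 * s;
    const double* p2 = X + 3 * ((s + 1) % M);
    for (int t = s + 2; t < M; ++t) {
      if (s == 0 && t == M - 1) continue;  // cyclic adjacency
      const double* q1 = X + 3 * t;
      const double* q2 = X + 3 * ((t + 1) % M);
      sum += wr_pair(p1, p2, q1, q2);
    }
  }
  return 2.0 * sum;
}

// [[Rcpp::export]]
double cpp_writhe(NumericMatrix pos, double ray_len) {
  int N = pos.nrow();
  std::vector<double> X(3 * N);
  for (int i = 0; i < N; ++i) {
    X[3 * i] = pos(i, 0);
    X[3 * i + 1] = pos(i, 1);
    X[3 * i + 2] = pos(i, 2);
  }
  return full_writhe(X.data(), N, ray_len);
}

// [[Rcpp::export]]
double cpp_writhe_closed(NumericMatrix pos) {
  int M = pos.nrow();
  std::vector<double> X(3 * M);
  for (int i = 0; i < M; ++i) {
    X[3 * i] = pos(i, 0);
    X[3 * i + 1] = pos(i, 1);
    X[3 * i + 2] = pos(i, 2);
  }
  return closed_writhe(X.data(), M);
}

// [[Rcpp::export]]
double cpp_min_nonadjacent_dist(NumericMatrix pos, int n_skip) {
  int N = pos.nrow();
  std::vector<double> X(3 * N);
  for (int i = 0; i < N; ++i) {
    X[3 * i] = pos(i, 0);
    X[3 * i + 1] = pos(i, 1);
    X[3 * i + 2] = pos(i, 2);
  }
  double best = R_PosInf;
  for (int s = 0; s < N - 1; ++s) {
    for (int t = s + n_skip + 1; t < N - 1; ++t) {
      double d2 = segseg_d2(X.data() + 3 * s, X.data() + 3 * (s + 1),
                            X.data() + 3 * t, X.data() + 3 * (t + 1));
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}

// [[Rcpp::export]]
IntegerVector cpp_plectoneme_labels(NumericMatrix pos, double a,
                                    double min_contour_sep, double r_thresh) {
  int N = pos.nrow();
  std::vector<double> X(3 * N);
  for (int i = 0; i < N; ++i) {
    X[3 * i] = pos(i, 0);
    X[3 * i + 1] = pos(i, 1);
    X[3 * i + 2] = pos(i, 2);
  }
  std::vector<int> lab(N);
  plect_labels(X.data(), N, a, min_contour_sep, r_thresh, lab.data());
  IntegerVector out(N);
  for (int i = 0; i < N; ++i) out[i] = lab[i];
  return out;
}

struct MoveStats {
  long prop_crank = 0, acc_crank = 0;
  long prop_pivot = 0, acc_pivot = 0;
  long rej_ev = 0, rej_wr = 0, rej_metro = 0, rej_bridge = 0;
};

// [[Rcpp::export]]
List cpp_mc_run(NumericMatrix pos, double a, double delta_lk,
                double A, double C, double kBT, double force,
                double excluded_diameter,
                double n_steps_d, int stride, double equil_steps_d, int seed,
                double theta_crank, double theta_pivot,
                int max_move_beads, int max_pivot_beads, double p_pivot,
                double p_pivot_long,
                int bridge_i, int bridge_j,
                double align_stiff, double plect_min_sep, double plect_radius) {
  const int N = pos.nrow();
  if (N < 6) stop("chain too short");
  const long n_steps = (long)n_steps_d;
  const long equil_steps = (long)equil_steps_d;
  const double L = (N - 1) * a;
  const double ray_len = 1000.0 * L;
  const double twist_k = 2.0 * M_PI * M_PI * C / L;  // kBT per turn^2
  const double bend_k = A / a;                       // kBT per (1 - cos)
  const double d2ex = excluded_diameter * excluded_diameter;
  const double f_red = force / kBT;                  // 1/nm
  // the hard core applies beyond a contour separation of twice the excluded
  // diameter; closer along the contour, local geometry is governed by the
  // bending potential (and such short loops are too small to be threaded)
  const int n_skip = (int)std::floor(2.0 * excluded_diameter / a + 1e-9);
  const int bead_skip = n_skip > 2 ? n_skip : 2;
  const double far2 = wr_far2_for(a);

  std::vector<double> buf1(3 * N), buf2(3 * N);
  double* X = buf1.data();
  double* Xp = buf2.data();
  for (int i = 0; i < N; ++i) {
    X[3 * i] = pos(i, 0);
    X[3 * i + 1] = pos(i, 1);
    X[3 * i + 2] = pos(i, 2);
  }

  const bool bridged = bridge_i > 0 && bridge_j > 0;
  const int bi = bridge_i - 1, bj = bridge_j - 1;  // 0-based site beads
  double pose0[4] = {0, 0, 0, 0};
  if (bridged) {
    if (bi < 1 || bj >= N - 1 || bi >= bj) stop("invalid bridge bead indices");
    double dvec[3], ti[3], tj[3];
    for (int d = 0; d < 3; ++d) {
      dvec[d] = X[3 * bj + d] - X[3 * bi + d];
      ti[d] = X[3 * (bi + 1) + d] - X[3 * bi + d];
      tj[d] = X[3 * (bj + 1) + d] - X[3 * bj + d];
    }
    pose0[0] = std::sqrt(vdot(dvec, dvec));
    pose0[1] = vdot(ti, tj);
    pose0[2] = vdot(ti, dvec);
    pose0[3] = vdot(tj, dvec);
  }

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  double Wr = full_writhe(X, N, ray_len);
  MoveStats st;

  long n_samples = n_steps / stride;
  NumericVector s_step(n_samples), s_z(n_samples), s_wr(n_samples),
      s_lp(n_samples), s_looplk(n_samples);
  std::vector<int> lab(N);
  long isample = 0;

  const double max_sweep_disp = 2.0;  // nm per excluded-volume substep
  const double theta_sub_cap = 10.0 * M_PI / 180.0;

  auto attempt_move = [&]() {
    double mv = unif(rng);
    bool pivot = mv < p_pivot + p_pivot_long;
    bool long_pivot = mv < p_pivot_long;
    int mlo, mhi;          // moved bead range (inclusive)
    int aLo, aHi;          // affected chain segments
    double O[3], axis[3], theta;
    int joint_b = -1, joint_b2 = -1;

    if (!pivot) {
      st.prop_crank++;
      int i = 1 + (int)(unif(rng) * (N - 3));
      if (i > N - 3) i = N - 3;
      int maxlen = N - 2 - i;
      if (maxlen > max_move_beads) maxlen = max_move_beads;
      if (maxlen < 1) return;
      int len = 1 + (int)(unif(rng) * maxlen);
      if (len > maxlen) len = maxlen;
      int j = i + len + 1;
      mlo = i + 1; mhi = j - 1;
      aLo = i; aHi = j - 1;
      joint_b = i; joint_b2 = j;
      if (bridged) {
        bool in_i = bi >= mlo && bi + 1 <= mhi;
        bool in_j = bj >= mlo && bj + 1 <= mhi;
        bool touch = !(bi + 1 < mlo || bi > mhi) || !(bj + 1 < mlo || bj > mhi);
        if (touch && !(in_i && in_j)) {
          st.rej_bridge++;
          return;
        }
      }
      for (int d = 0; d < 3; ++d) {
        O[d] = X[3 * i + d];
        axis[d] = X[3 * j + d] - X[3 * i + d];
      }
      double an = std::sqrt(vdot(axis, axis));
      if (an < 1e-9) return;
      for (int d = 0; d < 3; ++d) axis[d] /= an;
      theta = (2.0 * unif(rng) - 1.0) * theta_crank;
    } else {
      st.prop_pivot++;
      int k;
      if (long_pivot) {
        // base anywhere: rotates the whole upper chain, moving extension
        // (and contour slack) in large strides
        k = 2 + (int)(unif(rng) * (N - 4));
        if (k > N - 3) k = N - 3;
      } else {
        int tail = 1 + (int)(unif(rng) * max_pivot_beads);
        if (tail > max_pivot_beads) tail = max_pivot_beads;
        k = N - 1 - tail;
        if (k < 2) k = 2;
      }
      int tail = N - 1 - k;
      mlo = k + 1; mhi = N - 1;
      aLo = k; aHi = N - 2;
      joint_b = k;
      if (bridged) {
        // tail must lie fully above both sites (k >= bj+1) or move both
        // sites plus their tangent beads rigidly (k <= bi-1)
        if (!(k >= bj + 1 || k <= bi - 1)) {
          st.rej_bridge++;
          return;
        }
      }
      for (int d = 0; d < 3; ++d) O[d] = X[3 * k + d];
      // random axis, uniform on the sphere
      double zz = 2.0 * unif(rng) - 1.0, phi = 2.0 * M_PI * unif(rng);
      double rr = std::sqrt(std::max(0.0, 1.0 - zz * zz));
      axis[0] = rr * std::cos(phi);
      axis[1] = rr * std::sin(phi);
      axis[2] = zz;
      // longer tails get smaller angles; the proposal stays symmetric
      theta = (2.0 * unif(rng) - 1.0) * theta_pivot / std::sqrt((double)tail);
    }

    // lever arms for the sweep substep count
    double rmax2 = 0.0;
    for (int b = mlo; b <= mhi; ++b) {
      double v[3] = {X[3 * b] - O[0], X[3 * b + 1] - O[1], X[3 * b + 2] - O[2]};
      double du = vdot(axis, v);
      double r2 = vdot(v, v) - du * du;
      if (r2 > rmax2) rmax2 = r2;
    }
    double rmax = std::sqrt(std::max(rmax2, 0.0));
    double th_sub = theta_sub_cap;
    if (rmax > 1e-9) {
      double cap2 = max_sweep_disp / rmax;
      if (cap2 < th_sub) th_sub = cap2;
    }
    int n_sub = (int)std::ceil(std::fabs(theta) / th_sub);
    if (n_sub < 1) n_sub = 1;

    // sub-stepped sweep: moved beads vs static beads (skip contour
    // neighbours within 2; true excluded volume is the segment check below)
    bool collide = false;
    double tmp[3];
    bool sites_static = bridged && !(bi >= mlo && bi <= mhi);
    for (int ss = 1; ss <= n_sub && !collide; ++ss) {
      double th = theta * ss / n_sub;
      double cth = std::cos(th), sth = std::sin(th);
      for (int b = mlo; b <= mhi && !collide; ++b) {
        rodrigues(X + 3 * b, O, axis, cth, sth, tmp);
        for (int b2 = 0; b2 < N; ++b2) {
          if (b2 >= mlo && b2 <= mhi) continue;
          if (std::abs(b2 - b) <= bead_skip) continue;
          double dx = tmp[0] - X[3 * b2];
          double dy = tmp[1] - X[3 * b2 + 1];
          double dz = tmp[2] - X[3 * b2 + 2];
          if (dx * dx + dy * dy + dz * dz < d2ex) {
            collide = true;
            break;
          }
        }
        // the protein bridge itself is a hard obstacle: no moved bead may
        // sweep through the gate between the two bridged sites
        if (!collide && sites_static && std::abs(b - bi) > 1 &&
            std::abs(b - bj) > 1) {
          if (point_seg_d2(tmp, X + 3 * bi, X + 3 * bj) < d2ex) {
            collide = true;
          }
        }
      }
    }
    if (collide) {
      st.rej_ev++;
      return;
    }

    // proposal coordinates
    std::memcpy(Xp, X, sizeof(double) * 3 * N);
    {
      double cth = std::cos(theta), sth = std::sin(theta);
      for (int b = mlo; b <= mhi; ++b) {
        rodrigues(X + 3 * b, O, axis, cth, sth, Xp + 3 * b);
      }
    }

    // exact excluded-volume check: moved segments vs static segments
    for (int s = aLo; s <= aHi && !collide; ++s) {
      for (int t = 0; t < N - 1; ++t) {
        if (t >= aLo && t <= aHi) continue;
        if (std::abs(t - s) <= n_skip) continue;
        if (segseg_d2(Xp + 3 * s, Xp + 3 * (s + 1),
                      Xp + 3 * t, Xp + 3 * (t + 1)) < d2ex) {
          collide = true;
          break;
        }
      }
    }
    // the bridge chord blocks the gate: check it against every chain
    // segment that does not touch a site bead (using the proposal
    // coordinates, which are correct whether or not the sites moved)
    if (bridged && !collide) {
      for (int t = 0; t < N - 1 && !collide; ++t) {
        bool moved_t = t >= aLo && t <= aHi;
        bool sites_moved = !sites_static;
        // only pairs whose relative geometry changed need checking
        if (moved_t == sites_moved) continue;
        if (std::abs(t - bi) <= 1 || std::abs(t - bj) <= 1) continue;
        if (segseg_d2(Xp + 3 * bi, Xp + 3 * bj,
                      Xp + 3 * t, Xp + 3 * (t + 1)) < d2ex) {
          collide = true;
        }
      }
    }
    if (collide) {
      st.rej_ev++;
      return;
    }

    // writhe change from pairs involving the affected segments
    double wr_old = cross_sum(X, N, ray_len, aLo, aHi, pivot, far2);
    double wr_new = cross_sum(Xp, N, ray_len, aLo, aHi, pivot, far2);
    if (pivot) {
      wr_old += topray_vs(X, N, ray_len, aLo, N - 3);
      wr_new += topray_vs(Xp, N, ray_len, aLo, N - 3);
    }
    double dWr = 2.0 * (wr_new - wr_old);
    if (std::fabs(dWr) > 0.5) {
      st.rej_wr++;
      return;
    }

    // local energy change (kBT)
    double dE = 0.0;
    {
      auto joint_cos = [&](const double* Y, int b) {
        const double* u0 = Y + 3 * (b - 1);
        const double* u1 = Y + 3 * b;
        const double* u2 = Y + 3 * (b + 1);
        double t1[3] = {u1[0] - u0[0], u1[1] - u0[1], u1[2] - u0[2]};
        double t2[3] = {u2[0] - u1[0], u2[1] - u1[1], u2[2] - u1[2]};
        return vdot(t1, t2) / (a * a);
      };
      dE += bend_k * (joint_cos(X, joint_b) - joint_cos(Xp, joint_b));
      if (joint_b2 > 0) {
        dE += bend_k * (joint_cos(X, joint_b2) - joint_cos(Xp, joint_b2));
      }
      if (pivot) {
        double tz_old = (X[3 * (N - 1) + 2] - X[3 * (N - 2) + 2]) / a;
        double tz_new = (Xp[3 * (N - 1) + 2] - Xp[3 * (N - 2) + 2]) / a;
        dE += align_stiff * (tz_old - tz_new);
        dE -= f_red * (Xp[3 * (N - 1) + 2] - X[3 * (N - 1) + 2]);
      }
      double tw_old = delta_lk - Wr;
      double tw_new = delta_lk - (Wr + dWr);
      dE += twist_k * (tw_new * tw_new - tw_old * tw_old);
    }

    if (dE <= 0.0 || unif(rng) < std::exp(-dE)) {
      std::swap(X, Xp);
      Wr += dWr;
      if (pivot) st.acc_pivot++; else st.acc_crank++;
    } else {
      st.rej_metro++;
    }
  };

  for (long step = 1; step <= equil_steps + n_steps; ++step) {
    attempt_move();

    if (step > equil_steps && (step - equil_steps) % stride == 0 &&
        isample < n_samples) {
      Wr = full_writhe(X, N, ray_len);  // also kills incremental drift
      plect_labels(X, N, a, plect_min_sep, plect_radius, lab.data());
      s_step[isample] = (double)(step - equil_steps);
      s_z[isample] = X[3 * (N - 1) + 2];
      s_wr[isample] = Wr;
      s_lp[isample] = plect_length(lab.data(), N, a);
      if (bridged) {
        int M = bj - bi + 1;
        double lw = closed_writhe(X + 3 * bi, M);
        double dl = (bj - bi) * a;
        s_looplk[isample] = lw + (delta_lk - Wr) * dl / L;
        // verify the bridge pose is intact
        double dvec[3], ti[3], tj[3];
        for (int d = 0; d < 3; ++d) {
          dvec[d] = X[3 * bj + d] - X[3 * bi + d];
          ti[d] = X[3 * (bi + 1) + d] - X[3 * bi + d];
          tj[d] = X[3 * (bj + 1) + d] - X[3 * bj + d];
        }
        double drift =
            std::fabs(std::sqrt(vdot(dvec, dvec)) - pose0[0]) +
            std::fabs(vdot(ti, tj) - pose0[1]) +
            std::fabs(vdot(ti, dvec) - pose0[2]) +
            std::fabs(vdot(tj, dvec) - pose0[3]);
        if (drift > 1e-6) {
          stop("bridge constraint violated during simulation (pose drift %g "
               "at step %ld)", drift, step);
        }
      } else {
        s_looplk[isample] = NA_REAL;
      }
      isample++;
    }
  }

  NumericMatrix out_pos(N, 3);
  for (int i = 0; i < N; ++i) {
    out_pos(i, 0) = X[3 * i];
    out_pos(i, 1) = X[3 * i + 1];
    out_pos(i, 2) = X[3 * i + 2];
  }
  return List::create(
      _["step"] = s_step, _["z"] = s_z, _["wr"] = s_wr, _["lp"] = s_lp,
      _["loop_lk"] = s_looplk, _["positions"] = out_pos,
      _["wr_final"] = full_writhe(X, N, ray_len),
      _["acceptance"] = List::create(
          _["proposed_crankshaft"] = (double)st.prop_crank,
          _["accepted_crankshaft"] = (double)st.acc_crank,
          _["proposed_pivot"] = (double)st.prop_pivot,
          _["accepted_pivot"] = (double)st.acc_pivot,
          _["rejected_excluded_volume"] = (double)st.rej_ev,
          _["rejected_writhe_sentinel"] = (double)st.rej_wr,
          _["rejected_metropolis"] = (double)st.rej_metro,
          _["rejected_bridge"] = (double)st.rej_bridge));
}
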
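// Event-driven stochastic simulation of one growing lac operon cell.
//
// Exact SSA over the 25-reaction network with a piecewise-constant-volume
// approximation: the cell volume grows deterministically as
// V(t) = V0 * exp(g (t - t0)), and the volume-dependent propensity
// prefactors are refreshed after every refresh_dt minutes of silence as
// well as after every reaction event (events are so frequent that the
// volume moves by far less than refresh_dt * g between refreshes).
// DNA-duplication and division hazards enter the same total hazard.
// The kernel simulates from birth (or an arbitrary mid-cycle state) until
// the division event fires or t_end is reached; partitioning is done by
// the R caller so that one partitioning implementation serves all engines.
//
// Fast path RNG: xoshiro256++ seeded from R's RNG at entry, so runs are
// reproducible under set.seed() while the inner loop stays cheap.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

namespace {

// ---- xoshiro256++ ----------------------------------------------------
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0,1); never exactly 0
  double runif() {
    double u = (next() >> 11) * 0x1.0p-53;
    return u > 0.0 ? u : 0x1.0p-53;
  }
};

// parameter-vector layout (must match .PV_NAMES on the R side)
enum {
  P_k_sMR, P_k_sR, P_k_2R, P_k_m2R, P_k_r, P_k_mr,
  P_k_dr1, P_k_mdr1, P_k_dr2, P_k_mdr2,
  P_k_s1MY, P_k_s0MY, P_k_sY, P_k_p, P_k_mp, P_k_ft,
  P_ht_um, P_l_MR, P_l_MY, P_l_R, P_l_R2, P_l_Y, P_l_YIex, P_l_I2R2,
  P_I_ex, P_g, P_n_d, P_V_d_crit, P_q, P_n_s, P_V_s_crit, P_R0,
  P_N
};

// species indices
enum { MR, R, R2, O, R2O, I, I2R2, MY, Y, YIex };

// stoichiometry: per reaction, list of (species, delta)
struct Change { int sp; int d; };
static const Change STO[25][4] = {
  /* 1*/ {{MR, +1}, {-1, 0}, {-1, 0}, {-1, 0}},
  /* 2*/ {{R, +1}, {-1, 0}, {-1, 0}, {-1, 0}},
  /* 3*/ {{R, -2}, {R2, +1}, {-1, 0}, {-1, 0}},
  /* 4*/ {{R, +2}, {R2, -1}, {-1, 0}, {-1, 0}},
  /* 5*/ {{R2, -1}, {O, -1}, {R2O, +1}, {-1, 0}},
  /* 6*/ {{R2, +1}, {O, +1}, {R2O, -1}, {-1, 0}},
  /* 7*/ {{I, -2}, {R2O, -1}, {I2R2, +1}, {O, +1}},
  /* 8*/ {{I, +2}, {R2O, +1}, {I2R2, -1}, {O, -1}},
  /* 9*/ {{I, -2}, {R2, -1}, {I2R2, +1}, {-1, 0}},
  /*10*/ {{I, +2}, {R2, +1}, {I2R2, -1}, {-1, 0}},
  /*11*/ {{MY, +1}, {-1, 0}, {-1, 0}, {-1, 0}},
  /*12*/ {{MY, +1}, {-1, 0}, {-1, 0}, {-1, 0}},
  /*13*/ {{Y, +1}, {-1, 0}, {-1, 0}, {-1, 0}},
  /*14*/ {{Y, -1}, {YIex, +1}, {-1, 0}, {-1, 0}},
  /*15*/ {{Y, +1}, {YIex, -1}, {-1, 0}, {-1, 0}},
  /*16*/ {{Y, +1}, {I, +1}, {YIex, -1}, {-1, 0}},
  /*17*/ {{I, +1}, {-1, 0}, {-1, 0}, {-1, 0}},
  /*18*/ {{I, -1}, {-1, 0}, {-1, 0}, {-1, 0}},
  /*19*/ {{MR, -1}, {-1, 0}, {-1, 0}, {-1, 0}},
  /*20*/ {{MY, -1}, {-1, 0}, {-1, 0}, {-1, 0}},
  /*21*/ {{R, -1}, {-1, 0}, {-1, 0}, {-1, 0}},
  /*22*/ {{R2, -1}, {-1, 0}, {-1, 0}, {-1, 0}},
  /*23*/ {{Y, -1}, {-1, 0}, {-1, 0}, {-1, 0}},
  /*24*/ {{YIex, -1}, {-1, 0}, {-1, 0}, {-1, 0}},
  /*25*/ {{I, +2}, {I2R2, -1}, {-1, 0}, {-1, 0}}
};

// reactions whose propensity reads a given species
static const int DEP[10][8] = {
  /*MR*/   {1, 18, -1, -1, -1, -1, -1, -1},
  /*R*/    {2, 20, -1, -1, -1, -1, -1, -1},
  /*R2*/   {3, 4, 8, 21, -1, -1, -1, -1},
  /*O*/    {4, 7, 10, -1, -1, -1, -1, -1},
  /*R2O*/  {5, 6, 11, -1, -1, -1, -1, -1},
  /*I*/    {6, 8, 17, -1, -1, -1, -1, -1},
  /*I2R2*/ {7, 9, 24, -1, -1, -1, -1, -1},
  /*MY*/   {12, 19, -1, -1, -1, -1, -1, -1},
  /*Y*/    {13, 22, -1, -1, -1, -1, -1, -1},
  /*YIex*/ {14, 15, 23, -1, -1, -1, -1, -1}
};

struct Kernel {
  const double *p;    // parameter vector
  double x[10];       // copy numbers (held in doubles, always integral)
  double Om, AoV;     // volume-dependent scales (refreshed)
  double a[27];       // 25 reaction propensities + a_s + a_d
  double a0;          // running total (rebuilt at every refresh)
  bool duplicated;

  // volume-scaled rate prefactors, recomputed only at refreshes
  double c_2R, c_r, c_dr1, c_mdr2, c_dr2, c_ht, c_kp_Iex;

  void refresh_volume(double V, double R0) {
    Om  = 6.02214076e23 * V * 1e-24;
    AoV = 2.0 / R0 + (4.0 / 3.0) * M_PI * R0 * R0 / V;
    const double inv = 1.0 / Om, inv2 = inv * inv;
    c_2R   = p[P_k_2R] * inv;
    c_r    = p[P_k_r] * inv;
    c_dr1  = p[P_k_dr1] * inv2;
    c_mdr2 = p[P_k_mdr2] * inv;
    c_dr2  = p[P_k_dr2] * inv2;
    c_ht   = p[P_ht_um] * AoV;
    c_kp_Iex = p[P_k_p] * p[P_I_ex];
  }
  double prop(int j) const {
    switch (j) {
      case 0:  return p[P_k_sMR] * Om;
      case 1:  return p[P_k_sR] * x[MR];
      case 2:  return c_2R * x[R] * (x[R] - 1.0);
      case 3:  return p[P_k_m2R] * x[R2];
      case 4:  return c_r * x[R2] * x[O];
      case 5:  return p[P_k_mr] * x[R2O];
      case 6:  return c_dr1 * x[I] * (x[I] - 1.0) * x[R2O];
      case 7:  return c_mdr2 * x[I2R2] * x[O];
      case 8:  return c_dr2 * x[I] * (x[I] - 1.0) * x[R2];
      case 9:  return p[P_k_mdr1] * x[I2R2];
      case 10: return p[P_k_s1MY] * x[O];
      case 11: return p[P_k_s0MY] * x[R2O];
      case 12: return p[P_k_sY] * x[MY];
      case 13: return c_kp_Iex * x[Y];
      case 14: return p[P_k_mp] * x[YIex];
      case 15: return p[P_k_ft] * x[YIex];
      case 16: return c_ht * p[P_I_ex] * Om;
      case 17: return c_ht * x[I];
      case 18: return p[P_l_MR] * x[MR];
      case 19: return p[P_l_MY] * x[MY];
      case 20: return p[P_l_R] * x[R];
      case 21: return p[P_l_R2] * x[R2];
      case 22: return p[P_l_Y] * x[Y];
      case 23: return p[P_l_YIex] * x[YIex];
      case 24: return p[P_l_I2R2] * x[I2R2];
      default: return 0.0;
    }
  }
  void refresh_all(double V) {
    refresh_volume(V, p[P_R0]);
    for (int j = 0; j < 25; ++j) a[j] = prop(j);
    double g = p[P_g];
    a[25] = duplicated ? 0.0
      : g * p[P_n_s] * std::pow(V / p[P_V_s_crit], p[P_n_s]);
    a[26] = duplicated
      ? g * p[P_n_d] * std::pow(V / p[P_V_d_crit], p[P_n_d])
      : 0.0;
    a0 = 0.0;
    for (int j = 0; j < 27; ++j) a0 += a[j];
  }
  void apply(int j) {
    for (int k = 0; k < 4; ++k) {
      if (STO[j][k].sp < 0) break;
      x[STO[j][k].sp] += STO[j][k].d;
    }
    for (int k = 0; k < 4; ++k) {
      int sp = STO[j][k].sp;
      if (sp < 0) break;
      for (int m = 0; m < 8 && DEP[sp][m] >= 0; ++m) {
        int r = DEP[sp][m];
        double anew = prop(r);
        a0 += anew - a[r];
        a[r] = anew;
      }
    }
  }
};

} // namespace

static Rcpp::List ssa_cell(Rcpp::NumericVector x0, double V0,
                           bool duplicated0, double t0, double t_end,
                           Rcpp::NumericVector pv,
                           Rcpp::NumericVector sample_times,
                           double refresh_dt) {
  if (x0.size() != 10 || pv.size() != P_N)
    Rcpp::stop("bad state or parameter vector length");
  if (t_end <= t0) Rcpp::stop("t_end must exceed the start time");

  Kernel K;
  K.p = REAL(pv);
  for (int i = 0; i < 10; ++i) {
    K.x[i] = x0[i];
    if (K.x[i] < 0 || K.x[i] != std::floor(K.x[i]))
      Rcpp::stop("state corruption: negative or non-integer copy number");
  }
  K.duplicated = duplicated0;

  // seed the fast stream from R's RNG (reproducible under set.seed)
  uint64_t seed = (uint64_t)(unif_rand() * 4294967296.0) << 32
                | (uint64_t)(unif_rand() * 4294967296.0);
  Xoshiro rng(seed);

  const double g = K.p[P_g];
  double t = t0;
  double V = V0;
  K.refresh_all(V);

  const int ns = sample_times.size();
  Rcpp::NumericMatrix samples(ns, 12);  // time, V, x[10]
  int si = 0;
  auto record_until = [&](double tnew) {
    while (si < ns && sample_times[si] <= tnew) {
      double ts = sample_times[si];
      samples(si, 0) = ts;
      samples(si, 1) = V0 * std::exp(g * (ts - t0));
      for (int i = 0; i < 10; ++i) samples(si, 2 + i) = K.x[i];
      ++si;
    }
  };

  double t_dup = NA_REAL, t_div = NA_REAL;
  long long n_events = 0, n_refresh = 0;
  bool divided = false;

  // selection scan order: kept sorted by decreasing propensity at each
  // refresh so the linear search stays short
  int ORD[27];
  for (int j = 0; j < 27; ++j) ORD[j] = j;
  auto resort = [&]() {
    for (int i = 1; i < 27; ++i) {        // insertion sort: nearly sorted
      int key = ORD[i];
      double ak = K.a[key];
      int m = i - 1;
      while (m >= 0 && K.a[ORD[m]] < ak) { ORD[m + 1] = ORD[m]; --m; }
      ORD[m + 1] = key;
    }
  };
  resort();

  double t_refresh = t0 + refresh_dt;   // absolute refresh grid
  while (t < t_end) {
    if (t_refresh > t_end) t_refresh = t_end;
    double a0 = K.a0;
    if (!R_FINITE(a0)) Rcpp::stop("propensity overflow at t = %g", t);
    double tau = (a0 > 0.0) ? -std::log(rng.runif()) / a0 : R_PosInf;
    if (t + tau >= t_refresh) {
      // advance to the refresh point and re-evaluate volume prefactors
      record_until(t_refresh);
      t = t_refresh;
      t_refresh += refresh_dt;
      V = V0 * std::exp(g * (t - t0));
      K.refresh_all(V);
      resort();
      ++n_refresh;
      continue;
    }
    t += tau;
    record_until(t);
    // select event
    double r = rng.runif() * a0;
    int j = -1;
    for (int m = 0; m < 27; ++m) {
      double aj = K.a[ORD[m]];
      if (r < aj) { j = ORD[m]; break; }
      r -= aj;
    }
    if (j < 0) continue;  // rounding residue in the running total: no event
    if (j < 25) {
      K.apply(j);
      ++n_events;
    } else if (j == 25) {          // DNA duplication: new operator unit free
      K.x[O] += 1;
      K.duplicated = true;
      t_dup = t;
      V = V0 * std::exp(g * (t - t0));
      K.refresh_all(V);
    } else {                       // division
      t_div = t;
      divided = true;
      break;
    }
    if ((n_events & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  if (!divided) record_until(t_end);
  double t_stop = divided ? t_div : t_end;
  double V_stop = V0 * std::exp(g * (t_stop - t0));
  Rcpp::NumericVector xout(10);
  for (int i = 0; i < 10; ++i) xout[i] = K.x[i];

  return Rcpp::List::create(
    Rcpp::Named("divided") = divided,
    Rcpp::Named("t_stop") = t_stop,
    Rcpp::Named("V_stop") = V_stop,
    Rcpp::Named("x") = xout,
    Rcpp::Named("duplicated") = K.duplicated,
    Rcpp::Named("t_dup") = t_dup,
    Rcpp::Named("n_samples") = si,
    Rcpp::Named("samples") = samples,
    Rcpp::Named("n_events") = n_events,
    Rcpp::Named("n_refresh") = n_refresh
  );
}

// manual .Call binding (registration lives in init.c so that the deSolve
// right-hand-side symbols stay visible alongside the Rcpp entry point)
extern "C" SEXP c_ssa_cell(SEXP x0, SEXP V0, SEXP dup0, SEXP t0, SEXP t_end,
                           SEXP pv, SEXP sample_times, SEXP refresh_dt) {
  BEGIN_RCPP
  Rcpp::RNGScope rngScope;
  return Rcpp::wrap(ssa_cell(Rcpp::NumericVector(x0),
                             Rcpp::as<double>(V0), Rcpp::as<bool>(dup0),
                             Rcpp::as<double>(t0), Rcpp::as<double>(t_end),
                             Rcpp::NumericVector(pv),
                             Rcpp::NumericVector(sample_times),
                             Rcpp::as<double>(refresh_dt)));
  END_RCPP
}
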
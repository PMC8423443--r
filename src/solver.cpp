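// Implicit-Euler core for pairwise toxin-warfare competitions.
//
// State y = (C_A, C_B, T_A, T_B, N).  Each backward-Euler step solves
//   y_{n+1} = y_n + h * F(y_{n+1})
// by Newton iteration with the analytic 5x5 Jacobian.  Toxin investments
// f_A, f_B are evaluated from the state at the *start* of each step
// (Heaviside regulation stays outside the implicit solve) and held
// constant through the step.  After each step: any state variable below
// the clamp threshold is set to 0, then any strain biomass below the
// extinction threshold is set to 0 permanently.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Eco {
  double K, mu, k, lT, N0, C0A, C0B, tEnd, extThr, clampThr, dt;
  int substeps;  // integration substeps per rule interval dt
};

static Eco as_eco(const NumericVector& p) {
  Eco e;
  e.K = p[0]; e.mu = p[1]; e.k = p[2]; e.lT = p[3]; e.N0 = p[4];
  e.C0A = p[5]; e.C0B = p[6]; e.tEnd = p[7];
  e.extThr = p[8]; e.clampThr = p[9]; e.dt = p[10];
  e.substeps = (p.size() > 11) ? (int) p[11] : 1;
  if (e.substeps < 1) e.substeps = 1;
  return e;
}

// mode: 0 constitutive, 1 nutrient sensing, 2 toxin sensing, 3 quorum sensing
struct Strat { int mode; double f, fi, fd, thr; };

static Strat as_strat(const NumericVector& s) {
  Strat t;
  t.mode = (int) s[0]; t.f = s[1]; t.fi = s[2]; t.fd = s[3]; t.thr = s[4];
  return t;
}

// Realised investment under the on/off switch; H(0) = 1.
static inline double invest(const Strat& s, double Cown, double Topp,
                            double N, double N0) {
  double sig;
  switch (s.mode) {
  case 0: return s.f;
  case 1: sig = (N0 - N) - s.thr; break;   // nutrient depletion
  case 2: sig = Topp - s.thr; break;       // opponent toxin
  case 3: sig = Cown - s.thr; break;       // own biomass (quorum)
  default: stop("unknown strategy mode code: %d", s.mode);
  }
  return (sig >= 0.0) ? s.fd : s.fi;
}

// Gaussian elimination with partial pivoting, in place; x enters as rhs.
static bool solve5(double A[5][5], double x[5]) {
  int piv[5] = {0, 1, 2, 3, 4};
  for (int c = 0; c < 5; ++c) {
    int best = c;
    double amax = std::fabs(A[piv[c]][c]);
    for (int r = c + 1; r < 5; ++r) {
      double a = std::fabs(A[piv[r]][c]);
      if (a > amax) { amax = a; best = r; }
    }
    if (amax < 1e-300) return false;
    std::swap(piv[c], piv[best]);
    double d = A[piv[c]][c];
    for (int r = c + 1; r < 5; ++r) {
      double m = A[piv[r]][c] / d;
      if (m != 0.0) {
        for (int cc = c; cc < 5; ++cc) A[piv[r]][cc] -= m * A[piv[c]][cc];
        x[piv[r]] -= m * x[piv[c]];
      }
    }
  }
  double out[5];
  for (int c = 4; c >= 0; --c) {
    double s = x[piv[c]];
    for (int cc = c + 1; cc < 5; ++cc) s -= A[piv[c]][cc] * out[cc];
    out[c] = s / A[piv[c]][c];
  }
  for (int i = 0; i < 5; ++i) x[i] = out[i];
  return true;
}

// One Newton-solved backward-Euler step; writes into y only on convergence.
static bool be_step(double y[5], double h, double fA, double fB, const Eco& e) {
  double z[5];
  for (int i = 0; i < 5; ++i) z[i] = y[i];
  for (int it = 0; it < 50; ++it) {
    double CA = z[0], CB = z[1], TA = z[2], TB = z[3], N = z[4];
    double den = N + e.K;
    double M  = (den > 0.0) ? N / den : 0.0;
    double Mp = (den > 0.0) ? e.K / (den * den) : 0.0;

    double F0 = (1.0 - fA) * e.mu * M * CA - e.k * TB * CA;
    double F1 = (1.0 - fB) * e.mu * M * CB - e.k * TA * CB;
    double F2 = fA * M * CA - e.lT * TA;
    double F3 = fB * M * CB - e.lT * TB;
    double F4 = -M * (CA + CB);

    double G[5] = {
      z[0] - y[0] - h * F0,
      z[1] - y[1] - h * F1,
      z[2] - y[2] - h * F2,
      z[3] - y[3] - h * F3,
      z[4] - y[4] - h * F4
    };

    double J[5][5] = {{0}};
    J[0][0] = 1.0 - h * ((1.0 - fA) * e.mu * M - e.k * TB);
    J[0][3] = h * e.k * CA;
    J[0][4] = -h * (1.0 - fA) * e.mu * Mp * CA;
    J[1][1] = 1.0 - h * ((1.0 - fB) * e.mu * M - e.k * TA);
    J[1][2] = h * e.k * CB;
    J[1][4] = -h * (1.0 - fB) * e.mu * Mp * CB;
    J[2][0] = -h * fA * M;
    J[2][2] = 1.0 + h * e.lT;
    J[2][4] = -h * fA * Mp * CA;
    J[3][1] = -h * fB * M;
    J[3][3] = 1.0 + h * e.lT;
    J[3][4] = -h * fB * Mp * CB;
    J[4][0] = h * M;
    J[4][1] = h * M;
    J[4][4] = 1.0 + h * Mp * (CA + CB);

    double d[5];
    for (int i = 0; i < 5; ++i) d[i] = -G[i];
    if (!solve5(J, d)) return false;
    double mx = 0.0;
    for (int i = 0; i < 5; ++i) {
      z[i] += d[i];
      double a = std::fabs(d[i]);
      if (a > mx) mx = a;
    }
    if (mx < 1e-10) {
      for (int i = 0; i < 5; ++i) y[i] = z[i];
      return true;
    }
  }
  return false;
}

// Newton with step-halving fallback (investments held fixed).
static bool be_step_robust(double y[5], double h, double fA, double fB,
                           const Eco& e, int depth) {
  if (be_step(y, h, fA, fB, e)) return true;
  if (depth >= 12) return false;
  return be_step_robust(y, h / 2.0, fA, fB, e, depth + 1) &&
         be_step_robust(y, h / 2.0, fA, fB, e, depth + 1);
}

struct SimResult {
  double y[5];
  bool extA, extB;
};

static SimResult run_sim(const Strat& A, const Strat& B, const Eco& e,
                         NumericMatrix* traj) {
  SimResult r;
  r.y[0] = e.C0A; r.y[1] = e.C0B; r.y[2] = 0.0; r.y[3] = 0.0; r.y[4] = e.N0;
  r.extA = false; r.extB = false;

  int nfull = (int) std::floor(e.tEnd / e.dt + 1e-9);
  double rem = e.tEnd - nfull * e.dt;
  if (rem < 1e-12) rem = 0.0;
  int nsteps = nfull + (rem > 0.0 ? 1 : 0);

  if (traj) {
    double fA0 = invest(A, r.y[0], r.y[3], r.y[4], e.N0);
    double fB0 = invest(B, r.y[1], r.y[2], r.y[4], e.N0);
    (*traj)(0, 0) = 0.0;
    for (int i = 0; i < 5; ++i) (*traj)(0, i + 1) = r.y[i];
    (*traj)(0, 6) = fA0;
    (*traj)(0, 7) = fB0;
  }

  for (int s = 1; s <= nsteps; ++s) {
    double h = (s <= nfull) ? e.dt : rem;
    double t = (s <= nfull) ? s * e.dt : e.tEnd;
    double fA = r.extA ? 0.0 : invest(A, r.y[0], r.y[3], r.y[4], e.N0);
    double fB = r.extB ? 0.0 : invest(B, r.y[1], r.y[2], r.y[4], e.N0);
    double hs = h / e.substeps;
    for (int sub = 0; sub < e.substeps; ++sub) {
      if (!be_step_robust(r.y, hs, fA, fB, e, 0))
        stop("implicit step failed to converge at t = %.6f (step %d)", t, s);
    }
    for (int i = 0; i < 5; ++i)
      if (r.y[i] < e.clampThr) r.y[i] = 0.0;
    if (!r.extA && r.y[0] < e.extThr) { r.y[0] = 0.0; r.extA = true; }
    if (!r.extB && r.y[1] < e.extThr) { r.y[1] = 0.0; r.extB = true; }
    if (traj) {
      (*traj)(s, 0) = t;
      for (int i = 0; i < 5; ++i) (*traj)(s, i + 1) = r.y[i];
      (*traj)(s, 6) = fA;
      (*traj)(s, 7) = fB;
    }
  }
  return r;
}

// [[Rcpp::export]]
List sim_competition_cpp(NumericVector strategy_a, NumericVector strategy_b,
                         NumericVector eco, bool keep_trajectory) {
  Eco e = as_eco(eco);
  Strat A = as_strat(strategy_a), B = as_strat(strategy_b);
  int nfull = (int) std::floor(e.tEnd / e.dt + 1e-9);
  double rem = e.tEnd - nfull * e.dt;
  int nsteps = nfull + (rem >= 1e-12 ? 1 : 0);

  NumericMatrix traj;
  SimResult r;
  if (keep_trajectory) {
    traj = NumericMatrix(nsteps + 1, 8);
    r = run_sim(A, B, e, &traj);
  } else {
    r = run_sim(A, B, e, (NumericMatrix*) 0);
  }

  List out = List::create(
    _["final"]   = NumericVector::create(r.y[0], r.y[1], r.y[2], r.y[3], r.y[4]),
    _["extinct"] = LogicalVector::create(r.extA, r.extB),
    _["trajectory"] = keep_trajectory ? (SEXP) traj : R_NilValue
  );
  return out;
}

// W[i, j] = final biomass of strategy i competing against strategy j,
// from the n(n+1)/2 unordered competitions (the system is role-symmetric
// when C0_A = C0_B; for asymmetric seeding strategy i takes role A).
// [[Rcpp::export]]
NumericMatrix self_cross_final_cpp(NumericMatrix strategies, NumericVector eco) {
  Eco e = as_eco(eco);
  int n = strategies.nrow();
  std::vector<Strat> ss(n);
  for (int i = 0; i < n; ++i) {
    NumericVector row = strategies(i, _);
    ss[i] = as_strat(row);
  }
  NumericMatrix W(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      SimResult r = run_sim(ss[i], ss[j], e, (NumericMatrix*) 0);
      W(i, j) = r.y[0];
      W(j, i) = r.y[1];
      Rcpp::checkUserInterrupt();
    }
  }
  return W;
}

// All pairings of strategy set A (rows) against strategy set B (columns);
// returns the final biomass each side obtains in its pairing.
// [[Rcpp::export]]
List cross_final_cpp(NumericMatrix sa, NumericMatrix sb, NumericVector eco) {
  Eco e = as_eco(eco);
  int na = sa.nrow(), nb = sb.nrow();
  std::vector<Strat> A(na), B(nb);
  for (int i = 0; i < na; ++i) { NumericVector r = sa(i, _); A[i] = as_strat(r); }
  for (int j = 0; j < nb; ++j) { NumericVector r = sb(j, _); B[j] = as_strat(r); }
  NumericMatrix WA(na, nb), WB(na, nb);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      SimResult r = run_sim(A[i], B[j], e, (NumericMatrix*) 0);
      WA(i, j) = r.y[0];
      WB(i, j) = r.y[1];
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["biomass_a"] = WA, _["biomass_b"] = WB);
}
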
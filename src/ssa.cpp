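#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Two-regulator pulsing network, exact Doob-Gillespie sampling.
//
// Species order (fixed everywhere in the package):
//   0 G_A   free sporulation gene
//   1 BG_A  repressor-bound sporulation gene
//   2 G_B   stress-regulator gene
//   3 R_A   sporulation mRNA
//   4 R_B   stress-regulator mRNA
//   5 A     sporulation protein
//   6 B     stress-regulator protein
//
// Parameter vector order: zeta, s_A, s_B, beta, delta, epsilon, b_B, u_B.
//
// Reaction channels (binding/unbinding are the two directions of the
// reversible repressor-operator reaction):
//   0 G_A -> G_A + R_A   zeta*s_A*G_A
//   1 R_A -> R_A + A     beta*R_A
//   2 R_A -> 0           delta*R_A
//   3 A   -> 0           epsilon*A
//   4 G_B -> G_B + R_B   zeta*s_B*G_B
//   5 R_B -> R_B + B     beta*R_B
//   6 R_B -> 0           delta*R_B
//   7 B   -> 0           epsilon*B
//   8 B + G_A -> BG_A    b_B*B*G_A   (B sequestered)
//   9 BG_A -> B + G_A    u_B*BG_A    (B released)

enum { GA = 0, BGA, GB, RA, RB, PA, PB, NSPEC };
static const int NREACT = 10;

static inline double propensities_c(const double *par, const int *x, double *a) {
  const double zeta = par[0], sA = par[1], sB = par[2], beta = par[3],
               del = par[4], eps = par[5], bB = par[6], uB = par[7];
  a[0] = zeta * sA * x[GA];
  a[1] = beta * x[RA];
  a[2] = del * x[RA];
  a[3] = eps * x[PA];
  a[4] = zeta * sB * x[GB];
  a[5] = beta * x[RB];
  a[6] = del * x[RB];
  a[7] = eps * x[PB];
  a[8] = bB * x[PB] * x[GA];
  a[9] = uB * x[BGA];
  double s = 0.0;
  for (int i = 0; i < NREACT; ++i) s += a[i];
  return s;
}

static inline void apply_reaction(int r, int *x) {
  switch (r) {
  case 0: x[RA]++; break;
  case 1: x[PA]++; break;
  case 2: x[RA]--; break;
  case 3: x[PA]--; break;
  case 4: x[RB]++; break;
  case 5: x[PB]++; break;
  case 6: x[RB]--; break;
  case 7: x[PB]--; break;
  case 8: x[PB]--; x[GA]--; x[BGA]++; break;
  case 9: x[PB]++; x[GA]++; x[BGA]--; break;
  }
}

static inline int pick_reaction(const double *a, double a0) {
  double u = unif_rand() * a0, c = 0.0;
  for (int i = 0; i < NREACT; ++i) {
    c += a[i];
    if (u <= c) return i;
  }
  return NREACT - 1;  // numerical slack
}

// Full event log from the standard initial condition (G_A = G_B = 1, all
// other species absent). Uses R's RNG stream: seed with set.seed() in R.
// [[Rcpp::export]]
List ssa_simulate_cpp(NumericVector par, double t_total,
                      double max_events = 5e7) {
  if (t_total <= 0) stop("t_total must be positive");
  int x[NSPEC] = {1, 0, 1, 0, 0, 0, 0};
  double a[NREACT];
  std::vector<double> times;
  std::vector<int> log;
  times.reserve(4096);
  log.reserve(4096 * NSPEC);
  double t = 0.0;
  times.push_back(t);
  for (int s = 0; s < NSPEC; ++s) log.push_back(x[s]);
  double nev = 0;
  while (true) {
    double a0 = propensities_c(REAL(par), x, a);
    double tnext = (a0 <= 0.0) ? t_total : t + exp_rand() / a0;
    if (tnext >= t_total) break;
    int r = pick_reaction(a, a0);
    apply_reaction(r, x);
    t = tnext;
    times.push_back(t);
    for (int s = 0; s < NSPEC; ++s) log.push_back(x[s]);
    if (++nev > max_events) stop("event budget exceeded (max_events)");
  }
  int n = times.size();
  IntegerMatrix states(n, NSPEC);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < NSPEC; ++s) states(i, s) = log[i * NSPEC + s];
  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["states"] = states, _["t_end"] = t_total);
}

// Single-pass summary used for large ensembles: longest contiguous time A
// spends strictly above `theta` within [transient, t_total], B at t_total,
// and time averages of A, A^2 and B over the stationary window.
// [[Rcpp::export]]
NumericVector ssa_summary_cpp(NumericVector par, double t_total,
                              double transient, double theta,
                              double max_events = 5e7) {
  if (t_total <= 0) stop("t_total must be positive");
  if (transient < 0 || transient >= t_total)
    stop("transient must lie in [0, t_total)");
  int x[NSPEC] = {1, 0, 1, 0, 0, 0, 0};
  double a[NREACT];
  double t = 0.0, longest = 0.0, exc_start = 0.0;
  bool above = false;  // initial A = 0 cannot exceed a non-negative theta
  double sumA = 0.0, sumA2 = 0.0, sumB = 0.0;
  double nev = 0;
  while (true) {
    double a0 = propensities_c(REAL(par), x, a);
    double tnext = (a0 <= 0.0) ? t_total : t + exp_rand() / a0;
    double lo = std::max(t, transient), hi = std::min(tnext, t_total);
    if (hi > lo) {
      double dt = hi - lo, A = x[PA], B = x[PB];
      sumA += A * dt;
      sumA2 += A * A * dt;
      sumB += B * dt;
    }
    if (tnext >= t_total) {
      if (above) {
        double d = t_total - std::max(exc_start, transient);
        if (d > longest) longest = d;
      }
      double W = t_total - transient;
      return NumericVector::create(
          _["longest_excursion"] = longest, _["final_B"] = (double)x[PB],
          _["tavg_A"] = sumA / W, _["tavg_A2"] = sumA2 / W,
          _["tavg_B"] = sumB / W);
    }
    int r = pick_reaction(a, a0);
    apply_reaction(r, x);
    t = tnext;
    bool now = x[PA] > theta;
    if (now && !above) {
      above = true;
      exc_start = t;
    } else if (!now && above) {
      above = false;
      double d = t - std::max(exc_start, transient);
      if (d > longest) longest = d;
    }
    if (++nev > max_events) stop("event budget exceeded (max_events)");
  }
}

// Time-weighted occupancy of (R_A, A) over [transient, t_total]; states
// outside the truncation window accumulate into `excess`. Used for the
// SSA-vs-master-equation equivalence check on down-scaled parameters.
// [[Rcpp::export]]
List ssa_occupancy_cpp(NumericVector par, double t_total, double transient,
                       int max_R, int max_A, double max_events = 5e8) {
  if (t_total <= transient) stop("t_total must exceed transient");
  int x[NSPEC] = {1, 0, 1, 0, 0, 0, 0};
  double a[NREACT];
  NumericMatrix occ(max_R + 1, max_A + 1);
  double excess = 0.0, t = 0.0, nev = 0;
  while (true) {
    double a0 = propensities_c(REAL(par), x, a);
    double tnext = (a0 <= 0.0) ? t_total : t + exp_rand() / a0;
    double lo = std::max(t, transient), hi = std::min(tnext, t_total);
    if (hi > lo) {
      double dt = hi - lo;
      if (x[RA] <= max_R && x[PA] <= max_A)
        occ(x[RA], x[PA]) += dt;
      else
        excess += dt;
    }
    if (tnext >= t_total) break;
    int r = pick_reaction(a, a0);
    apply_reaction(r, x);
    t = tnext;
    if (++nev > max_events) stop("event budget exceeded (max_events)");
  }
  double W = t_total - transient;
  for (int i = 0; i <= max_R; ++i)
    for (int j = 0; j <= max_A; ++j) occ(i, j) /= W;
  return List::create(_["occupancy"] = occ, _["excess"] = excess / W);
}
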
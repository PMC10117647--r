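#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shared simulation parameters for the hybrid Moran/branching engine.
// All draws go through R's RNG (unif_rand) so runs are reproducible with
// set.seed() from R.
struct EngineParams {
  double N, d, r0, r1, rS1, rS, dS, mu1, muS1, muS;
  double thr, hybrid_mult, max_time;
  int redraw_cap;
};

static EngineParams make_params(double N, double d, double r0, double r1,
                                double rS1, double rS, double dS, double mu1,
                                double muS1, double muS, double thr,
                                double hybrid_mult, double max_time,
                                int redraw_cap) {
  EngineParams p;
  p.N = N; p.d = d; p.r0 = r0; p.r1 = r1; p.rS1 = rS1;
  p.rS = rS; p.dS = dS; p.mu1 = mu1; p.muS1 = muS1; p.muS = muS;
  p.thr = thr; p.hybrid_mult = hybrid_mult; p.max_time = max_time;
  p.redraw_cap = redraw_cap;
  return p;
}

// One Moran turnover event in the well-mixed tissue: a uniformly chosen cell
// dies and the vacancy is refilled by a fitness-weighted division draw.
// Division numerators use the pre-death composition, exactly as written in
// the transition probabilities. A malignant-daughter draw increments the
// off-tissue tumor count and the vacancy draw repeats; the returned value is
// the number of malignant births produced during this single turnover.
static int turnover_event(long &X0, long &X1, long &XS1,
                          const EngineParams &p) {
  long N = X0 + X1 + XS1;
  double u = unif_rand() * (double)N;
  int dying = (u < (double)X0) ? 0 : (u < (double)(X0 + X1) ? 1 : 2);

  double F = p.r0 * X0 + p.r1 * X1 + p.rS1 * XS1;
  if (F <= 0.0)
    stop("no cell can divide: total division weight F is zero");
  double pS = p.rS1 * XS1 * p.muS / F;
  double p0 = p.r0 * X0 * (1.0 - p.mu1) / F;
  double p1 = (p.r1 * X1 * (1.0 - p.muS1) + p.r0 * X0 * p.mu1) / F;

  int sbirths = 0;
  int daughter = -1;
  for (int k = 0; k <= p.redraw_cap; ++k) {
    double v = unif_rand();
    if (v < pS) { ++sbirths; continue; }
    v -= pS;
    if (v < p0) { daughter = 0; break; }
    v -= p0;
    if (v < p1) { daughter = 1; break; }
    daughter = 2; break;
  }
  if (daughter < 0)
    stop("redraw cap exceeded while refilling a vacancy (muS too close to 1)");

  if (dying == 0) --X0; else if (dying == 1) --X1; else --XS1;
  if (daughter == 0) ++X0; else if (daughter == 1) ++X1; else ++XS1;
  return sbirths;
}

// Tissue-only turnover for a fixed duration (used while tumor growth is in
// its deterministic regime; tumor birth/death channels are suspended and
// malignant daughters arising from tissue divisions are ignored as
// negligible against a macroscopic tumor).
static void turnover_for_duration(long &X0, long &X1, long &XS1,
                                  double duration, const EngineParams &p) {
  double rate = p.d * p.N;
  if (rate <= 0.0 || duration <= 0.0) return;
  double nsteps_d = std::floor(duration * rate);
  long nsteps = (long)nsteps_d;
  for (long s = 0; s < nsteps; ++s)
    turnover_event(X0, X1, XS1, p);
}

// One simulation phase: from a given tissue/tumor state, run the hybrid
// process until the tumor reaches the detection threshold or phase time
// exceeds max_time. Time advances by the mean waiting time of Eq-style
// Gillespie steps; once the tumor exceeds hybrid_mult * N its growth is
// treated as deterministic exponential expansion while tissue turnover
// continues for that interval.
static List run_phase(long X0, long X1, long XS1, double XS,
                      const EngineParams &p) {
  double t = 0.0;
  bool detected = false;
  double switch_size = p.hybrid_mult * p.N;

  while (true) {
    if (XS >= switch_size) {
      double dts = std::log(p.thr / XS) / (p.rS - p.dS);
      if (t + dts > p.max_time) {
        turnover_for_duration(X0, X1, XS1, p.max_time - t, p);
        t = p.max_time;
        break;
      }
      turnover_for_duration(X0, X1, XS1, dts, p);
      t += dts;
      detected = true;
      XS = p.thr;
      break;
    }
    if (XS >= p.thr) { detected = true; break; }
    if (t >= p.max_time) break;

    double turn_rate = p.d * p.N;
    double total = turn_rate + (p.rS + p.dS) * XS;
    if (total <= 0.0)
      stop("frozen system: all event rates are zero");
    double dt = 1.0 / total;
    double u = unif_rand() * total;
    if (u < turn_rate) {
      XS += turnover_event(X0, X1, XS1, p);
    } else if (u < turn_rate + p.rS * XS) {
      XS += 1.0;
    } else {
      XS -= 1.0;
    }
    t += dt;
  }

  return List::create(_["detected"] = detected, _["t"] = t,
                      _["X0"] = (double)X0, _["X1"] = (double)X1,
                      _["XS1"] = (double)XS1, _["XS"] = XS);
}

// [[Rcpp::export]]
List cpp_run_phase(double X0, double X1, double XS1, double XS, double N,
                   double d, double r0, double r1, double rS1, double rS,
                   double dS, double mu1, double muS1, double muS, double thr,
                   double hybrid_mult, double max_time, int redraw_cap) {
  EngineParams p = make_params(N, d, r0, r1, rS1, rS, dS, mu1, muS1, muS,
                               thr, hybrid_mult, max_time, redraw_cap);
  return run_phase((long)X0, (long)X1, (long)XS1, XS, p);
}

// ---------------------------------------------------------------------------
// Spatial (2D lattice, 4-neighbor, wall boundary) variant.
// Grid codes: 0 = Type 0, 1 = Type 1, 2 = Type S-1. Malignant cells live
// off-lattice as a count, since the Moran process no longer applies to them.
// ---------------------------------------------------------------------------

static int spatial_turnover_event(IntegerVector &g, int I, int J,
                                  const EngineParams &p) {
  int n = I * J;
  int site = (int)(unif_rand() * n);
  if (site >= n) site = n - 1;
  int i = site / J, j = site % J;

  double c0 = 0.0, c1 = 0.0, cS1 = 0.0;
  int nb[4];
  int nnb = 0;
  if (i > 0)     nb[nnb++] = site - J;
  if (i < I - 1) nb[nnb++] = site + J;
  if (j > 0)     nb[nnb++] = site - 1;
  if (j < J - 1) nb[nnb++] = site + 1;
  for (int k = 0; k < nnb; ++k) {
    int code = g[nb[k]];
    if (code == 0) c0 += 1.0; else if (code == 1) c1 += 1.0; else cS1 += 1.0;
  }

  double F = p.r0 * c0 + p.r1 * c1 + p.rS1 * cS1;
  if (F <= 0.0)
    stop("no neighbor can divide: local division weight F is zero");
  double pS = p.rS1 * cS1 * p.muS / F;
  double p0 = p.r0 * c0 * (1.0 - p.mu1) / F;
  double p1 = (p.r1 * c1 * (1.0 - p.muS1) + p.r0 * c0 * p.mu1) / F;

  int sbirths = 0;
  int daughter = -1;
  for (int k = 0; k <= p.redraw_cap; ++k) {
    double v = unif_rand();
    if (v < pS) { ++sbirths; continue; }
    v -= pS;
    if (v < p0) { daughter = 0; break; }
    v -= p0;
    if (v < p1) { daughter = 1; break; }
    daughter = 2; break;
  }
  if (daughter < 0)
    stop("redraw cap exceeded while refilling a vacancy (muS too close to 1)");

  g[site] = daughter;
  return sbirths;
}

static void spatial_turnover_for_duration(IntegerVector &g, int I, int J,
                                          double duration,
                                          const EngineParams &p) {
  double rate = p.d * p.N;
  if (rate <= 0.0 || duration <= 0.0) return;
  long nsteps = (long)std::floor(duration * rate);
  for (long s = 0; s < nsteps; ++s)
    spatial_turnover_event(g, I, J, p);
}

// [[Rcpp::export]]
List cpp_run_phase_spatial(IntegerVector grid, int I, int J, double XS,
                           double d, double r0, double r1, double rS1,
                           double rS, double dS, double mu1, double muS1,
                           double muS, double thr, double hybrid_mult,
                           double max_time, int redraw_cap) {
  IntegerVector g = clone(grid);
  EngineParams p = make_params((double)I * J, d, r0, r1, rS1, rS, dS, mu1,
                               muS1, muS, thr, hybrid_mult, max_time,
                               redraw_cap);
  double t = 0.0;
  bool detected = false;
  double switch_size = p.hybrid_mult * p.N;

  while (true) {
    if (XS >= switch_size) {
      double dts = std::log(p.thr / XS) / (p.rS - p.dS);
      if (t + dts > p.max_time) {
        spatial_turnover_for_duration(g, I, J, p.max_time - t, p);
        t = p.max_time;
        break;
      }
      spatial_turnover_for_duration(g, I, J, dts, p);
      t += dts;
      detected = true;
      XS = p.thr;
      break;
    }
    if (XS >= p.thr) { detected = true; break; }
    if (t >= p.max_time) break;

    double turn_rate = p.d * p.N;
    double total = turn_rate + (p.rS + p.dS) * XS;
    if (total <= 0.0)
      stop("frozen system: all event rates are zero");
    double dt = 1.0 / total;
    double u = unif_rand() * total;
    if (u < turn_rate) {
      XS += spatial_turnover_event(g, I, J, p);
    } else if (u < turn_rate + p.rS * XS) {
      XS += 1.0;
    } else {
      XS -= 1.0;
    }
    t += dt;
  }

  double c0 = 0.0, c1 = 0.0, cS1 = 0.0;
  for (int k = 0; k < I * J; ++k) {
    if (g[k] == 0) c0 += 1.0; else if (g[k] == 1) c1 += 1.0; else cS1 += 1.0;
  }
  return List::create(_["detected"] = detected, _["t"] = t, _["grid"] = g,
                      _["X0"] = c0, _["X1"] = c1, _["XS1"] = cS1,
                      _["XS"] = XS);
}

// ---------------------------------------------------------------------------
// Validation helpers (cross-checked against exact Markov-chain and
// deterministic-limit oracles in the test suite).
// ---------------------------------------------------------------------------

// Number of turnover events until the first malignant birth, counting the
// event in which it occurs; tissue-only dynamics (no tumor channels).
// [[Rcpp::export]]
NumericVector cpp_steps_to_first_sbirth(int N, int reps, double r0, double r1,
                                        double rS1, double mu1, double muS1,
                                        double muS, double max_steps,
                                        int redraw_cap) {
  EngineParams p = make_params((double)N, 1.0, r0, r1, rS1, 1.0, 0.0, mu1,
                               muS1, muS, R_PosInf, R_PosInf, R_PosInf,
                               redraw_cap);
  NumericVector out(reps);
  for (int r = 0; r < reps; ++r) {
    long X0 = N, X1 = 0, XS1 = 0;
    double steps = 0.0;
    while (steps < max_steps) {
      steps += 1.0;
      if (turnover_event(X0, X1, XS1, p) > 0) break;
    }
    out[r] = steps;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_steps_to_first_sbirth_spatial(int I, int J, int reps,
                                                double r0, double r1,
                                                double rS1, double mu1,
                                                double muS1, double muS,
                                                double max_steps,
                                                int redraw_cap) {
  EngineParams p = make_params((double)I * J, 1.0, r0, r1, rS1, 1.0, 0.0,
                               mu1, muS1, muS, R_PosInf, R_PosInf, R_PosInf,
                               redraw_cap);
  NumericVector out(reps);
  for (int r = 0; r < reps; ++r) {
    IntegerVector g(I * J, 0);
    double steps = 0.0;
    while (steps < max_steps) {
      steps += 1.0;
      if (spatial_turnover_event(g, I, J, p) > 0) break;
    }
    out[r] = steps;
  }
  return out;
}

// Fixation probability of a mutation-free two-type Moran process started
// with k Type 1 cells; returns the fraction of runs in which Type 1 fixed.
// [[Rcpp::export]]
double cpp_fixation_type1(int N, int k, double r0, double r1, int reps) {
  EngineParams p = make_params((double)N, 1.0, r0, r1, 1.0, 1.0, 0.0, 0.0,
                               0.0, 0.0, R_PosInf, R_PosInf, R_PosInf, 10000);
  long fixed = 0;
  for (int r = 0; r < reps; ++r) {
    long X0 = N - k, X1 = k, XS1 = 0;
    while (X1 > 0 && X1 < N)
      turnover_event(X0, X1, XS1, p);
    if (X1 == N) ++fixed;
  }
  return (double)fixed / (double)reps;
}

// Pure stochastic birth-death passage from x0 to threshold using mean
// waiting-time increments; NA time when the lineage goes extinct first.
// [[Rcpp::export]]
NumericVector cpp_birth_death_passage(double x0, double rS, double dS,
                                      double threshold, int reps) {
  NumericVector out(reps);
  for (int r = 0; r < reps; ++r) {
    double X = x0, t = 0.0;
    while (X > 0.0 && X < threshold) {
      double total = (rS + dS) * X;
      t += 1.0 / total;
      if (unif_rand() * (rS + dS) < rS) X += 1.0; else X -= 1.0;
    }
    out[r] = (X <= 0.0) ? NA_REAL : t;
  }
  return out;
}
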
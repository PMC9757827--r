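#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Stable log-space addition: log(exp(a) + exp(b)).
// Shared by every code path (serial fill, parallel fill, end accumulation) so
// that operand-for-operand the two engines perform identical float operations.
static inline double add_log1(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  if (a >= b) return a + log1p(exp(b - a));
  return b + log1p(exp(a - b));
}

// [[Rcpp::export]]
NumericVector cpp_add_log(NumericVector a, NumericVector b) {
  R_xlen_t n = a.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = add_log1(a[i], b[i]);
  return out;
}

static const double LOG_SQRT_2PI = 0.918938533204672741780329736406;

static inline double lp_gauss(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -LOG_SQRT_2PI - log(sd) - 0.5 * z * z;
}

// [[Rcpp::export]]
NumericVector cpp_lp_gauss(NumericVector x, NumericVector mu, NumericVector sd) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = lp_gauss(x[i], mu[i], sd[i]);
  return out;
}

// State offsets within a block (column order KMER_SKIP, BAD_EVENT, MATCH).
static const int SKIP = 0;
static const int BAD = 1;
static const int MATCH = 2;
static const int NUM_STATES = 3;

struct HmmParams {
  double lp_stay, lp_step, lp_skip, lp_bad, lp_bad_emit, lp_end;
};

// MATCH update: combine, in fixed order, step transitions from the three
// states of (row-1, block-1) then stay transitions from the three states of
// (row-1, block); transitions out of row 0 are begin transitions with
// log-weight 0 (lp_start). Emission added last.
static inline double compute_match(const NumericMatrix& fm, int r, int b,
                                   double emit, const HmmParams& p) {
  double lp_step_r = (r == 1) ? 0.0 : p.lp_step;
  double lp_stay_r = (r == 1) ? 0.0 : p.lp_stay;
  double acc = R_NegInf;
  if (b > 0) {
    int prev = NUM_STATES * (b - 1);
    acc = add_log1(acc, fm(r - 1, prev + SKIP) + lp_step_r);
    acc = add_log1(acc, fm(r - 1, prev + BAD) + lp_step_r);
    acc = add_log1(acc, fm(r - 1, prev + MATCH) + lp_step_r);
  }
  int cur = NUM_STATES * b;
  acc = add_log1(acc, fm(r - 1, cur + SKIP) + lp_stay_r);
  acc = add_log1(acc, fm(r - 1, cur + BAD) + lp_stay_r);
  acc = add_log1(acc, fm(r - 1, cur + MATCH) + lp_stay_r);
  return acc + emit;
}

// BAD_EVENT update: combine the three states of (row-1, block) under the bad
// transition, then add the flat bad-event emission penalty.
static inline double compute_bad(const NumericMatrix& fm, int r, int b,
                                 const HmmParams& p) {
  double lp_bad_r = (r == 1) ? 0.0 : p.lp_bad;
  int cur = NUM_STATES * b;
  double acc = R_NegInf;
  acc = add_log1(acc, fm(r - 1, cur + SKIP) + lp_bad_r);
  acc = add_log1(acc, fm(r - 1, cur + BAD) + lp_bad_r);
  acc = add_log1(acc, fm(r - 1, cur + MATCH) + lp_bad_r);
  return acc + p.lp_bad_emit;
}

// KMER_SKIP update: same-row dependency on the three states of (row, block-1).
static inline double compute_skip(const NumericMatrix& fm, int r, int b,
                                  const HmmParams& p) {
  if (b == 0) return R_NegInf;
  int prev = NUM_STATES * (b - 1);
  double acc = R_NegInf;
  acc = add_log1(acc, fm(r, prev + SKIP));
  acc = add_log1(acc, fm(r, prev + BAD));
  acc = add_log1(acc, fm(r, prev + MATCH));
  return acc + p.lp_skip;
}

// Fill the probability matrix. engine 0 = serial (row-major, block
// left-to-right, Algorithm-1 style); engine 1 = two-phase parallel: per row,
// phase A computes MATCH and BAD_EVENT of every block (these read only
// row-1), blocks assigned round-robin to `workers`; an explicit barrier point
// separates phase A from phase B, in which one designated worker scans blocks
// left-to-right filling KMER_SKIP and then accumulates the end state.
// [[Rcpp::export]]
List cpp_hmm_fill(NumericVector event_means, NumericVector mu, NumericVector sd,
                  double lp_stay, double lp_step, double lp_skip, double lp_bad,
                  double lp_bad_emit, double lp_end, int engine, int workers) {
  int n_events = event_means.size();
  int nb = mu.size();
  if (n_events < 1) stop("at least one event is required");
  if (nb < 1) stop("at least one k-mer block is required");
  if (workers < 1) stop("workers must be >= 1");

  HmmParams p;
  p.lp_stay = lp_stay; p.lp_step = lp_step; p.lp_skip = lp_skip;
  p.lp_bad = lp_bad; p.lp_bad_emit = lp_bad_emit; p.lp_end = lp_end;

  int n_row = n_events + 1;
  NumericMatrix fm(n_row, NUM_STATES * nb);
  std::fill(fm.begin(), fm.end(), R_NegInf);

  // Row 0: "no events consumed". The begin state seeds MATCH of block 0 with
  // lp_start = 0; leading k-mers may be skipped before the first event, so
  // KMER_SKIP of row 0 is filled left-to-right.
  fm(0, NUM_STATES * 0 + MATCH) = 0.0;
  for (int b = 0; b < nb; ++b)
    fm(0, NUM_STATES * b + SKIP) = compute_skip(fm, 0, b, p);

  double end_score = R_NegInf;
  int last_match = NUM_STATES * (nb - 1) + MATCH;

  for (int r = 1; r <= n_events; ++r) {
    double e = event_means[r - 1];
    if (engine == 0) {
      for (int b = 0; b < nb; ++b) {
        int cur = NUM_STATES * b;
        fm(r, cur + SKIP) = compute_skip(fm, r, b, p);
        fm(r, cur + BAD) = compute_bad(fm, r, b, p);
        fm(r, cur + MATCH) = compute_match(fm, r, b, lp_gauss(e, mu[b], sd[b]), p);
      }
    } else {
      // Phase A: block-independent updates (read only row r-1). The chunk
      // schedule cannot affect any value: cells are disjoint and inputs fixed.
      for (int w = 0; w < workers; ++w) {
        for (int b = w; b < nb; b += workers) {
          int cur = NUM_STATES * b;
          fm(r, cur + BAD) = compute_bad(fm, r, b, p);
          fm(r, cur + MATCH) = compute_match(fm, r, b, lp_gauss(e, mu[b], sd[b]), p);
        }
      }
      // --- barrier: phase A complete for row r ---
      // Phase B: designated worker, serial left-to-right KMER_SKIP scan.
      for (int b = 0; b < nb; ++b)
        fm(r, NUM_STATES * b + SKIP) = compute_skip(fm, r, b, p);
    }
    // End accumulation after the last block of the row: the alignment may end
    // here, from MATCH of the last block.
    end_score = add_log1(end_score, fm(r, last_match) + p.lp_end);
  }

  return List::create(_["fm"] = fm, _["end_score"] = end_score);
}

// Banded event-to-kmer alignment (simplified fixed-band DP, Viterbi max).
// Moves: step (event i -> kmer j from i-1,j-1), stay (event i -> kmer j from
// i-1,j), skip (kmer j unexplained, from i,j-1). Step/stay score the Gaussian
// emission of the event against the k-mer; the band is centred on the ideal
// diagonal. Returns a 2-column 1-based (event_index, kmer_index) matrix of
// the traceback, or a 0-row matrix when no cell at (n, m) is reachable.
// [[Rcpp::export]]
IntegerMatrix cpp_banded_align(NumericVector event_means, NumericVector mu,
                               NumericVector sd, double lp_step, double lp_stay,
                               double lp_skip, int bandwidth) {
  int n = event_means.size();
  int m = mu.size();
  if (n < 1 || m < 1) stop("need >= 1 event and >= 1 k-mer");
  int hw = bandwidth / 2;
  if (hw < 1) hw = 1;

  const int MV_NONE = 0, MV_STEP = 1, MV_STAY = 2, MV_SKIP = 3;
  NumericMatrix S(n + 1, m + 1);
  IntegerMatrix MV(n + 1, m + 1);
  std::fill(S.begin(), S.end(), R_NegInf);
  std::fill(MV.begin(), MV.end(), MV_NONE);

  auto center = [&](int i) { return (int)std::lround((double)i * m / n); };

  S(0, 0) = 0.0;
  {
    int lo = std::max(0, center(0) - hw), hi = std::min(m, center(0) + hw);
    for (int j = std::max(1, lo); j <= hi; ++j) {
      S(0, j) = S(0, j - 1) + lp_skip;
      MV(0, j) = MV_SKIP;
    }
  }

  for (int i = 1; i <= n; ++i) {
    int lo = std::max(1, center(i) - hw), hi = std::min(m, center(i) + hw);
    double e = event_means[i - 1];
    for (int j = lo; j <= hi; ++j) {
      double emit = lp_gauss(e, mu[j - 1], sd[j - 1]);
      double best = S(i - 1, j - 1) + lp_step + emit;
      int mv = MV_STEP;
      double stay = S(i - 1, j) + lp_stay + emit;
      if (stay > best) { best = stay; mv = MV_STAY; }
      double skip = S(i, j - 1) + lp_skip;
      if (skip > best) { best = skip; mv = MV_SKIP; }
      if (best == R_NegInf) continue;
      S(i, j) = best;
      MV(i, j) = mv;
    }
  }

  if (S(n, m) == R_NegInf) return IntegerMatrix(0, 2);

  std::vector<int> ev, km;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int mv = MV(i, j);
    if (mv == MV_STEP) { ev.push_back(i); km.push_back(j); --i; --j; }
    else if (mv == MV_STAY) { ev.push_back(i); km.push_back(j); --i; }
    else if (mv == MV_SKIP) { --j; }
    else break; // unreachable interior cell; defensive
  }
  int np = ev.size();
  IntegerMatrix out(np, 2);
  for (int t = 0; t < np; ++t) {
    out(t, 0) = ev[np - 1 - t];
    out(t, 1) = km[np - 1 - t];
  }
  colnames(out) = CharacterVector::create("event_index", "kmer_index");
  return out;
}
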
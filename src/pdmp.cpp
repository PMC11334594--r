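#include <Rcpp.h>
using namespace Rcpp;

// Deterministic flow of the scaled telegraph model between switching events:
// on-state relaxes toward 1, off-state decays toward 0, both at rate d.
static inline double flow1(double x, int e, double dt, double d) {
  if (e == 1) return 1.0 + (x - 1.0) * std::exp(-d * dt);
  return x * std::exp(-d * dt);
}

// Exact simulation of one cell's promoter/protein trajectory over [0, T]:
// exponential waiting times between promoter switches, closed-form flow in
// between.  Uses R's RNG so set.seed() gives reproducible paths.
// [[Rcpp::export(name = ".cpp_simulate_cell")]]
NumericVector cpp_simulate_cell(double x, int e, double T,
                                double k_on, double k_off, double d) {
  double t = 0.0;
  while (true) {
    double rate = (e == 1) ? k_off : k_on;
    double tau = (rate > 0.0) ? R::rexp(1.0 / rate) : R_PosInf;
    if (t + tau >= T) {
      x = flow1(x, e, T - t, d);
      break;
    }
    x = flow1(x, e, tau, d);
    e = 1 - e;
    t += tau;
  }
  return NumericVector::create(x, (double)e);
}

struct PendingCell {
  double x;
  int e;
  double t;  // time already elapsed within the current chunk
};

// Branching PDMP population with division intensity r(x) = r0 + r1 x,
// simulated exactly by thinning against the bound rmax = max(r(0), r(1))
// (r is affine, so its maximum on [0,1] sits at an endpoint).  Daughters
// copy (x, promoter state) at birth.  The run is split into chunks of at
// most ~one expected doubling; after each chunk, populations above
// `max_cells` are uniformly subsampled (without replacement) and the common
// lineage weight is multiplied by the inverse keep fraction, so the
// weighted population size stays an unbiased estimate of the true one.
// [[Rcpp::export(name = ".cpp_simulate_population")]]
List cpp_simulate_population(NumericVector x0, IntegerVector e0,
                             double T, double k_on, double k_off, double d,
                             double r0, double r1, int max_cells) {
  const double rmax = std::max(r0, r0 + r1);
  if (rmax < 0) stop("division rate must be nonnegative on [0,1]");
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<int> e(e0.begin(), e0.end());
  double weight = 1.0;

  int nchunk = 1;
  if (rmax > 0.0) nchunk = std::max(1, (int)std::ceil(T * rmax / 0.7));
  const double dt_chunk = T / nchunk;

  for (int c = 0; c < nchunk; ++c) {
    std::vector<double> nx;
    std::vector<int> ne;
    nx.reserve(x.size());
    ne.reserve(e.size());
    std::vector<PendingCell> stack;
    for (size_t i = 0; i < x.size(); ++i) {
      stack.push_back(PendingCell{x[i], e[i], 0.0});
      while (!stack.empty()) {
        PendingCell cell = stack.back();
        stack.pop_back();
        double xs = cell.x, ts = cell.t;
        int es = cell.e;
        while (true) {
          double sw = (es == 1) ? k_off : k_on;
          double rate = sw + rmax;
          double tau = (rate > 0.0) ? R::rexp(1.0 / rate) : R_PosInf;
          if (ts + tau >= dt_chunk) {
            xs = flow1(xs, es, dt_chunk - ts, d);
            break;
          }
          xs = flow1(xs, es, tau, d);
          ts += tau;
          if (unif_rand() * rate < sw) {
            es = 1 - es;  // promoter switch
          } else if (rmax > 0.0 && unif_rand() * rmax < r0 + r1 * xs) {
            // accepted division: daughter inherits state, lives out the chunk
            stack.push_back(PendingCell{xs, es, ts});
          }
        }
        nx.push_back(xs);
        ne.push_back(es);
      }
    }
    x.swap(nx);
    e.swap(ne);
    // uniform subsampling with weight bookkeeping
    int n = (int)x.size();
    if (n > max_cells) {
      for (int k = 0; k < max_cells; ++k) {
        int pick = k + (int)(unif_rand() * (n - k));
        if (pick >= n) pick = n - 1;
        std::swap(x[k], x[pick]);
        std::swap(e[k], e[pick]);
      }
      weight *= (double)n / (double)max_cells;
      x.resize(max_cells);
      e.resize(max_cells);
    }
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["e"] = IntegerVector(e.begin(), e.end()),
                      _["weight"] = weight);
}
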
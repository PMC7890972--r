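#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// FIFO multi-server assignment: given sorted arrival times and per-call
// service durations, compute each call's service start time with k
// identical servers. A min-heap holds the times at which servers free up.
// [[Rcpp::export]]
NumericVector mmk_service_starts(NumericVector arrivals,
                                 NumericVector services, int k) {
  int n = arrivals.size();
  if (services.size() != n) stop("arrivals/services length mismatch");
  if (k < 1) stop("k must be >= 1");
  NumericVector starts(n);
  std::priority_queue<double, std::vector<double>,
                      std::greater<double>> free_at;
  for (int i = 0; i < k; ++i) free_at.push(0.0);
  for (int i = 0; i < n; ++i) {
    double t = arrivals[i];
    double f = free_at.top();
    free_at.pop();
    double s = (f > t) ? f : t;
    starts[i] = s;
    free_at.push(s + services[i]);
  }
  return starts;
}
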
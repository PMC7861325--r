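#include <Rcpp.h>
using namespace Rcpp;

// Greedy dispersion-threshold (I-DT) scan over one contiguous segment of
// averaged-eye positions. A window grows from its anchor while
// (max-min of x) + (max-min of y) stays <= dispersion; when the next sample
// would break the bound the window is emitted as a fixation if it covers at
// least min_samples samples, and a new window starts at that sample.
// Returns a 2-column matrix of 1-based [start, end] sample indices.
// [[Rcpp::export]]
IntegerMatrix idt_runs_cpp(NumericVector x, NumericVector y,
                           double dispersion, int min_samples) {
  int n = x.size();
  std::vector<int> starts, ends;
  int i = 0;
  while (i < n) {
    double xmin = x[i], xmax = x[i], ymin = y[i], ymax = y[i];
    int j = i + 1;
    while (j < n) {
      double nxmin = std::min(xmin, x[j]), nxmax = std::max(xmax, x[j]);
      double nymin = std::min(ymin, y[j]), nymax = std::max(ymax, y[j]);
      if ((nxmax - nxmin) + (nymax - nymin) > dispersion) break;
      xmin = nxmin; xmax = nxmax; ymin = nymin; ymax = nymax;
      ++j;
    }
    if (j - i >= min_samples) {
      starts.push_back(i + 1);
      ends.push_back(j);
    }
    i = j > i ? j : i + 1;
  }
  IntegerMatrix out(starts.size(), 2);
  for (size_t k = 0; k < starts.size(); ++k) {
    out(k, 0) = starts[k];
    out(k, 1) = ends[k];
  }
  return out;
}
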
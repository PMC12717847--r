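#include <Rcpp.h>
using namespace Rcpp;

// Greedy broken-stick selection on a time-depth profile.
// Starts from the two endpoints; each iteration adds the sample with maximum
// absolute vertical deviation from the current piecewise-linear
// reconstruction (ties broken by earliest time). Returns 1-based indices of
// the k added interior points (in order of addition) and the deviation that
// selected each.
// [[Rcpp::export(name = ".broken_stick_cpp")]]
List broken_stick_cpp(NumericVector t, NumericVector d, int k) {
  int n = t.size();
  std::vector<int> sel;          // sorted selected indices (0-based)
  sel.push_back(0);
  sel.push_back(n - 1);
  IntegerVector chosen(k);
  NumericVector dev(k);

  for (int it = 0; it < k; ++it) {
    double best = -1.0;
    int best_i = -1;
    // walk segments between consecutive selected points
    for (size_t s = 0; s + 1 < sel.size(); ++s) {
      int a = sel[s], b = sel[s + 1];
      if (b - a < 2) continue;
      double ta = t[a], tb = t[b], da = d[a], db = d[b];
      double slope = (tb > ta) ? (db - da) / (tb - ta) : 0.0;
      for (int i = a + 1; i < b; ++i) {
        double pred = da + slope * (t[i] - ta);
        double dv = std::fabs(d[i] - pred);
        if (dv > best) { best = dv; best_i = i; }  // strict ">" keeps earliest tie
      }
    }
    if (best_i < 0) {
      // profile already exactly represented: add the earliest unselected
      // sample so that exactly k points are always returned
      for (int i = 1; i < n - 1; ++i) {
        if (std::find(sel.begin(), sel.end(), i) == sel.end()) { best_i = i; best = 0.0; break; }
      }
      if (best_i < 0) stop("profile has fewer than k interior samples");
    }
    chosen[it] = best_i + 1;
    dev[it] = best;
    sel.insert(std::upper_bound(sel.begin(), sel.end(), best_i), best_i);
  }

  // final max reconstruction error over all samples
  double maxerr = 0.0;
  for (size_t s = 0; s + 1 < sel.size(); ++s) {
    int a = sel[s], b = sel[s + 1];
    double ta = t[a], tb = t[b], da = d[a], db = d[b];
    double slope = (tb > ta) ? (db - da) / (tb - ta) : 0.0;
    for (int i = a + 1; i < b; ++i) {
      double pred = da + slope * (t[i] - ta);
      double dv = std::fabs(d[i] - pred);
      if (dv > maxerr) maxerr = dv;
    }
  }

  return List::create(_["chosen"] = chosen, _["deviation"] = dev,
                      _["max_error"] = maxerr);
}
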
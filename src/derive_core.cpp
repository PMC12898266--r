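#include <Rcpp.h>
using namespace Rcpp;

// Single pass over a grouped, day-sorted long table of readings (one reading
// per day within a group), maintaining the same accumulators as the R
// running summary and emitting the 13-parameter row at each group end.
// Column order matches parameter_names(). Missing values are NA.
// [[Rcpp::export]]
NumericMatrix derive_core_cpp(NumericVector day, NumericVector value,
                              LogicalVector new_grp, NumericVector lo,
                              NumericVector hi, bool twa_full) {
  const R_xlen_t n = day.size();
  if (n == 0) return NumericMatrix(0, 13);
  R_xlen_t G = 0;
  for (R_xlen_t i = 0; i < n; ++i) if (new_grp[i]) ++G;
  NumericMatrix out(G, 13);

  // per-group state
  double first_day = 0, first_val = 0, last_day = 0, last_val = 0;
  double sum = 0, sum2 = 0, auc = 0, abnauc = 0, fu = 0, mvd = 0;
  double cl_start = 0, cl_last = 0, max_clust = -1;
  double lagbuf[4];  // ring of the last up-to-4 values
  int nobs = 0, numnot = 0, cl_count = 0, num_clust = 0;
  bool last_abn = false;
  R_xlen_t g = -1;

  auto flush = [&](R_xlen_t gi) {
    if (gi < 0 || nobs == 0) return;
    const double na = NA_REAL;
    out(gi, 0) = last_val;                         // Value1
    out(gi, 1) = fu;                               // FUDaysNotAtGoal
    out(gi, 2) = numnot;                           // NumNotAtGoal
    if (nobs >= 2) {
      out(gi, 3) = abnauc;                         // AbnAUC
      double span = last_day - first_day;
      out(gi, 4) = span > 0 ? (twa_full ? auc : abnauc) / span : na;
    } else {
      out(gi, 3) = na;
      out(gi, 4) = na;
    }
    if (last_abn) {
      out(gi, 5) = cl_last - cl_start;             // TimeNotAtGoal
      out(gi, 6) = cl_count;                       // CtNotAtGoal
    } else {
      out(gi, 5) = na;
      out(gi, 6) = na;
    }
    out(gi, 7) = max_clust >= 0 ? max_clust : na;  // MaxClustDays
    out(gi, 8) = num_clust;                        // NumClust
    if (nobs >= 2) {
      double mean = sum / nobs;
      double var = (sum2 - nobs * mean * mean) / (nobs - 1);
      if (var < 0) var = 0;
      out(gi, 9) = mean != 0 ? std::sqrt(var) / mean : na;   // CoeffVar
      out(gi, 10) = mvd / (nobs - 1);              // MeanValDiff
    } else {
      out(gi, 9) = na;
      out(gi, 10) = na;
    }
    out(gi, 11) = last_val - first_val;            // NetChange
    if (nobs >= 4) {
      // lag-3 mean: the 3 values preceding the most recent one
      double l3 = (lagbuf[(nobs - 2) % 4] + lagbuf[(nobs - 3) % 4] +
                   lagbuf[(nobs - 4) % 4]) / 3.0;
      out(gi, 12) = l3 != 0 ? (last_val - l3) / l3 : na;     // Lag3Dev
    } else {
      out(gi, 12) = na;
    }
  };

  for (R_xlen_t i = 0; i < n; ++i) {
    const double d = day[i], v = value[i];
    const bool abn = v < lo[i] || v > hi[i];
    const double e = std::max(v - hi[i], 0.0) + std::max(lo[i] - v, 0.0);
    if (new_grp[i]) {
      flush(g);
      ++g;
      nobs = 0; numnot = 0; cl_count = 0; num_clust = 0;
      sum = 0; sum2 = 0; auc = 0; abnauc = 0; fu = 0; mvd = 0;
      max_clust = -1; last_abn = false;
      first_day = d; first_val = v;
    } else {
      const double span = d - last_day;
      const double e_prev = std::max(last_val - hi[i], 0.0) +
        std::max(lo[i] - last_val, 0.0);
      auc += (last_val + v) / 2.0 * span;
      abnauc += (e_prev + e) / 2.0 * span;
      if (last_abn && abn) fu += span;
      mvd += std::fabs(v - last_val);
    }
    if (abn) {
      if (last_abn && nobs > 0) {
        cl_last = d;
        ++cl_count;
      } else {
        cl_start = d; cl_last = d; cl_count = 1;
        ++num_clust;
      }
      if (cl_count >= 2 && cl_last - cl_start > max_clust)
        max_clust = cl_last - cl_start;
      ++numnot;
    } else {
      cl_count = 0;
    }
    last_abn = abn;
    lagbuf[nobs % 4] = v;
    ++nobs;
    last_day = d;
    last_val = v;
    sum += v;
    sum2 += v * v;
  }
  flush(g);
  return out;
}
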
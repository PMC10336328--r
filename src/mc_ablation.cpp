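#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Multi-pulse Monte Carlo lesion formation.
//
// Per pulse: every thrombus pixel whose nucleation probability exceeds a
// fresh uniform draw nucleates a bubble; the bubble radius follows the
// analytic Kelvin-Voigt maximum-radius model with the elastic modulus
// averaged over a disk around the nucleation site; red-blood-cell pixels
// within the bubble footprint are relabelled as ablated (liquefied).
// Bubbles within one pulse are independent: modulus averages are evaluated
// on the state at the start of the pulse (footprints are applied after all
// of the pulse's bubbles have been sized).
//
// Candidate pixels (thrombus pixels with probability > prob_floor) are
// enumerated once in column-major order; each receives one unif_rand() draw
// per pulse, so an R-level reference using runif() on the same seed can
// replay the identical stream.
//
// Disk sums use per-row prefix tables: thrombus and fibrin counts are static;
// remaining-RBC counts are updated as pixels are relabelled.

namespace {

struct PrefixCounts {
  int nr, nc;
  std::vector<int> cum;  // (nc + 1) entries per row
  void build(const IntegerVector &lab, int nrow, int ncol, int code_a,
             int code_b) {
    nr = nrow;
    nc = ncol;
    cum.assign((size_t)nr * (nc + 1), 0);
    for (int i = 0; i < nr; ++i) {
      int *row = &cum[(size_t)i * (nc + 1)];
      for (int j = 0; j < nc; ++j) {
        int v = lab[(size_t)j * nr + i];
        row[j + 1] = row[j] + ((v == code_a || v == code_b) ? 1 : 0);
      }
    }
  }
  // count over columns [j0, j1] inclusive in row i
  inline int segment(int i, int j0, int j1) const {
    const int *row = &cum[(size_t)i * (nc + 1)];
    return row[j1 + 1] - row[j0];
  }
  // decrement the running count at (i, j)
  inline void remove_at(int i, int j) {
    int *row = &cum[(size_t)i * (nc + 1)];
    for (int k = j + 1; k <= nc; ++k) row[k] -= 1;
  }
};

}  // namespace

// [[Rcpp::export]]
List mc_run_cpp(IntegerMatrix labels, NumericMatrix pneg, int n_pulses,
                double threshold_mean, double threshold_sd, double P0_MPa,
                double rho, double R0_nm, double tau, double G_fibrin,
                double G_rbc, double G_ablated, double pixel_um,
                double avg_radius_um, double prob_floor) {
  const int nr = labels.nrow(), nc = labels.ncol();
  if (pneg.nrow() != nr || pneg.ncol() != nc)
    stop("pressure field and section grids do not match");

  IntegerMatrix lab = clone(labels);
  const double P0 = P0_MPa * 1e6;
  const double R0 = R0_nm * 1e-9;
  const double pixel_m = pixel_um * 1e-6;

  // candidates: thrombus pixels with non-negligible nucleation probability
  std::vector<int> cand_i, cand_j;
  std::vector<double> cand_p, cand_pa;  // probability, pressure (Pa)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (lab(i, j) == 0) continue;
      double pr = R::pnorm(pneg(i, j), threshold_mean, threshold_sd, 1, 0);
      if (pr > prob_floor) {
        cand_i.push_back(i);
        cand_j.push_back(j);
        cand_p.push_back(pr);
        cand_pa.push_back(pneg(i, j) * 1e6);
      }
    }
  const int n_cand = (int)cand_i.size();

  PrefixCounts thrombus, fibrin, rbc;
  thrombus.build(lab, nr, nc, 1, 3);  // RBC or ablated
  {  // thrombus = RBC + ablated + fibrin: fold fibrin in
    PrefixCounts fib_only;
    fib_only.build(lab, nr, nc, 2, 2);
    fibrin = fib_only;
    for (size_t k = 0; k < thrombus.cum.size(); ++k)
      thrombus.cum[k] += fib_only.cum[k];
  }
  rbc.build(lab, nr, nc, 1, 1);

  // averaging-disk row halfwidths
  const double ra = avg_radius_um / pixel_um;
  const int ga = (int)std::floor(ra);
  std::vector<int> ghw(2 * ga + 1);
  for (int d = -ga; d <= ga; ++d)
    ghw[d + ga] = (int)std::floor(std::sqrt(ra * ra - (double)d * d));

  // largest possible footprint (fluid limit, G = 0) at the field peak: a
  // nucleation with no remaining RBC pixels inside this radius is a no-op
  // and can skip the modulus average and the stamp
  double p_peak = 0.0;
  for (int k = 0; k < n_cand; ++k) p_peak = std::max(p_peak, cand_pa[k]);
  double rf_px = 0.0;
  if (p_peak > P0) {
    const double xi0 = (p_peak - P0) / P0;
    rf_px = (R0 + std::sqrt(2.0 * P0 * xi0 / (9.0 * rho)) * tau *
                      std::cbrt(xi0 / 3.0 + 1.0)) /
            pixel_m;
  }
  const int rf = (int)std::floor(rf_px);
  std::vector<int> fhw(2 * rf + 1);
  for (int d = -rf; d <= rf; ++d)
    fhw[d + rf] = (int)std::floor(std::sqrt(rf_px * rf_px - (double)d * d));

  std::vector<int> nuc_idx;
  std::vector<double> nuc_rpx;
  NumericVector area_px(n_pulses);
  long ablated_count = 0;
  // count pixels already ablated in the input state (resumed treatments)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) == 3) ++ablated_count;

  for (int pulse = 0; pulse < n_pulses; ++pulse) {
    // 1. nucleation draws and bubble sizing on the pulse-start state
    nuc_idx.clear();
    nuc_rpx.clear();
    for (int k = 0; k < n_cand; ++k) {
      double u = unif_rand();
      if (cand_p[k] <= u) continue;
      const int i0 = cand_i[k], j0 = cand_j[k];
      bool any_rbc = false;
      for (int d = -rf; d <= rf && !any_rbc; ++d) {
        int i = i0 + d;
        if (i < 0 || i >= nr) continue;
        int hw = fhw[d + rf];
        int j1 = j0 - hw < 0 ? 0 : j0 - hw;
        int j2 = j0 + hw >= nc ? nc - 1 : j0 + hw;
        if (rbc.segment(i, j1, j2) > 0) any_rbc = true;
      }
      if (!any_rbc) continue;
      // local mean elastic modulus over the averaging disk
      double g_sum = 0.0;
      long t_cnt = 0;
      for (int d = -ga; d <= ga; ++d) {
        int i = i0 + d;
        if (i < 0 || i >= nr) continue;
        int hw = ghw[d + ga];
        int j1 = j0 - hw < 0 ? 0 : j0 - hw;
        int j2 = j0 + hw >= nc ? nc - 1 : j0 + hw;
        int t = thrombus.segment(i, j1, j2);
        if (t == 0) continue;
        int f = fibrin.segment(i, j1, j2);
        int rb = rbc.segment(i, j1, j2);
        g_sum += G_fibrin * f + G_rbc * rb + G_ablated * (t - f - rb);
        t_cnt += t;
      }
      if (t_cnt == 0) continue;  // degenerate neighbourhood
      const double G = g_sum / (double)t_cnt;
      const double xi = (cand_pa[k] - P0) / P0 - 6.0 * G / P0;
      if (xi <= 0.0) continue;  // growth arrested: nucleus-sized bubble
      const double peff = P0 + 4.0 * G / 3.0;
      const double rmax =
          R0 + std::sqrt(2.0 * P0 * xi / (9.0 * rho)) * tau *
                   std::cbrt(xi * P0 / (3.0 * peff) + 1.0);
      const double rpx = rmax / pixel_m;
      if (rpx < 0.0) continue;
      nuc_idx.push_back(k);
      nuc_rpx.push_back(rpx);
    }

    // 2. apply all footprints: RBC pixels within rpx become ablated
    for (size_t b = 0; b < nuc_idx.size(); ++b) {
      const int i0 = cand_i[nuc_idx[b]], j0 = cand_j[nuc_idx[b]];
      const double rpx = nuc_rpx[b];
      const int rr = (int)std::floor(rpx);
      for (int d = -rr; d <= rr; ++d) {
        int i = i0 + d;
        if (i < 0 || i >= nr) continue;
        int hw = (int)std::floor(std::sqrt(rpx * rpx - (double)d * d));
        int j1 = j0 - hw < 0 ? 0 : j0 - hw;
        int j2 = j0 + hw >= nc ? nc - 1 : j0 + hw;
        if (rbc.segment(i, j1, j2) == 0) continue;
        for (int j = j1; j <= j2; ++j) {
          if (lab(i, j) == 1) {
            lab(i, j) = 3;
            rbc.remove_at(i, j);
            ++ablated_count;
          }
        }
      }
    }
    area_px[pulse] = (double)ablated_count;
  }

  return List::create(_["labels"] = lab, _["ablated_px"] = area_px,
                      _["n_candidates"] = n_cand);
}
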
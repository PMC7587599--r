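#include "core.h"
using namespace Rcpp;

// Per-chain radius of gyration, end-to-end distance and centre of mass for
// every frame of a trajectory. Coordinates must be unwrapped (whole
// molecules); the engine propagates unwrapped positions so its snapshots
// qualify directly.

// [[Rcpp::export]]
List chain_metrics_cpp(NumericVector frames, IntegerVector chain_id,
                       NumericVector mass, int n_chains) {
  IntegerVector dims = frames.attr("dim");
  int n = dims[0], n_frames = dims[2];
  NumericMatrix rg(n_frames, n_chains), dee(n_frames, n_chains);
  NumericVector com(Dimension(n_frames, n_chains, 3));
  std::vector<double> M(n_chains, 0.0);
  std::vector<int> first(n_chains, -1), last(n_chains, -1);
  for (int i = 0; i < n; ++i) {
    int c = chain_id[i] - 1;
    M[c] += mass[i];
    if (first[c] < 0) first[c] = i;
    last[c] = i;
  }
  for (int fr = 0; fr < n_frames; ++fr) {
    R_xlen_t base = (R_xlen_t)3 * n * fr;
    std::vector<double> cx(n_chains, 0), cy(n_chains, 0), cz(n_chains, 0);
    for (int i = 0; i < n; ++i) {
      int c = chain_id[i] - 1;
      cx[c] += mass[i] * frames[base + i];
      cy[c] += mass[i] * frames[base + i + n];
      cz[c] += mass[i] * frames[base + i + 2 * n];
    }
    for (int c = 0; c < n_chains; ++c) {
      cx[c] /= M[c];
      cy[c] /= M[c];
      cz[c] /= M[c];
      com[fr + (R_xlen_t)n_frames * c] = cx[c];
      com[fr + (R_xlen_t)n_frames * (c + n_chains)] = cy[c];
      com[fr + (R_xlen_t)n_frames * (c + 2 * n_chains)] = cz[c];
    }
    std::vector<double> s(n_chains, 0.0);
    for (int i = 0; i < n; ++i) {
      int c = chain_id[i] - 1;
      double dx = frames[base + i] - cx[c];
      double dy = frames[base + i + n] - cy[c];
      double dz = frames[base + i + 2 * n] - cz[c];
      s[c] += mass[i] * (dx * dx + dy * dy + dz * dz);
    }
    for (int c = 0; c < n_chains; ++c) {
      rg(fr, c) = std::sqrt(s[c] / M[c]);
      double dx = frames[base + last[c]] - frames[base + first[c]];
      double dy = frames[base + last[c] + n] - frames[base + first[c] + n];
      double dz =
          frames[base + last[c] + 2 * n] - frames[base + first[c] + 2 * n];
      dee(fr, c) = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  }
  return List::create(_["rg"] = rg, _["dee"] = dee, _["com"] = com);
}

// Contact counts per chain per frame at cutoff r_contact (reduced units),
// under minimum image. Intra contacts: same-chain bead pairs |i-j| >= min_sep
// (min_sep = 3 reproduces the reference contact tallies; min_sep = 2 excludes
// only directly bonded pairs).
// Inter contacts: bead-bead pairs between different chains; with
// mode = "pairs" every bead-bead pair below the cutoff adds one contact to
// both chains; with mode = "beads" each foreign bead is counted at most once
// per reference chain.

// [[Rcpp::export]]
List contact_counts_cpp(NumericVector frames, NumericMatrix frame_box,
                        IntegerVector chain_id, int n_chains, double r_contact,
                        std::string mode, int min_sep) {
  IntegerVector dims = frames.attr("dim");
  int n = dims[0], n_frames = dims[2];
  double rc2 = r_contact * r_contact;
  NumericMatrix intra(n_frames, n_chains), inter(n_frames, n_chains);
  bool unique_beads = (mode == "beads");
  // bead index within its chain, for the |i-j| >= min_sep rule
  std::vector<int> pos_in_chain(n);
  {
    std::vector<int> cnt(n_chains, 0);
    for (int i = 0; i < n; ++i) pos_in_chain[i] = cnt[chain_id[i] - 1]++;
  }
  std::vector<char> seen;
  if (unique_beads) seen.assign((size_t)n * n_chains, 0);
  for (int fr = 0; fr < n_frames; ++fr) {
    R_xlen_t base = (R_xlen_t)3 * n * fr;
    double bx = frame_box(fr, 0), by = frame_box(fr, 1), bz = frame_box(fr, 2);
    if (unique_beads) std::fill(seen.begin(), seen.end(), 0);
    for (int i = 0; i < n - 1; ++i) {
      int ci = chain_id[i] - 1;
      double xi = frames[base + i], yi = frames[base + i + n],
             zi = frames[base + i + 2 * n];
      for (int j = i + 1; j < n; ++j) {
        double dx = min_img(xi - frames[base + j], bx);
        double dy = min_img(yi - frames[base + j + n], by);
        double dz = min_img(zi - frames[base + j + 2 * n], bz);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= rc2) continue;
        int cj = chain_id[j] - 1;
        if (ci == cj) {
          if (std::abs(pos_in_chain[i] - pos_in_chain[j]) >= min_sep)
            intra(fr, ci) += 1.0;
        } else {
          if (unique_beads) {
            if (!seen[(size_t)j * n_chains + ci]) {
              seen[(size_t)j * n_chains + ci] = 1;
              inter(fr, ci) += 1.0;
            }
            if (!seen[(size_t)i * n_chains + cj]) {
              seen[(size_t)i * n_chains + cj] = 1;
              inter(fr, cj) += 1.0;
            }
          } else {
            inter(fr, ci) += 1.0;
            inter(fr, cj) += 1.0;
          }
        }
      }
    }
  }
  return List::create(_["intra"] = intra, _["inter"] = inter);
}

// Binned density profile along one axis, averaged over frames.
// Returns mean reduced density per bin.

// [[Rcpp::export]]
NumericVector density_profile_cpp(NumericVector frames,
                                  NumericMatrix frame_box, int axis,
                                  int n_bins, double sigma) {
  IntegerVector dims = frames.attr("dim");
  int n = dims[0], n_frames = dims[2];
  NumericVector prof(n_bins);
  for (int fr = 0; fr < n_frames; ++fr) {
    R_xlen_t base = (R_xlen_t)3 * n * fr;
    double L = frame_box(fr, axis);
    double area = 1.0;
    for (int d = 0; d < 3; ++d)
      if (d != axis) area *= frame_box(fr, d);
    double binw = L / n_bins;
    double s3 = sigma * sigma * sigma;
    for (int i = 0; i < n; ++i) {
      double c = wrap0(frames[base + i + (R_xlen_t)n * axis], L);
      int b = (int)(c / binw);
      if (b >= n_bins) b = n_bins - 1;
      prof[b] += s3 / (binw * area);
    }
  }
  for (int b = 0; b < n_bins; ++b) prof[b] /= n_frames;
  return prof;
}
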
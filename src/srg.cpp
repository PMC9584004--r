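#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

namespace {

struct Cand {
  double dist;
  int row, col, region;
};

// min-heap: smallest distance first, ties by (row, col, region)
struct CandCmp {
  bool operator()(const Cand &a, const Cand &b) const {
    if (a.dist != b.dist) return a.dist > b.dist;
    if (a.row != b.row) return a.row > b.row;
    if (a.col != b.col) return a.col > b.col;
    return a.region > b.region;
  }
};

} // namespace

// Seeded region growing over one or more feature layers.
// features: list of nr x nc numeric matrices (already standardised by the
// caller when more than one); seeds: m x 2 matrix of 1-based (row, col);
// threshold: maximum Euclidean feature distance between a frontier cell and
// the running mean of the adjoining region; max_cells: per-region area cap.
// Returns nr x nc integer labels, 0 = unassigned. 4-connectivity.
// [[Rcpp::export]]
IntegerMatrix srg_cpp(List features, IntegerMatrix seeds, double threshold,
                      int max_cells) {
  int nl = features.size();
  std::vector<NumericMatrix> lay;
  for (int l = 0; l < nl; ++l) lay.push_back(as<NumericMatrix>(features[l]));
  int nr = lay[0].nrow(), nc = lay[0].ncol();

  IntegerMatrix labels(nr, nc);
  int n_seed = seeds.nrow();
  std::vector<std::vector<double>> sum(n_seed + 1,
                                       std::vector<double>(nl, 0.0));
  std::vector<int> count(n_seed + 1, 0);

  std::priority_queue<Cand, std::vector<Cand>, CandCmp> pq;
  const int drs[4] = {-1, 1, 0, 0};
  const int dcs[4] = {0, 0, -1, 1};

  auto is_valid = [&](int r, int c) {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return false;
    for (int l = 0; l < nl; ++l)
      if (NumericMatrix::is_na(lay[l](r, c))) return false;
    return true;
  };
  auto dist_to_region = [&](int r, int c, int reg) {
    double d2 = 0.0;
    for (int l = 0; l < nl; ++l) {
      double diff = lay[l](r, c) - sum[reg][l] / count[reg];
      d2 += diff * diff;
    }
    return std::sqrt(d2);
  };
  auto assign = [&](int r, int c, int reg) {
    labels(r, c) = reg;
    for (int l = 0; l < nl; ++l) sum[reg][l] += lay[l](r, c);
    count[reg] += 1;
    for (int k = 0; k < 4; ++k) {
      int rr = r + drs[k], cc = c + dcs[k];
      if (is_valid(rr, cc) && labels(rr, cc) == 0) {
        Cand cd{dist_to_region(rr, cc, reg), rr, cc, reg};
        if (cd.dist <= threshold) pq.push(cd);
      }
    }
  };

  for (int s = 0; s < n_seed; ++s) {
    int r = seeds(s, 0) - 1, c = seeds(s, 1) - 1;
    if (!is_valid(r, c) || labels(r, c) != 0) continue;
    assign(r, c, s + 1);
  }

  while (!pq.empty()) {
    Cand cd = pq.top();
    pq.pop();
    if (labels(cd.row, cd.col) != 0) continue;
    if (count[cd.region] >= max_cells) continue;
    double d = dist_to_region(cd.row, cd.col, cd.region);
    if (d > cd.dist + 1e-12) {
      // the region mean moved since this candidate was queued
      if (d <= threshold) {
        pq.push(Cand{d, cd.row, cd.col, cd.region});
      }
      continue;
    }
    assign(cd.row, cd.col, cd.region);
  }
  return labels;
}
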
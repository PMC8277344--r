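#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Neighborhood offsets; first 4 entries are the 4-neighborhood.
static const int DR[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC[8] = {0, 0, -1, 1, -1, 1, -1, 1};

// Connected component of {I <= threshold} containing the seed.
// Plain breadth-first flood fill; stops (leaked = true) once the region
// exceeds max_px.
// [[Rcpp::export]]
List rg_fixed_cpp(NumericMatrix img, int seed_r, int seed_c, double threshold,
                  int connectivity, int max_px) {
  const int nr = img.nrow(), nc = img.ncol();
  const int nn = (connectivity == 8) ? 8 : 4;
  LogicalMatrix mask(nr, nc);
  bool leaked = false;
  int count = 0;
  if (img(seed_r, seed_c) <= threshold) {
    std::queue<std::pair<int, int> > q;
    mask(seed_r, seed_c) = true;
    ++count;
    q.push(std::make_pair(seed_r, seed_c));
    while (!q.empty()) {
      std::pair<int, int> p = q.front();
      q.pop();
      for (int k = 0; k < nn; ++k) {
        int r = p.first + DR[k], c = p.second + DC[k];
        if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
        if (mask(r, c) || img(r, c) > threshold) continue;
        mask(r, c) = true;
        if (++count > max_px) { leaked = true; goto done; }
        q.push(std::make_pair(r, c));
      }
    }
  }
done:
  return List::create(_["mask"] = mask, _["leaked"] = leaked,
                      _["area"] = count);
}

// Seeded region growing with the region-mean criterion: repeatedly admit
// the boundary pixel minimizing |I(p) - mean(region)| while that difference
// is <= tau. Ties broken by insertion order (earliest first). The candidate
// boundary is rescanned each step because the region mean moves; region
// sizes here are small enough that the quadratic scan is immaterial.
// [[Rcpp::export]]
List rg_mean_cpp(NumericMatrix img, int seed_r, int seed_c, double tau,
                 int connectivity, int max_px) {
  const int nr = img.nrow(), nc = img.ncol();
  const int nn = (connectivity == 8) ? 8 : 4;
  LogicalMatrix mask(nr, nc);
  std::vector<char> queued(static_cast<size_t>(nr) * nc, 0);
  std::vector<int> brow, bcol;   // boundary candidates in insertion order
  std::vector<char> used;
  bool leaked = false;

  mask(seed_r, seed_c) = true;
  double sum = img(seed_r, seed_c);
  int count = 1;
  queued[static_cast<size_t>(seed_c) * nr + seed_r] = 1;

  int cur_r = seed_r, cur_c = seed_c;
  for (;;) {
    // push unqueued neighbors of the pixel admitted last
    for (int k = 0; k < nn; ++k) {
      int r = cur_r + DR[k], c = cur_c + DC[k];
      if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
      size_t idx = static_cast<size_t>(c) * nr + r;
      if (queued[idx]) continue;
      queued[idx] = 1;
      brow.push_back(r);
      bcol.push_back(c);
      used.push_back(0);
    }
    // scan boundary for the best candidate (strict < keeps earliest tie)
    double mean = sum / count, best = R_PosInf;
    long best_i = -1;
    for (size_t i = 0; i < brow.size(); ++i) {
      if (used[i]) continue;
      double d = std::fabs(img(brow[i], bcol[i]) - mean);
      if (d < best) { best = d; best_i = static_cast<long>(i); }
    }
    if (best_i < 0 || best > tau) break;
    used[best_i] = 1;
    cur_r = brow[best_i];
    cur_c = bcol[best_i];
    mask(cur_r, cur_c) = true;
    sum += img(cur_r, cur_c);
    if (++count > max_px) { leaked = true; break; }
  }
  return List::create(_["mask"] = mask, _["leaked"] = leaked,
                      _["area"] = count);
}
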
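#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Multi-source geodesic region growing (level-synchronous BFS).
//
// Seeds keep their labels everywhere (even outside the foreground mask);
// growth proceeds only through foreground pixels, 4-connected. Each
// unlabelled foreground pixel reached at BFS round d receives the minimum
// label among its already-labelled neighbours, which is provably the
// minimum label over all seeds at minimal geodesic distance d — i.e. the
// nearest-seed partition with ties broken toward the smaller label.
// [[Rcpp::export]]
IntegerMatrix seeded_growth_cpp(IntegerMatrix seeds, LogicalMatrix foreground) {
  const int nr = seeds.nrow(), nc = seeds.ncol();
  if (foreground.nrow() != nr || foreground.ncol() != nc)
    stop("seeds and foreground must have identical dimensions");

  IntegerMatrix labels(nr, nc);
  std::vector<int> frontier;
  frontier.reserve(1024);

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int s = seeds(i, j);
      if (s > 0) {
        labels(i, j) = s;
        if (foreground(i, j)) frontier.push_back(i + j * nr);
      }
    }

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  std::vector<int> touched;   // proposals made this round
  std::vector<int> next;

  while (!frontier.empty()) {
    touched.clear();
    next.clear();
    for (size_t k = 0; k < frontier.size(); ++k) {
      const int idx = frontier[k];
      const int i = idx % nr, j = idx / nr;
      const int lab = labels(i, j);
      for (int d = 0; d < 4; ++d) {
        const int ni = i + dr[d], nj = j + dc[d];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        if (!foreground(ni, nj)) continue;
        int cur = labels(ni, nj);
        if (cur == 0) {                       // first proposal this round
          labels(ni, nj) = -lab;              // negative marks "pending"
          touched.push_back(ni + nj * nr);
        } else if (cur < 0 && -cur > lab) {   // smaller label wins the tie
          labels(ni, nj) = -lab;
        }
      }
    }
    for (size_t k = 0; k < touched.size(); ++k) {
      const int idx = touched[k];
      const int i = idx % nr, j = idx / nr;
      labels(i, j) = -labels(i, j);           // commit
      next.push_back(idx);
    }
    frontier.swap(next);
  }
  return labels;
}

// Per-label area and intensity sum in one pass; used by measure_objects.
// [[Rcpp::export]]
List label_stats_cpp(IntegerMatrix labels, NumericMatrix intensity) {
  const int nr = labels.nrow(), nc = labels.ncol();
  if (intensity.nrow() != nr || intensity.ncol() != nc)
    stop("labels and intensity must have identical dimensions");
  int maxlab = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (labels(i, j) > maxlab) maxlab = labels(i, j);
  std::vector<double> area(maxlab + 1, 0.0), total(maxlab + 1, 0.0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const int l = labels(i, j);
      if (l > 0) {
        area[l] += 1.0;
        total[l] += intensity(i, j);
      }
    }
  NumericVector a(maxlab), s(maxlab);
  for (int l = 1; l <= maxlab; ++l) {
    a[l - 1] = area[l];
    s[l - 1] = total[l];
  }
  return List::create(_["label"] = seq_len(maxlab), _["area"] = a, _["sum"] = s);
}
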
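#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 4- or 8-connected component labelling of a binary raster.
// Returns integer matrix with 0 on background, components numbered 1..K.
// [[Rcpp::export(name = ".ccl_cpp")]]
IntegerMatrix ccl_cpp(LogicalMatrix x, int connectivity) {
  int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  int k = 0;
  std::vector<int> dr, dc;
  dr = {-1, 1, 0, 0};
  dc = {0, 0, -1, 1};
  if (connectivity == 8) {
    dr.insert(dr.end(), {-1, -1, 1, 1});
    dc.insert(dc.end(), {-1, 1, -1, 1});
  }
  std::queue<std::pair<int,int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!x(i, j) || lab(i, j) != 0) continue;
      ++k;
      lab(i, j) = k;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (size_t d = 0; d < dr.size(); ++d) {
          int ii = p.first + dr[d], jj = p.second + dc[d];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (x(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = k;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}

// SLIC superpixels restricted to a validity region.
// r, g, b: colour planes on a common scale (0..255); inside: validity mask.
// Returns integer matrix: superpixel id 1..K inside, -1 outside.
// [[Rcpp::export(name = ".slic_cpp")]]
IntegerMatrix slic_cpp(NumericMatrix r, NumericMatrix g, NumericMatrix b,
                       LogicalMatrix inside, int step, double compactness,
                       int max_iter) {
  int nr = r.nrow(), nc = r.ncol();

  // seed cluster centres on a regular grid over the validity region
  std::vector<double> cr, cg, cb, ci, cj;
  for (int j = step / 2; j < nc; j += step) {
    for (int i = step / 2; i < nr; i += step) {
      if (!inside(i, j)) continue;
      cr.push_back(r(i, j)); cg.push_back(g(i, j)); cb.push_back(b(i, j));
      ci.push_back(i); cj.push_back(j);
    }
  }
  int K = (int) cr.size();
  if (K == 0) stop("no superpixel seeds fall inside the validity region; region_size_px too large for the spot");

  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), -1);
  NumericMatrix dist(nr, nc);
  double m2 = (compactness / step) * (compactness / step);

  for (int iter = 0; iter < max_iter; ++iter) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int k = 0; k < K; ++k) {
      int i0 = std::max(0, (int) ci[k] - step), i1 = std::min(nr - 1, (int) ci[k] + step);
      int j0 = std::max(0, (int) cj[k] - step), j1 = std::min(nc - 1, (int) cj[k] + step);
      for (int j = j0; j <= j1; ++j) {
        for (int i = i0; i <= i1; ++i) {
          if (!inside(i, j)) continue;
          double dc = (r(i, j) - cr[k]) * (r(i, j) - cr[k]) +
                      (g(i, j) - cg[k]) * (g(i, j) - cg[k]) +
                      (b(i, j) - cb[k]) * (b(i, j) - cb[k]);
          double ds = (i - ci[k]) * (i - ci[k]) + (j - cj[k]) * (j - cj[k]);
          double D = dc + m2 * ds;
          if (D < dist(i, j)) { dist(i, j) = D; lab(i, j) = k; }
        }
      }
    }
    // update centres
    std::vector<double> sr(K, 0), sg(K, 0), sb(K, 0), si(K, 0), sj(K, 0), n(K, 0);
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        int k = lab(i, j);
        if (k < 0) continue;
        sr[k] += r(i, j); sg[k] += g(i, j); sb[k] += b(i, j);
        si[k] += i; sj[k] += j; n[k] += 1;
      }
    for (int k = 0; k < K; ++k) {
      if (n[k] == 0) continue;
      cr[k] = sr[k] / n[k]; cg[k] = sg[k] / n[k]; cb[k] = sb[k] / n[k];
      ci[k] = si[k] / n[k]; cj[k] = sj[k] / n[k];
    }
  }

  // any inside pixel missed by all windows: assign to nearest centre spatially
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!inside(i, j) || lab(i, j) >= 0) continue;
      double best = R_PosInf; int bk = 0;
      for (int k = 0; k < K; ++k) {
        double ds = (i - ci[k]) * (i - ci[k]) + (j - cj[k]) * (j - cj[k]);
        if (ds < best) { best = ds; bk = k; }
      }
      lab(i, j) = bk;
    }

  // enforce connectivity: relabel connected fragments, absorbing fragments
  // smaller than step*step/4 into an adjacent already-relabelled superpixel
  IntegerMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), -1);
  int min_size = std::max(1, step * step / 4);
  int next = 0;
  int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
  std::vector<std::pair<int,int> > comp;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (lab(i, j) < 0 || out(i, j) >= 0) continue;
      comp.clear();
      int adj = -1;  // neighbouring new label seen while flood-filling
      std::queue<std::pair<int,int> > q;
      q.push(std::make_pair(i, j));
      out(i, j) = next + 1;
      comp.push_back(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (int d = 0; d < 4; ++d) {
          int ii = p.first + dr4[d], jj = p.second + dc4[d];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (lab(ii, jj) < 0) continue;
          if (out(ii, jj) >= 0 && out(ii, jj) != next + 1) adj = out(ii, jj);
          if (lab(ii, jj) == lab(i, j) && out(ii, jj) < 0) {
            out(ii, jj) = next + 1;
            comp.push_back(std::make_pair(ii, jj));
            q.push(std::make_pair(ii, jj));
          }
        }
      }
      if ((int) comp.size() < min_size && adj > 0) {
        for (size_t t = 0; t < comp.size(); ++t)
          out(comp[t].first, comp[t].second) = adj;
      } else {
        ++next;
      }
    }
  }
  return out;
}
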
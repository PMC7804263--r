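#include <Rcpp.h>
#include <map>
#include <set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Connected components (4-connectivity) of a logical mask. Labels 1..k in
// raster scan order of first encounter; 0 outside the mask.
// [[Rcpp::export]]
IntegerMatrix cpp_connected_components(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        const int dr[4] = {-1, 1, 0, 0};
        const int dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// One-pass majority filter on a categorical raster. NA cells stay NA and do
// not vote. Ties: keep the current class if it is among the modes, else the
// smallest class code (deterministic).
// [[Rcpp::export]]
IntegerMatrix cpp_majority_filter(IntegerMatrix lab, int halfwidth) {
  int nr = lab.nrow(), nc = lab.ncol();
  IntegerMatrix out(nr, nc);
  if (halfwidth <= 0) { std::copy(lab.begin(), lab.end(), out.begin()); return out; }
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int cur = lab(r, c);
      if (cur == NA_INTEGER) { out(r, c) = NA_INTEGER; continue; }
      std::map<int, int> counts;
      for (int dc = -halfwidth; dc <= halfwidth; ++dc) {
        int c2 = c + dc;
        if (c2 < 0 || c2 >= nc) continue;
        for (int dr = -halfwidth; dr <= halfwidth; ++dr) {
          int r2 = r + dr;
          if (r2 < 0 || r2 >= nr) continue;
          int v = lab(r2, c2);
          if (v != NA_INTEGER) counts[v]++;
        }
      }
      int best = cur, bestn = -1;
      for (std::map<int, int>::iterator it = counts.begin(); it != counts.end(); ++it) {
        if (it->second > bestn) { bestn = it->second; best = it->first; }
      }
      if (counts.count(cur) && counts[cur] == bestn) best = cur;
      out(r, c) = best;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Pairwise Bray-Curtis similarity (percent) between rows of a non-negative
// matrix. A pair of all-zero rows gets similarity 0.
// [[Rcpp::export]]
NumericMatrix cpp_bray_curtis(NumericMatrix x) {
  int n = x.nrow(), p = x.ncol();
  NumericMatrix s(n, n);
  for (int i = 0; i < n; ++i) s(i, i) = 100.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double num = 0.0, den = 0.0;
      for (int k = 0; k < p; ++k) {
        double a = x(i, k), b = x(j, k);
        num += (a < b ? a : b);
        den += a + b;
      }
      double sim = (den > 0.0) ? 100.0 * 2.0 * num / den : 0.0;
      s(i, j) = sim;
      s(j, i) = sim;
    }
  }
  return s;
}

static void bc_profile(const std::vector<double>& x, int n, int p,
                       std::vector<double>& prof) {
  // x column-major n x p; prof gets sorted ascending pairwise similarities
  int m = n * (n - 1) / 2, q = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double num = 0.0, den = 0.0;
      for (int k = 0; k < p; ++k) {
        double a = x[i + k * n], b = x[j + k * n];
        num += (a < b ? a : b);
        den += a + b;
      }
      prof[q++] = (den > 0.0) ? 100.0 * 2.0 * num / den : 0.0;
    }
  }
  (void)m;
  std::sort(prof.begin(), prof.end());
}

static void permute_columns(std::vector<double>& x, int n, int p) {
  // Fisher-Yates within each column, driven by R's RNG for reproducibility
  for (int k = 0; k < p; ++k) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(x[i + k * n], x[j + k * n]);
    }
  }
}

// ---------------------------------------------------------------------------
// SIMPROF test for one group of units (rows of x, a transformed community
// matrix). Permutes values independently across units within each taxon.
// Returns pi (observed departure from the mean permuted similarity profile)
// and the permutation p-value with the (1+count)/(1+nperm) estimator.
// [[Rcpp::export]]
List cpp_simprof_test(NumericMatrix x, int nperm_mean, int nperm_test) {
  int n = x.nrow(), p = x.ncol();
  int m = n * (n - 1) / 2;
  std::vector<double> dat(x.begin(), x.end());
  std::vector<double> obs(m), mean_prof(m, 0.0), prof(m), work(dat);
  bc_profile(dat, n, p, obs);
  GetRNGstate();
  for (int b = 0; b < nperm_mean; ++b) {
    work = dat;
    permute_columns(work, n, p);
    bc_profile(work, n, p, prof);
    for (int q = 0; q < m; ++q) mean_prof[q] += prof[q];
  }
  for (int q = 0; q < m; ++q) mean_prof[q] /= nperm_mean;
  double pi_obs = 0.0;
  for (int q = 0; q < m; ++q) pi_obs += std::fabs(obs[q] - mean_prof[q]);
  int count = 0;
  for (int b = 0; b < nperm_test; ++b) {
    work = dat;
    permute_columns(work, n, p);
    bc_profile(work, n, p, prof);
    double pi_b = 0.0;
    for (int q = 0; q < m; ++q) pi_b += std::fabs(prof[q] - mean_prof[q]);
    if (pi_b >= pi_obs) ++count;
  }
  PutRNGstate();
  double pval = (1.0 + count) / (1.0 + nperm_test);
  return List::create(_["pi"] = pi_obs, _["p"] = pval,
                      _["n_perm"] = nperm_test);
}

// ---------------------------------------------------------------------------
// Multiresolution (Baatz-Schape) bottom-up region merging.
// layers: list of numeric matrices (same dims); mask: logical matrix;
// merge cost f = (1-shape_w) * sum_l w_l * D(n*sd_l)
//              + shape_w * (cmpct_w * D(n*perim/sqrt(n))
//                           + (1-cmpct_w) * D(n*perim/bboxperim))
// where D(h) = h_merged - (h_a + h_b). Merging allowed while f < scale^2,
// scheduled by local mutual best fitting with lowest-id tie-breaking.
// Returns segment label matrix (1..k, raster-scan compacted; NA off-mask).

struct Seg {
  double n;
  std::vector<double> sum, sumsq;
  double perim;
  int rmin, rmax, cmin, cmax;
  std::map<int, int> nbr;   // neighbor id -> shared edge count
  bool alive;
};

static inline double seg_shape_h(const Seg& s, bool compact) {
  if (compact) return s.n * s.perim / std::sqrt(s.n);
  double bb = 2.0 * ((s.rmax - s.rmin + 1) + (s.cmax - s.cmin + 1));
  return s.n * s.perim / bb;
}

static double merge_cost(const Seg& a, const Seg& b, int shared,
                         const std::vector<double>& bw,
                         double shape_w, double cmpct_w) {
  int L = (int)bw.size();
  double color = 0.0;
  double n = a.n + b.n;
  for (int l = 0; l < L; ++l) {
    if (bw[l] <= 0) continue;
    double sum = a.sum[l] + b.sum[l], ssq = a.sumsq[l] + b.sumsq[l];
    double var = ssq / n - (sum / n) * (sum / n);
    double sd = var > 0 ? std::sqrt(var) : 0.0;
    double va = a.sumsq[l] / a.n - (a.sum[l] / a.n) * (a.sum[l] / a.n);
    double vb = b.sumsq[l] / b.n - (b.sum[l] / b.n) * (b.sum[l] / b.n);
    double sda = va > 0 ? std::sqrt(va) : 0.0;
    double sdb = vb > 0 ? std::sqrt(vb) : 0.0;
    color += bw[l] * (n * sd - (a.n * sda + b.n * sdb));
  }
  double f = (1.0 - shape_w) * color;
  if (shape_w > 0) {
    Seg m;
    m.n = n;
    m.perim = a.perim + b.perim - 2.0 * shared;
    m.rmin = std::min(a.rmin, b.rmin); m.rmax = std::max(a.rmax, b.rmax);
    m.cmin = std::min(a.cmin, b.cmin); m.cmax = std::max(a.cmax, b.cmax);
    double hc = seg_shape_h(m, true)  - (seg_shape_h(a, true)  + seg_shape_h(b, true));
    double hs = seg_shape_h(m, false) - (seg_shape_h(a, false) + seg_shape_h(b, false));
    f += shape_w * (cmpct_w * hc + (1.0 - cmpct_w) * hs);
  }
  return f;
}

// best neighbor of s: minimal cost, ties to smallest neighbor id
static int best_neighbor(int sid, std::vector<Seg>& segs,
                         const std::vector<double>& bw,
                         double shape_w, double cmpct_w, double* cost_out) {
  Seg& s = segs[sid];
  int best = -1;
  double bestc = R_PosInf;
  for (std::map<int, int>::iterator it = s.nbr.begin(); it != s.nbr.end(); ++it) {
    double c = merge_cost(s, segs[it->first], it->second, bw, shape_w, cmpct_w);
    if (c < bestc - 1e-12) { bestc = c; best = it->first; }
  }
  *cost_out = bestc;
  return best;
}

// [[Rcpp::export]]
IntegerMatrix cpp_multiresolution_segment(List layers, LogicalMatrix mask,
                                          double scale, double shape_w,
                                          double cmpct_w, NumericVector band_w) {
  int L = layers.size();
  NumericMatrix first = layers[0];
  int nr = first.nrow(), nc = first.ncol();
  std::vector<NumericMatrix> lay;
  for (int l = 0; l < L; ++l) lay.push_back(as<NumericMatrix>(layers[l]));
  std::vector<double> bw(band_w.begin(), band_w.end());

  // map masked pixels -> dense ids in raster scan (row-major by row, col)
  std::vector<int> pid(nr * nc, -1);
  int nseg = 0;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (mask(r, c)) pid[r + c * nr] = nseg++;
  if (nseg == 0) stop("empty mask");

  std::vector<Seg> segs(nseg);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int id = pid[r + c * nr];
      if (id < 0) continue;
      Seg& s = segs[id];
      s.n = 1.0; s.perim = 4.0; s.alive = true;
      s.rmin = s.rmax = r; s.cmin = s.cmax = c;
      s.sum.resize(L); s.sumsq.resize(L);
      for (int l = 0; l < L; ++l) {
        double v = lay[l](r, c);
        s.sum[l] = v; s.sumsq[l] = v * v;
      }
      if (r + 1 < nr && pid[(r + 1) + c * nr] >= 0) {
        int id2 = pid[(r + 1) + c * nr];
        s.nbr[id2] = 1;
      }
      if (c + 1 < nc && pid[r + (c + 1) * nr] >= 0) {
        int id2 = pid[r + (c + 1) * nr];
        s.nbr[id2] = 1;
      }
    }
  }
  // symmetrize adjacency
  for (int i = 0; i < nseg; ++i)
    for (std::map<int, int>::iterator it = segs[i].nbr.begin(); it != segs[i].nbr.end(); ++it)
      segs[it->first].nbr[i] = it->second;

  double thr = scale * scale;
  std::vector<int> parent(nseg);
  for (int i = 0; i < nseg; ++i) parent[i] = i;
  std::set<int> active;
  for (int i = 0; i < nseg; ++i) active.insert(i);

  if (thr > 0) {
    bool merged_any = true;
    while (merged_any) {
      merged_any = false;
      for (std::set<int>::iterator it = active.begin(); it != active.end(); ) {
        int s = *it;
        double cs, cb;
        int b = best_neighbor(s, segs, bw, shape_w, cmpct_w, &cs);
        if (b >= 0 && cs < thr) {
          int bb = best_neighbor(b, segs, bw, shape_w, cmpct_w, &cb);
          if (bb == s) {
            // merge into the smaller id
            int keep = std::min(s, b), drop = std::max(s, b);
            Seg& K = segs[keep];
            Seg& D = segs[drop];
            int shared = K.nbr[drop];
            K.n += D.n;
            for (int l = 0; l < L; ++l) { K.sum[l] += D.sum[l]; K.sumsq[l] += D.sumsq[l]; }
            K.perim += D.perim - 2.0 * shared;
            K.rmin = std::min(K.rmin, D.rmin); K.rmax = std::max(K.rmax, D.rmax);
            K.cmin = std::min(K.cmin, D.cmin); K.cmax = std::max(K.cmax, D.cmax);
            K.nbr.erase(drop);
            for (std::map<int, int>::iterator jt = D.nbr.begin(); jt != D.nbr.end(); ++jt) {
              int o = jt->first;
              if (o == keep) continue;
              K.nbr[o] += jt->second;
              segs[o].nbr.erase(drop);
              segs[o].nbr[keep] = K.nbr[o];
            }
            D.alive = false;
            D.nbr.clear(); D.sum.clear(); D.sumsq.clear();
            parent[drop] = keep;
            merged_any = true;
            if (drop == s) {
              // current iterator element vanished
              it = active.erase(it);
              continue;
            } else {
              active.erase(drop);
            }
          }
        }
        ++it;
      }
    }
  }

  // resolve parents (path compression)
  for (int i = 0; i < nseg; ++i) {
    int p = i;
    while (parent[p] != p) p = parent[p];
    int q = i;
    while (parent[q] != q) { int nq = parent[q]; parent[q] = p; q = nq; }
  }
  // compact labels in raster-scan order of first occurrence
  std::map<int, int> relab;
  int next = 0;
  IntegerMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_INTEGER);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int id = pid[r + c * nr];
      if (id < 0) continue;
      int root = parent[id];
      std::map<int, int>::iterator f = relab.find(root);
      int lab;
      if (f == relab.end()) { lab = ++next; relab[root] = lab; } else lab = f->second;
      out(r, c) = lab;
    }
  }
  return out;
}
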
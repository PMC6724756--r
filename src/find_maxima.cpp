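#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <queue>
using namespace Rcpp;

// Noise-tolerance (prominence) maxima of a 2D image.
//
// A regional maximum m (a connected plateau of equal value v_m with no
// strictly higher 8-neighbour) is accepted iff no path starting at m along
// pixels with value > v_m - tolerance reaches a pixel with value > v_m.
// A maximum with no higher ground anywhere takes the image minimum as its
// reference level: it is accepted iff v_m - min(img) >= tolerance.
//
// Implemented as a descending-order union-find sweep: components grow from
// peaks downwards; when a component with lower peak merges into higher
// ground at saddle level s, its live candidate maxima (all at the component
// peak) are accepted iff s <= v_m - tolerance, otherwise rejected.
// Equal-peak components merge with all candidates kept live (neither side
// has strictly higher ground). Accepted plateaus are deduplicated and
// reduced to their centroid, rounded half-up.

static inline int find_root(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// [[Rcpp::export(name = ".find_maxima_cpp")]]
DataFrame find_maxima_cpp(NumericMatrix img, double tolerance,
                          int exclude_border) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = nr * nc;
  const double* v = img.begin();  // column-major, idx = r + c*nr

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (v[a] != v[b]) return v[a] > v[b];
    return a < b;
  });

  std::vector<int> parent(n, -1);          // -1 = unprocessed
  std::vector<double> peak(n, 0.0);        // valid at roots
  // candidate maxima: seed pixel + value + status (0 live, 1 acc, 2 rej)
  std::vector<int> cand_seed;
  std::vector<double> cand_value;
  std::vector<int> cand_status;
  std::vector<std::vector<int> > live(n);  // live candidate ids, at roots

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  double img_min = v[order[n - 1]];

  for (int oi = 0; oi < n; ++oi) {
    const int p = order[oi];
    const int pr = p % nr, pc = p / nr;
    const double vp = v[p];

    int roots[8];
    int nroots = 0;
    for (int k = 0; k < 8; ++k) {
      const int rr = pr + dr[k], cc = pc + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int q = rr + cc * nr;
      if (parent[q] < 0) continue;
      const int rt = find_root(parent, q);
      bool seen = false;
      for (int t = 0; t < nroots; ++t) if (roots[t] == rt) { seen = true; break; }
      if (!seen) roots[nroots++] = rt;
    }

    if (nroots == 0) {
      // new component: p is (part of) a candidate plateau
      parent[p] = p;
      peak[p] = vp;
      const int cid = (int) cand_seed.size();
      cand_seed.push_back(p);
      cand_value.push_back(vp);
      cand_status.push_back(0);
      live[p].push_back(cid);
      continue;
    }

    // attach p to the first root, then merge the rest at saddle level vp
    int ra = roots[0];
    parent[p] = ra;
    for (int t = 1; t < nroots; ++t) {
      int rb = roots[t];
      // keep the higher-peak root (tie: keep ra)
      if (peak[rb] > peak[ra]) std::swap(ra, rb);
      if (peak[rb] < peak[ra]) {
        // all live candidates of the lower component resolve at saddle vp
        for (size_t u = 0; u < live[rb].size(); ++u) {
          const int cid = live[rb][u];
          cand_status[cid] = (vp > cand_value[cid] - tolerance) ? 2 : 1;
        }
        live[rb].clear();
      } else {
        // equal peaks: neither side is higher ground; keep all live
        live[ra].insert(live[ra].end(), live[rb].begin(), live[rb].end());
        live[rb].clear();
      }
      parent[rb] = ra;
    }
  }

  // survivors: no higher ground anywhere; reference level = image minimum
  for (size_t cid = 0; cid < cand_seed.size(); ++cid) {
    if (cand_status[cid] == 0)
      cand_status[cid] = (cand_value[cid] - img_min >= tolerance) ? 1 : 2;
  }

  // plateau extraction for accepted candidates, dedup by plateau min index
  std::vector<int> plateau_of(n, -1);
  std::vector<double> out_r, out_c, out_v;
  std::vector<int> visit_stack;
  for (size_t cid = 0; cid < cand_seed.size(); ++cid) {
    if (cand_status[cid] != 1) continue;
    const int seed = cand_seed[cid];
    if (plateau_of[seed] >= 0) continue;  // plateau already emitted
    const double vm = cand_value[cid];
    visit_stack.clear();
    visit_stack.push_back(seed);
    plateau_of[seed] = (int) cid;
    double sum_r = 0, sum_c = 0;
    int npix = 0;
    while (!visit_stack.empty()) {
      const int q = visit_stack.back();
      visit_stack.pop_back();
      const int qr = q % nr, qc = q / nr;
      sum_r += qr; sum_c += qc; ++npix;
      for (int k = 0; k < 8; ++k) {
        const int rr = qr + dr[k], cc = qc + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int w = rr + cc * nr;
        if (plateau_of[w] < 0 && v[w] == vm) {
          plateau_of[w] = (int) cid;
          visit_stack.push_back(w);
        }
      }
    }
    // centroid rounded half-up, converted to 1-based coordinates
    const double cr = std::floor(sum_r / npix + 0.5) + 1.0;
    const double cc2 = std::floor(sum_c / npix + 0.5) + 1.0;
    if (exclude_border > 0) {
      if (cr <= exclude_border || cr > nr - exclude_border ||
          cc2 <= exclude_border || cc2 > nc - exclude_border)
        continue;
    }
    out_r.push_back(cr);
    out_c.push_back(cc2);
    out_v.push_back(vm);
  }

  // deterministic order: by row, then column
  std::vector<int> idx(out_r.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = (int) i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (out_r[a] != out_r[b]) return out_r[a] < out_r[b];
    return out_c[a] < out_c[b];
  });
  IntegerVector row(idx.size()), col(idx.size());
  NumericVector val(idx.size());
  for (size_t i = 0; i < idx.size(); ++i) {
    row[i] = (int) out_r[idx[i]];
    col[i] = (int) out_c[idx[i]];
    val[i] = out_v[idx[i]];
  }
  return DataFrame::create(_["row"] = row, _["col"] = col,
                           _["value"] = val);
}
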
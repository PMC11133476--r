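#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
#include <functional>
using namespace Rcpp;

// Best placement of `motif` in `seq`: minimal Hamming mismatch count among
// windows with <= max_mm mismatches, leftmost window on ties. Any character
// difference (including 'N') is a mismatch.
static void best_window(const char* s, int ls, const char* m, int lm,
                        int max_mm, int* out_start, int* out_mm) {
  int bs = -1, bm = max_mm + 1;
  for (int o = 0; o + lm <= ls; ++o) {
    int mm = 0;
    for (int k = 0; k < lm; ++k) {
      if (s[o + k] != m[k] && ++mm >= bm) break;
    }
    if (mm < bm) {
      bm = mm;
      bs = o;
      if (bm == 0) break;  // 0 mismatches, leftmost: cannot be beaten
    }
  }
  *out_start = bs;
  *out_mm = (bs < 0) ? -1 : bm;
}

// [[Rcpp::export]]
IntegerVector cpp_scan_motif(std::string seq, std::string motif, int max_mm) {
  int start, mm;
  if (motif.size() > seq.size()) return IntegerVector::create(-1, -1);
  best_window(seq.c_str(), (int)seq.size(), motif.c_str(), (int)motif.size(),
              max_mm, &start, &mm);
  return IntegerVector::create(start, mm);
}

// For each read, find the best placement of flank5 + <insert_len nt> + flank3
// where each flank has <= max_mm mismatches. Best = minimal total mismatches,
// leftmost on ties. Returns a matrix with columns (start0, mm5, mm3), start0
// = 0-based offset of flank5, or -1 if no placement qualifies.
// [[Rcpp::export]]
IntegerMatrix cpp_scan_inserts(CharacterVector reads, std::string flank5,
                               std::string flank3, int insert_len, int max_mm) {
  int n = reads.size();
  int l5 = (int)flank5.size(), l3 = (int)flank3.size();
  int total = l5 + insert_len + l3;
  const char* f5 = flank5.c_str();
  const char* f3 = flank3.c_str();
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int ls = (int)std::char_traits<char>::length(s);
    int bs = -1, b5 = 0, b3 = 0, bt = 2 * max_mm + 1;
    for (int o = 0; o + total <= ls; ++o) {
      int mm5 = 0;
      bool ok = true;
      for (int k = 0; k < l5; ++k) {
        if (s[o + k] != f5[k] && ++mm5 > max_mm) { ok = false; break; }
      }
      if (!ok) continue;
      int o3 = o + l5 + insert_len;
      int mm3 = 0;
      for (int k = 0; k < l3; ++k) {
        if (s[o3 + k] != f3[k] && ++mm3 > max_mm) { ok = false; break; }
      }
      if (!ok) continue;
      int t = mm5 + mm3;
      if (t < bt) {
        bt = t; bs = o; b5 = mm5; b3 = mm3;
        if (t == 0) break;
      }
    }
    out(i, 0) = bs;
    out(i, 1) = (bs < 0) ? -1 : b5;
    out(i, 2) = (bs < 0) ? -1 : b3;
  }
  return out;
}

// Pairwise normalized Hamming distances for equal-length strings.
// [[Rcpp::export]]
NumericMatrix cpp_hamming_matrix(CharacterVector peps) {
  int n = peps.size();
  NumericMatrix d(n, n);
  if (n == 0) return d;
  int L = (int)std::char_traits<char>::length(CHAR(STRING_ELT(peps, 0)));
  std::vector<const char*> p(n);
  for (int i = 0; i < n; ++i) p[i] = CHAR(STRING_ELT(peps, i));
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int mm = 0;
      for (int k = 0; k < L; ++k) if (p[i][k] != p[j][k]) ++mm;
      double v = (double)mm / (double)L;
      d(i, j) = v;
      d(j, i) = v;
    }
  }
  return d;
}

// Union-find over merges with height <= h: returns, for every leaf, the
// representative leaf (1-based) of its cluster.
// [[Rcpp::export]]
IntegerVector cpp_cut_merges(IntegerMatrix merge, NumericVector height,
                             double h) {
  int m = merge.nrow();
  int n = m + 1;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  };
  std::vector<int> rep(m);  // representative leaf (0-based) of merge node
  for (int s = 0; s < m; ++s) {
    int a = merge(s, 0), b = merge(s, 1);
    int la = a < 0 ? -a - 1 : rep[a - 1];
    int lb = b < 0 ? -b - 1 : rep[b - 1];
    rep[s] = la;
    if (height[s] <= h) parent[find(lb)] = find(la);
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = find(i) + 1;
  return out;
}

// WPGMA agglomeration. At each step the closest active pair is merged at
// height equal to its current distance; distances to the merged node are
// the arithmetic mean of the two children's distances. Ties are broken by
// the smallest (row, column) position pair in the current matrix ordering
// (the merged node keeps the position of its left child).
//
// Uses cached per-row minima that are maintained as exact values or as
// stale lower bounds (marked invalid) and re-verified lazily during the
// selection scan, so the selected pair is always identical to a full
// O(n^2) scan while typical cost stays near O(n^2) overall.
static void wpgma_core(std::vector<double>& D, int n,
                       IntegerMatrix& merge, NumericVector& height) {
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<int> order(n);          // active slots in current order
  std::vector<int> pos(n);            // slot -> position in `order`
  std::vector<int> node_id(n);        // slot -> hclust node id
  std::vector<double> cached(n, INF); // slot -> cached row minimum (cols after)
  std::vector<int> carg(n, -1);       // slot -> argmin slot
  std::vector<bool> valid(n, false);  // cached value exact (else lower bound)
  std::vector<int> born(n, -1);       // merge step that created the slot's
                                      // cluster (-1 for leaves)

  for (int i = 0; i < n; ++i) {
    order[i] = i;
    pos[i] = i;
    node_id[i] = -(i + 1);
  }

  // The current distance of a pair is kept in the row of the younger
  // cluster only, so merge updates touch memory contiguously; for two
  // leaves the original matrix is symmetric and either row serves.
  auto dval = [&](int a_, int b_) -> double {
    return born[a_] >= born[b_] ? D[(size_t)a_ * n + b_]
                                : D[(size_t)b_ * n + a_];
  };

  int a = n;  // number of active slots
  // exact row minimum over columns after position `p` in current order
  auto recompute = [&](int p) {
    int r = order[p];
    double best = INF;
    int barg = -1;
    for (int q = p + 1; q < a; ++q) {
      double v = dval(r, order[q]);
      if (v < best) { best = v; barg = order[q]; }
    }
    cached[r] = best;
    carg[r] = barg;
    valid[r] = true;
  };
  for (int p = 0; p < n; ++p) recompute(p);

  for (int s = 0; s < n - 1; ++s) {
    // selection scan: strictly-smaller keeps the earliest qualifying row
    double bestval = INF;
    int bestpos = -1;
    for (int p = 0; p < a - 1; ++p) {
      int r = order[p];
      if (cached[r] < bestval) {
        if (!valid[r]) recompute(p);
        if (cached[r] < bestval) { bestval = cached[r]; bestpos = p; }
      }
    }
    int ri = order[bestpos];
    int rj = carg[ri];
    int pj = pos[rj];

    merge(s, 0) = node_id[ri];
    merge(s, 1) = node_id[rj];
    height[s] = bestval;
    node_id[ri] = s + 1;

    // WPGMA distance update and cache maintenance
    int pi = bestpos;
    double* rowi = &D[(size_t)ri * n];
    for (int p = 0; p < a; ++p) {
      int k = order[p];
      if (k == ri || k == rj) continue;
      double v = 0.5 * (dval(k, ri) + dval(k, rj));
      rowi[k] = v;
      if (p < pi) {  // both ri and rj were in k's column range
        if (carg[k] == rj) {
          valid[k] = false;  // cached stays as a lower bound
        } else if (carg[k] == ri) {
          if (v != cached[k]) valid[k] = false;  // v >= cached always
        } else if (v < cached[k]) {
          cached[k] = v; carg[k] = ri; valid[k] = true;
        } else if (v == cached[k] && pos[carg[k]] > pi) {
          carg[k] = ri;  // leftmost-column tie now at ri
        }
      } else if (p < pj) {  // only rj was in k's column range
        if (carg[k] == rj) valid[k] = false;
      }
    }
    valid[ri] = false;
    born[ri] = s;  // ri is now the youngest cluster; reads go to its row

    // drop rj from the ordering
    for (int p = pj; p < a - 1; ++p) {
      order[p] = order[p + 1];
      pos[order[p]] = p;
    }
    --a;
  }
}

// [[Rcpp::export]]
List cpp_wpgma(NumericMatrix dmat) {
  int n = dmat.nrow();
  IntegerMatrix merge(std::max(n - 1, 0), 2);
  NumericVector height(std::max(n - 1, 0));
  if (n < 2) return List::create(_["merge"] = merge, _["height"] = height);
  std::vector<double> D((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) D[(size_t)i * n + j] = dmat(i, j);
  wpgma_core(D, n, merge, height);
  return List::create(_["merge"] = merge, _["height"] = height);
}

// Distance computation and WPGMA in one pass, avoiding any R-level
// n x n matrix: the normalized Hamming distances are written straight
// into the working buffer of the agglomeration.
// [[Rcpp::export]]
List cpp_cluster_peptides(CharacterVector peps) {
  int n = peps.size();
  IntegerMatrix merge(std::max(n - 1, 0), 2);
  NumericVector height(std::max(n - 1, 0));
  if (n < 2) return List::create(_["merge"] = merge, _["height"] = height);
  int L = (int)std::char_traits<char>::length(CHAR(STRING_ELT(peps, 0)));
  std::vector<const char*> p(n);
  for (int i = 0; i < n; ++i) p[i] = CHAR(STRING_ELT(peps, i));
  // reuse the working buffer across calls: repeated large clusterings
  // (e.g. simulation sweeps) then avoid refaulting hundreds of MB
  static std::vector<double> D;
  if (D.size() < (size_t)n * n) D.resize((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    D[(size_t)i * n + i] = 0.0;
    for (int j = i + 1; j < n; ++j) {
      int mm = 0;
      for (int k = 0; k < L; ++k) if (p[i][k] != p[j][k]) ++mm;
      double v = (double)mm / (double)L;  // same arithmetic as cpp_hamming_matrix
      D[(size_t)i * n + j] = v;
      D[(size_t)j * n + i] = v;
    }
  }
  wpgma_core(D, n, merge, height);
  return List::create(_["merge"] = merge, _["height"] = height);
}
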
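#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
using namespace Rcpp;

// Simulate an order-o Markov chain over A,C,G,T.
// trans: (4^o) x 4 row-stochastic matrix; row = current state (the last o
// bases, first base most significant), cols = next base. init: start
// distribution over states. Uses R's RNG (seed-reproducible).
// [[Rcpp::export]]
std::string cpp_markov_seq(int n, NumericMatrix trans, NumericVector init,
                           int order) {
  static const char bases[] = {'A', 'C', 'G', 'T'};
  const int S = trans.nrow();
  std::string out(n, 'A');
  std::vector<double> cum(S * 4);
  for (int r = 0; r < S; ++r) {
    double s = 0.0;
    for (int c = 0; c < 4; ++c) { s += trans(r, c); cum[r * 4 + c] = s; }
  }
  // initial state
  double s = 0.0;
  std::vector<double> cinit(S);
  for (int c = 0; c < S; ++c) { s += init[c]; cinit[c] = s; }
  double u = unif_rand() * s;
  int state = 0;
  while (state < S - 1 && u > cinit[state]) ++state;
  // emit the initial state's bases
  int emit = n < order ? n : order;
  for (int j = 0; j < emit; ++j)
    out[j] = bases[(state >> (2 * (order - 1 - j))) & 3];
  const int mask = S - 1;
  for (int i = order; i < n; ++i) {
    double tot = cum[state * 4 + 3];
    double v = unif_rand() * tot;
    int b = 0;
    while (b < 3 && v > cum[state * 4 + b]) ++b;
    out[i] = bases[b];
    state = ((state << 2) | b) & mask;
  }
  return out;
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Gapped k-mer count featurization.
// seqs: DNA strings; masks: k x M matrix of 1-based informative positions
// within an l-long word. Feature index (1-based) = mask_id * 4^k + code + 1,
// where code reads the k informative bases most-significant-first.
// With collapse, a token and its reverse complement (mask mirrored, bases
// complemented and reversed) share the lexicographically smaller index.
// Returns triplets (i, j, x) for building a sparse matrix.
// [[Rcpp::export]]
List cpp_gkm_featurize(CharacterVector seqs, IntegerMatrix masks, int l, int k,
                       bool collapse) {
  const int M = masks.ncol();
  int P = 1;
  for (int j = 0; j < k; ++j) P *= 4;

  // map mask position-vector -> id, to find each mask's mirror
  std::map<std::vector<int>, int> mask_id;
  for (int m = 0; m < M; ++m) {
    std::vector<int> key(k);
    for (int j = 0; j < k; ++j) key[j] = masks(j, m);
    mask_id[key] = m;
  }
  std::vector<int> rc_mask(M);
  for (int m = 0; m < M; ++m) {
    std::vector<int> key(k);
    for (int j = 0; j < k; ++j) key[j] = l + 1 - masks(k - 1 - j, m);
    std::map<std::vector<int>, int>::iterator it = mask_id.find(key);
    if (it == mask_id.end()) stop("mask set is not closed under mirroring");
    rc_mask[m] = it->second;
  }

  std::vector<int> pow4(k);
  pow4[k - 1] = 1;
  for (int j = k - 2; j >= 0; --j) pow4[j] = pow4[j + 1] * 4;

  std::vector<int> I, J;
  std::vector<double> X;
  std::vector<int> codes;
  std::vector<int> b(k);
  // dense accumulator with touched-entry reset: much faster than hashing
  std::vector<double> acc((size_t)M * P, 0.0);
  std::vector<int> touched;

  for (int s = 0; s < seqs.size(); ++s) {
    const char *str = CHAR(STRING_ELT(seqs, s));
    int L = LENGTH(STRING_ELT(seqs, s));
    touched.clear();
    if (L >= l) {
      codes.resize(L);
      for (int i = 0; i < L; ++i) codes[i] = base_code(str[i]);
      for (int w = 0; w + l <= L; ++w) {
        for (int m = 0; m < M; ++m) {
          int code = 0;
          bool ok = true;
          for (int j = 0; j < k; ++j) {
            int c = codes[w + masks(j, m) - 1];
            if (c < 0) { ok = false; break; }
            b[j] = c;
            code += c * pow4[j];
          }
          if (!ok) continue;
          int idx = m * P + code;
          if (collapse) {
            int rccode = 0;
            for (int j = 0; j < k; ++j) rccode += (3 - b[k - 1 - j]) * pow4[j];
            int ridx = rc_mask[m] * P + rccode;
            if (ridx < idx) idx = ridx;
          }
          if (acc[idx] == 0.0) touched.push_back(idx);
          acc[idx] += 1.0;
        }
      }
    }
    std::sort(touched.begin(), touched.end());
    for (size_t t = 0; t < touched.size(); ++t) {
      I.push_back(s + 1);
      J.push_back(touched[t] + 1);
      X.push_back(acc[touched[t]]);
      acc[touched[t]] = 0.0;
    }
  }
  return List::create(Named("i") = I, Named("j") = J, Named("x") = X,
                      Named("nfeat") = M * P);
}

// Random k-mer-count-preserving shuffle for k >= 2 (Altschul-Erickson):
// random arborescence toward the terminal (k-1)-mer via Wilson's algorithm,
// random orderings of the remaining out-edges, then the Eulerian walk.
// vertex/edge structure is prepared in R; uses R's RNG.
// from, to: 0-based vertex ids per edge (in input order); nv: vertex count;
// start, last: 0-based start/terminal vertex ids.
// Returns the edge indices (1-based, input order) along the Eulerian path.
// [[Rcpp::export]]
IntegerVector cpp_euler_walk(IntegerVector from, IntegerVector to, int nv,
                             int start, int last) {
  const int ne = from.size();
  // out-edge lists
  std::vector<std::vector<int> > out(nv);
  for (int e = 0; e < ne; ++e) out[from[e]].push_back(e);

  // Wilson's algorithm: uniform random arborescence oriented toward `last`
  std::vector<int> next_edge(nv, -1);
  std::vector<char> in_tree(nv, 0);
  in_tree[last] = 1;
  for (int v0 = 0; v0 < nv; ++v0) {
    int u = v0;
    while (!in_tree[u]) {
      const std::vector<int> &oe = out[u];
      next_edge[u] = oe[(int)(unif_rand() * oe.size()) % oe.size()];
      u = to[next_edge[u]];
    }
    u = v0;
    while (!in_tree[u]) {
      in_tree[u] = 1;
      u = to[next_edge[u]];
    }
  }

  // per-vertex edge order: random permutation, arborescence edge last
  std::vector<std::vector<int> > order(nv);
  for (int v = 0; v < nv; ++v) {
    std::vector<int> rest;
    rest.reserve(out[v].size());
    for (size_t j = 0; j < out[v].size(); ++j) {
      if (v != last && out[v][j] == next_edge[v]) continue;
      rest.push_back(out[v][j]);
    }
    // Fisher-Yates
    for (int j = (int)rest.size() - 1; j > 0; --j) {
      int r = (int)(unif_rand() * (j + 1)) % (j + 1);
      std::swap(rest[j], rest[r]);
    }
    if (v != last && next_edge[v] >= 0) rest.push_back(next_edge[v]);
    order[v] = rest;
  }

  // Eulerian walk from `start`
  std::vector<int> ptr(nv, 0);
  IntegerVector path(ne);
  int cur = start;
  for (int step = 0; step < ne; ++step) {
    if (ptr[cur] >= (int)order[cur].size()) stop("Eulerian walk failed");
    int e = order[cur][ptr[cur]++];
    path[step] = e + 1;
    cur = to[e];
  }
  return path;
}
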
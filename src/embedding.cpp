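#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Self-contained 64-bit RNG so results are identical across platforms and
// independent of R's RNG state.
namespace {

struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  uint64_t below(uint64_t n) { return next() % n; }
};

uint64_t fnv1a(const std::string& s) {
  uint64_t h = 1469598103934665603ULL;
  for (unsigned char c : s) {
    h ^= c;
    h *= 1099511628211ULL;
  }
  return h;
}

bool contains_sorted(const std::vector<int>& v, int x) {
  return std::binary_search(v.begin(), v.end(), x);
}

} // namespace

// Deterministic per-identifier initial vectors (word2vec-style: each
// identifier's row depends only on its own name and the seed, so the same
// node name gets the same starting point in any network). Values are
// uniform(-0.5, 0.5)/dim.
// [[Rcpp::export]]
NumericMatrix cpp_init_vectors(CharacterVector names, int dim, double seed) {
  int n = names.size();
  NumericMatrix out(n, dim);
  for (int i = 0; i < n; ++i) {
    std::string nm = as<std::string>(names[i]);
    SplitMix64 rng(fnv1a(nm) ^ static_cast<uint64_t>(seed));
    for (int j = 0; j < dim; ++j)
      out(i, j) = (rng.unif() - 0.5) / dim;
  }
  return out;
}

// Second-order biased random walks (node2vec). adj is a 1-based adjacency
// list; returns a (num_walks * n) x walk_length matrix of 1-based node
// indices. return_param (p) penalises immediate backtracking, inout_param
// (q) penalises moving away from the previous node's neighborhood. For
// p = q = 1 the walk reduces to a uniform first-order walk.
// [[Rcpp::export]]
IntegerMatrix cpp_random_walks(List adj, int num_walks, int walk_length,
                               double return_param, double inout_param,
                               double seed) {
  int n = adj.size();
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector a = adj[i];
    nb[i].assign(a.begin(), a.end());
    for (int& x : nb[i]) x -= 1;          // to 0-based
    std::sort(nb[i].begin(), nb[i].end());
    if (nb[i].empty())
      stop("node %d has no neighbors; walks require a connected context", i + 1);
  }
  bool unbiased = (return_param == 1.0 && inout_param == 1.0);
  IntegerMatrix walks(num_walks * n, walk_length);
  SplitMix64 rng(static_cast<uint64_t>(seed) ^ 0x51a5c1ULL);
  std::vector<double> w;
  int row = 0;
  for (int r = 0; r < num_walks; ++r) {
    for (int start = 0; start < n; ++start, ++row) {
      int cur = start, prev = -1;
      walks(row, 0) = cur + 1;
      for (int step = 1; step < walk_length; ++step) {
        const std::vector<int>& cand = nb[cur];
        int nxt;
        if (unbiased || prev < 0) {
          nxt = cand[rng.below(cand.size())];
        } else {
          w.resize(cand.size());
          double tot = 0.0;
          for (size_t k = 0; k < cand.size(); ++k) {
            double wk;
            if (cand[k] == prev) wk = 1.0 / return_param;
            else if (contains_sorted(nb[prev], cand[k])) wk = 1.0;
            else wk = 1.0 / inout_param;
            w[k] = wk;
            tot += wk;
          }
          double u = rng.unif() * tot, acc = 0.0;
          size_t k = 0;
          for (; k < cand.size() - 1; ++k) {
            acc += w[k];
            if (u < acc) break;
          }
          nxt = cand[k];
        }
        walks(row, step) = nxt + 1;
        prev = cur;
        cur = nxt;
      }
    }
  }
  return walks;
}

// Skip-gram with negative sampling over a walk corpus. Single-threaded and
// fully deterministic given (corpus, init, seed). `init` supplies the input
// (projection) layer start values, one row per vocabulary item; the output
// layer starts at zero, as in word2vec. Window use follows word2vec: for
// each center position a reduced window b ~ uniform{1..window} is drawn and
// positions within +-b (same walk) are contexts. The learning rate decays
// linearly from `alpha` to alpha/10000 over all center positions.
// [[Rcpp::export]]
NumericMatrix cpp_sgns(IntegerMatrix walks, int vocab, int dim, int window,
                       int epochs, int negative, double alpha, double seed,
                       NumericMatrix init) {
  if (init.nrow() != vocab || init.ncol() != dim)
    stop("init matrix must be vocab x dim");
  int nwalk = walks.nrow(), wl = walks.ncol();

  std::vector<double> syn0(static_cast<size_t>(vocab) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab) * dim, 0.0);
  for (int i = 0; i < vocab; ++i)
    for (int j = 0; j < dim; ++j)
      syn0[static_cast<size_t>(i) * dim + j] = init(i, j);

  // unigram^0.75 negative-sampling table
  std::vector<double> cnt(vocab, 0.0);
  for (int r = 0; r < nwalk; ++r)
    for (int c = 0; c < wl; ++c)
      cnt[walks(r, c) - 1] += 1.0;
  const int table_size = 100000;
  std::vector<int> table(table_size);
  double z = 0.0;
  for (int i = 0; i < vocab; ++i) z += std::pow(cnt[i], 0.75);
  {
    int i = 0;
    double acc = std::pow(cnt[0], 0.75) / z;
    for (int t = 0; t < table_size; ++t) {
      table[t] = i;
      if ((t + 1.0) / table_size > acc && i < vocab - 1) {
        ++i;
        acc += std::pow(cnt[i], 0.75) / z;
      }
    }
  }

  SplitMix64 rng(static_cast<uint64_t>(seed) ^ 0x5965ULL);
  std::vector<double> grad(dim);
  const double total = static_cast<double>(nwalk) * wl * epochs;
  double processed = 0.0;
  const double min_alpha = alpha * 1e-4;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int r = 0; r < nwalk; ++r) {
      for (int c = 0; c < wl; ++c) {
        double lr = alpha * (1.0 - processed / total);
        if (lr < min_alpha) lr = min_alpha;
        processed += 1.0;
        int center = walks(r, c) - 1;
        int b = 1 + static_cast<int>(rng.below(window));
        int lo = std::max(0, c - b), hi = std::min(wl - 1, c + b);
        for (int cc = lo; cc <= hi; ++cc) {
          if (cc == c) continue;
          int ctx = walks(r, cc) - 1;
          double* v = &syn0[static_cast<size_t>(ctx) * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = center;
              label = 1.0;
            } else {
              target = table[rng.below(table_size)];
              if (target == center) continue;
              label = 0.0;
            }
            double* u = &syn1[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int j = 0; j < dim; ++j) dot += v[j] * u[j];
            double g = (label - 1.0 / (1.0 + std::exp(-dot))) * lr;
            for (int j = 0; j < dim; ++j) {
              grad[j] += g * u[j];
              u[j] += g * v[j];
            }
          }
          for (int j = 0; j < dim; ++j) v[j] += grad[j];
        }
      }
    }
  }

  NumericMatrix out(vocab, dim);
  for (int i = 0; i < vocab; ++i)
    for (int j = 0; j < dim; ++j)
      out(i, j) = syn0[static_cast<size_t>(i) * dim + j];
  return out;
}
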
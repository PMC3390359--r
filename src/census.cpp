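// Exhaustive attractor censuses.
//
// Both entry points enumerate a genotype library, build each genotype's
// transition map over the 2^n states, and pool attractors across the
// whole library.  Attractor identity is the exact canonical cyclic
// state sequence (rotated so the minimal state code comes first); fixed
// points are identified by their single state.  Cycle detection is the
// standard functional-graph walk: every state is visited once per
// genotype, each walk stopping at the first state already seen, so the
// census costs O(2^n) per genotype on top of building the map.

#include <Rcpp.h>
#include <set>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

struct CensusPool {
  std::vector<char> fixed_seen;         // by state code
  std::set<std::vector<int>> cycles;    // canonical periodic sequences
  long long n_genotypes = 0;
  explicit CensusPool(int nstates) : fixed_seen(nstates, 0) {}
};

class Detector {
public:
  explicit Detector(int nstates)
    : nstates_(nstates), visit_(nstates, -1), walk_(nstates, -1),
      pos_(nstates, 0), epoch_(0), walk_id_(0) {
    path_.reserve(nstates);
  }

  // Census one transition map T (array of nstates successors) into pool.
  void census(const int* T, CensusPool& pool) {
    ++epoch_;
    ++pool.n_genotypes;
    for (int s0 = 0; s0 < nstates_; ++s0) {
      if (visit_[s0] == epoch_) continue;
      ++walk_id_;
      path_.clear();
      int s = s0;
      while (visit_[s] != epoch_) {
        visit_[s] = epoch_;
        walk_[s] = walk_id_;
        pos_[s] = static_cast<int>(path_.size());
        path_.push_back(s);
        s = T[s];
      }
      if (walk_[s] == walk_id_) {           // new cycle found on this walk
        int start = pos_[s];
        int len = static_cast<int>(path_.size()) - start;
        if (len == 1) {
          pool.fixed_seen[path_[start]] = 1;
        } else {
          record_cycle(&path_[start], len, pool);
        }
      }
    }
  }

private:
  void record_cycle(const int* cyc, int len, CensusPool& pool) {
    int kmin = 0;
    for (int k = 1; k < len; ++k) if (cyc[k] < cyc[kmin]) kmin = k;
    std::vector<int> canon(len);
    for (int k = 0; k < len; ++k) canon[k] = cyc[(kmin + k) % len];
    pool.cycles.insert(std::move(canon));
  }

  int nstates_;
  std::vector<long long> visit_, walk_;
  std::vector<int> pos_;
  std::vector<int> path_;
  long long epoch_, walk_id_;
};

List pool_to_list(const CensusPool& pool) {
  std::vector<int> fixed;
  for (int s = 0; s < static_cast<int>(pool.fixed_seen.size()); ++s)
    if (pool.fixed_seen[s]) fixed.push_back(s);
  List per(pool.cycles.size());
  int k = 0;
  for (const auto& cyc : pool.cycles) per[k++] = IntegerVector(cyc.begin(), cyc.end());
  return List::create(_["fixed"] = IntegerVector(fixed.begin(), fixed.end()),
                      _["periodic"] = per,
                      _["n_genotypes"] = static_cast<double>(pool.n_genotypes));
}

}  // namespace

// Census of the full 3^n wild/null/constitutive allele library of a
// threshold network.  `wild` is the 2^n x n matrix of wild-type update
// bits (threshold_wild_columns()).  Transition maps are assembled
// incrementally along a depth-first walk over the nodes: entering a
// branch adds the node's contribution column (nothing for null, the
// shifted wild column for wild, the constant bit for constitutive) and
// leaving subtracts it, so each leaf costs O(2^n) detection plus an
// amortized O(2^n) of column updates.
// [[Rcpp::export]]
List cpp_threshold_census(IntegerMatrix wild) {
  const int nstates = wild.nrow();
  const int n = wild.ncol();
  if (nstates != (1 << n)) stop("wild must be 2^n x n");

  // shifted wild columns: contribution of node i when wild
  std::vector<std::vector<int>> wshift(n, std::vector<int>(nstates));
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < nstates; ++s)
      wshift[i][s] = wild(s, i) << i;

  CensusPool pool(nstates);
  Detector det(nstates);
  std::vector<int> T(nstates, 0);

  // iterative depth-first product over alleles {null, wild, constitutive}
  std::vector<int> choice(n, -1);
  int depth = 0;
  auto add_node = [&](int i, int a, int sign) {
    if (a == 1) {
      const int* w = wshift[i].data();
      if (sign > 0) for (int s = 0; s < nstates; ++s) T[s] += w[s];
      else          for (int s = 0; s < nstates; ++s) T[s] -= w[s];
    } else if (a == 2) {
      const int bit = sign > 0 ? (1 << i) : -(1 << i);
      for (int s = 0; s < nstates; ++s) T[s] += bit;
    }
  };
  while (depth >= 0) {
    if (depth == n) {
      det.census(T.data(), pool);
      --depth;
      continue;
    }
    int a = ++choice[depth];
    if (a > 0) add_node(depth, a - 1, -1);  // undo previous branch
    if (a == 3) {
      choice[depth] = -1;
      --depth;
      continue;
    }
    add_node(depth, a, +1);
    ++depth;
  }
  return pool_to_list(pool);
}

// Exhaustive census of the full order-n library (all (2^(2^n))^n truth
// tables), n <= 3, pooled overall and split by network size (number of
// derived edges under essential dependence).
// [[Rcpp::export]]
List cpp_full_order_census(int order) {
  if (order < 1 || order > 3) stop("order must be 1..3");
  const int nstates = 1 << order;
  const int nfun = 1 << nstates;           // update columns per node
  const int max_edges = order * order;

  // essential-input mask per function
  std::vector<int> essmask(nfun, 0), esscount(nfun, 0);
  for (int f = 0; f < nfun; ++f) {
    for (int j = 0; j < order; ++j) {
      bool ess = false;
      for (int s = 0; s < nstates && !ess; ++s)
        if (((f >> s) & 1) != ((f >> (s ^ (1 << j))) & 1)) ess = true;
      if (ess) { essmask[f] |= (1 << j); ++esscount[f]; }
    }
  }
  // per-node transition contribution of function f: bit i of successor
  // (filled per node below since the shift differs)

  CensusPool total(nstates);
  std::vector<CensusPool> by_size(max_edges + 1, CensusPool(nstates));
  Detector det(nstates);

  std::vector<int> T(nstates);
  std::vector<int> fidx(order, 0);
  long long ngeno = 1;
  for (int i = 0; i < order; ++i) ngeno *= nfun;

  for (long long g = 0; g < ngeno; ++g) {
    long long rest = g;
    int edges = 0;
    for (int s = 0; s < nstates; ++s) T[s] = 0;
    for (int i = 0; i < order; ++i) {
      int f = static_cast<int>(rest % nfun);
      rest /= nfun;
      edges += esscount[f];
      for (int s = 0; s < nstates; ++s) T[s] |= ((f >> s) & 1) << i;
    }
    det.census(T.data(), total);
    det.census(T.data(), by_size[edges]);
  }

  List per(max_edges + 1);
  for (int k = 0; k <= max_edges; ++k) per[k] = pool_to_list(by_size[k]);
  return List::create(_["total"] = pool_to_list(total), _["per_size"] = per);
}
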
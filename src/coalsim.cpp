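// Hudson-style ancestral recombination graph simulator with piecewise-constant
// population sizes and backward-time population merges. Ancestral material is
// tracked per lineage as half-open intervals [a, b) carrying a 64-bit bitmask
// of descendant samples, so at most 64 sampled haplotypes are supported.
// Mutation is a competing exponential event alongside coalescence and
// recombination; a mutation records its position and the descendant mask of
// the interval it falls on. Material that reaches its local MRCA (mask equal
// to the full sample mask) is discarded, so mutations older than the sample
// MRCA are never generated.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Seg {
  double a, b;
  uint64_t mask;
};

struct Lin {
  std::vector<Seg> segs;
  int pop;
  int pop_pos;  // index into the per-population lineage list
  double tot;   // total ancestral length
  double lo, hi;

  void refresh() {
    tot = 0.0;
    for (const Seg& s : segs) tot += s.b - s.a;
    if (segs.empty()) {
      lo = hi = 0.0;
    } else {
      lo = segs.front().a;
      hi = segs.back().b;
    }
  }
};

inline void push_seg(std::vector<Seg>& out, double a, double b, uint64_t mask,
                     uint64_t full) {
  if (b <= a || mask == full) return;
  if (!out.empty() && out.back().b == a && out.back().mask == mask) {
    out.back().b = b;
  } else {
    out.push_back({a, b, mask});
  }
}

// union overlay of two sorted disjoint segment lists, OR-ing masks on overlap
void merge_segs(const std::vector<Seg>& A, const std::vector<Seg>& B,
                uint64_t full, std::vector<Seg>& out) {
  out.clear();
  size_t i = 0, j = 0;
  Seg x{}, y{};
  bool hx = i < A.size(), hy = j < B.size();
  if (hx) x = A[i++];
  if (hy) y = B[j++];
  while (hx && hy) {
    if (x.b <= y.a) {
      push_seg(out, x.a, x.b, x.mask, full);
      hx = i < A.size();
      if (hx) x = A[i++];
    } else if (y.b <= x.a) {
      push_seg(out, y.a, y.b, y.mask, full);
      hy = j < B.size();
      if (hy) y = B[j++];
    } else {
      if (x.a < y.a) {
        push_seg(out, x.a, y.a, x.mask, full);
        x.a = y.a;
      } else if (y.a < x.a) {
        push_seg(out, y.a, x.a, y.mask, full);
        y.a = x.a;
      }
      double hi = std::min(x.b, y.b);
      push_seg(out, x.a, hi, x.mask | y.mask, full);
      if (x.b > hi) {
        x.a = hi;
        hy = j < B.size();
        if (hy) y = B[j++];
      } else if (y.b > hi) {
        y.a = hi;
        hx = i < A.size();
        if (hx) x = A[i++];
      } else {
        hx = i < A.size();
        if (hx) x = A[i++];
        hy = j < B.size();
        if (hy) y = B[j++];
      }
    }
  }
  while (hx) {
    push_seg(out, x.a, x.b, x.mask, full);
    hx = i < A.size();
    if (hx) x = A[i++];
  }
  while (hy) {
    push_seg(out, y.a, y.b, y.mask, full);
    hy = j < B.size();
    if (hy) y = B[j++];
  }
}

// Fenwick tree over lineage slots for O(log n) weighted selection of the
// lineage hit by a recombination (weight = breakable span) or mutation
// (weight = ancestral length) event.
struct Fenwick {
  std::vector<double> t, w;

  void ensure(size_t n) {
    if (n <= w.size()) return;
    size_t cap = w.empty() ? 128 : w.size();
    while (cap < n) cap *= 2;
    w.resize(cap, 0.0);
    t.assign(cap, 0.0);
    for (size_t i = 0; i < cap; ++i) {
      if (w[i] != 0.0) {
        for (size_t j = i + 1; j <= cap; j += j & (~j + 1)) t[j - 1] += w[i];
      }
    }
  }
  void add(int i, double delta) {
    w[i] += delta;
    for (size_t j = i + 1; j <= t.size(); j += j & (~j + 1)) t[j - 1] += delta;
  }
  // weighted pick: index whose cumulative-weight interval contains v
  int pick(double v, size_t n) const {
    size_t idx = 0, bit = 1;
    while (bit * 2 <= t.size()) bit *= 2;
    for (; bit > 0; bit /= 2) {
      size_t nxt = idx + bit;
      if (nxt <= t.size() && t[nxt - 1] <= v) {
        v -= t[nxt - 1];
        idx = nxt;
      }
    }
    return (int)std::min(idx, n - 1);
  }
};

struct Graph {
  std::vector<Lin> lins;
  std::vector<std::vector<int>> bypop;
  uint64_t full;
  double sum_tot = 0.0, sum_span = 0.0;
  Fenwick f_span;

  void add_lineage(Lin&& l) {
    l.refresh();
    if (l.segs.empty()) return;
    l.pop_pos = (int)bypop[l.pop].size();
    sum_tot += l.tot;
    sum_span += l.hi - l.lo;
    bypop[l.pop].push_back((int)lins.size());
    int idx = (int)lins.size();
    f_span.ensure(idx + 1);
    f_span.add(idx, l.hi - l.lo);
    lins.push_back(std::move(l));
  }

  void remove_lineage(int idx) {
    Lin& l = lins[idx];
    sum_tot -= l.tot;
    sum_span -= l.hi - l.lo;
    f_span.add(idx, -(l.hi - l.lo));
    // unlink from pop list
    std::vector<int>& pl = bypop[l.pop];
    int last = pl.back();
    pl[l.pop_pos] = last;
    lins[last].pop_pos = l.pop_pos;
    pl.pop_back();
    pool.push_back(std::move(l.segs));
    // swap-remove from lins, moving the tail lineage's weights too
    int tail = (int)lins.size() - 1;
    if (idx != tail) {
      f_span.add(tail, -(lins[tail].hi - lins[tail].lo));
      lins[idx] = std::move(lins[tail]);
      bypop[lins[idx].pop][lins[idx].pop_pos] = idx;
      f_span.add(idx, lins[idx].hi - lins[idx].lo);
    }
    lins.pop_back();
  }

  int pick_tot(double v) const {
    double acc = 0.0;
    for (size_t i = 0; i < lins.size(); ++i) {
      acc += lins[i].tot;
      if (v < acc) return (int)i;
    }
    return (int)lins.size() - 1;
  }
  int pick_span(double v) const { return f_span.pick(v, lins.size()); }

  // segment-buffer pool: ARGs at high recombination rates perform hundreds of
  // thousands of lineage creations per replicate; recycling the vectors keeps
  // the event loop allocation-free at steady state
  std::vector<std::vector<Seg>> pool;
  std::vector<Seg> grab() {
    if (pool.empty()) return {};
    std::vector<Seg> v = std::move(pool.back());
    pool.pop_back();
    v.clear();
    return v;
  }

  // refresh weights of lineage idx after its segments changed in place;
  // removes the lineage when no ancestral material remains
  void update_lineage(int idx) {
    Lin& l = lins[idx];
    double old_tot = l.tot, old_span = l.hi - l.lo;
    l.refresh();
    if (l.segs.empty()) {
      l.tot = old_tot;
      l.lo = 0.0;
      l.hi = old_span;  // restore so remove_lineage subtracts the old weights
      remove_lineage(idx);
      return;
    }
    sum_tot += l.tot - old_tot;
    sum_span += (l.hi - l.lo) - old_span;
    if ((l.hi - l.lo) != old_span) f_span.add(idx, (l.hi - l.lo) - old_span);
  }

  void move_pop(int from, int to) {
    std::vector<int>& pl = bypop[from];
    for (int idx : pl) {
      lins[idx].pop = to;
      lins[idx].pop_pos = (int)bypop[to].size();
      bypop[to].push_back(idx);
    }
    pl.clear();
  }
};

}  // namespace

// samples: haploid sample count per population
// sizes:   initial (present-day) effective diploid size per population
// ev_time / ev_type / ev_pop / ev_val: demographic events sorted by time
//   (generations); type 0 = set size of pop to val, type 1 = merge pop into
//   population val (backward in time).
// [[Rcpp::export]]
List sv_simulate_cpp(double L, IntegerVector samples, NumericVector sizes,
                     double rec_rate, double mut_rate, NumericVector ev_time,
                     IntegerVector ev_type, IntegerVector ev_pop,
                     NumericVector ev_val) {
  int npop = samples.size();
  int ntot = 0;
  for (int p = 0; p < npop; ++p) ntot += samples[p];
  if (ntot < 2 || ntot > 64) stop("total sample size must be in [2, 64]");
  if (L < 1) stop("L must be >= 1");

  Graph arg;
  arg.bypop.assign(npop, {});
  arg.full = (ntot == 64) ? ~0ULL : ((1ULL << ntot) - 1ULL);
  int s = 0;
  for (int p = 0; p < npop; ++p) {
    for (int k = 0; k < samples[p]; ++k, ++s) {
      Lin l;
      l.segs.push_back({0.0, L, 1ULL << s});
      l.pop = p;
      arg.add_lineage(std::move(l));
    }
  }
  std::vector<double> N(sizes.begin(), sizes.end());
  for (double x : N)
    if (x <= 0) stop("population sizes must be positive");

  std::vector<double> mut_pos;
  std::vector<uint64_t> mut_mask;
  std::vector<Seg> scratch;
  double t = 0.0;
  int ei = 0, nev = ev_time.size();
  long long n_coal = 0, n_rec = 0;
  const long long max_events = 200000000LL;
  long long iter = 0;

  RNGScope rng;
  while (arg.sum_tot > 1e-9 && arg.lins.size() > 1) {
    if (++iter > max_events) stop("event cap exceeded in ARG simulation");
    double r_rec = rec_rate * arg.sum_span;
    double r_mut = mut_rate * arg.sum_tot;
    double r_coal = 0.0;
    for (int p = 0; p < npop; ++p) {
      double k = (double)arg.bypop[p].size();
      r_coal += k * (k - 1.0) / (4.0 * N[p]);
    }
    double r_tot = r_rec + r_mut + r_coal;
    double dt = (r_tot > 0) ? R::exp_rand() / r_tot : R_PosInf;
    if (ei < nev && t + dt >= ev_time[ei]) {
      t = ev_time[ei];
      if (ev_type[ei] == 0) {
        N[ev_pop[ei]] = ev_val[ei];
      } else {
        arg.move_pop(ev_pop[ei], (int)ev_val[ei]);
      }
      ++ei;
      continue;
    }
    if (!R_finite(dt)) stop("stalled ARG: zero total rate with no pending event");
    t += dt;
    double u = unif_rand() * r_tot;
    if (u < r_coal) {
      // coalescence: choose population, then a uniform pair
      int p = 0;
      double acc = 0.0;
      for (; p < npop; ++p) {
        double k = (double)arg.bypop[p].size();
        acc += k * (k - 1.0) / (4.0 * N[p]);
        if (u < acc) break;
      }
      if (p >= npop) p = npop - 1;
      std::vector<int>& pl = arg.bypop[p];
      int k = (int)pl.size();
      int i1 = (int)(unif_rand() * k);
      if (i1 >= k) i1 = k - 1;
      int i2 = (int)(unif_rand() * (k - 1));
      if (i2 >= k - 1) i2 = k - 2;
      if (i2 >= i1) ++i2;
      int a = pl[i1], b = pl[i2];
      int keep = std::min(a, b), rem = std::max(a, b);
      merge_segs(arg.lins[keep].segs, arg.lins[rem].segs, arg.full, scratch);
      arg.remove_lineage(rem);  // keep < rem stays valid under swap-remove
      std::swap(arg.lins[keep].segs, scratch);
      arg.update_lineage(keep);
      ++n_coal;
    } else if (u < r_coal + r_rec) {
      // recombination: lineage weighted by breakable span
      double v = (u - r_coal) / rec_rate;
      int idx = arg.pick_span(v);
      Lin& l = arg.lins[idx];
      double span = l.hi - l.lo;
      if (span <= 0) continue;
      double x = l.lo + unif_rand() * span;
      if (x <= l.lo || x >= l.hi) continue;
      // split the segment list at x, copying the smaller side into a pooled
      // buffer and truncating/erasing the existing vector in place
      size_t cut = 0;
      while (cut < l.segs.size() && l.segs[cut].b <= x) ++cut;
      bool split_mid = cut < l.segs.size() && l.segs[cut].a < x;
      size_t n_right = l.segs.size() - cut;  // segments (or parts) right of x
      size_t n_left = cut + (split_mid ? 1 : 0);
      Lin other;
      other.segs = arg.grab();
      other.pop = l.pop;
      if (n_left <= n_right) {
        // move the left side out, keep the right side in place
        for (size_t q = 0; q < cut; ++q) other.segs.push_back(l.segs[q]);
        if (split_mid) {
          other.segs.push_back({l.segs[cut].a, x, l.segs[cut].mask});
          l.segs[cut].a = x;
        }
        l.segs.erase(l.segs.begin(), l.segs.begin() + cut);
      } else {
        // move the right side out, keep the left side in place
        if (split_mid) {
          other.segs.push_back({x, l.segs[cut].b, l.segs[cut].mask});
          l.segs[cut].b = x;
        }
        for (size_t q = cut + (split_mid ? 1 : 0); q < l.segs.size(); ++q)
          other.segs.push_back(l.segs[q]);
        l.segs.resize(cut + (split_mid ? 1 : 0));
      }
      if (l.segs.empty() || other.segs.empty()) continue;
      arg.update_lineage(idx);
      arg.add_lineage(std::move(other));
      ++n_rec;
    } else {
      // mutation: lineage weighted by ancestral length, uniform within it
      double v = (u - r_coal - r_rec) / mut_rate;
      int idx = arg.pick_tot(v);
      double w = unif_rand() * arg.lins[idx].tot;
      double run = 0.0;
      for (const Seg& sg : arg.lins[idx].segs) {
        double len = sg.b - sg.a;
        if (w < run + len) {
          mut_pos.push_back(sg.a + (w - run));
          mut_mask.push_back(sg.mask);
          break;
        }
        run += len;
      }
    }
  }

  // order mutations by position and expand masks to a 0/1 matrix
  int S = (int)mut_pos.size();
  std::vector<int> ord(S);
  for (int i = 0; i < S; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return mut_pos[a] < mut_pos[b]; });
  NumericVector pos(S);
  IntegerMatrix G(ntot, S);
  for (int c = 0; c < S; ++c) {
    int m = ord[c];
    pos[c] = mut_pos[m];
    uint64_t msk = mut_mask[m];
    for (int rix = 0; rix < ntot; ++rix) {
      G(rix, c) = (msk >> rix) & 1ULL;
    }
  }
  return List::create(_["positions"] = pos, _["genotypes"] = G,
                      _["n_coalescence"] = (double)n_coal,
                      _["n_recombination"] = (double)n_rec,
                      _["tmrca_last"] = t);
}
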
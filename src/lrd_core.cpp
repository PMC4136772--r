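// Compiled kernels for Local Rank Distance and the LRD aligners.
//
// Sequences arrive as std::string over {A,C,G,T,N}; validation and
// uppercasing happen on the R side. k-mers are 2-bit encoded into a 64-bit
// code (k <= 31); any k-mer containing N gets code -1 and matches nothing.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

typedef long long ll;
static const ll NO_CODE = -1;
static const ll BIG = 1LL << 60;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1; // N
  }
}

// rolling 2-bit codes for all k-mer start positions; -1 where the window
// contains an ambiguous base
static std::vector<ll> kmer_codes(const std::string& s, int k) {
  const int n = (int) s.size();
  const int nk = n - k + 1;
  std::vector<ll> codes;
  if (nk <= 0) return codes;
  codes.assign(nk, NO_CODE);
  const ll mask = (k == 32) ? ~0LL : ((1LL << (2 * k)) - 1);
  ll code = 0;
  int last_bad = -1; // most recent position holding a non-ACGT base
  for (int i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { last_bad = i; b = 0; }
    code = ((code << 2) | b) & mask;
    int start = i - k + 1;
    if (start >= 0 && last_bad < start) codes[start] = code;
  }
  return codes;
}

typedef std::unordered_map<ll, std::vector<int> > PosMap;

static PosMap build_pos_map(const std::vector<ll>& codes) {
  PosMap map;
  map.reserve(codes.size() * 2);
  for (int i = 0; i < (int) codes.size(); ++i)
    if (codes[i] != NO_CODE) map[codes[i]].push_back(i);
  return map;
}

// nearest element of ascending `v` to q; ties toward the smaller element;
// returns absolute offset, BIG when v is empty
static inline ll nearest_offset(const std::vector<int>& v, int q) {
  if (v.empty()) return BIG;
  std::vector<int>::const_iterator it = std::lower_bound(v.begin(), v.end(), q);
  ll best = BIG;
  if (it != v.end()) best = (ll)(*it) - q;
  if (it != v.begin()) {
    ll d = (ll) q - *(it - 1);
    if (d <= best) best = d; // tie -> smaller position
  }
  return best;
}

// nearest element of `v` to q restricted to [lo, hi]; BIG when none
static inline ll nearest_offset_in_range(const std::vector<int>& v, int q,
                                         int lo, int hi) {
  std::vector<int>::const_iterator from =
    std::lower_bound(v.begin(), v.end(), lo);
  std::vector<int>::const_iterator to =
    std::upper_bound(v.begin(), v.end(), hi);
  if (from == to) return BIG;
  std::vector<int>::const_iterator it = std::lower_bound(from, to, q);
  ll best = BIG;
  if (it != to) best = (ll)(*it) - q;
  if (it != from) {
    ll d = (ll) q - *(it - 1);
    if (d <= best) best = d;
  }
  return best;
}

// one-sided partial sum Delta_{x->y}: every k-mer of x is charged the
// capped offset to the nearest identical k-mer of y (m when absent)
// [[Rcpp::export(name = ".delta_one_sided_cpp")]]
double delta_one_sided_cpp(std::string x, std::string y, int k, int m) {
  std::vector<ll> cx = kmer_codes(x, k);
  PosMap my = build_pos_map(kmer_codes(y, k));
  double total = 0.0;
  for (int p = 0; p < (int) cx.size(); ++p) {
    ll d = BIG;
    if (cx[p] != NO_CODE) {
      PosMap::const_iterator it = my.find(cx[p]);
      if (it != my.end()) d = nearest_offset(it->second, p);
    }
    total += (double) std::min<ll>(d, (ll) m);
  }
  return total;
}

// classical rank distance on occurrence-indexed characters
// [[Rcpp::export(name = ".rank_distance_cpp")]]
double rank_distance_cpp(std::string x, std::string y, double penalty) {
  std::unordered_map<char, std::vector<int> > px, py;
  for (int i = 0; i < (int) x.size(); ++i) px[x[i]].push_back(i);
  for (int i = 0; i < (int) y.size(); ++i) py[y[i]].push_back(i);
  double total = 0.0;
  std::unordered_map<char, std::vector<int> >::const_iterator it;
  for (it = px.begin(); it != px.end(); ++it) {
    const std::vector<int>& a = it->second;
    PosMap::mapped_type const* b = 0;
    std::unordered_map<char, std::vector<int> >::const_iterator jt =
      py.find(it->first);
    size_t nb = 0;
    if (jt != py.end()) { b = &jt->second; nb = b->size(); }
    size_t shared = std::min(a.size(), nb);
    for (size_t i = 0; i < shared; ++i)
      total += std::abs((double) a[i] - (double) (*b)[i]);
    total += penalty * (double) (a.size() - shared);
  }
  for (it = py.begin(); it != py.end(); ++it) {
    size_t na = 0;
    std::unordered_map<char, std::vector<int> >::const_iterator jt =
      px.find(it->first);
    if (jt != px.end()) na = jt->second.size();
    if (it->second.size() > na)
      total += penalty * (double) (it->second.size() - na);
  }
  return total;
}

// presence of each reference k-mer in the read index, plus the sliding
// count of present k-mers per candidate window start
// [[Rcpp::export(name = ".shared_kmer_counts_cpp")]]
List shared_kmer_counts_cpp(std::string read, std::string reference, int k) {
  PosMap idx = build_pos_map(kmer_codes(read, k));
  std::vector<ll> cr = kmer_codes(reference, k);
  const int n_ref_kmers = (int) cr.size();
  const int read_kmers = (int) read.size() - k + 1;
  LogicalVector presence(n_ref_kmers);
  for (int j = 0; j < n_ref_kmers; ++j)
    presence[j] = (cr[j] != NO_CODE) && idx.count(cr[j]) > 0;
  const int n_windows = (int) reference.size() - (int) read.size() + 1;
  IntegerVector counts(n_windows);
  int run = 0;
  for (int j = 0; j < read_kmers; ++j) run += presence[j] ? 1 : 0;
  int maxc = 0;
  for (int i = 0; i < n_windows; ++i) {
    counts[i] = run;
    if (run > maxc) maxc = run;
    if (i + 1 < n_windows) {
      run -= presence[i] ? 1 : 0;
      run += presence[i + read_kmers] ? 1 : 0;
    }
  }
  return List::create(_["presence"] = presence, _["counts"] = counts,
                      _["max_count"] = maxc);
}

// Delta_{window->read} at window start i using the read's inverted index;
// returns NA once the running sum exceeds abort_above (< 0 disables)
static ll delta_window_to_read(const std::vector<ll>& ref_codes,
                               const PosMap& idx, int i, int read_kmers,
                               int m, ll abort_above, bool* aborted) {
  ll total = 0;
  *aborted = false;
  const ll cap = abort_above < 0 ? BIG : abort_above;
  for (int t = 0; t < read_kmers; ++t) {
    ll code = ref_codes[i + t];
    ll d = BIG;
    if (code != NO_CODE) {
      PosMap::const_iterator it = idx.find(code);
      if (it != idx.end()) d = nearest_offset(it->second, t);
    }
    total += std::min<ll>(d, (ll) m);
    if (total > cap) { *aborted = true; return total; }
  }
  return total;
}

// Delta_{read->window}: every read k-mer looked up among the reference
// k-mer starts restricted to the window [i, i + read_kmers - 1]
static ll delta_read_to_window(const std::vector<ll>& read_codes,
                               const PosMap& ref_map, int i, int m) {
  ll total = 0;
  const int read_kmers = (int) read_codes.size();
  for (int t = 0; t < read_kmers; ++t) {
    ll code = read_codes[t];
    ll d = BIG;
    if (code != NO_CODE) {
      PosMap::const_iterator it = ref_map.find(code);
      if (it != ref_map.end())
        d = nearest_offset_in_range(it->second, i + t, i, i + read_kmers - 1);
    }
    total += std::min<ll>(d, (ll) m);
  }
  return total;
}

// [[Rcpp::export(name = ".delta_at_window_cpp")]]
SEXP delta_at_window_cpp(std::string read, std::string reference, int i,
                         int k, int m, double abort_above) {
  std::vector<ll> cr = kmer_codes(reference, k);
  PosMap idx = build_pos_map(kmer_codes(read, k));
  const int read_kmers = (int) read.size() - k + 1;
  bool aborted;
  ll cap = abort_above < 0 ? -1 : (ll) abort_above;
  ll d = delta_window_to_read(cr, idx, i, read_kmers, m, cap, &aborted);
  if (aborted) return wrap(NA_REAL);
  return wrap((double) d);
}

// Shared driver for the exhaustive and hash aligners. Windows are visited
// left to right; the leftmost window attaining the minimum wins.
//   exhaustive: evaluate every window fully (no skips, no abort).
//   hash: rule 1 skips window i when counts[i] < S * max_count; rule 2
//   skips when (read_kmers - counts[i]) * m already exceeds the best
//   distance so far; surviving windows may abort once they exceed it.
// [[Rcpp::export(name = ".align_core_cpp")]]
List align_core_cpp(std::string read, std::string reference, int k, int m,
                    bool exhaustive, double S, bool use_rule2, bool use_abort,
                    bool read_to_window) {
  const int n_windows = (int) reference.size() - (int) read.size() + 1;
  const int read_kmers = (int) read.size() - k + 1;
  std::vector<ll> ref_codes = kmer_codes(reference, k);
  std::vector<ll> read_codes = kmer_codes(read, k);
  PosMap idx = build_pos_map(read_codes);
  PosMap ref_map;
  if (read_to_window) ref_map = build_pos_map(ref_codes);

  std::vector<int> counts;
  int maxc = 0;
  if (!exhaustive) {
    counts.assign(n_windows, 0);
    int run = 0;
    std::vector<char> pres(ref_codes.size(), 0);
    for (size_t j = 0; j < ref_codes.size(); ++j)
      pres[j] = (ref_codes[j] != NO_CODE && idx.count(ref_codes[j]) > 0);
    for (int j = 0; j < read_kmers; ++j) run += pres[j];
    for (int i = 0; i < n_windows; ++i) {
      counts[i] = run;
      if (run > maxc) maxc = run;
      if (i + 1 < n_windows) run += pres[i + read_kmers] - pres[i];
    }
  }

  ll best = BIG;
  int best_pos = -1;
  int visited = 0;
  for (int i = 0; i < n_windows; ++i) {
    if (!exhaustive) {
      if ((double) counts[i] < S * (double) maxc) continue;   // rule 1
      if (use_rule2 &&
          (ll)(read_kmers - counts[i]) * (ll) m > best) continue; // rule 2
    }
    ++visited;
    ll d;
    if (read_to_window) {
      d = delta_read_to_window(read_codes, ref_map, i, m);
    } else {
      bool aborted;
      ll cap = (!exhaustive && use_abort && best < BIG) ? best : -1;
      d = delta_window_to_read(ref_codes, idx, i, read_kmers, m, cap, &aborted);
      if (aborted) continue;
    }
    if (d < best) { best = d; best_pos = i; }
  }
  return List::create(_["position"] = best_pos,
                      _["distance"] = (double) best,
                      _["visited"] = visited);
}
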
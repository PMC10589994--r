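// Streaming anchor/target engine.
//
// The hot loop (one hash lookup plus up to two dictionary updates per
// anchor position, ~100 positions per read) is the only part of the
// package that needs compiled code; everything statistical stays in R.
//
// K-mers are 2-bit packed into uint64_t (so k <= 31); windows containing
// any non-ACGT base are skipped.  All randomness (the 50% key-replacement
// draws) comes from R's RNG so a single set.seed() call makes a whole run
// reproducible.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static std::string decode_kmer(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BASES[code & 3ULL];
    code >>= 2;
  }
  return s;
}

// Encode s[pos..pos+k) or return false if it contains a non-ACGT base.
static bool encode_kmer(const char* s, int pos, int k, uint64_t& out) {
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(s[pos + i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  out = code;
  return true;
}

// Sorted unique set of all overlapping sub_k-mers of a packed k-mer.
static void subkmer_set(uint64_t code, int k, int sub_k,
                        std::vector<uint32_t>& out) {
  out.clear();
  const uint64_t mask = (1ULL << (2 * sub_k)) - 1ULL;
  for (int i = 0; i + sub_k <= k; ++i) {
    int shift = 2 * (k - sub_k - i);
    out.push_back((uint32_t)((code >> shift) & mask));
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

// Jaccard similarity of two sorted unique sets.
static double jaccard_sets(const std::vector<uint32_t>& a,
                           const std::vector<uint32_t>& b) {
  size_t i = 0, j = 0, inter = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) { ++inter; ++i; ++j; }
    else if (a[i] < b[j]) ++i;
    else ++j;
  }
  size_t uni = a.size() + b.size() - inter;
  return uni == 0 ? 0.0 : (double)inter / (double)uni;
}

struct Cluster {
  uint64_t key;
  std::vector<uint32_t> subs;
  uint32_t count;
};

struct TDict {
  std::vector<Cluster> clusters;
  uint64_t traj[2] = {0, 0};  // trajectory bits; bit n-1 set = rank n opened a cluster
  uint16_t N = 0;
};

struct AState {
  TDict dir[2];               // 0 = upstream, 1 = downstream
  uint32_t first_seen = 0;
  uint16_t max_within_read = 1;
};

// One dictionary update: recruit to the first cluster (insertion order)
// with JS strictly above the threshold, replacing its key with probability
// replace_prob; otherwise open a new cluster.  Returns true if a new
// cluster was created.  Caller must ensure d.N < Nmax.
static bool td_update(TDict& d, uint64_t tcode, int k, int sub_k,
                      double js_threshold, double replace_prob,
                      std::vector<uint32_t>& subs_buf) {
  subkmer_set(tcode, k, sub_k, subs_buf);
  for (Cluster& cl : d.clusters) {
    double js = jaccard_sets(subs_buf, cl.subs);
    if (js > js_threshold) {
      cl.count++;
      if (unif_rand() < replace_prob) {
        cl.key = tcode;
        cl.subs = subs_buf;
      }
      d.N++;
      return false;
    }
  }
  Cluster cl;
  cl.key = tcode;
  cl.subs = subs_buf;
  cl.count = 1;
  d.clusters.push_back(std::move(cl));
  int bit = d.N;  // 0-based rank of this target
  d.traj[bit >> 6] |= (1ULL << (bit & 63));
  d.N++;
  return true;
}

static inline bool traj_bit(const TDict& d, int n0) {  // n0 = 0-based rank
  return (d.traj[n0 >> 6] >> (n0 & 63)) & 1ULL;
}

// P[N >= Nmin] for N ~ Binomial(L, x/l), normal approximation with
// continuity correction; degenerate rates handled exactly.
static double retention_prob_cpp(double x, double l, double L, double Nmin) {
  if (x <= 0) return Nmin <= 0 ? 1.0 : 0.0;
  double rate = x / l;
  if (rate >= 1.0) rate = 1.0;
  double mu = L * rate, var = L * rate * (1.0 - rate);
  if (var <= 0) return mu >= Nmin ? 1.0 : 0.0;
  double p = R::pnorm(Nmin - 0.5, mu, std::sqrt(var), 0, 0);
  if (p < 0) p = 0;
  if (p > 1) p = 1;
  return p;
}

// [[Rcpp::export]]
double cpp_jaccard(std::string t1, std::string t2, int sub_k) {
  int k1 = (int)t1.size(), k2 = (int)t2.size();
  if (sub_k < 1 || sub_k > k1 || sub_k > k2)
    stop("sub_k must satisfy 1 <= sub_k <= nchar(target)");
  if (k1 > 31 || k2 > 31) stop("k-mers longer than 31 bases are not supported");
  uint64_t c1, c2;
  if (!encode_kmer(t1.c_str(), 0, k1, c1) || !encode_kmer(t2.c_str(), 0, k2, c2))
    stop("targets must be over the alphabet {A,C,G,T}");
  std::vector<uint32_t> s1, s2;
  subkmer_set(c1, k1, sub_k, s1);
  subkmer_set(c2, k2, sub_k, s2);
  return jaccard_sets(s1, s2);
}

// Single-step dictionary update on R-level state (keys + counts +
// trajectory).  Shares td_update() with the streaming engine so the two
// code paths cannot drift apart.
// [[Rcpp::export]]
List cpp_td_update(CharacterVector keys, IntegerVector counts,
                   std::string target, double js_threshold, int sub_k,
                   double replace_prob) {
  int k = (int)target.size();
  if (sub_k > k) stop("sub_k must not exceed the k-mer length");
  TDict d;
  std::vector<uint32_t> buf;
  for (int i = 0; i < keys.size(); ++i) {
    Cluster cl;
    std::string ks = as<std::string>(keys[i]);
    if ((int)ks.size() != k) stop("all cluster keys must have the target's length");
    if (!encode_kmer(ks.c_str(), 0, k, cl.key)) stop("invalid cluster key");
    subkmer_set(cl.key, k, sub_k, cl.subs);
    cl.count = counts[i];
    d.clusters.push_back(cl);
  }
  uint64_t tcode;
  if (!encode_kmer(target.c_str(), 0, k, tcode))
    stop("target must be over the alphabet {A,C,G,T}");
  bool created = td_update(d, tcode, k, sub_k, js_threshold, replace_prob, buf);
  CharacterVector new_keys(d.clusters.size());
  IntegerVector new_counts(d.clusters.size());
  for (size_t i = 0; i < d.clusters.size(); ++i) {
    new_keys[i] = decode_kmer(d.clusters[i].key, k);
    new_counts[i] = d.clusters[i].count;
  }
  return List::create(_["keys"] = new_keys, _["counts"] = new_counts,
                      _["new_cluster"] = created);
}

// Anchor/target tuples of a single read: for each anchor position p the
// upstream target is seq[p-k-g, p-g) and the downstream target is
// seq[p+k+g, p+2k+g), each emitted only when it fits and contains no N.
// Also reports the within-read occurrence count of every valid anchor.
// [[Rcpp::export]]
List cpp_extract_pairs(std::string seq, int k, int g) {
  int len = (int)seq.size();
  std::vector<std::string> anchors, targets, dirs;
  std::unordered_map<uint64_t, int> occ;
  std::vector<uint64_t> occ_order;
  const char* s = seq.c_str();
  for (int p = 0; p + k <= len; ++p) {
    uint64_t acode;
    if (!encode_kmer(s, p, k, acode)) continue;
    auto it = occ.find(acode);
    if (it == occ.end()) { occ[acode] = 1; occ_order.push_back(acode); }
    else it->second++;
    uint64_t tcode;
    int pu = p - k - g;
    if (pu >= 0 && encode_kmer(s, pu, k, tcode)) {
      anchors.push_back(decode_kmer(acode, k));
      dirs.push_back("up");
      targets.push_back(decode_kmer(tcode, k));
    }
    int pd = p + k + g;
    if (pd + k <= len && encode_kmer(s, pd, k, tcode)) {
      anchors.push_back(decode_kmer(acode, k));
      dirs.push_back("down");
      targets.push_back(decode_kmer(tcode, k));
    }
  }
  CharacterVector canchor(anchors.begin(), anchors.end());
  CharacterVector cdir(dirs.begin(), dirs.end());
  CharacterVector ctarget(targets.begin(), targets.end());
  CharacterVector onames(occ_order.size());
  IntegerVector ocounts(occ_order.size());
  for (size_t i = 0; i < occ_order.size(); ++i) {
    onames[i] = decode_kmer(occ_order[i], k);
    ocounts[i] = occ[occ_order[i]];
  }
  ocounts.attr("names") = onames;
  return List::create(_["anchor"] = canchor, _["direction"] = cdir,
                      _["target"] = ctarget, _["anchor_counts"] = ocounts);
}

// Full streaming pass over one sample's reads.
// [[Rcpp::export]]
List cpp_stream(CharacterVector seqs, int k, int g, int Nmin, int Nmax,
                double js_threshold, int sub_k, double replace_prob,
                double admission_alpha, double retention_cutoff,
                int sweep_every, bool keep_trajectories, bool keep_clusters) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if (sub_k < 1 || sub_k >= k) stop("sub_k must be in [1, k)");
  if (Nmax > 128) stop("Nmax must be <= 128");
  const int L = seqs.size();
  const double p_min = L > 0 ? std::min(1.0, (double)Nmin / (double)L) : 1.0;
  const double log_alpha = std::log(admission_alpha);
  // smallest l with (1 - p_min)^l < admission_alpha (log-domain; p_min = 1
  // closes after the first record)
  long l_close;
  if (p_min >= 1.0) l_close = 1;
  else if (p_min <= 0.0) l_close = L + 1;
  else {
    l_close = (long)std::floor(log_alpha / std::log1p(-p_min)) + 1;
    while ((double)(l_close - 1) * std::log1p(-p_min) < log_alpha) --l_close;
    while ((double)l_close * std::log1p(-p_min) >= log_alpha) ++l_close;
  }

  std::unordered_map<uint64_t, AState> store;
  std::vector<uint32_t> subs_buf;
  std::vector<int> codes;
  std::vector<uint64_t> wcode;     // packed window at p (valid entries only meaningful)
  std::vector<char> wvalid;
  std::vector<uint64_t> read_anchors;
  long n_evicted = 0;

  for (int r = 0; r < L; ++r) {
    bool admission_open = r < l_close;
    const char* s = CHAR(STRING_ELT(seqs, r));
    int len = (int)LENGTH(STRING_ELT(seqs, r));
    int nw = len - k + 1;
    if (nw > 0) {
      codes.assign(len, -1);
      for (int i = 0; i < len; ++i) codes[i] = base_code(s[i]);
      wcode.assign(nw, 0);
      wvalid.assign(nw, 0);
      // rolling window with invalid-base counter
      uint64_t code = 0;
      int bad = 0;
      const uint64_t mask = (k == 31) ? ~0ULL >> 2 : (1ULL << (2 * k)) - 1ULL;
      for (int i = 0; i < len; ++i) {
        int b = codes[i];
        if (b < 0) { bad++; code = (code << 2) & mask; }
        else code = ((code << 2) | (uint64_t)b) & mask;
        if (i >= k) {
          if (codes[i - k] < 0) bad--;
        }
        if (i >= k - 1) {
          wcode[i - k + 1] = code;
          wvalid[i - k + 1] = (bad == 0);
        }
      }
      read_anchors.clear();
      for (int p = 0; p < nw; ++p) {
        if (!wvalid[p]) continue;
        uint64_t acode = wcode[p];
        read_anchors.push_back(acode);
        int pu = p - k - g, pd = p + k + g;
        bool up_ok = pu >= 0 && wvalid[pu];
        bool down_ok = pd < nw && wvalid[pd];
        if (!up_ok && !down_ok) continue;
        auto it = store.find(acode);
        if (it == store.end()) {
          if (!admission_open) continue;
          AState st;
          st.first_seen = (uint32_t)r;
          it = store.emplace(acode, std::move(st)).first;
        }
        AState& st = it->second;
        if (up_ok && st.dir[0].N < Nmax)
          td_update(st.dir[0], wcode[pu], k, sub_k, js_threshold, replace_prob,
                    subs_buf);
        if (down_ok && st.dir[1].N < Nmax)
          td_update(st.dir[1], wcode[pd], k, sub_k, js_threshold, replace_prob,
                    subs_buf);
      }
      // within-read multiplicity (any valid anchor window counts)
      if (read_anchors.size() > 1) {
        std::sort(read_anchors.begin(), read_anchors.end());
        size_t i = 0;
        while (i < read_anchors.size()) {
          size_t j = i + 1;
          while (j < read_anchors.size() && read_anchors[j] == read_anchors[i]) ++j;
          if (j - i > 1) {
            auto it = store.find(read_anchors[i]);
            if (it != store.end() && it->second.max_within_read < j - i)
              it->second.max_within_read = (uint16_t)(j - i);
          }
          i = j;
        }
      }
    }
    // retention sweep: only after admission has closed
    long l_done = (long)r + 1;
    if (sweep_every > 0 && l_done >= l_close && (l_done % sweep_every) == 0 &&
        l_done < L) {
      for (auto it = store.begin(); it != store.end();) {
        const AState& st = it->second;
        double pu, pd;
        if (st.dir[0].N >= Nmin) pu = 1.0;
        else pu = retention_prob_cpp(st.dir[0].N, (double)l_done, (double)L,
                                     (double)Nmin);
        if (st.dir[1].N >= Nmin) pd = 1.0;
        else pd = retention_prob_cpp(st.dir[1].N, (double)l_done, (double)L,
                                     (double)Nmin);
        if (std::max(pu, pd) < retention_cutoff) {
          it = store.erase(it);
          ++n_evicted;
        } else ++it;
      }
    }
    if ((r % 4096) == 0) Rcpp::checkUserInterrupt();
  }

  // deterministic output order: sort by packed anchor code (= lexicographic)
  std::vector<uint64_t> keys;
  keys.reserve(store.size());
  for (auto& kv : store) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());

  size_t n = keys.size();
  CharacterVector anchor(n);
  IntegerVector up_N(n), up_C(n), down_N(n), down_C(n), mwr(n), first_seen(n);
  NumericVector numer(Nmax), denom(Nmax);
  List up_traj(keep_trajectories ? n : 0), down_traj(keep_trajectories ? n : 0);
  List up_keys(keep_clusters ? n : 0), up_counts(keep_clusters ? n : 0);
  List down_keys(keep_clusters ? n : 0), down_counts(keep_clusters ? n : 0);

  for (size_t i = 0; i < n; ++i) {
    const AState& st = store[keys[i]];
    anchor[i] = decode_kmer(keys[i], k);
    up_N[i] = st.dir[0].N; up_C[i] = (int)st.dir[0].clusters.size();
    down_N[i] = st.dir[1].N; down_C[i] = (int)st.dir[1].clusters.size();
    mwr[i] = st.max_within_read;
    first_seen[i] = (int)st.first_seen;
    for (int d = 0; d < 2; ++d) {
      const TDict& td = st.dir[d];
      for (int n0 = 0; n0 < td.N; ++n0) {
        denom[n0] += 1.0;
        if (traj_bit(td, n0)) numer[n0] += 1.0;
      }
    }
    if (keep_trajectories) {
      IntegerVector tu(st.dir[0].N), tdn(st.dir[1].N);
      for (int n0 = 0; n0 < st.dir[0].N; ++n0) tu[n0] = traj_bit(st.dir[0], n0);
      for (int n0 = 0; n0 < st.dir[1].N; ++n0) tdn[n0] = traj_bit(st.dir[1], n0);
      up_traj[i] = tu; down_traj[i] = tdn;
    }
    if (keep_clusters) {
      for (int d = 0; d < 2; ++d) {
        const TDict& td = st.dir[d];
        CharacterVector ck(td.clusters.size());
        IntegerVector cc(td.clusters.size());
        for (size_t j = 0; j < td.clusters.size(); ++j) {
          ck[j] = decode_kmer(td.clusters[j].key, k);
          cc[j] = (int)td.clusters[j].count;
        }
        if (d == 0) { up_keys[i] = ck; up_counts[i] = cc; }
        else { down_keys[i] = ck; down_counts[i] = cc; }
      }
    }
  }

  List out = List::create(
      _["anchor"] = anchor, _["up_N"] = up_N, _["up_C"] = up_C,
      _["down_N"] = down_N, _["down_C"] = down_C,
      _["max_within_read"] = mwr, _["first_seen"] = first_seen,
      _["null_numer"] = numer, _["null_denom"] = denom,
      _["L"] = L, _["l_close"] = (double)std::min<long>(l_close, (long)L + 1),
      _["n_evicted"] = (double)n_evicted);
  if (keep_trajectories) {
    out["up_traj"] = up_traj;
    out["down_traj"] = down_traj;
  }
  if (keep_clusters) {
    out["up_keys"] = up_keys; out["up_counts"] = up_counts;
    out["down_keys"] = down_keys; out["down_counts"] = down_counts;
  }
  return out;
}
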
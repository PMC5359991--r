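// Light-weight reference mapper: prefix-anchored k-mer index, ungapped
// seed-and-extend with a mismatch-tolerance rate, reverse-complement
// ("palindrome") fallback, segment re-mapping of unmapped reads, and the
// exact decoder-side inverse (reconstruction from match records).

#include <Rcpp.h>
#include <unordered_map>
#include "fqzip_common.h"

using namespace Rcpp;

// ---- index -----------------------------------------------------------------

// [[Rcpp::export(name = ".c_build_index")]]
List c_build_index(std::string ref, int k, std::string prefix) {
  if (k < 1) stop("k must be >= 1");
  if ((int)prefix.size() >= k) stop("prefix must be shorter than k");
  std::vector<std::string> kmers;
  std::vector<std::vector<int>> positions;
  std::unordered_map<std::string, int> slot;
  if ((long)ref.size() >= (long)k) {
    size_t last = ref.size() - (size_t)k;
    for (size_t i = 0; i <= last; ++i) {
      if (ref.compare(i, prefix.size(), prefix) != 0) continue;
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        char c = ref[i + j];
        if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { ok = false; break; }
      }
      if (!ok) continue;
      std::string km = ref.substr(i, k);
      auto it = slot.find(km);
      if (it == slot.end()) {
        slot.emplace(km, (int)kmers.size());
        kmers.push_back(km);
        positions.push_back(std::vector<int>{(int)i});
      } else {
        positions[it->second].push_back((int)i);
      }
    }
  }
  List pos(positions.size());
  for (size_t i = 0; i < positions.size(); ++i)
    pos[i] = IntegerVector(positions[i].begin(), positions[i].end());
  return List::create(_["kmers"] = CharacterVector(kmers.begin(), kmers.end()),
                      _["positions"] = pos);
}

// ---- alignment core --------------------------------------------------------

struct Seg {
  int ref_pos = -1;
  bool pal = false;
  std::vector<int> runs;
  std::string mism;
};

// Ungapped full-length alignment of `seq` at reference offset s.
// Succeeds iff in bounds, no junction crossed, length >= L and the
// mismatch count stays within floor(e * length).
static bool try_align(const std::string &seq, const std::string &ref, long s,
                      const std::vector<int> &junctions, int L, double e, Seg &out) {
  long n = (long)seq.size();
  if (n < L) return false;
  if (s < 0 || s + n > (long)ref.size()) return false;
  for (int j : junctions)
    if ((long)j > s && (long)j < s + n) return false;
  int maxmm = (int)std::floor(e * (double)n);
  int mm = 0;
  for (long i = 0; i < n; ++i)
    if (seq[i] != ref[s + i] && ++mm > maxmm) return false;
  out.ref_pos = (int)s;
  out.runs.clear();
  out.mism.clear();
  int run = 0;
  for (long i = 0; i < n; ++i) {
    if (seq[i] == ref[s + i]) ++run;
    else { out.runs.push_back(run); out.mism.push_back(seq[i]); run = 0; }
  }
  out.runs.push_back(run);
  return true;
}

// Index table plus mapping parameters; anchors are tried in read-offset
// order, then reference-position order, and the first extension that
// satisfies L and e wins.
struct MapCtx {
  std::unordered_map<std::string, std::pair<const int *, int>> table;
  std::vector<IntegerVector> keep;
  int k, L, segment_len;
  double e;
  std::string prefix;
  const std::string *ref;
  std::vector<int> junctions;

  bool map_whole(const std::string &seq, Seg &out) const {
    long n = (long)seq.size();
    if (n < k) return false;
    size_t plen = prefix.size();
    for (long i = 0; i + k <= n; ++i) {
      if (seq.compare(i, plen, prefix) != 0) continue;
      auto it = table.find(seq.substr(i, k));
      if (it == table.end()) continue;
      const int *pos = it->second.first;
      int m = it->second.second;
      for (int j = 0; j < m; ++j)
        if (try_align(seq, *ref, (long)pos[j] - i, junctions, L, e, out)) return true;
    }
    return false;
  }
};

static MapCtx make_ctx(List index_tbl, const std::string *ref, IntegerVector junctions,
                       int k, std::string prefix, int L, double e, int segment_len) {
  MapCtx ctx;
  ctx.k = k; ctx.L = L; ctx.e = e; ctx.segment_len = segment_len;
  ctx.prefix = prefix; ctx.ref = ref;
  ctx.junctions = std::vector<int>(junctions.begin(), junctions.end());
  CharacterVector kmers = index_tbl["kmers"];
  List positions = index_tbl["positions"];
  ctx.keep.reserve(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    IntegerVector p = positions[i];
    ctx.keep.push_back(p);
    ctx.table.emplace(as<std::string>(kmers[i]),
                      std::make_pair((const int *)INTEGER(ctx.keep.back()), (int)p.size()));
  }
  return ctx;
}

static List seg_to_list(const Seg &s, int seg_len) {
  return List::create(_["kind"] = "MAP",
                      _["ref_pos"] = s.ref_pos,
                      _["palindrome"] = s.pal,
                      _["run_lengths"] = IntegerVector(s.runs.begin(), s.runs.end()),
                      _["mismatch_bases"] = s.mism,
                      _["raw_bases"] = "",
                      _["length"] = seg_len);
}

static List raw_seg(const std::string &bases) {
  return List::create(_["kind"] = "RAW",
                      _["ref_pos"] = NA_INTEGER,
                      _["palindrome"] = false,
                      _["run_lengths"] = IntegerVector(0),
                      _["mismatch_bases"] = "",
                      _["raw_bases"] = bases,
                      _["length"] = (int)bases.size());
}

static List map_one(const std::string &read, const MapCtx &ctx) {
  int n = (int)read.size();
  if (!all_acgt(read)) {
    return List::create(_["match_type"] = "RAW", _["segments"] = List(0),
                        _["raw_bases"] = read, _["read_len"] = n);
  }
  Seg seg;
  // (1) forward whole-read
  if (ctx.map_whole(read, seg)) {
    std::string type = seg.mism.empty() ? "FULL_EXACT" : "FULL_SUB";
    return List::create(_["match_type"] = type,
                        _["segments"] = List::create(seg_to_list(seg, n)),
                        _["raw_bases"] = "", _["read_len"] = n);
  }
  // (2) palindrome (reverse complement) whole-read
  std::string rc = revcomp_str(read);
  if (ctx.map_whole(rc, seg)) {
    seg.pal = true;
    std::string type = seg.mism.empty() ? "FULL_EXACT" : "FULL_SUB";
    return List::create(_["match_type"] = type,
                        _["segments"] = List::create(seg_to_list(seg, n)),
                        _["raw_bases"] = "", _["read_len"] = n);
  }
  // (3) re-partition into segment_len pieces, map each independently
  bool any = false;
  std::vector<List> segs;
  for (int off = 0; off < n; off += ctx.segment_len) {
    int len = std::min(ctx.segment_len, n - off);
    std::string piece = read.substr(off, len);
    Seg ps;
    if (ctx.map_whole(piece, ps)) {
      any = true;
      segs.push_back(seg_to_list(ps, len));
    } else {
      std::string prc = revcomp_str(piece);
      if (ctx.map_whole(prc, ps)) {
        ps.pal = true;
        any = true;
        segs.push_back(seg_to_list(ps, len));
      } else {
        segs.push_back(raw_seg(piece));
      }
    }
  }
  if (any) {
    List out(segs.size());
    for (size_t i = 0; i < segs.size(); ++i) out[i] = segs[i];
    return List::create(_["match_type"] = "SEGMENTED", _["segments"] = out,
                        _["raw_bases"] = "", _["read_len"] = n);
  }
  // (4) raw fallback
  return List::create(_["match_type"] = "RAW", _["segments"] = List(0),
                      _["raw_bases"] = read, _["read_len"] = n);
}

// [[Rcpp::export(name = ".c_map_reads")]]
List c_map_reads(CharacterVector reads, List index_tbl, std::string ref,
                 IntegerVector junctions, int k, std::string prefix,
                 int L, double e, int segment_len) {
  MapCtx ctx = make_ctx(index_tbl, &ref, junctions, k, prefix, L, e, segment_len);
  List out(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i)
    out[i] = map_one(as<std::string>(reads[i]), ctx);
  return out;
}

// [[Rcpp::export(name = ".c_find_seeds")]]
List c_find_seeds(std::string read, List index_tbl, int k, std::string prefix) {
  CharacterVector kmers = index_tbl["kmers"];
  List positions = index_tbl["positions"];
  std::unordered_map<std::string, IntegerVector> table;
  for (R_xlen_t i = 0; i < kmers.size(); ++i)
    table.emplace(as<std::string>(kmers[i]), (IntegerVector)positions[i]);
  std::vector<int> roff, rpos;
  long n = (long)read.size();
  for (long i = 0; i + k <= n; ++i) {
    auto it = table.find(read.substr(i, k));
    if (it == table.end()) continue;
    for (int p : it->second) { roff.push_back((int)i); rpos.push_back(p); }
  }
  return List::create(_["read_offset"] = IntegerVector(roff.begin(), roff.end()),
                      _["ref_pos"] = IntegerVector(rpos.begin(), rpos.end()));
}

// [[Rcpp::export(name = ".c_extend_seed")]]
List c_extend_seed(std::string read, std::string ref, int read_offset, int ref_pos,
                   IntegerVector junctions, int L, double e) {
  std::vector<int> jx(junctions.begin(), junctions.end());
  Seg seg;
  if (!try_align(read, ref, (long)ref_pos - (long)read_offset, jx, L, e, seg))
    return List(0);
  return List::create(seg_to_list(seg, (int)read.size()));
}

// ---- reconstruction --------------------------------------------------------

static std::string reconstruct_one(List rec, const std::string &ref) {
  std::string type = as<std::string>(rec["match_type"]);
  if (type == "RAW") return as<std::string>(rec["raw_bases"]);
  List segs = rec["segments"];
  std::string out;
  for (R_xlen_t i = 0; i < segs.size(); ++i) {
    List s = segs[i];
    std::string kind = as<std::string>(s["kind"]);
    if (kind == "RAW") {
      out += as<std::string>(s["raw_bases"]);
      continue;
    }
    int pos = as<int>(s["ref_pos"]);
    IntegerVector runs = s["run_lengths"];
    std::string mism = as<std::string>(s["mismatch_bases"]);
    if ((size_t)runs.size() != mism.size() + 1)
      stop("corrupted match record: run/mismatch counts disagree");
    long span = 0;
    for (int r : runs) span += r;
    span += (long)mism.size();
    if (pos < 0 || (long)pos + span > (long)ref.size())
      stop("corrupted match record: segment exceeds reference length");
    std::string piece;
    piece.reserve(span);
    long rp = pos;
    for (R_xlen_t j = 0; j < runs.size(); ++j) {
      piece.append(ref, rp, runs[j]);
      rp += runs[j];
      if (j < (R_xlen_t)mism.size()) { piece.push_back(mism[j]); ++rp; }
    }
    if (as<bool>(s["palindrome"])) piece = revcomp_str(piece);
    out += piece;
  }
  return out;
}

// [[Rcpp::export(name = ".c_reconstruct_reads")]]
CharacterVector c_reconstruct_reads(List records, std::string ref) {
  CharacterVector out(records.size());
  for (R_xlen_t i = 0; i < records.size(); ++i)
    out[i] = reconstruct_one((List)records[i], ref);
  return out;
}

// [[Rcpp::export(name = ".c_revcomp")]]
CharacterVector c_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    try {
      out[i] = revcomp_str(as<std::string>(seqs[i]));
    } catch (std::runtime_error &e) {
      stop(e.what());
    }
  }
  return out;
}

// Longest exact suffix(a)/prefix(b) overlap of length >= omin.
// [[Rcpp::export(name = ".c_max_overlap")]]
int c_max_overlap(std::string a, std::string b, int omin) {
  int maxo = (int)std::min(a.size(), b.size());
  for (int o = maxo; o >= omin; --o)
    if (a.compare(a.size() - o, o, b, 0, o) == 0) return o;
  return 0;
}
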
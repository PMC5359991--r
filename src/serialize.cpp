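// Wire serialization of the intermediate streams: match-record structure,
// delta-coded segment positions, mismatch bases, raw sequences, incremental
// metadata deltas and run-length-limited quality planes.  All integers are
// LEB128 varints; positions are zigzag-coded deltas between consecutive
// mapped segments within a block.

#include <Rcpp.h>
#include "fqzip_common.h"

using namespace Rcpp;

// match_type codes on the wire
static const int T_FULL_EXACT = 0, T_FULL_SUB = 1, T_SEGMENTED = 2, T_RAW = 3;

// The match structure is carried in four homogeneous planes so that the
// high-order bit-context coder sees locally repetitive streams instead of
// interleaved constant/random bytes:
//   tokens  - per record: type byte; for SEGMENTED a segment-count varint;
//             per segment a kind byte (0 forward, 1 palindrome, 2 raw)
//   lengths - per mapped segment its length; per raw segment/record the
//             literal length (varints; constant under fixed-length reads)
//   counts  - per mapped segment the mismatch count (varint)
//   runs    - the leading run lengths (varints); the final run is derived
//             at decode time as seg_len - sum(leading) - n_mismatches
// Positions are zigzag varint deltas between consecutive mapped segments.

// [[Rcpp::export(name = ".c_pack_records")]]
List c_pack_records(List records) {
  std::vector<uint8_t> tokens, lengths, counts, runsv, positions;
  std::string mism, rawseq;
  int64_t prev_pos = 0;
  for (R_xlen_t i = 0; i < records.size(); ++i) {
    List rec = records[i];
    std::string type = as<std::string>(rec["match_type"]);
    List segs = rec["segments"];
    if (type == "RAW") {
      tokens.push_back((uint8_t)T_RAW);
      std::string rb = as<std::string>(rec["raw_bases"]);
      put_varint(lengths, rb.size());
      rawseq += rb;
      continue;
    }
    int tcode = (type == "FULL_EXACT") ? T_FULL_EXACT
              : (type == "FULL_SUB")   ? T_FULL_SUB
              : (type == "SEGMENTED")  ? T_SEGMENTED : -1;
    if (tcode < 0) stop("unknown match_type");
    tokens.push_back((uint8_t)tcode);
    if (tcode == T_SEGMENTED) put_varint(tokens, segs.size());
    for (R_xlen_t j = 0; j < segs.size(); ++j) {
      List s = segs[j];
      std::string kind = as<std::string>(s["kind"]);
      if (kind == "RAW") {
        tokens.push_back(2);
        std::string rb = as<std::string>(s["raw_bases"]);
        put_varint(lengths, rb.size());
        rawseq += rb;
      } else {
        bool pal = as<bool>(s["palindrome"]);
        tokens.push_back(pal ? 1 : 0);
        IntegerVector runs = s["run_lengths"];
        put_varint(lengths, (uint64_t)as<int>(s["length"]));
        put_varint(counts, (uint64_t)(runs.size() - 1));
        for (R_xlen_t r = 0; r + 1 < runs.size(); ++r)
          put_varint(runsv, (uint64_t)runs[r]);
        mism += as<std::string>(s["mismatch_bases"]);
        int pos = as<int>(s["ref_pos"]);
        put_varint(positions, zigzag((int64_t)pos - prev_pos));
        prev_pos = pos;
      }
    }
  }
  return List::create(
      _["tokens"] = RawVector(tokens.begin(), tokens.end()),
      _["lengths"] = RawVector(lengths.begin(), lengths.end()),
      _["counts"] = RawVector(counts.begin(), counts.end()),
      _["runs"] = RawVector(runsv.begin(), runsv.end()),
      _["positions"] = RawVector(positions.begin(), positions.end()),
      _["mismatch"] = mism,
      _["rawseq"] = rawseq);
}

// [[Rcpp::export(name = ".c_unpack_records")]]
List c_unpack_records(RawVector tokens, RawVector lengths, RawVector counts,
                      RawVector runsv, RawVector positions, std::string mism,
                      std::string rawseq, int n_records) {
  const uint8_t *tb = (const uint8_t *)RAW(tokens);
  size_t tn = tokens.size(), tp = 0;
  const uint8_t *lb = (const uint8_t *)RAW(lengths);
  size_t ln = lengths.size(), lp = 0;
  const uint8_t *cb = (const uint8_t *)RAW(counts);
  size_t cn = counts.size(), cp = 0;
  const uint8_t *rb_ = (const uint8_t *)RAW(runsv);
  size_t rn = runsv.size(), rvp = 0;
  const uint8_t *pb = (const uint8_t *)RAW(positions);
  size_t pn = positions.size(), pp = 0;
  size_t mp = 0, rp = 0;
  int64_t prev_pos = 0;
  List out(n_records);
  try {
    for (int i = 0; i < n_records; ++i) {
      if (tp >= tn) throw std::runtime_error("corrupted stream: structure tokens exhausted");
      int tcode = tb[tp++];
      if (tcode == T_RAW) {
        uint64_t len = get_varint(lb, ln, lp);
        if (rp + len > rawseq.size()) throw std::runtime_error("corrupted stream: raw-sequence stream exhausted");
        std::string rbs = rawseq.substr(rp, len);
        rp += len;
        out[i] = List::create(_["match_type"] = "RAW", _["segments"] = List(0),
                              _["raw_bases"] = rbs, _["read_len"] = (int)len);
        continue;
      }
      uint64_t nseg = 1;
      if (tcode == T_SEGMENTED) nseg = get_varint(tb, tn, tp);
      else if (tcode != T_FULL_EXACT && tcode != T_FULL_SUB)
        throw std::runtime_error("corrupted stream: unknown match-type code");
      List segs(nseg);
      int read_len = 0;
      for (uint64_t j = 0; j < nseg; ++j) {
        if (tp >= tn) throw std::runtime_error("corrupted stream: structure tokens exhausted");
        int kind = tb[tp++];
        if (kind == 2) {
          uint64_t len = get_varint(lb, ln, lp);
          if (rp + len > rawseq.size()) throw std::runtime_error("corrupted stream: raw-sequence stream exhausted");
          std::string rbs = rawseq.substr(rp, len);
          rp += len;
          read_len += (int)len;
          segs[j] = List::create(_["kind"] = "RAW", _["ref_pos"] = NA_INTEGER,
                                 _["palindrome"] = false,
                                 _["run_lengths"] = IntegerVector(0),
                                 _["mismatch_bases"] = "", _["raw_bases"] = rbs,
                                 _["length"] = (int)len);
        } else if (kind == 0 || kind == 1) {
          uint64_t seg_len = get_varint(lb, ln, lp);
          uint64_t nmm = get_varint(cb, cn, cp);
          IntegerVector runs((R_xlen_t)(nmm + 1));
          long lead = 0;
          for (uint64_t r = 0; r < nmm; ++r) {
            uint64_t v = get_varint(rb_, rn, rvp);
            runs[r] = (int)v;
            lead += (long)v;
          }
          long last = (long)seg_len - lead - (long)nmm;
          if (last < 0) throw std::runtime_error("corrupted stream: segment runs exceed segment length");
          runs[(R_xlen_t)nmm] = (int)last;
          if (mp + nmm > mism.size()) throw std::runtime_error("corrupted stream: mismatch stream exhausted");
          std::string mm = mism.substr(mp, nmm);
          mp += nmm;
          int64_t delta = unzigzag(get_varint(pb, pn, pp));
          int64_t pos = prev_pos + delta;
          prev_pos = pos;
          read_len += (int)seg_len;
          segs[j] = List::create(_["kind"] = "MAP", _["ref_pos"] = (int)pos,
                                 _["palindrome"] = (kind == 1),
                                 _["run_lengths"] = runs,
                                 _["mismatch_bases"] = mm, _["raw_bases"] = "",
                                 _["length"] = (int)seg_len);
        } else {
          throw std::runtime_error("corrupted stream: unknown segment kind");
        }
      }
      std::string type = (tcode == T_FULL_EXACT) ? "FULL_EXACT"
                       : (tcode == T_FULL_SUB)   ? "FULL_SUB" : "SEGMENTED";
      out[i] = List::create(_["match_type"] = type, _["segments"] = segs,
                            _["raw_bases"] = "", _["read_len"] = read_len);
    }
    if (tp != tn || lp != ln || cp != cn || rvp != rn || pp != pn ||
        mp != mism.size() || rp != rawseq.size())
      throw std::runtime_error("corrupted stream: trailing bytes in intermediate streams");
  } catch (std::runtime_error &e) {
    stop(e.what());
  }
  return out;
}

// ---- metadata: incremental (shared-prefix) coding ---------------------------

// [[Rcpp::export(name = ".c_lcp_lengths")]]
IntegerVector c_lcp_lengths(CharacterVector lines) {
  IntegerVector out(lines.size());
  std::string prev;
  for (R_xlen_t i = 0; i < lines.size(); ++i) {
    std::string cur = as<std::string>(lines[i]);
    size_t m = std::min(prev.size(), cur.size()), l = 0;
    while (l < m && prev[l] == cur[l]) ++l;
    out[i] = (int)l;
    prev = cur;
  }
  return out;
}

// [[Rcpp::export(name = ".c_meta_pack")]]
RawVector c_meta_pack(CharacterVector lines) {
  std::vector<uint8_t> out;
  std::string prev;
  for (R_xlen_t i = 0; i < lines.size(); ++i) {
    std::string cur = as<std::string>(lines[i]);
    size_t m = std::min(prev.size(), cur.size()), l = 0;
    while (l < m && prev[l] == cur[l]) ++l;
    put_varint(out, l);
    put_varint(out, cur.size() - l);
    out.insert(out.end(), cur.begin() + l, cur.end());
    prev = cur;
  }
  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export(name = ".c_meta_unpack")]]
List c_meta_unpack(RawVector packed, int n_lines, double offset) {
  const uint8_t *buf = (const uint8_t *)RAW(packed);
  size_t n = packed.size(), pos = (size_t)offset;
  CharacterVector out(n_lines);
  std::string prev;
  try {
    for (int i = 0; i < n_lines; ++i) {
      uint64_t lcp = get_varint(buf, n, pos);
      uint64_t slen = get_varint(buf, n, pos);
      if (lcp > prev.size()) throw std::runtime_error("corrupted stream: metadata prefix length exceeds previous line");
      if (pos + slen > n) throw std::runtime_error("corrupted stream: metadata suffix truncated");
      std::string cur = prev.substr(0, lcp) + std::string((const char *)buf + pos, slen);
      pos += slen;
      out[i] = cur;
      prev = cur;
    }
  } catch (std::runtime_error &e) {
    stop(e.what());
  }
  return List::create(_["lines"] = out, _["offset"] = (double)pos);
}

// ---- quality scores: run-length-limited two-plane coding --------------------
// Control byte: 0 = literal (one symbol); c in [run_min, run_cap] = run of c.

// [[Rcpp::export(name = ".c_rll_pack")]]
List c_rll_pack(CharacterVector quals, int run_min, int run_cap) {
  if (run_min < 2) stop("run_min must be >= 2");
  if (run_cap > 255 || run_cap < run_min) stop("run_cap must be in [run_min, 255]");
  std::vector<uint8_t> symbols, control;
  for (R_xlen_t i = 0; i < quals.size(); ++i) {
    std::string q = as<std::string>(quals[i]);
    size_t j = 0, n = q.size();
    while (j < n) {
      size_t r = j + 1;
      while (r < n && q[r] == q[j]) ++r;
      size_t rem = r - j;
      char sym = q[j];
      while (rem > 0) {
        size_t chunk = std::min(rem, (size_t)run_cap);
        if (chunk >= (size_t)run_min) {
          symbols.push_back((uint8_t)sym);
          control.push_back((uint8_t)chunk);
          rem -= chunk;
        } else {
          for (size_t t = 0; t < rem; ++t) {
            symbols.push_back((uint8_t)sym);
            control.push_back(0);
          }
          rem = 0;
        }
      }
      j = r;
    }
  }
  return List::create(_["symbols"] = RawVector(symbols.begin(), symbols.end()),
                      _["control"] = RawVector(control.begin(), control.end()));
}

// [[Rcpp::export(name = ".c_rll_unpack")]]
CharacterVector c_rll_unpack(RawVector symbols, RawVector control, IntegerVector lengths,
                             int run_min, int run_cap) {
  const uint8_t *sy = (const uint8_t *)RAW(symbols);
  const uint8_t *ct = (const uint8_t *)RAW(control);
  size_t nt = control.size(), pos = 0;
  if ((size_t)symbols.size() != nt) stop("corrupted stream: quality planes disagree in length");
  CharacterVector out(lengths.size());
  for (R_xlen_t i = 0; i < lengths.size(); ++i) {
    int need = lengths[i];
    std::string q;
    q.reserve(need);
    while ((int)q.size() < need) {
      if (pos >= nt) stop("corrupted stream: quality token stream exhausted");
      int c = ct[pos];
      char s = (char)sy[pos];
      ++pos;
      if (c == 0) q.push_back(s);
      else if (c >= run_min && c <= run_cap) q.append((size_t)c, s);
      else stop("corrupted stream: run length outside [run_min, run_cap]");
    }
    if ((int)q.size() != need) stop("corrupted stream: quality run overflows read length");
    out[i] = q;
  }
  if (pos != nt) stop("corrupted stream: trailing quality tokens");
  return out;
}

// ---- misc helpers -----------------------------------------------------------

// [[Rcpp::export(name = ".c_varint_encode")]]
RawVector c_varint_encode(NumericVector values) {
  std::vector<uint8_t> out;
  for (double v : values) {
    if (v < 0) stop("varint values must be non-negative");
    put_varint(out, (uint64_t)v);
  }
  return RawVector(out.begin(), out.end());
}

// Reads `count` varints starting at `offset` (0-based); returns values and
// the offset just past the last one.
// [[Rcpp::export(name = ".c_varint_decode")]]
List c_varint_decode(RawVector buf, double offset, int count) {
  const uint8_t *b = (const uint8_t *)RAW(buf);
  size_t n = buf.size(), pos = (size_t)offset;
  NumericVector out(count);
  try {
    for (int i = 0; i < count; ++i) out[i] = (double)get_varint(b, n, pos);
  } catch (std::runtime_error &e) {
    stop(e.what());
  }
  return List::create(_["values"] = out, _["offset"] = (double)pos);
}
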
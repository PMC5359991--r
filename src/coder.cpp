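// Adaptive bitwise context model ("PPM-style") + binary arithmetic coder.
//
// The model predicts each bit from the previous `order_bits` coded bits
// (order 32 = a 4-byte rolling context for general byte streams; order 28
// for the 2-bit-packed mismatch-base stream).  Per-context (n0, n1)
// counters give p1 = (n1+delta)/(n0+n1+2*delta); when either counter
// exceeds counter_cap both are halved (rounding up), which keeps the model
// adaptive while letting the estimate approach the source statistics.
//
// The coder keeps 32-bit low/high registers, emits a byte whenever the top
// bytes agree, and resolves straddled tiny intervals (< 2^16) by
// deterministically discarding the smaller side ("underflow narrowing") so
// that the interval never collapses.  Probabilities are quantized to 16
// bits; the whole coding path is integer-only, hence bit-exact across
// platforms.

#include <Rcpp.h>
#include <unordered_map>
#include "fqzip_common.h"

using namespace Rcpp;

struct Counts { uint16_t n0 = 0, n1 = 0; };

class BitModel {
public:
  uint32_t ctx = 0;
  uint32_t mask;
  uint32_t cap, delta;
  std::unordered_map<uint32_t, Counts> store;

  BitModel(int order_bits, int cap_, int delta_) {
    if (order_bits < 1 || order_bits > 32) stop("order_bits must be in [1, 32]");
    if (cap_ < 2 || cap_ > 65534) stop("counter_cap must be in [2, 65534]");
    if (delta_ < 1) stop("delta must be >= 1");
    mask = (order_bits >= 32) ? 0xFFFFFFFFu : ((1u << order_bits) - 1u);
    cap = (uint32_t)cap_;
    delta = (uint32_t)delta_;
  }

  // 16-bit quantized probability of a 1 bit in the current context
  uint32_t p16() const {
    uint32_t n0 = 0, n1 = 0;
    auto it = store.find(ctx);
    if (it != store.end()) { n0 = it->second.n0; n1 = it->second.n1; }
    uint32_t p = (uint32_t)((((uint64_t)(n1 + delta)) << 16) / (n0 + n1 + 2 * delta));
    if (p < 1) p = 1;
    if (p > 65535) p = 65535;
    return p;
  }

  double prob1() const {
    uint32_t n0 = 0, n1 = 0;
    auto it = store.find(ctx);
    if (it != store.end()) { n0 = it->second.n0; n1 = it->second.n1; }
    return (double)(n1 + delta) / (double)(n0 + n1 + 2.0 * delta);
  }

  void counts(uint32_t &n0, uint32_t &n1) const {
    n0 = n1 = 0;
    auto it = store.find(ctx);
    if (it != store.end()) { n0 = it->second.n0; n1 = it->second.n1; }
  }

  void update(int bit) {
    Counts &c = store[ctx];
    if (bit) ++c.n1; else ++c.n0;
    if (c.n0 > cap || c.n1 > cap) {
      c.n0 = (uint16_t)((c.n0 + 1) >> 1);
      c.n1 = (uint16_t)((c.n1 + 1) >> 1);
    }
    ctx = ((ctx << 1) | (uint32_t)bit) & mask;
  }
};

class ArEncoder {
public:
  uint32_t x1 = 0, x2 = 0xFFFFFFFFu;
  std::vector<uint8_t> out;

  void encode(int bit, uint32_t p1) {
    uint32_t range = x2 - x1; // interval [x1, x2] inclusive; range >= 2^16 here
    uint32_t xmid = x1 + (uint32_t)(((uint64_t)range * p1) >> 16);
    if (xmid >= x2) xmid = x2 - 1; // both subintervals stay non-empty
    if (bit) x2 = xmid; else x1 = xmid + 1;
    renorm();
  }

  void renorm() {
    for (;;) {
      if (((x1 ^ x2) & 0xFF000000u) == 0) {
        out.push_back((uint8_t)(x2 >> 24));
        x1 <<= 8;
        x2 = (x2 << 8) | 0xFFu;
      } else if (x2 - x1 < 0x10000u) {
        // straddled byte boundary with a tiny interval: keep the larger side
        uint32_t b = x2 & 0xFF000000u;
        if (b - 1 - x1 >= x2 - b) x2 = b - 1; else x1 = b;
      } else break;
    }
  }

  void flush() {
    for (int i = 3; i >= 0; --i) out.push_back((uint8_t)(x1 >> (8 * i)));
  }
};

class ArDecoder {
public:
  const uint8_t *buf;
  size_t n, pos = 0;
  uint32_t x1 = 0, x2 = 0xFFFFFFFFu, x = 0;

  ArDecoder(const uint8_t *buf_, size_t n_) : buf(buf_), n(n_) {
    for (int i = 0; i < 4; ++i) x = (x << 8) | next_byte();
  }

  uint8_t next_byte() {
    if (pos >= n) throw std::runtime_error("corrupted stream: truncated arithmetic-coded body");
    return buf[pos++];
  }

  int decode(uint32_t p1) {
    uint32_t range = x2 - x1;
    uint32_t xmid = x1 + (uint32_t)(((uint64_t)range * p1) >> 16);
    if (xmid >= x2) xmid = x2 - 1;
    int bit = (x <= xmid) ? 1 : 0;
    if (bit) x2 = xmid; else x1 = xmid + 1;
    for (;;) {
      if (((x1 ^ x2) & 0xFF000000u) == 0) {
        x1 <<= 8;
        x2 = (x2 << 8) | 0xFFu;
        x = (x << 8) | next_byte();
      } else if (x2 - x1 < 0x10000u) {
        uint32_t b = x2 & 0xFF000000u;
        if (b - 1 - x1 >= x2 - b) x2 = b - 1; else x1 = b;
      } else break;
    }
    return bit;
  }
};

// ---- framed stream codecs -------------------------------------------------
// Frame: [varint raw_len][coded body][8-byte FNV-1a of the raw payload];
// an empty payload is the single varint byte 0x00.

static void append_u64(std::vector<uint8_t> &out, uint64_t v) {
  for (int i = 7; i >= 0; --i) out.push_back((uint8_t)(v >> (8 * i)));
}

static uint64_t read_u64(const uint8_t *buf, size_t n, size_t &pos) {
  if (pos + 8 > n) throw std::runtime_error("corrupted stream: truncated checksum");
  uint64_t v = 0;
  for (int i = 0; i < 8; ++i) v = (v << 8) | buf[pos++];
  return v;
}

// [[Rcpp::export(name = ".c_encode_stream")]]
RawVector c_encode_stream(RawVector payload, int order_bits, int counter_cap, int delta) {
  std::vector<uint8_t> out;
  size_t n = payload.size();
  put_varint(out, (uint64_t)n);
  if (n > 0) {
    BitModel m(order_bits, counter_cap, delta);
    ArEncoder enc;
    const uint8_t *p = (const uint8_t *)RAW(payload);
    for (size_t i = 0; i < n; ++i) {
      uint8_t byte = p[i];
      for (int b = 7; b >= 0; --b) {
        int bit = (byte >> b) & 1;
        enc.encode(bit, m.p16());
        m.update(bit);
      }
    }
    enc.flush();
    out.insert(out.end(), enc.out.begin(), enc.out.end());
    append_u64(out, fnv1a64(p, n));
  }
  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export(name = ".c_decode_stream")]]
RawVector c_decode_stream(RawVector coded, int order_bits, int counter_cap, int delta) {
  const uint8_t *buf = (const uint8_t *)RAW(coded);
  size_t nb = coded.size(), pos = 0;
  uint64_t n;
  try {
    n = get_varint(buf, nb, pos);
    if (n == 0) {
      if (pos != nb) throw std::runtime_error("corrupted stream: trailing bytes after empty payload");
      return RawVector(0);
    }
    if (nb < pos + 8) throw std::runtime_error("corrupted stream: too short");
    BitModel m(order_bits, counter_cap, delta);
    ArDecoder dec(buf + pos, nb - pos - 8); // body excludes trailing checksum
    std::vector<uint8_t> out;
    out.reserve(n);
    for (uint64_t i = 0; i < n; ++i) {
      uint8_t byte = 0;
      for (int b = 0; b < 8; ++b) {
        int bit = dec.decode(m.p16());
        m.update(bit);
        byte = (uint8_t)((byte << 1) | bit);
      }
      out.push_back(byte);
    }
    size_t cpos = pos + dec.n;
    uint64_t want = read_u64(buf, nb, cpos);
    if (want != fnv1a64(out.data(), out.size()))
      throw std::runtime_error("corrupted stream: payload checksum mismatch");
    return RawVector(out.begin(), out.end());
  } catch (std::runtime_error &e) {
    stop(e.what());
  }
}

// 2-bit packed nucleotide stream (A=00, C=01, G=10, T=11), order-28 model.
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// [[Rcpp::export(name = ".c_encode_bases")]]
RawVector c_encode_bases(std::string bases, int order_bits, int counter_cap, int delta) {
  std::vector<uint8_t> out;
  size_t n = bases.size();
  put_varint(out, (uint64_t)n);
  if (n > 0) {
    BitModel m(order_bits, counter_cap, delta);
    ArEncoder enc;
    for (size_t i = 0; i < n; ++i) {
      int code = base_code(bases[i]);
      if (code < 0) stop("encode_bases: character outside {A,C,G,T}");
      for (int b = 1; b >= 0; --b) {
        int bit = (code >> b) & 1;
        enc.encode(bit, m.p16());
        m.update(bit);
      }
    }
    enc.flush();
    out.insert(out.end(), enc.out.begin(), enc.out.end());
    append_u64(out, fnv1a64((const uint8_t *)bases.data(), n));
  }
  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export(name = ".c_decode_bases")]]
std::string c_decode_bases(RawVector coded, int order_bits, int counter_cap, int delta) {
  const uint8_t *buf = (const uint8_t *)RAW(coded);
  size_t nb = coded.size(), pos = 0;
  try {
    uint64_t n = get_varint(buf, nb, pos);
    if (n == 0) {
      if (pos != nb) throw std::runtime_error("corrupted stream: trailing bytes after empty payload");
      return std::string();
    }
    if (nb < pos + 8) throw std::runtime_error("corrupted stream: too short");
    BitModel m(order_bits, counter_cap, delta);
    ArDecoder dec(buf + pos, nb - pos - 8);
    static const char LUT[4] = {'A', 'C', 'G', 'T'};
    std::string out(n, 'A');
    for (uint64_t i = 0; i < n; ++i) {
      int code = 0;
      for (int b = 0; b < 2; ++b) {
        int bit = dec.decode(m.p16());
        m.update(bit);
        code = (code << 1) | bit;
      }
      out[i] = LUT[code];
    }
    size_t cpos = pos + dec.n;
    uint64_t want = read_u64(buf, nb, cpos);
    if (want != fnv1a64((const uint8_t *)out.data(), out.size()))
      throw std::runtime_error("corrupted stream: payload checksum mismatch");
    return out;
  } catch (std::runtime_error &e) {
    stop(e.what());
  }
}

// Raw bit-vector codec (used to study the coder against entropy bounds).
// [[Rcpp::export(name = ".c_encode_bits")]]
RawVector c_encode_bits(IntegerVector bits, int order_bits, int counter_cap, int delta) {
  std::vector<uint8_t> out;
  size_t n = bits.size();
  put_varint(out, (uint64_t)n);
  if (n > 0) {
    BitModel m(order_bits, counter_cap, delta);
    ArEncoder enc;
    uint64_t h = 14695981039346656037ULL;
    for (size_t i = 0; i < n; ++i) {
      int bit = bits[i];
      if (bit != 0 && bit != 1) stop("bits must be 0 or 1");
      enc.encode(bit, m.p16());
      m.update(bit);
      h ^= (uint64_t)bit; h *= 1099511628211ULL;
    }
    enc.flush();
    out.insert(out.end(), enc.out.begin(), enc.out.end());
    append_u64(out, h);
  }
  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export(name = ".c_decode_bits")]]
IntegerVector c_decode_bits(RawVector coded, int order_bits, int counter_cap, int delta) {
  const uint8_t *buf = (const uint8_t *)RAW(coded);
  size_t nb = coded.size(), pos = 0;
  try {
    uint64_t n = get_varint(buf, nb, pos);
    if (n == 0) return IntegerVector(0);
    if (nb < pos + 8) throw std::runtime_error("corrupted stream: too short");
    BitModel m(order_bits, counter_cap, delta);
    ArDecoder dec(buf + pos, nb - pos - 8);
    IntegerVector out((R_xlen_t)n);
    uint64_t h = 14695981039346656037ULL;
    for (uint64_t i = 0; i < n; ++i) {
      int bit = dec.decode(m.p16());
      m.update(bit);
      out[i] = bit;
      h ^= (uint64_t)bit; h *= 1099511628211ULL;
    }
    size_t cpos = pos + dec.n;
    if (read_u64(buf, nb, cpos) != h)
      throw std::runtime_error("corrupted stream: payload checksum mismatch");
    return out;
  } catch (std::runtime_error &e) {
    stop(e.what());
  }
}

// Byte-wise order-0 baseline: context is the partial byte seen so far
// (with a leading marker bit), reset at every byte boundary.
// [[Rcpp::export(name = ".c_encode_order0")]]
RawVector c_encode_order0(RawVector payload, int counter_cap, int delta) {
  std::vector<uint8_t> out;
  size_t n = payload.size();
  put_varint(out, (uint64_t)n);
  if (n > 0) {
    BitModel m(9, counter_cap, delta);
    ArEncoder enc;
    const uint8_t *p = (const uint8_t *)RAW(payload);
    for (size_t i = 0; i < n; ++i) {
      uint8_t byte = p[i];
      m.ctx = 1;
      for (int b = 7; b >= 0; --b) {
        int bit = (byte >> b) & 1;
        enc.encode(bit, m.p16());
        m.update(bit);
      }
    }
    enc.flush();
    out.insert(out.end(), enc.out.begin(), enc.out.end());
    append_u64(out, fnv1a64(p, n));
  }
  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export(name = ".c_decode_order0")]]
RawVector c_decode_order0(RawVector coded, int counter_cap, int delta) {
  const uint8_t *buf = (const uint8_t *)RAW(coded);
  size_t nb = coded.size(), pos = 0;
  try {
    uint64_t n = get_varint(buf, nb, pos);
    if (n == 0) return RawVector(0);
    if (nb < pos + 8) throw std::runtime_error("corrupted stream: too short");
    BitModel m(9, counter_cap, delta);
    ArDecoder dec(buf + pos, nb - pos - 8);
    std::vector<uint8_t> out;
    out.reserve(n);
    for (uint64_t i = 0; i < n; ++i) {
      uint8_t byte = 0;
      m.ctx = 1;
      for (int b = 0; b < 8; ++b) {
        int bit = dec.decode(m.p16());
        m.update(bit);
        byte = (uint8_t)((byte << 1) | bit);
      }
      out.push_back(byte);
    }
    size_t cpos = pos + dec.n;
    if (read_u64(buf, nb, cpos) != fnv1a64(out.data(), out.size()))
      throw std::runtime_error("corrupted stream: payload checksum mismatch");
    return RawVector(out.begin(), out.end());
  } catch (std::runtime_error &e) {
    stop(e.what());
  }
}

// ---- stateful predictor handle (inspection / unit testing) ---------------

// [[Rcpp::export(name = ".c_bp_new")]]
SEXP c_bp_new(int order_bits, int counter_cap, int delta) {
  XPtr<BitModel> p(new BitModel(order_bits, counter_cap, delta), true);
  return p;
}

// [[Rcpp::export(name = ".c_bp_predict")]]
double c_bp_predict(SEXP ptr) {
  XPtr<BitModel> p(ptr);
  return p->prob1();
}

// [[Rcpp::export(name = ".c_bp_update")]]
void c_bp_update(SEXP ptr, int bit) {
  if (bit != 0 && bit != 1) stop("bit must be 0 or 1");
  XPtr<BitModel> p(ptr);
  p->update(bit);
}

// [[Rcpp::export(name = ".c_bp_state")]]
List c_bp_state(SEXP ptr) {
  XPtr<BitModel> p(ptr);
  uint32_t n0, n1;
  p->counts(n0, n1);
  return List::create(_["n0"] = (double)n0, _["n1"] = (double)n1,
                      _["context"] = (double)p->ctx);
}

// [[Rcpp::export(name = ".c_fnv64")]]
RawVector c_fnv64(RawVector data) {
  uint64_t h = fnv1a64((const uint8_t *)RAW(data), data.size());
  RawVector out(8);
  for (int i = 0; i < 8; ++i) out[i] = (uint8_t)(h >> (8 * (7 - i)));
  return out;
}
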
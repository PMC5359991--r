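#ifndef FQZIP_COMMON_H
#define FQZIP_COMMON_H

#include <cstdint>
#include <vector>
#include <string>
#include <stdexcept>

// FNV-1a 64-bit digest; the package's stream/reference checksum.
inline uint64_t fnv1a64(const uint8_t *data, size_t n) {
  uint64_t h = 14695981039346656037ULL;
  for (size_t i = 0; i < n; ++i) {
    h ^= (uint64_t)data[i];
    h *= 1099511628211ULL;
  }
  return h;
}

inline void put_varint(std::vector<uint8_t> &out, uint64_t v) {
  while (v >= 0x80) {
    out.push_back((uint8_t)(v & 0x7F) | 0x80);
    v >>= 7;
  }
  out.push_back((uint8_t)v);
}

inline uint64_t get_varint(const uint8_t *buf, size_t n, size_t &pos) {
  uint64_t v = 0;
  int shift = 0;
  for (;;) {
    if (pos >= n) throw std::runtime_error("corrupted stream: truncated varint");
    uint8_t b = buf[pos++];
    v |= (uint64_t)(b & 0x7F) << shift;
    if (!(b & 0x80)) return v;
    shift += 7;
    if (shift > 63) throw std::runtime_error("corrupted stream: varint overflow");
  }
}

inline uint64_t zigzag(int64_t v) {
  return ((uint64_t)v << 1) ^ (uint64_t)(v >> 63);
}
inline int64_t unzigzag(uint64_t v) {
  return (int64_t)(v >> 1) ^ -(int64_t)(v & 1);
}

inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'N': return 'N';
  default: return 0;
  }
}

inline std::string revcomp_str(const std::string &s) {
  std::string out(s.size(), 0);
  for (size_t i = 0; i < s.size(); ++i) {
    char c = comp_base(s[s.size() - 1 - i]);
    if (c == 0) throw std::runtime_error("reverse_complement: character outside {A,C,G,T,N}");
    out[i] = c;
  }
  return out;
}

inline bool all_acgt(const std::string &s) {
  for (char c : s)
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return false;
  return true;
}

#endif
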
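// 127-bit modular ring kernels.
//
// Ring elements cross the R boundary as canonical decimal strings (no sign,
// no leading zeros) so that arbitrary moduli up to 2^127 - 1 are exact.
// All arithmetic is done in unsigned __int128; a + b for a, b < 2^127
// cannot overflow 2^128, so a single conditional subtraction reduces sums.

#include <Rcpp.h>
#include <cstdint>
#include <string>

using namespace Rcpp;

typedef unsigned __int128 u128;
typedef __int128 i128;

static const u128 U128_MAX = ~(u128)0;

// ---- decimal string <-> u128 ----------------------------------------------

static bool parse_u128_str(const char* s, u128& out, bool allow_leading_zero) {
  if (s == NULL || *s == '\0') return false;
  if (!allow_leading_zero && s[1] != '\0' && s[0] == '0') return false;
  u128 v = 0;
  const u128 cap = U128_MAX / 10;
  for (const char* p = s; *p; ++p) {
    if (*p < '0' || *p > '9') return false;
    if (v > cap) return false;
    v *= 10;
    unsigned d = (unsigned)(*p - '0');
    if (U128_MAX - v < (u128)d) return false;
    v += d;
  }
  out = v;
  return true;
}

static std::string format_u128(u128 v) {
  if (v == 0) return "0";
  char buf[48];
  int i = 47;
  buf[i] = '\0';
  while (v > 0) {
    buf[--i] = (char)('0' + (int)(v % 10));
    v /= 10;
  }
  return std::string(buf + i);
}

static u128 parse_modulus(const std::string& mod) {
  u128 m;
  if (!parse_u128_str(mod.c_str(), m, false))
    stop("invalid modulus '%s'", mod.c_str());
  if (m < 3) stop("modulus must be >= 3");
  if ((m & 1) == 0) stop("modulus must be odd");
  return m;
}

static u128 parse_elem(SEXP x, R_xlen_t i, u128 m) {
  const char* s = CHAR(STRING_ELT(x, i));
  u128 v;
  if (!parse_u128_str(s, v, false))
    stop("invalid ring element '%s' (position %d)", s, (int)(i + 1));
  if (v >= m)
    stop("ring element '%s' not below modulus (position %d)", s, (int)(i + 1));
  return v;
}

// ---- modular ops ----------------------------------------------------------

// [[Rcpp::export]]
CharacterVector big_mod_add(CharacterVector a, CharacterVector b, std::string mod) {
  u128 m = parse_modulus(mod);
  R_xlen_t na = a.size(), nb = b.size();
  if (na != nb && na != 1 && nb != 1)
    stop("length mismatch: %d vs %d", (int)na, (int)nb);
  R_xlen_t n = std::max(na, nb);
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    u128 x = parse_elem(a, na == 1 ? 0 : i, m);
    u128 y = parse_elem(b, nb == 1 ? 0 : i, m);
    u128 s = x + y;  // < 2^128 since x, y < 2^127
    if (s >= m) s -= m;
    out[i] = format_u128(s);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector big_mod_sub(CharacterVector a, CharacterVector b, std::string mod) {
  u128 m = parse_modulus(mod);
  R_xlen_t na = a.size(), nb = b.size();
  if (na != nb && na != 1 && nb != 1)
    stop("length mismatch: %d vs %d", (int)na, (int)nb);
  R_xlen_t n = std::max(na, nb);
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    u128 x = parse_elem(a, na == 1 ? 0 : i, m);
    u128 y = parse_elem(b, nb == 1 ? 0 : i, m);
    u128 s = (x >= y) ? (x - y) : (m - y + x);
    out[i] = format_u128(s);
  }
  return out;
}

// Sum of all elements modulo mod.
// [[Rcpp::export]]
std::string big_mod_sum(CharacterVector x, std::string mod) {
  u128 m = parse_modulus(mod);
  if (x.size() == 0) stop("empty element list");
  u128 acc = 0;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    acc += parse_elem(x, i, m);
    if (acc >= m) acc -= m;
  }
  return format_u128(acc);
}

// [[Rcpp::export]]
LogicalVector big_mod_valid(CharacterVector x, std::string mod) {
  u128 m = parse_modulus(mod);
  LogicalVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    u128 v;
    out[i] = parse_u128_str(CHAR(STRING_ELT(x, i)), v, false) && v < m;
  }
  return out;
}

// ---- uniform draws from raw bytes -----------------------------------------

// Consume 16-byte big-endian blocks; rejection-sample so accepted draws are
// exactly uniform on [0, mod). Returns as many draws as the bytes allowed.
// [[Rcpp::export]]
CharacterVector big_from_bytes(RawVector bytes, std::string mod) {
  u128 m = parse_modulus(mod);
  R_xlen_t nblocks = bytes.size() / 16;
  // threshold = largest multiple of m that fits in 2^128; reject r >= threshold
  u128 rem = (U128_MAX % m + 1) % m;  // 2^128 mod m
  std::vector<std::string> acc;
  acc.reserve(nblocks);
  for (R_xlen_t b = 0; b < nblocks; ++b) {
    u128 r = 0;
    for (int j = 0; j < 16; ++j) r = (r << 8) | (u128)bytes[b * 16 + j];
    if (rem != 0 && r >= (u128)0 - rem) continue;  // reject top partial cycle
    acc.push_back(format_u128(r % m));
  }
  return wrap(acc);
}

// ---- signed fixed-point encode/decode -------------------------------------

static u128 pow10_u128(int k) {
  u128 v = 1;
  for (int i = 0; i < k; ++i) v *= 10;
  return v;
}

// Parse a plain signed decimal literal with at most `frac` fractional digits
// into scaled magnitude (value * 10^frac) + sign. Excess fractional digits
// are an error (never silently rounded).
static bool parse_fixed(const char* s, int frac, u128& mag, bool& neg,
                        std::string& err) {
  neg = false;
  const char* p = s;
  if (*p == '+' || *p == '-') { neg = (*p == '-'); ++p; }
  const char* ip = p;
  while (*p >= '0' && *p <= '9') ++p;
  int nint = (int)(p - ip);
  const char* fp = NULL;
  int nfrac = 0;
  if (*p == '.') {
    ++p;
    fp = p;
    while (*p >= '0' && *p <= '9') ++p;
    nfrac = (int)(p - fp);
  }
  if (*p != '\0' || (nint == 0 && nfrac == 0)) {
    err = "malformed decimal literal";
    return false;
  }
  if (nfrac > frac) {
    // allow excess digits only if they are all zeros
    for (int i = frac; i < nfrac; ++i)
      if (fp[i] != '0') {
        err = "precision error: more fractional digits than the fixed-point scale allows";
        return false;
      }
    nfrac = frac;
  }
  const u128 cap = U128_MAX / 10;
  u128 v = 0;
  for (int i = 0; i < nint; ++i) {
    if (v > cap) { err = "range error: magnitude overflows 128 bits"; return false; }
    v = v * 10 + (u128)(ip[i] - '0');
  }
  for (int i = 0; i < nfrac; ++i) {
    if (v > cap) { err = "range error: magnitude overflows 128 bits"; return false; }
    v = v * 10 + (u128)(fp[i] - '0');
  }
  for (int i = nfrac; i < frac; ++i) {
    if (v > cap) { err = "range error: magnitude overflows 128 bits"; return false; }
    v = v * 10;
  }
  mag = v;
  return true;
}

// [[Rcpp::export]]
CharacterVector fixed_encode_cpp(CharacterVector dec, std::string mod, int frac) {
  u128 m = parse_modulus(mod);
  u128 half = (m - 1) / 2;
  CharacterVector out(dec.size());
  for (R_xlen_t i = 0; i < dec.size(); ++i) {
    u128 mag;
    bool neg;
    std::string err;
    const char* s = CHAR(STRING_ELT(dec, i));
    if (!parse_fixed(s, frac, mag, neg, err))
      stop("%s ('%s', position %d)", err.c_str(), s, (int)(i + 1));
    if (mag > half)
      stop("range error: |%s| exceeds the representable window (position %d)",
           s, (int)(i + 1));
    u128 v = (neg && mag > 0) ? (m - mag) : mag;
    out[i] = format_u128(v);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector fixed_decode_cpp(CharacterVector x, std::string mod, int frac) {
  u128 m = parse_modulus(mod);
  u128 half = (m - 1) / 2;
  u128 scale = pow10_u128(frac);
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    u128 v = parse_elem(x, i, m);
    bool neg = v > half;
    u128 mag = neg ? (m - v) : v;
    u128 ip = mag / scale;
    u128 fr = mag % scale;
    std::string s = format_u128(ip);
    if (fr > 0) {
      std::string f = format_u128(fr);
      f.insert(f.begin(), (size_t)frac - f.size(), '0');
      while (!f.empty() && f.back() == '0') f.pop_back();
      s += "." + f;
    }
    if (neg && mag > 0) s.insert(s.begin(), '-');
    out[i] = s;
  }
  return out;
}

// Exact (non-modular) sum of signed fixed-point decimal literals; the
// independent ground-truth path for the synthetic-study generator.
// [[Rcpp::export]]
std::string dec_fixed_sum(CharacterVector dec, int frac) {
  i128 acc = 0;
  const i128 IMAX = (i128)(U128_MAX >> 1);
  for (R_xlen_t i = 0; i < dec.size(); ++i) {
    u128 mag;
    bool neg;
    std::string err;
    const char* s = CHAR(STRING_ELT(dec, i));
    if (!parse_fixed(s, frac, mag, neg, err))
      stop("%s ('%s', position %d)", err.c_str(), s, (int)(i + 1));
    if (mag > (u128)IMAX) stop("range error: '%s' too large for exact sum", s);
    i128 v = neg ? -(i128)mag : (i128)mag;
    if ((v > 0 && acc > IMAX - v) || (v < 0 && acc < -IMAX - v))
      stop("range error: exact sum overflows 127 bits");
    acc += v;
  }
  bool neg = acc < 0;
  u128 mag = neg ? (u128)(-acc) : (u128)acc;
  u128 scale = pow10_u128(frac);
  std::string s = format_u128(mag / scale);
  u128 fr = mag % scale;
  if (fr > 0) {
    std::string f = format_u128(fr);
    f.insert(f.begin(), (size_t)frac - f.size(), '0');
    while (!f.empty() && f.back() == '0') f.pop_back();
    s += "." + f;
  }
  if (neg && mag > 0) s.insert(s.begin(), '-');
  return s;
}

// ---- CRC-32 (IEEE 802.3, poly 0xEDB88320) ---------------------------------

static uint32_t crc_table[256];
static bool crc_init_done = false;

static void crc_init() {
  for (uint32_t n = 0; n < 256; ++n) {
    uint32_t c = n;
    for (int k = 0; k < 8; ++k)
      c = (c & 1) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
    crc_table[n] = c;
  }
  crc_init_done = true;
}

// [[Rcpp::export]]
std::string crc32_hex(std::string s) {
  if (!crc_init_done) crc_init();
  uint32_t c = 0xFFFFFFFFu;
  for (size_t i = 0; i < s.size(); ++i)
    c = crc_table[(c ^ (unsigned char)s[i]) & 0xFFu] ^ (c >> 8);
  c ^= 0xFFFFFFFFu;
  char buf[9];
  snprintf(buf, sizeof(buf), "%08x", c);
  return std::string(buf);
}
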
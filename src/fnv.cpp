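#include <Rcpp.h>
#include <cstdint>
#include <cstdio>

using namespace Rcpp;

// FNV-1a 64-bit over the UTF-8 bytes of a string.  This is the stable hash
// behind both self-contained fingerprint schemes; any re-implementation
// (e.g. a test oracle) must agree byte for byte.
static uint64_t fnv1a64(const char *s) {
  uint64_t h = 0xcbf29ce484222325ULL;
  for (const unsigned char *p = (const unsigned char *)s; *p; ++p) {
    h ^= (uint64_t)(*p);
    h *= 0x100000001b3ULL;
  }
  return h;
}

// [[Rcpp::export]]
CharacterVector fnv1a64_hex(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  char buf[17];
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    uint64_t h = fnv1a64(CHAR(STRING_ELT(x, i)));
    std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
    out[i] = buf;
  }
  return out;
}

// Residue of the FNV-1a 64-bit hash modulo n_bits (bit index of a feature).
// [[Rcpp::export]]
IntegerVector fnv1a64_mod(CharacterVector x, int n_bits) {
  if (n_bits <= 0) stop("n_bits must be positive");
  R_xlen_t n = x.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_INTEGER; continue; }
    uint64_t h = fnv1a64(CHAR(STRING_ELT(x, i)));
    out[i] = (int)(h % (uint64_t)n_bits);
  }
  return out;
}
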
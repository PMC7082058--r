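#include <Rcpp.h>
#include <cstdint>
#include <cinttypes>

using namespace Rcpp;

// FNV-1a 64-bit over the raw bytes of the canonical peptide sequence.
// Chosen because it is a fixed, published, dependency-free hash: databases
// built on any platform agree. Returned as the *signed* 64-bit value printed
// in decimal (R has no native int64; SQLite CASTs the string to INTEGER).
static inline uint64_t fnv1a64_bytes(const char* s, size_t n) {
  uint64_t h = 14695981039346656037ULL;
  for (size_t i = 0; i < n; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  return h;
}

// [[Rcpp::export(name = ".fnv1a64")]]
CharacterVector fnv1a64(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  char buf[24];
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    const char* s = CHAR(STRING_ELT(x, i));
    size_t len = LENGTH(STRING_ELT(x, i));
    if (len == 0) stop("cannot hash an empty peptide sequence");
    int64_t v = (int64_t)fnv1a64_bytes(s, len);
    snprintf(buf, sizeof(buf), "%" PRId64, v);
    out[i] = buf;
  }
  return out;
}
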
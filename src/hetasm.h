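#ifndef HETASM_H
#define HETASM_H

#include <cstdint>
#include <string>
#include <vector>

// 2-bit nucleotide encoding; k-mers with k <= 31 fit a 64-bit word.

static inline int base2bits(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t revcomp_kmer(uint64_t x, int k) {
    uint64_t rc = 0;
    for (int i = 0; i < k; ++i) {
        rc = (rc << 2) | (3ULL - (x & 3ULL));
        x >>= 2;
    }
    return rc;
}

static inline uint64_t canon_kmer(uint64_t x, int k) {
    uint64_t rc = revcomp_kmer(x, k);
    return x < rc ? x : rc;
}

static inline std::string decode_kmer(uint64_t x, int k) {
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        s[i] = BITS2BASE[x & 3ULL];
        x >>= 2;
    }
    return s;
}

static inline std::string revcomp_str(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) {
        switch (r[i]) {
        case 'A': r[i] = 'T'; break;
        case 'C': r[i] = 'G'; break;
        case 'G': r[i] = 'C'; break;
        case 'T': r[i] = 'A'; break;
        default: r[i] = 'N'; break;
        }
    }
    return r;
}

// Rolling scan over a sequence calling f(pos_of_last_base, fwd, rc) for
// every k-mer free of non-ACGT symbols.
template <typename F>
static inline void scan_kmers(const char *s, size_t n, int k, F f) {
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t fwd = 0, rc = 0;
    int valid = 0;
    const int shift = 2 * (k - 1);
    for (size_t i = 0; i < n; ++i) {
        int b = base2bits(s[i]);
        if (b < 0) { valid = 0; fwd = 0; rc = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
        if (++valid >= k) f(i, fwd, rc);
    }
}

#endif
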
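#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include "hetasm.h"

using namespace Rcpp;

// Count canonical k-mers across a set of reads and return the multiplicity
// histogram (multiplicity -> number of distinct canonical k-mers seen that
// many times).  k-mers containing non-ACGT symbols are skipped.
// [[Rcpp::export]]
DataFrame cpp_kmer_spectrum(CharacterVector reads, int k) {
    std::unordered_map<uint64_t, uint32_t> counts;
    counts.reserve(1 << 20);
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        const char *s = CHAR(STRING_ELT(reads, r));
        size_t n = LENGTH(STRING_ELT(reads, r));
        scan_kmers(s, n, k, [&](size_t, uint64_t fwd, uint64_t rc) {
            ++counts[fwd < rc ? fwd : rc];
        });
    }
    std::map<uint32_t, double> hist;
    for (const auto &kv : counts) hist[kv.second] += 1.0;
    IntegerVector mult(hist.size());
    NumericVector cnt(hist.size());
    R_xlen_t i = 0;
    for (const auto &kv : hist) {
        mult[i] = (int)kv.first;
        cnt[i] = kv.second;
        ++i;
    }
    return DataFrame::create(_["multiplicity"] = mult, _["count"] = cnt);
}
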
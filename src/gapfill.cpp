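#include <Rcpp.h>
#include <unordered_map>
#include "hetasm.h"

using namespace Rcpp;

namespace {

typedef std::unordered_map<uint64_t, uint32_t> KmerCounts;

// Greedy unambiguous extension: starting from the (k-1)-mer `seed`, append
// a base while exactly one of the four extensions is supported by >=
// min_count read k-mers.  Stops on a branch (>= 2 supported), a dead end,
// or after max_walk steps.
std::string greedy_walk(const std::string &seed, const KmerCounts &counts,
                        int k, int max_walk, int min_count) {
    std::string s = seed;
    for (int step = 0; step < max_walk; ++step) {
        int nsup = 0;
        char pick = 0;
        for (int b = 0; b < 4; ++b) {
            std::string cand = s.substr(s.size() - (k - 1)) + BITS2BASE[b];
            uint64_t x = 0;
            for (int t = 0; t < k; ++t)
                x = (x << 2) | (uint64_t)base2bits(cand[t]);
            uint64_t key = canon_kmer(x, k);
            auto it = counts.find(key);
            if (it != counts.end() && (int)it->second >= min_count) {
                ++nsup;
                pick = BITS2BASE[b];
            }
        }
        if (nsup != 1) break;
        s.push_back(pick);
    }
    return s;
}

} // namespace

// Attempt to fill one inter-contig gap by flank-anchored greedy k-mer
// extension.  Walks inward from the end of `left` and (via reverse
// complement) from the start of `right`; the gap is accepted as closed only
// when the two walks overlap exactly over >= k-1 bases.  Returns the bases
// that replace the N run (possibly ""), or NULL when the gap cannot be
// closed unambiguously.
// [[Rcpp::export]]
SEXP cpp_fill_gap(std::string left, std::string right, CharacterVector reads,
                  int k, int max_walk, int min_count) {
    int km1 = k - 1;
    if ((int)left.size() < km1 || (int)right.size() < km1)
        return R_NilValue;

    KmerCounts counts;
    counts.reserve(1 << 16);
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        const char *s = CHAR(STRING_ELT(reads, r));
        size_t n = LENGTH(STRING_ELT(reads, r));
        scan_kmers(s, n, k, [&](size_t, uint64_t fwd, uint64_t rc) {
            ++counts[fwd < rc ? fwd : rc];
        });
    }

    // left walk: starts with the last k-1 bases of the left flank
    std::string w1 = greedy_walk(left.substr(left.size() - km1), counts, k,
                                 max_walk, min_count);
    // right walk: extend revcomp(right) rightwards, flip back; w2 ends with
    // the first k-1 bases of the right flank
    std::string rcr = revcomp_str(right.substr(0, km1));
    std::string w2 = revcomp_str(greedy_walk(rcr, counts, k, max_walk, min_count));

    std::string rstart = right.substr(0, km1);
    std::string lend = left.substr(left.size() - km1);

    // full span: the left walk reaches the start of the right flank
    size_t pos = w1.find(rstart, 1);
    if (pos != std::string::npos) {
        if ((int)pos <= km1) return wrap(std::string(""));  // flanks touch
        return wrap(w1.substr(km1, pos - km1));
    }
    // or the right walk reaches back into the left flank
    pos = w2.rfind(lend);
    if (pos != std::string::npos) {
        long start = (long)pos + km1;            // first base after left flank
        long stop = (long)w2.size() - km1;       // first base of right flank
        if (start >= stop) return wrap(std::string(""));  // flanks touch
        return wrap(w2.substr(start, stop - start));
    }
    // otherwise: largest exact overlap >= k-1 between a suffix of w1 and
    // a prefix of w2 (both walks stopped mid-gap and meet)
    int maxo = (int)std::min(w1.size(), w2.size());
    for (int o = maxo; o >= km1; --o) {
        if (w1.compare(w1.size() - o, o, w2, 0, o) == 0) {
            std::string merged = w1 + w2.substr(o);
            if ((int)merged.size() < 2 * km1) break;
            std::string fill =
                merged.substr(km1, merged.size() - 2 * km1);
            return wrap(fill);
        }
    }
    return R_NilValue;
}
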
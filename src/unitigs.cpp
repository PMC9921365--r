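#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include "hetasm.h"

using namespace Rcpp;

namespace {

struct Dbg {
    int k;
    uint64_t mask;
    std::unordered_set<uint64_t> nodes; // canonical k-mers

    bool has(uint64_t oriented) const {
        return nodes.count(canon_kmer(oriented, k)) > 0;
    }
    // successors of an oriented k-mer (shift left, append base)
    void succ(uint64_t x, std::vector<uint64_t> &out) const {
        out.clear();
        for (uint64_t b = 0; b < 4; ++b) {
            uint64_t y = ((x << 2) | b) & mask;
            if (has(y)) out.push_back(y);
        }
    }
    // predecessors of an oriented k-mer (shift right, prepend base)
    void pred(uint64_t x, std::vector<uint64_t> &out) const {
        out.clear();
        const int shift = 2 * (k - 1);
        for (uint64_t b = 0; b < 4; ++b) {
            uint64_t y = (x >> 2) | (b << shift);
            if (has(y)) out.push_back(y);
        }
    }
};

} // namespace

// Build unitigs (maximal non-branching paths) from the de Bruijn graph of
// canonical k-mers with count >= min_count.  Bubbles and tips are
// deliberately left intact: haplotype duplication is resolved later at the
// contig stage, so the graph stage must preserve both haplotype paths.
// [[Rcpp::export]]
CharacterVector cpp_build_unitigs(CharacterVector reads, int k, int min_count) {
    std::unordered_map<uint64_t, uint32_t> counts;
    counts.reserve(1 << 20);
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        const char *s = CHAR(STRING_ELT(reads, r));
        size_t n = LENGTH(STRING_ELT(reads, r));
        scan_kmers(s, n, k, [&](size_t, uint64_t fwd, uint64_t rc) {
            ++counts[fwd < rc ? fwd : rc];
        });
    }

    Dbg g;
    g.k = k;
    g.mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    g.nodes.reserve(counts.size());
    for (const auto &kv : counts)
        if ((int)kv.second >= min_count) g.nodes.insert(kv.first);
    counts.clear();

    // deterministic iteration order regardless of hash layout
    std::vector<uint64_t> ordered(g.nodes.begin(), g.nodes.end());
    std::sort(ordered.begin(), ordered.end());

    std::unordered_set<uint64_t> visited;
    visited.reserve(g.nodes.size());
    std::vector<std::string> unitigs;
    std::vector<uint64_t> nb, nb2;

    auto walk = [&](uint64_t start) {
        std::string s = decode_kmer(start, k);
        visited.insert(canon_kmer(start, k));
        uint64_t cur = start;
        while (true) {
            g.succ(cur, nb);
            if (nb.size() != 1) break;
            uint64_t y = nb[0];
            uint64_t cy = canon_kmer(y, k);
            if (visited.count(cy)) break;
            g.pred(y, nb2);
            if (nb2.size() != 1) break;
            s.push_back(BITS2BASE[y & 3ULL]);
            visited.insert(cy);
            cur = y;
        }
        unitigs.push_back(s);
    };

    for (uint64_t c : ordered) {
        if (visited.count(c)) continue;
        uint64_t orients[2] = {c, revcomp_kmer(c, k)};
        for (int o = 0; o < 2; ++o) {
            uint64_t x = orients[o];
            g.pred(x, nb);
            bool start = true;
            if (nb.size() == 1) {
                g.succ(nb[0], nb2);
                if (nb2.size() == 1) start = false;
            }
            if (start) { walk(x); break; }
        }
    }
    // remaining nodes lie on perfect cycles; linearize each once
    for (uint64_t c : ordered)
        if (!visited.count(c)) walk(c);

    return wrap(unitigs);
}
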
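#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include "hetasm.h"

using namespace Rcpp;

namespace {

struct Hit { int32_t ref; int32_t pos; uint8_t orient; };

struct Cand {
    int32_t ref;
    int32_t start;   // implied 0-based start of (oriented) read on ref
    char strand;
    bool operator==(const Cand &o) const {
        return ref == o.ref && start == o.start && strand == o.strand;
    }
};

} // namespace

// Map reads to reference sequences by exact canonical k-mer seeding and
// ungapped extension.  A placement's score is its number of matching bases
// over the read/reference overlap (reads may overhang reference ends and
// are clipped).  A read is "uniquely" placed when its best score is
// strictly greater than the second best -- the unambiguous-placement rule
// used for depth, link building and coverage QC.
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector refs, CharacterVector reads, int seed_k,
                   int seed_step, double min_identity, int min_overlap,
                   int max_candidates = 200) {
    // ---- index ----
    std::unordered_map<uint64_t, std::vector<Hit>> index;
    index.reserve(1 << 20);
    std::vector<std::string> refseq(refs.size());
    for (R_xlen_t r = 0; r < refs.size(); ++r) {
        refseq[r] = std::string(CHAR(STRING_ELT(refs, r)),
                                LENGTH(STRING_ELT(refs, r)));
        const std::string &s = refseq[r];
        scan_kmers(s.c_str(), s.size(), seed_k,
                   [&](size_t i, uint64_t fwd, uint64_t rc) {
            uint64_t key = fwd < rc ? fwd : rc;
            Hit h;
            h.ref = (int32_t)r;
            h.pos = (int32_t)(i + 1 - seed_k);
            h.orient = fwd <= rc ? 0 : 1;
            index[key].push_back(h);
        });
    }

    R_xlen_t n = reads.size();
    IntegerVector out_ref(n, NA_INTEGER), out_pos(n, NA_INTEGER),
        out_matches(n, 0), out_overlap(n, 0), out_second(n, 0),
        out_rstart(n, NA_INTEGER), out_rend(n, NA_INTEGER);
    CharacterVector out_strand(n, NA_STRING);
    LogicalVector out_unique(n, false);

    std::vector<Cand> cands;
    for (R_xlen_t ri = 0; ri < n; ++ri) {
        std::string read(CHAR(STRING_ELT(reads, ri)),
                         LENGTH(STRING_ELT(reads, ri)));
        int len = (int)read.size();
        if (len < seed_k) continue;

        // seed positions: 0, step, 2*step, ..., plus the final k-mer
        cands.clear();
        bool overflow = false;
        std::vector<int> seed_pos;
        for (int j = 0; j + seed_k <= len; j += seed_step) seed_pos.push_back(j);
        if (seed_pos.empty() || seed_pos.back() != len - seed_k)
            seed_pos.push_back(len - seed_k);

        const uint64_t mask =
            (seed_k == 32) ? ~0ULL : ((1ULL << (2 * seed_k)) - 1);
        const int shift = 2 * (seed_k - 1);
        for (int j : seed_pos) {
            uint64_t fwd = 0, rc = 0;
            bool ok = true;
            for (int t = 0; t < seed_k; ++t) {
                int b = base2bits(read[j + t]);
                if (b < 0) { ok = false; break; }
                fwd = ((fwd << 2) | (uint64_t)b) & mask;
                rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
            }
            if (!ok) continue;
            uint64_t key = fwd < rc ? fwd : rc;
            uint8_t ro = fwd <= rc ? 0 : 1;
            auto it = index.find(key);
            if (it == index.end()) continue;
            for (const Hit &h : it->second) {
                Cand c;
                c.ref = h.ref;
                if (ro == h.orient) {
                    c.strand = '+';
                    c.start = h.pos - j;
                } else {
                    c.strand = '-';
                    c.start = h.pos - (len - seed_k - j);
                }
                if (std::find(cands.begin(), cands.end(), c) == cands.end()) {
                    cands.push_back(c);
                    if ((int)cands.size() > max_candidates) { overflow = true; break; }
                }
            }
            if (overflow) break;
        }
        if (cands.empty()) continue;
        if (overflow) { out_unique[ri] = false; continue; }

        std::string rcread;
        int best = -1, second = -1, best_i = -1, best_ov = 0;
        for (size_t ci = 0; ci < cands.size(); ++ci) {
            const Cand &c = cands[ci];
            const std::string &ref = refseq[c.ref];
            const std::string *q = &read;
            if (c.strand == '-') {
                if (rcread.empty()) rcread = revcomp_str(read);
                q = &rcread;
            }
            int lo = std::max(0, -c.start);
            int hi = std::min(len, (int)ref.size() - c.start);
            int overlap = hi - lo;
            if (overlap < min_overlap) continue;
            int matches = 0;
            for (int t = lo; t < hi; ++t)
                if ((*q)[t] == ref[c.start + t]) ++matches;
            if (matches < min_identity * overlap) continue;
            if (matches > best) {
                second = best;
                best = matches;
                best_i = (int)ci;
                best_ov = overlap;
            } else if (matches > second) {
                second = matches;
            }
        }
        if (best_i < 0) continue;
        const Cand &b = cands[best_i];
        out_ref[ri] = b.ref + 1;
        out_pos[ri] = b.start;
        out_strand[ri] = b.strand == '+' ? "+" : "-";
        out_matches[ri] = best;
        out_overlap[ri] = best_ov;
        out_second[ri] = second < 0 ? 0 : second;
        out_unique[ri] = best > second;
        out_rstart[ri] = std::max(0, b.start);
        out_rend[ri] = std::min((int)refseq[b.ref].size(), b.start + len);
    }

    return List::create(
        _["ref"] = out_ref, _["pos"] = out_pos, _["strand"] = out_strand,
        _["matches"] = out_matches, _["overlap"] = out_overlap,
        _["second_matches"] = out_second, _["unique"] = out_unique,
        _["ref_start"] = out_rstart, _["ref_end"] = out_rend);
}
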
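// Core sequence-hashing primitives: canonical (strand-invariant) k-mer
// hashing, the cascading common Bloom filter, and windowed minimizer
// selection. 64-bit hashes cross the R boundary as 16-char lowercase hex
// strings so that lexicographic order equals unsigned numeric order.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <deque>
#include <string>

using namespace Rcpp;

// Per-base seed constants (ntHash lineage; any fixed published seeds work --
// only determinism and strand invariance are contracts).
static const uint64_t SEED_TAB[4] = {
    0x3c8bfbb395c60474ULL,  // A
    0x3193c18562a02b4cULL,  // C
    0x20323ed082572324ULL,  // G
    0x295549f54be24456ULL   // T
};

static inline int baseCode(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static inline uint64_t rotl64(uint64_t x, int r) {
    return (x << r) | (x >> (64 - r));
}

static inline uint64_t splitmix64(uint64_t x) {
    x += 0x9e3779b97f4a7c15ULL;
    x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
    x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
    return x ^ (x >> 31);
}

// Canonical hash of the k-mer starting at codes[pos]; requires all codes
// valid. Returns min(forward, revcomp) hash; *plus set true when the forward
// hash is the canonical one (ties -> forward).
static inline uint64_t canonHash(const std::vector<int8_t>& codes, size_t pos,
                                 int k, bool* plus) {
    uint64_t hf = 0, hr = 0;
    for (int i = 0; i < k; ++i) {
        hf = rotl64(hf, 1) ^ SEED_TAB[(int)codes[pos + i]];
        hr = rotl64(hr, 1) ^ SEED_TAB[3 - (int)codes[pos + k - 1 - i]];
    }
    if (hf <= hr) { if (plus) *plus = true;  return hf; }
    else          { if (plus) *plus = false; return hr; }
}

static std::vector<int8_t> encode(const std::string& s) {
    std::vector<int8_t> codes(s.size());
    for (size_t i = 0; i < s.size(); ++i) codes[i] = (int8_t)baseCode(s[i]);
    return codes;
}

static std::string toHex(uint64_t x) {
    static const char* digits = "0123456789abcdef";
    std::string out(16, '0');
    for (int i = 15; i >= 0; --i) { out[i] = digits[x & 0xf]; x >>= 4; }
    return out;
}

static uint64_t fromHex(const std::string& s) {
    uint64_t x = 0;
    for (char c : s) {
        x <<= 4;
        if (c >= '0' && c <= '9') x |= (uint64_t)(c - '0');
        else if (c >= 'a' && c <= 'f') x |= (uint64_t)(c - 'a' + 10);
        else if (c >= 'A' && c <= 'F') x |= (uint64_t)(c - 'A' + 10);
        else stop("invalid hex string");
    }
    return x;
}

// ---- Bloom filter primitives ------------------------------------------------

static inline void bloomSet(std::vector<uint8_t>& bits, uint64_t bfsize,
                            uint64_t h, int numHashes) {
    uint64_t h2 = splitmix64(h) | 1ULL;
    for (int j = 0; j < numHashes; ++j) {
        uint64_t idx = (h + (uint64_t)j * h2) % bfsize;
        bits[idx >> 3] |= (uint8_t)(1u << (idx & 7));
    }
}

static inline bool bloomGet(const uint8_t* bits, uint64_t bfsize,
                            uint64_t h, int numHashes) {
    uint64_t h2 = splitmix64(h) | 1ULL;
    for (int j = 0; j < numHashes; ++j) {
        uint64_t idx = (h + (uint64_t)j * h2) % bfsize;
        if (!(bits[idx >> 3] & (1u << (idx & 7)))) return false;
    }
    return true;
}

// Build the cascade: level 1 holds all canonical k-mers of genome 1; level i
// holds k-mers of genome i already present in level i-1. At most two levels
// live at once. Returns the final level plus per-genome valid-k-mer counts.
// [[Rcpp::export]]
List cpp_bloom_build_cascade(List genomes, int k, double bfsizeD,
                             int numHashes) {
    if (k < 1) stop("k must be >= 1");
    uint64_t bfsize = (uint64_t)bfsizeD;
    if (bfsize < 1) stop("bfsize must be >= 1");
    size_t nbytes = (size_t)((bfsize + 7) / 8);
    int n = genomes.size();
    if (n < 2) stop("need at least two genomes");

    std::vector<uint8_t> prev, cur;
    IntegerVector validCounts(n);

    for (int g = 0; g < n; ++g) {
        cur.assign(nbytes, 0);
        CharacterVector contigs = genomes[g];
        long long nValid = 0;
        for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
            std::string seq = as<std::string>(contigs[ci]);
            if ((int)seq.size() < k) continue;
            std::vector<int8_t> codes = encode(seq);
            // rolling invalid-in-window count
            int bad = 0;
            for (int i = 0; i < k - 1; ++i) if (codes[i] < 0) ++bad;
            size_t nk = seq.size() - k + 1;
            for (size_t p = 0; p < nk; ++p) {
                if (codes[p + k - 1] < 0) ++bad;
                if (bad == 0) {
                    uint64_t h = canonHash(codes, p, k, nullptr);
                    if (g == 0) {
                        bloomSet(cur, bfsize, h, numHashes);
                        ++nValid;
                    } else {
                        ++nValid;
                        if (bloomGet(prev.data(), bfsize, h, numHashes))
                            bloomSet(cur, bfsize, h, numHashes);
                    }
                }
                if (codes[p] < 0) --bad;
            }
        }
        validCounts[g] = (int)std::min<long long>(nValid, INT_MAX);
        prev.swap(cur);
        cur.clear(); cur.shrink_to_fit();
    }

    RawVector out(nbytes);
    std::copy(prev.begin(), prev.end(), out.begin());
    return List::create(_["bits"] = out, _["valid_kmers"] = validCounts);
}

// Membership queries for explicit k-mer strings (canonical form). Non-ACGT
// or wrong-length queries return FALSE (length is validated in R).
// [[Rcpp::export]]
LogicalVector cpp_bloom_contains(RawVector bits, double bfsizeD,
                                 CharacterVector kmers, int k,
                                 int numHashes) {
    uint64_t bfsize = (uint64_t)bfsizeD;
    LogicalVector out(kmers.size());
    const uint8_t* p = (const uint8_t*)RAW(bits);
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        std::string s = as<std::string>(kmers[i]);
        if ((int)s.size() != k) { out[i] = false; continue; }
        std::vector<int8_t> codes = encode(s);
        bool ok = true;
        for (int j = 0; j < k; ++j) if (codes[j] < 0) { ok = false; break; }
        if (!ok) { out[i] = false; continue; }
        uint64_t h = canonHash(codes, 0, k, nullptr);
        out[i] = bloomGet(p, bfsize, h, numHashes);
    }
    return out;
}

// Canonical (strand-invariant) hash of each k-mer string, as 16-char hex.
// Non-ACGT input yields NA.
// [[Rcpp::export]]
CharacterVector cpp_canonical_hash_hex(CharacterVector kmers) {
    CharacterVector out(kmers.size());
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        std::string s = as<std::string>(kmers[i]);
        if (s.size() < 1) { out[i] = NA_STRING; continue; }
        std::vector<int8_t> codes = encode(s);
        bool ok = true;
        for (size_t j = 0; j < s.size(); ++j)
            if (codes[j] < 0) { ok = false; break; }
        if (!ok) { out[i] = NA_STRING; continue; }
        out[i] = toHex(canonHash(codes, 0, (int)s.size(), nullptr));
    }
    return out;
}

// splitmix64 finalizer applied to hex-encoded 64-bit values (the second,
// reporting hash of the sketch).
// [[Rcpp::export]]
CharacterVector cpp_mix_hash_hex(CharacterVector hex) {
    CharacterVector out(hex.size());
    for (R_xlen_t i = 0; i < hex.size(); ++i) {
        if (hex[i] == NA_STRING) { out[i] = NA_STRING; continue; }
        out[i] = toHex(splitmix64(fromHex(as<std::string>(hex[i]))));
    }
    return out;
}

// Windowed minimizer selection over one sequence. A window is w consecutive
// k-mer start positions; among eligible k-mers (ACGT-only and, when a filter
// is supplied, present in it) the one with the smallest canonical hash wins,
// leftmost on ties. Consecutive windows sharing a selected occurrence emit
// one entry. Sequences with fewer than w k-mers form a single window.
// Reported hash = splitmix64(canonical hash), hex-encoded.
// [[Rcpp::export]]
DataFrame cpp_minimizers(std::string seq, int k, int w, RawVector bits,
                         double bfsizeD, int numHashes, bool useFilter) {
    std::vector<int> outPos;
    std::vector<std::string> outStrand, outHash;

    long long nk = (long long)seq.size() - k + 1;
    if (nk >= 1 && w >= 1) {
        uint64_t bfsize = (uint64_t)bfsizeD;
        const uint8_t* fb = useFilter ? (const uint8_t*)RAW(bits) : nullptr;
        std::vector<int8_t> codes = encode(seq);
        int effW = (int)std::min<long long>((long long)w, nk);

        struct Cand { long long pos; uint64_t h; bool plus; };
        std::deque<Cand> dq;
        long long lastEmitted = -1;
        int bad = 0;
        for (int i = 0; i < k - 1; ++i) if (codes[i] < 0) ++bad;

        for (long long p = 0; p < nk; ++p) {
            if (codes[p + k - 1] < 0) ++bad;
            if (bad == 0) {
                bool plus;
                uint64_t h = canonHash(codes, (size_t)p, k, &plus);
                bool eligible = true;
                if (useFilter && !bloomGet(fb, bfsize, h, numHashes))
                    eligible = false;
                if (eligible) {
                    while (!dq.empty() && dq.back().h > h) dq.pop_back();
                    dq.push_back({p, h, plus});
                }
            }
            if (codes[p] < 0) --bad;
            // window ending at p is [p - effW + 1, p]
            if (p >= effW - 1) {
                while (!dq.empty() && dq.front().pos < p - effW + 1)
                    dq.pop_front();
                if (!dq.empty() && dq.front().pos != lastEmitted) {
                    const Cand& c = dq.front();
                    outPos.push_back((int)c.pos);
                    outStrand.push_back(c.plus ? "+" : "-");
                    outHash.push_back(toHex(splitmix64(c.h)));
                    lastEmitted = c.pos;
                }
            }
        }
    }

    return DataFrame::create(_["pos"] = outPos,
                             _["strand"] = outStrand,
                             _["hash"] = outHash,
                             _["stringsAsFactors"] = false);
}
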
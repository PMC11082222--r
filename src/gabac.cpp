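// Core codec: symbol-level sequence transforms (equality / match / run-length),
// subsymbol splitting, context-conditioned LUT transform, binarizations
// (binary / truncated unary / exponential Golomb) and an adaptive binary
// range coder with coding orders 0-2. All functions are deterministic and
// exact inverses of each other; the R layer owns configuration and framing.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <map>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

// ------------------------------------------------------------------
// adaptive binary range coder (carry-less, LZMA-style renormalization)
// ------------------------------------------------------------------

static const int PROB_BITS = 11;                     // probability precision
static const uint16_t PROB_INIT = 1 << (PROB_BITS - 1); // P(0) = 0.5
static const int ADAPT_SHIFT = 5;                    // adaptation rate
static const uint32_t TOP = 1u << 24;
static const int NCTX = 1 << 16;                     // bounded context table

struct RangeEncoder {
    uint64_t low;
    uint32_t range;
    uint8_t cache;
    uint64_t cacheSize;
    std::vector<uint8_t> out;
    RangeEncoder() : low(0), range(0xFFFFFFFFu), cache(0), cacheSize(1) {}
    void shiftLow() {
        if ((uint32_t)low < 0xFF000000u || (low >> 32) != 0) {
            uint8_t carry = (uint8_t)(low >> 32);
            uint8_t temp = cache;
            do {
                out.push_back((uint8_t)(temp + carry));
                temp = 0xFF;
            } while (--cacheSize != 0);
            cache = (uint8_t)(low >> 24);
        }
        ++cacheSize;
        low = (low << 8) & 0xFFFFFFFFu;
    }
    void encodeBit(uint16_t &prob, int bit) {
        uint32_t bound = (range >> PROB_BITS) * prob;
        if (bit == 0) {
            range = bound;
            prob += ((1 << PROB_BITS) - prob) >> ADAPT_SHIFT;
        } else {
            low += bound;
            range -= bound;
            prob -= prob >> ADAPT_SHIFT;
        }
        if (range < TOP) { range <<= 8; shiftLow(); }
    }
    void flush() { for (int i = 0; i < 5; ++i) shiftLow(); }
};

struct RangeDecoder {
    const uint8_t *in;
    size_t len, pos;
    uint32_t range, code;
    bool overrun;
    RangeDecoder(const uint8_t *p, size_t l)
        : in(p), len(l), pos(0), range(0xFFFFFFFFu), code(0), overrun(false) {
        nextByte(); // skip the encoder's leading cache byte
        for (int i = 0; i < 4; ++i) code = (code << 8) | nextByte();
    }
    uint8_t nextByte() {
        if (pos < len) return in[pos++];
        overrun = true;
        return 0;
    }
    int decodeBit(uint16_t &prob) {
        uint32_t bound = (range >> PROB_BITS) * prob;
        int bit;
        if (code < bound) {
            bit = 0;
            range = bound;
            prob += ((1 << PROB_BITS) - prob) >> ADAPT_SHIFT;
        } else {
            bit = 1;
            code -= bound;
            range -= bound;
            prob -= prob >> ADAPT_SHIFT;
        }
        if (range < TOP) { range <<= 8; code = (code << 8) | nextByte(); }
        return bit;
    }
};

// context id: previous 1-2 (sub)symbol values (masked to 8 bits) combined
// with the bin's position inside its binarized word, multiplicatively hashed
// into a bounded table. Collisions merge probability states; harmless for
// correctness, documented as non-conformant with any standardized scheme.
static inline uint16_t ctxHash(int order, uint32_t p1, uint32_t p2, int binIdx) {
    uint32_t key = (uint32_t)(binIdx > 63 ? 63 : binIdx);
    if (order >= 1) key |= (p1 & 0xFFu) << 6;
    if (order >= 2) key |= (p2 & 0xFFu) << 14;
    key *= 2654435761u;
    return (uint16_t)(key >> 16);
}

static inline int bitsFor(uint32_t v) {
    int n = 0;
    while (v) { ++n; v >>= 1; }
    return n == 0 ? 1 : n;
}

// ------------------------------------------------------------------
// sequence transforms
// ------------------------------------------------------------------

// [[Rcpp::export(name = ".eq_encode")]]
List eq_encode_cpp(IntegerVector seq) {
    std::vector<int> flags, res;
    flags.reserve(seq.size());
    long prev = 0; // value preceding the first symbol is defined as 0
    for (R_xlen_t i = 0; i < seq.size(); ++i) {
        long s = seq[i];
        if (s == prev) {
            flags.push_back(1);
        } else {
            flags.push_back(0);
            res.push_back((int)(s < prev ? s : s - 1));
            prev = s;
        }
    }
    return List::create(_["flags"] = wrap(flags), _["residuals"] = wrap(res));
}

// [[Rcpp::export(name = ".eq_decode")]]
IntegerVector eq_decode_cpp(IntegerVector flags, IntegerVector residuals) {
    int nz = 0;
    for (R_xlen_t i = 0; i < flags.size(); ++i) if (flags[i] == 0) ++nz;
    if (nz != residuals.size())
        stop("equality decode: residual count (%d) does not match zero-flag count (%d)",
             (int)residuals.size(), nz);
    IntegerVector out(flags.size());
    long prev = 0;
    int j = 0;
    for (R_xlen_t i = 0; i < flags.size(); ++i) {
        if (flags[i] == 1) {
            out[i] = (int)prev;
        } else {
            long r = residuals[j++];
            long s = (r < prev) ? r : r + 1;
            out[i] = (int)s;
            prev = s;
        }
    }
    return out;
}

// [[Rcpp::export(name = ".match_encode")]]
List match_encode_cpp(IntegerVector seq, int B) {
    if (B <= 1) stop("match buffer size B must be > 1");
    std::vector<int> ptrs, lens, lits;
    int n = (int)seq.size();
    int i = 0;
    while (i < n) {
        int lo = std::max(0, i - B);
        int maxL = std::min(B, n - i);
        int bestLen = 0, bestJ = -1;
        for (int j = lo; j < i; ++j) {
            int cap = std::min(maxL, i - j); // match source must stay in buffer
            if (cap <= bestLen || cap < 2) break; // cap is non-increasing in j
            if (seq[j] != seq[i]) continue;
            int l = 1;
            while (l < cap && seq[j + l] == seq[i + l]) ++l;
            if (l >= 2 && l > bestLen) { // earliest start wins on ties
                bestLen = l;
                bestJ = j;
                if (bestLen == maxL) break;
            }
        }
        if (bestLen >= 2) {
            ptrs.push_back(bestJ - lo);
            lens.push_back(bestLen);
            i += bestLen;
        } else {
            lens.push_back(0);
            lits.push_back(seq[i]);
            ++i;
        }
    }
    return List::create(_["pointers"] = wrap(ptrs), _["lengths"] = wrap(lens),
                        _["literals"] = wrap(lits));
}

// [[Rcpp::export(name = ".match_decode")]]
IntegerVector match_decode_cpp(IntegerVector pointers, IntegerVector lengths,
                               IntegerVector literals, int B) {
    if (B <= 1) stop("match buffer size B must be > 1");
    std::vector<int> out;
    int pi = 0, li = 0;
    for (R_xlen_t k = 0; k < lengths.size(); ++k) {
        int l = lengths[k];
        if (l == 0) {
            if (li >= literals.size()) stop("match decode: literal stream exhausted");
            out.push_back(literals[li++]);
        } else {
            if (pi >= pointers.size()) stop("match decode: pointer stream exhausted");
            int ptr = pointers[pi++];
            int lo = std::max(0, (int)out.size() - B);
            int W = (int)out.size() - lo;
            if (ptr < 0 || ptr + l > W)
                stop("match decode: pointer %d + length %d exceeds buffer of %d", ptr, l, W);
            int src = lo + ptr;
            for (int t = 0; t < l; ++t) out.push_back(out[src + t]);
        }
    }
    return wrap(out);
}

// [[Rcpp::export(name = ".rle_encode")]]
List rle_encode_cpp(IntegerVector seq, int G) {
    if (G < 1) stop("run-length guard G must be >= 1");
    std::vector<int> lens, syms;
    int n = (int)seq.size();
    int i = 0;
    while (i < n) {
        int j = i;
        while (j < n && seq[j] == seq[i]) ++j;
        long L = j - i;
        long nj = (L - 1) / G;       // L = nj*G + r with 0 < r <= G
        long r = L - nj * G;
        for (long t = 0; t < nj; ++t) lens.push_back(G);
        lens.push_back((int)(r - 1));
        syms.push_back(seq[i]);
        i = j;
    }
    return List::create(_["lengths"] = wrap(lens), _["symbols"] = wrap(syms));
}

// [[Rcpp::export(name = ".rle_decode")]]
IntegerVector rle_decode_cpp(IntegerVector lengths, IntegerVector symbols, int G) {
    if (G < 1) stop("run-length guard G must be >= 1");
    std::vector<int> out;
    R_xlen_t k = 0;
    for (R_xlen_t s = 0; s < symbols.size(); ++s) {
        long n = 0;
        while (k < lengths.size() && lengths[k] == G) { ++n; ++k; }
        if (k >= lengths.size())
            stop("run-length decode: dangling guard run at stream end");
        long v = lengths[k++];
        if (v > G) stop("run-length decode: length symbol %ld exceeds guard %d", v, G);
        long L = n * G + v + 1;
        for (long t = 0; t < L; ++t) out.push_back(symbols[s]);
    }
    if (k != lengths.size())
        stop("run-length decode: %d unconsumed length symbols", (int)(lengths.size() - k));
    return wrap(out);
}

// ------------------------------------------------------------------
// subsymbol splitting (big-endian: most significant subsymbol first)
// ------------------------------------------------------------------

static void splitInto(const int *symbols, int n, int symbolBits, int factor,
                      std::vector<uint32_t> &subs) {
    int subBits = symbolBits / factor;
    uint32_t mask = (subBits >= 32) ? 0xFFFFFFFFu : ((1u << subBits) - 1u);
    subs.resize((size_t)n * factor);
    size_t k = 0;
    for (int i = 0; i < n; ++i) {
        uint32_t v = (uint32_t)symbols[i];
        for (int f = factor - 1; f >= 0; --f)
            subs[k++] = (uint32_t)((v >> (f * subBits)) & mask);
    }
}

// [[Rcpp::export(name = ".split_subsymbols")]]
IntegerVector split_subsymbols_cpp(IntegerVector symbols, int symbolBits, int factor) {
    if (factor < 1 || symbolBits % factor != 0)
        stop("subsymbol width must divide the symbol width (%d bits / factor %d)",
             symbolBits, factor);
    std::vector<uint32_t> subs;
    splitInto(INTEGER(symbols), (int)symbols.size(), symbolBits, factor, subs);
    IntegerVector out(subs.size());
    for (size_t i = 0; i < subs.size(); ++i) out[i] = (int)subs[i];
    return out;
}

// [[Rcpp::export(name = ".merge_subsymbols")]]
IntegerVector merge_subsymbols_cpp(IntegerVector subs, int symbolBits, int factor) {
    if (factor < 1 || symbolBits % factor != 0)
        stop("subsymbol width must divide the symbol width");
    if (subs.size() % factor != 0)
        stop("subsymbol count is not a multiple of the split factor");
    int subBits = symbolBits / factor;
    R_xlen_t n = subs.size() / factor;
    IntegerVector out(n);
    R_xlen_t k = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        uint32_t v = 0;
        for (int f = 0; f < factor; ++f)
            v = (subBits >= 32) ? (uint32_t)subs[k++]
                                : ((v << subBits) | (uint32_t)subs[k++]);
        out[i] = (int)v;
    }
    return out;
}

// ------------------------------------------------------------------
// LUT transform: frequency-ranked substitution conditioned on the
// previous 1 (order 1) or 2 (order 2) subsymbols; missing predecessors
// at the sequence start take value 0. Ties rank the smaller value first.
// ------------------------------------------------------------------

static inline uint32_t lutCtxKey(int order, uint32_t p1, uint32_t p2) {
    uint32_t key = p1 & 0xFFu;
    if (order >= 2) key |= (p2 & 0xFFu) << 8;
    return key;
}

struct LutModel {
    // ctx key -> ranked subsymbol values (index 0 = most frequent)
    std::map<uint32_t, std::vector<uint8_t> > ranked;
};

static void lutBuild(const std::vector<uint32_t> &subs, int order, int alphabet,
                     LutModel &model) {
    std::unordered_map<uint32_t, std::vector<uint32_t> > counts;
    uint32_t p1 = 0, p2 = 0;
    for (size_t i = 0; i < subs.size(); ++i) {
        uint32_t key = lutCtxKey(order, p1, p2);
        std::vector<uint32_t> &c = counts[key];
        if (c.empty()) c.assign(alphabet, 0u);
        ++c[subs[i]];
        p2 = p1;
        p1 = subs[i];
    }
    for (std::unordered_map<uint32_t, std::vector<uint32_t> >::iterator it = counts.begin();
         it != counts.end(); ++it) {
        std::vector<std::pair<int64_t, int> > order_vec;
        for (int v = 0; v < alphabet; ++v)
            if (it->second[v] > 0)
                order_vec.push_back(std::make_pair(-(int64_t)it->second[v], v));
        std::sort(order_vec.begin(), order_vec.end());
        std::vector<uint8_t> r(order_vec.size());
        for (size_t k = 0; k < order_vec.size(); ++k) r[k] = (uint8_t)order_vec[k].second;
        model.ranked[it->first] = r;
    }
}

static void lutForwardApply(const std::vector<uint32_t> &subs, int order,
                            const LutModel &model, std::vector<uint32_t> &idx) {
    // value -> rank lookup per context
    std::unordered_map<uint32_t, std::vector<uint16_t> > inv;
    for (std::map<uint32_t, std::vector<uint8_t> >::const_iterator it = model.ranked.begin();
         it != model.ranked.end(); ++it) {
        std::vector<uint16_t> m(256, 0xFFFF);
        for (size_t k = 0; k < it->second.size(); ++k) m[it->second[k]] = (uint16_t)k;
        inv[it->first] = m;
    }
    idx.resize(subs.size());
    uint32_t p1 = 0, p2 = 0;
    for (size_t i = 0; i < subs.size(); ++i) {
        uint32_t key = lutCtxKey(order, p1, p2);
        idx[i] = inv[key][subs[i]];
        p2 = p1;
        p1 = subs[i];
    }
}

static void lutSerialize(const LutModel &model, std::vector<uint8_t> &out) {
    uint32_t nctx = (uint32_t)model.ranked.size();
    out.push_back((uint8_t)(nctx & 0xFF));
    out.push_back((uint8_t)((nctx >> 8) & 0xFF));
    out.push_back((uint8_t)((nctx >> 16) & 0xFF));
    out.push_back((uint8_t)((nctx >> 24) & 0xFF));
    for (std::map<uint32_t, std::vector<uint8_t> >::const_iterator it = model.ranked.begin();
         it != model.ranked.end(); ++it) {
        out.push_back((uint8_t)(it->first & 0xFF));
        out.push_back((uint8_t)((it->first >> 8) & 0xFF));
        uint16_t sz = (uint16_t)it->second.size();
        out.push_back((uint8_t)(sz & 0xFF));
        out.push_back((uint8_t)((sz >> 8) & 0xFF));
        for (size_t k = 0; k < it->second.size(); ++k) out.push_back(it->second[k]);
    }
}

static size_t lutDeserialize(const uint8_t *buf, size_t len, LutModel &model) {
    if (len < 4) stop("LUT tables truncated");
    size_t p = 0;
    uint32_t nctx = (uint32_t)buf[0] | ((uint32_t)buf[1] << 8) |
                    ((uint32_t)buf[2] << 16) | ((uint32_t)buf[3] << 24);
    p = 4;
    for (uint32_t c = 0; c < nctx; ++c) {
        if (p + 4 > len) stop("LUT tables truncated");
        uint32_t key = (uint32_t)buf[p] | ((uint32_t)buf[p + 1] << 8);
        uint16_t sz = (uint16_t)buf[p + 2] | ((uint16_t)buf[p + 3] << 8);
        p += 4;
        if (p + sz > len) stop("LUT tables truncated");
        std::vector<uint8_t> r(buf + p, buf + p + sz);
        p += sz;
        model.ranked[key] = r;
    }
    return p;
}

// [[Rcpp::export(name = ".lut_forward")]]
List lut_forward_cpp(IntegerVector subs, int order, int subBits) {
    if (order < 1 || order > 2) stop("LUT order must be 1 or 2");
    if (subBits > 8) stop("LUT transform supports subsymbols of at most 8 bits");
    int alphabet = 1 << subBits;
    std::vector<uint32_t> s(subs.size());
    for (R_xlen_t i = 0; i < subs.size(); ++i) {
        if (subs[i] < 0 || subs[i] >= alphabet) stop("subsymbol outside alphabet");
        s[i] = (uint32_t)subs[i];
    }
    LutModel model;
    lutBuild(s, order, alphabet, model);
    std::vector<uint32_t> idx;
    lutForwardApply(s, order, model, idx);
    List tables;
    IntegerVector keys((int)model.ranked.size());
    List ranked((int)model.ranked.size());
    int k = 0;
    for (std::map<uint32_t, std::vector<uint8_t> >::const_iterator it = model.ranked.begin();
         it != model.ranked.end(); ++it, ++k) {
        keys[k] = (int)it->first;
        IntegerVector rv((int)it->second.size());
        for (size_t j = 0; j < it->second.size(); ++j) rv[j] = it->second[j];
        ranked[k] = rv;
    }
    IntegerVector out(idx.size());
    for (size_t i = 0; i < idx.size(); ++i) out[i] = (int)idx[i];
    return List::create(_["contextKeys"] = keys, _["ranked"] = ranked,
                        _["indices"] = out);
}

// [[Rcpp::export(name = ".lut_inverse")]]
IntegerVector lut_inverse_cpp(IntegerVector contextKeys, List ranked,
                              IntegerVector indices, int order) {
    if (order < 1 || order > 2) stop("LUT order must be 1 or 2");
    LutModel model;
    for (R_xlen_t k = 0; k < contextKeys.size(); ++k) {
        IntegerVector rv = ranked[k];
        std::vector<uint8_t> r(rv.size());
        for (R_xlen_t j = 0; j < rv.size(); ++j) r[j] = (uint8_t)rv[j];
        model.ranked[(uint32_t)contextKeys[k]] = r;
    }
    IntegerVector out(indices.size());
    uint32_t p1 = 0, p2 = 0;
    for (R_xlen_t i = 0; i < indices.size(); ++i) {
        uint32_t key = lutCtxKey(order, p1, p2);
        std::map<uint32_t, std::vector<uint8_t> >::const_iterator it = model.ranked.find(key);
        if (it == model.ranked.end())
            stop("LUT inverse: unknown context %u at position %d", key, (int)i + 1);
        if (indices[i] < 0 || (size_t)indices[i] >= it->second.size())
            stop("LUT inverse: index %d outside table for its context", (int)indices[i]);
        uint32_t v = it->second[indices[i]];
        out[i] = (int)v;
        p2 = p1;
        p1 = v;
    }
    return out;
}

// ------------------------------------------------------------------
// binarizations + fused arithmetic coding of a subsymbol stream
// binarization codes: 0 = binary, 1 = truncated unary, 2 = exp-Golomb
// ------------------------------------------------------------------

static void encodeWord(RangeEncoder &rc, std::vector<uint16_t> &probs, int order,
                       uint32_t p1, uint32_t p2, uint32_t v, int binar,
                       int nbits, uint32_t tuMax) {
    int bi = 0;
    if (binar == 0) {
        for (int k = nbits - 1; k >= 0; --k)
            rc.encodeBit(probs[ctxHash(order, p1, p2, bi++)], (int)((v >> k) & 1u));
    } else if (binar == 1) {
        for (uint32_t k = 0; k < v; ++k)
            rc.encodeBit(probs[ctxHash(order, p1, p2, bi++)], 1);
        if (v < tuMax)
            rc.encodeBit(probs[ctxHash(order, p1, p2, bi)], 0);
    } else {
        uint32_t w = v + 1u;
        int N = bitsFor(w);
        for (int k = 0; k < N - 1; ++k)
            rc.encodeBit(probs[ctxHash(order, p1, p2, bi++)], 0);
        for (int k = N - 1; k >= 0; --k)
            rc.encodeBit(probs[ctxHash(order, p1, p2, bi++)], (int)((w >> k) & 1u));
    }
}

static uint32_t decodeWord(RangeDecoder &rc, std::vector<uint16_t> &probs, int order,
                           uint32_t p1, uint32_t p2, int binar, int nbits,
                           uint32_t tuMax) {
    int bi = 0;
    if (binar == 0) {
        uint32_t v = 0;
        for (int k = 0; k < nbits; ++k)
            v = (v << 1) | (uint32_t)rc.decodeBit(probs[ctxHash(order, p1, p2, bi++)]);
        return v;
    } else if (binar == 1) {
        uint32_t v = 0;
        while (v < tuMax) {
            if (rc.decodeBit(probs[ctxHash(order, p1, p2, bi++)]) == 0) break;
            ++v;
        }
        return v;
    } else {
        int Z = 0;
        while (rc.decodeBit(probs[ctxHash(order, p1, p2, bi++)]) == 0) {
            ++Z;
            if (Z > 40) stop("corrupt stream: exp-Golomb prefix too long");
        }
        uint32_t w = 1;
        for (int k = 0; k < Z; ++k)
            w = (w << 1) | (uint32_t)rc.decodeBit(probs[ctxHash(order, p1, p2, bi++)]);
        return w - 1u;
    }
}

static std::vector<uint8_t> compress_block_core(const int *symbols, int n,
                                                int symbolBits, int splitFactor,
                                                bool lut, int codingOrder,
                                                int binarization) {
    if (symbolBits < 1 || symbolBits > 32) stop("symbol width must be 1..32 bits");
    if (symbolBits % splitFactor != 0)
        stop("split factor %d does not divide symbol width %d", splitFactor, symbolBits);
    if (codingOrder < 0 || codingOrder > 2) stop("coding order must be 0..2");
    int subBits = symbolBits / splitFactor;
    if (lut && subBits > 8) stop("LUT transform requires subsymbols of at most 8 bits");
    if (n == 0) return std::vector<uint8_t>(); // empty stream: no payload

    std::vector<uint32_t> subs;
    splitInto(symbols, n, symbolBits, splitFactor, subs);

    std::vector<uint8_t> head;
    std::vector<uint32_t> vals;
    LutModel model;
    int lutOrder = codingOrder >= 2 ? 2 : 1;
    if (lut) {
        lutBuild(subs, lutOrder, 1 << subBits, model);
        lutForwardApply(subs, lutOrder, model, vals);
        lutSerialize(model, head);
    } else {
        vals.swap(subs);
    }

    uint32_t tuMax = 0;
    if (binarization == 1) {
        for (size_t i = 0; i < vals.size(); ++i) tuMax = std::max(tuMax, vals[i]);
        head.push_back((uint8_t)(tuMax & 0xFF));
        head.push_back((uint8_t)((tuMax >> 8) & 0xFF));
        head.push_back((uint8_t)((tuMax >> 16) & 0xFF));
        head.push_back((uint8_t)((tuMax >> 24) & 0xFF));
    }

    RangeEncoder rc;
    std::vector<uint16_t> probs(NCTX, PROB_INIT);
    uint32_t p1 = 0, p2 = 0;
    for (size_t i = 0; i < vals.size(); ++i) {
        encodeWord(rc, probs, codingOrder, p1, p2, vals[i], binarization, subBits, tuMax);
        p2 = p1;
        p1 = vals[i];
    }
    rc.flush();

    head.insert(head.end(), rc.out.begin(), rc.out.end());
    return head;
}

// Compressed block layout: [LUT tables, if lut] [u32 tuMax, if TU] [rc payload]
// [[Rcpp::export(name = ".gc_compress_block")]]
RawVector gc_compress_block(IntegerVector symbols, int symbolBits, int splitFactor,
                            bool lut, int codingOrder, int binarization) {
    std::vector<uint8_t> out = compress_block_core(INTEGER(symbols),
                                                   (int)symbols.size(),
                                                   symbolBits, splitFactor, lut,
                                                   codingOrder, binarization);
    return RawVector(out.begin(), out.end());
}

// Exhaustive-search helper: compressed byte count for each configuration
// (columns of equal-length vectors), avoiding per-configuration R overhead.
// [[Rcpp::export(name = ".gc_enumerate_sizes")]]
NumericVector gc_enumerate_sizes(IntegerVector symbols, int symbolBits,
                                 IntegerVector orders, IntegerVector splits,
                                 LogicalVector luts, IntegerVector binars) {
    R_xlen_t k = orders.size();
    if (splits.size() != k || luts.size() != k || binars.size() != k)
        stop("configuration vectors must have equal length");
    NumericVector out(k);
    for (R_xlen_t i = 0; i < k; ++i) {
        out[i] = (double)compress_block_core(INTEGER(symbols),
                                             (int)symbols.size(), symbolBits,
                                             splits[i], luts[i] == TRUE,
                                             orders[i], binars[i]).size();
    }
    return out;
}

// [[Rcpp::export(name = ".gc_decompress_block")]]
IntegerVector gc_decompress_block(RawVector block, int nSymbols, int symbolBits,
                                  int splitFactor, bool lut, int codingOrder,
                                  int binarization) {
    if (symbolBits % splitFactor != 0)
        stop("split factor does not divide symbol width");
    int subBits = symbolBits / splitFactor;
    if (nSymbols == 0) return IntegerVector(0);
    size_t nSubs = (size_t)nSymbols * splitFactor;
    const uint8_t *buf = (const uint8_t *)RAW(block);
    size_t len = block.size(), p = 0;

    LutModel model;
    int lutOrder = codingOrder >= 2 ? 2 : 1;
    if (lut) p = lutDeserialize(buf, len, model);

    uint32_t tuMax = 0;
    if (binarization == 1) {
        if (p + 4 > len) stop("corrupt stream: truncated header");
        tuMax = (uint32_t)buf[p] | ((uint32_t)buf[p + 1] << 8) |
                ((uint32_t)buf[p + 2] << 16) | ((uint32_t)buf[p + 3] << 24);
        p += 4;
    }

    RangeDecoder rc(buf + p, len - p);
    std::vector<uint16_t> probs(NCTX, PROB_INIT);
    std::vector<uint32_t> subs(nSubs);
    uint32_t p1 = 0, p2 = 0;     // previous decoded (post-LUT-domain) values
    uint32_t o1 = 0, o2 = 0;     // previous original subsymbols (LUT context)
    for (size_t i = 0; i < nSubs; ++i) {
        uint32_t v = decodeWord(rc, probs, codingOrder, p1, p2, binarization,
                                subBits, tuMax);
        p2 = p1;
        p1 = v;
        if (lut) {
            uint32_t key = lutCtxKey(lutOrder, o1, o2);
            std::map<uint32_t, std::vector<uint8_t> >::const_iterator it =
                model.ranked.find(key);
            if (it == model.ranked.end())
                stop("corrupt stream: unknown LUT context");
            if ((size_t)v >= it->second.size())
                stop("corrupt stream: LUT index outside table for its context");
            uint32_t orig = it->second[v];
            o2 = o1;
            o1 = orig;
            subs[i] = orig;
        } else {
            subs[i] = v;
        }
    }
    if (rc.overrun) stop("corrupt stream: premature end of compressed data");

    IntegerVector out(nSymbols);
    size_t k = 0;
    for (int i = 0; i < nSymbols; ++i) {
        uint32_t v = 0;
        for (int f = 0; f < splitFactor; ++f)
            v = (subBits >= 32) ? subs[k++] : ((v << subBits) | subs[k++]);
        out[i] = (int)v;
    }
    return out;
}

// ------------------------------------------------------------------
// direct bin-level coder access (for entropy sanity tests); contexts
// supplied explicitly by the caller.
// ------------------------------------------------------------------

// [[Rcpp::export(name = ".rc_encode_bits")]]
RawVector rc_encode_bits(IntegerVector bits, IntegerVector contexts) {
    if (bits.size() != contexts.size())
        stop("bits and contexts must have equal length");
    RangeEncoder rc;
    std::vector<uint16_t> probs(NCTX, PROB_INIT);
    for (R_xlen_t i = 0; i < bits.size(); ++i)
        rc.encodeBit(probs[(uint16_t)(contexts[i] & 0xFFFF)], bits[i] ? 1 : 0);
    rc.flush();
    return RawVector(rc.out.begin(), rc.out.end());
}

// [[Rcpp::export(name = ".rc_decode_bits")]]
IntegerVector rc_decode_bits(RawVector bytes, int n, IntegerVector contexts) {
    if (n != contexts.size()) stop("context id required per bit");
    RangeDecoder rc((const uint8_t *)RAW(bytes), bytes.size());
    std::vector<uint16_t> probs(NCTX, PROB_INIT);
    IntegerVector out(n);
    for (int i = 0; i < n; ++i)
        out[i] = rc.decodeBit(probs[(uint16_t)(contexts[i] & 0xFFFF)]);
    if (rc.overrun) stop("corrupt stream: premature end of compressed data");
    return out;
}

// ------------------------------------------------------------------
// CRC32 (IEEE) for per-access-unit payload integrity
// ------------------------------------------------------------------

// [[Rcpp::export(name = ".crc32")]]
double crc32_cpp(RawVector data) {
    static uint32_t table[256];
    static bool init = false;
    if (!init) {
        for (uint32_t i = 0; i < 256; ++i) {
            uint32_t c = i;
            for (int k = 0; k < 8; ++k)
                c = (c & 1) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
            table[i] = c;
        }
        init = true;
    }
    uint32_t crc = 0xFFFFFFFFu;
    for (R_xlen_t i = 0; i < data.size(); ++i)
        crc = table[(crc ^ RAW(data)[i]) & 0xFF] ^ (crc >> 8);
    crc ^= 0xFFFFFFFFu;
    return (double)crc;
}
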
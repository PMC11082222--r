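# Binarizations and the entropy-coding stage. The reference R
# implementations of the binarizations are exported for inspection and
# testing; the compression hot path fuses binarization and arithmetic
# coding in C++ (.gc_compress_block / .gc_decompress_block).

#' Binarize an integer value into a prefix-free bit pattern
#'
#' Three binarizations are supported. `BINARY`: the value as an `nBits`-bit
#' big-endian binary number. `TRUNCATED_UNARY`: `S` one-bits followed by a
#' zero bit, with the trailing zero truncated when `S` equals `maxValue`.
#' `EXP_GOLOMB`: with `N` the number of bits of `S + 1`, `N - 1` zero bits
#' followed by the `N`-bit binary representation of `S + 1` (the standard
#' prefix-decodable exponential Golomb construction).
#'
#' @param value non-negative integer
#' @param kind one of `"BINARY"`, `"TRUNCATED_UNARY"`, `"EXP_GOLOMB"`
#' @param nBits word width (BINARY only)
#' @param maxValue largest representable value (TRUNCATED_UNARY only)
#' @return integer vector of bits
#' @export
binarize <- function(value, kind = BINARIZATIONS, nBits = NULL,
                     maxValue = NULL) {
    kind <- match.arg(kind)
    value <- as.integer(value)
    if (value < 0L) stop("binarization requires non-negative values")
    switch(kind,
        BINARY = {
            stopifnot(!is.null(nBits))
            if (nBits < 31L && value >= bitwShiftL(1L, nBits))
                stop(sprintf("value %d does not fit in %d bits", value, nBits))
            as.integer(bitwAnd(bitwShiftR(value, (nBits - 1L):0L), 1L))
        },
        TRUNCATED_UNARY = {
            stopifnot(!is.null(maxValue))
            if (value > maxValue)
                stop(sprintf("value %d exceeds truncated-unary maximum %d",
                             value, maxValue))
            c(rep.int(1L, value), if (value < maxValue) 0L)
        },
        EXP_GOLOMB = {
            w <- value + 1L
            N <- floor(log2(w)) + 1L
            c(rep.int(0L, N - 1L),
              as.integer(bitwAnd(bitwShiftR(w, (N - 1L):0L), 1L)))
        })
}

#' @rdname binarize
#' @param bits integer bit vector positioned at the start of one word
#' @return `list(value=, consumed=)` - the decoded value and the number of
#'   bits consumed
#' @export
debinarize <- function(bits, kind = BINARIZATIONS, nBits = NULL,
                       maxValue = NULL) {
    kind <- match.arg(kind)
    switch(kind,
        BINARY = {
            stopifnot(!is.null(nBits), length(bits) >= nBits)
            v <- 0L
            for (k in seq_len(nBits)) v <- bitwOr(bitwShiftL(v, 1L), bits[k])
            list(value = v, consumed = nBits)
        },
        TRUNCATED_UNARY = {
            stopifnot(!is.null(maxValue))
            v <- 0L
            k <- 1L
            while (v < maxValue) {
                if (k > length(bits)) stop("truncated-unary word truncated")
                if (bits[k] == 0L) break
                v <- v + 1L
                k <- k + 1L
            }
            list(value = v, consumed = if (v < maxValue) v + 1L else v)
        },
        EXP_GOLOMB = {
            Z <- 0L
            k <- 1L
            while (k <= length(bits) && bits[k] == 0L) { Z <- Z + 1L; k <- k + 1L }
            if (k + Z - 1L >= length(bits) + 1L && Z > 0L && k > length(bits))
                stop("exp-Golomb word truncated")
            w <- 1L
            for (j in seq_len(Z)) {
                if (k + j > length(bits)) stop("exp-Golomb word truncated")
                w <- bitwOr(bitwShiftL(w, 1L), bits[k + j])
            }
            list(value = w - 1L, consumed = 2L * Z + 1L)
        })
}

#' Context-adaptive binary arithmetic coding of a bin sequence
#'
#' Encodes a sequence of bins, each with a caller-supplied context id, with
#' an adaptive binary range coder (11-bit probability states initialized to
#' 0.5, one state per context id modulo 2^16). Decoding mirrors the state
#' evolution bin for bin; identical input always yields byte-identical
#' output.
#'
#' @param bits integer vector of 0/1 bins
#' @param contexts integer context id per bin (reduced modulo 2^16)
#' @return raw vector (compressed stream, byte-aligned flush included)
#' @export
cabacEncode <- function(bits, contexts = integer(length(bits)))
    .rc_encode_bits(as.integer(bits), as.integer(contexts))

#' @rdname cabacEncode
#' @param bytes raw vector from [cabacEncode()]
#' @param n number of bins to decode
#' @export
cabacDecode <- function(bytes, n, contexts = integer(n))
    .rc_decode_bits(bytes, as.integer(n), as.integer(contexts))

# ---- entropy configuration space --------------------------------------

# Fixed per-transformed-stream container overhead (symbol count + byte
# length), used consistently by the optimizer's size accounting.
STREAM_OVERHEAD_BYTES <- 8L

#' Enumerate valid entropy configurations for a transformed subsequence
#'
#' The cross product of coding order (0,1,2), subsymbol split factor
#' (1,2,4,8), subsymbol transform (none / LUT) and binarization (binary,
#' truncated unary, exponential Golomb), minus combinations invalid for the
#' stream: split factors not dividing the width, LUT on subsymbols wider
#' than 8 bits, and truncated unary when the observed (sub)symbol maximum
#' exceeds 255. Enumeration order is fixed and documented; ties elsewhere
#' are broken by this order.
#'
#' @param bits symbol width of the transformed subsequence
#' @param maxSubsymbol largest subsymbol value observed per split factor,
#'   as returned by [maxSubsymbols()]; used to gate truncated unary
#' @return data.frame with columns order, split, lut, binarization
#' @export
.CONFIG_GRID <- expand.grid(order = 0:2, split = c(1L, 2L, 4L, 8L),
                            lut = c(FALSE, TRUE),
                            binarization = c("BINARY", "TRUNCATED_UNARY",
                                             "EXP_GOLOMB"),
                            stringsAsFactors = FALSE)

validEntropyConfigs <- function(bits, maxSubsymbol = NULL) {
    g <- .CONFIG_GRID
    keep <- bits %% g$split == 0L
    keep <- keep & (!g$lut | bits %/% g$split <= 8L)
    if (!is.null(maxSubsymbol)) {
        tu <- g$binarization == "TRUNCATED_UNARY"
        mx <- maxSubsymbol[match(g$split, as.integer(names(maxSubsymbol)))]
        keep <- keep & (!tu | (keep & !is.na(mx) & mx <= 255L))
    }
    g[keep, , drop = FALSE]
}

#' Largest subsymbol value per split factor
#'
#' @param symbols integer symbol vector
#' @param bits symbol width
#' @return named integer vector, names `"1","2","4","8"`, `NA` for factors
#'   that do not divide `bits`
#' @export
maxSubsymbols <- function(symbols, bits) {
    out <- c(`1` = NA_integer_, `2` = NA_integer_, `4` = NA_integer_,
             `8` = NA_integer_)
    for (f in c(1L, 2L, 4L, 8L)) {
        if (bits %% f != 0L) next
        out[as.character(f)] <- if (!length(symbols)) 0L
            else max(.split_subsymbols(symbols, bits, f))
    }
    out
}

defaultEntropyConfig <- function()
    list(order = 1L, split = 1L, lut = FALSE, binarization = "EXP_GOLOMB")

defaultStreamConfig <- function(transform = "NONE")
    list(transform = transform, B = 255L, G = 255L,
         streams = rep(list(defaultEntropyConfig()),
                       nTransformedStreams(transform)))

.binCode <- function(kind) match(kind, BINARIZATIONS) - 1L

compressTransformedStream <- function(symbols, bits, cfg) {
    .gc_compress_block(as.integer(symbols), as.integer(bits),
                       as.integer(cfg$split), isTRUE(cfg$lut),
                       as.integer(cfg$order), .binCode(cfg$binarization))
}

decompressTransformedStream <- function(block, n, bits, cfg) {
    .gc_decompress_block(block, as.integer(n), as.integer(bits),
                         as.integer(cfg$split), isTRUE(cfg$lut),
                         as.integer(cfg$order), .binCode(cfg$binarization))
}

#' Compress one descriptor subsequence under a full stream configuration
#'
#' Applies the configured sequence transform, then compresses each
#' transformed subsequence with its entropy configuration (subsymbol split,
#' optional LUT, binarization, CABAC coding order).
#'
#' @param symbols integer symbol vector
#' @param bits symbol width
#' @param cfg `list(transform=, B=, G=, streams=)` as stored in a
#'   [ParameterSet-class]
#' @return `list(origN=, trStreams=)`; each transformed stream carries its
#'   symbol count and compressed bytes
#' @export
compressStream <- function(symbols, bits, cfg) {
    tr <- applySequenceTransform(symbols, bits, cfg$transform, cfg$B, cfg$G)
    trStreams <- vector("list", length(tr))
    for (i in seq_along(tr)) {
        trStreams[[i]] <- list(
            n = length(tr[[i]]$symbols),
            data = compressTransformedStream(tr[[i]]$symbols, tr[[i]]$bits,
                                             cfg$streams[[i]]))
    }
    list(origN = length(symbols), trStreams = trStreams)
}

#' @rdname compressStream
#' @param block the list returned by [compressStream()]
#' @export
decompressStream <- function(block, bits, cfg) {
    layoutBits <- switch(cfg$transform,
        NONE = bits, EQUALITY = c(1L, bits), MATCH = c(8L, 8L, bits),
        RLE = c(8L, bits))
    if (length(block$trStreams) != length(layoutBits))
        stop("corrupt stream: transformed-subsequence count mismatch")
    streams <- vector("list", length(layoutBits))
    for (i in seq_along(layoutBits)) {
        streams[[i]] <- decompressTransformedStream(
            block$trStreams[[i]]$data, block$trStreams[[i]]$n, layoutBits[i],
            cfg$streams[[i]])
    }
    invertSequenceTransform(streams, cfg$transform, block$origN, cfg$B, cfg$G)
}
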
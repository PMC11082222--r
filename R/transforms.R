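# Symbol-level sequence transforms and subsymbol-level transforms.
# All heavy lifting happens in C++ (src/gabac.cpp); these wrappers define
# the public API and the stream layout each transform demultiplexes into.

#' Equality transform
#'
#' Demultiplexes a symbol stream into a binary flag stream and a residual
#' stream. Flag `F_i = 1` means `S_i = S_{i-1}` (the symbol before the
#' first is defined as 0); for `F_i = 0` a residual is emitted: `S_i` if
#' `S_i < S_{i-1}`, else `S_i - 1`.
#'
#' @param seq integer symbol vector
#' @return `list(flags=, residuals=)`
#' @export
equalityEncode <- function(seq) .eq_encode(as.integer(seq))

#' @rdname equalityEncode
#' @param flags binary flag stream
#' @param residuals residual stream (one entry per zero flag)
#' @export
equalityDecode <- function(flags, residuals)
    .eq_decode(as.integer(flags), as.integer(residuals))

#' Match transform (windowed LZ-style)
#'
#' Keeps a buffer of the last `B` raw symbols. At each step the longest
#' match of length `l` with `1 < l <= B` between the upcoming symbols and a
#' substring fully inside the buffer is sought (greedy; the smallest buffer
#' start index wins ties). A match emits its buffer start index to the
#' pointer stream and `l` to the length stream; otherwise 0 goes to the
#' length stream and the symbol to the literal stream.
#'
#' @param seq integer symbol vector
#' @param B buffer size (> 1); default 255 keeps pointer and length
#'   streams within 8 bits
#' @return `list(pointers=, lengths=, literals=)`
#' @export
matchEncode <- function(seq, B = 255L) .match_encode(as.integer(seq), as.integer(B))

#' @rdname matchEncode
#' @param pointers,lengths,literals the three transformed streams
#' @export
matchDecode <- function(pointers, lengths, literals, B = 255L)
    .match_decode(as.integer(pointers), as.integer(lengths),
                  as.integer(literals), as.integer(B))

#' Run-length transform
#'
#' Partitions the stream into maximal runs `(L_j, S_j)`. Each length is
#' decomposed as `L_j = n_j * G + r_j` with `0 < r_j <= G`; the length
#' stream receives `n_j` guard symbols of value `G` followed by one symbol
#' `r_j - 1`, and the symbol stream receives `S_j`.
#'
#' @param seq integer symbol vector
#' @param G guard value (>= 1); default 255 keeps the length stream within
#'   8 bits
#' @return `list(lengths=, symbols=)`
#' @export
rleEncode <- function(seq, G = 255L) .rle_encode(as.integer(seq), as.integer(G))

#' @rdname rleEncode
#' @param lengths,symbols the two transformed streams
#' @export
rleDecode <- function(lengths, symbols, G = 255L)
    .rle_decode(as.integer(lengths), as.integer(symbols), as.integer(G))

#' Subsymbol splitting
#'
#' Splits each symbol into `splitFactor` equal-width subsymbols, most
#' significant first. The subsymbol width must divide the symbol width.
#'
#' @param symbols integer symbol vector
#' @param symbolBits symbol width in bits
#' @param splitFactor 1, 2, 4 or 8
#' @return integer subsymbol vector of length `length(symbols) * splitFactor`
#' @export
splitSubsymbols <- function(symbols, symbolBits, splitFactor)
    .split_subsymbols(as.integer(symbols), as.integer(symbolBits),
                      as.integer(splitFactor))

#' @rdname splitSubsymbols
#' @param subsymbols integer subsymbol vector
#' @export
mergeSubsymbols <- function(subsymbols, symbolBits, splitFactor)
    .merge_subsymbols(as.integer(subsymbols), as.integer(symbolBits),
                      as.integer(splitFactor))

#' Context-conditioned LUT transform
#'
#' Samples subsymbol frequencies conditioned on the previous one (order 1)
#' or two (order 2) subsymbols (value 0 stands in for missing predecessors
#' at the stream start), ranks each context's subsymbols by descending
#' frequency (ties by ascending value) and substitutes every subsymbol by
#' its rank. The tables required for inversion are returned and serialized
#' ahead of the indices in compressed blocks.
#'
#' @param subsymbols integer subsymbol vector (width at most 8 bits)
#' @param order 1 or 2
#' @param subsymbolBits subsymbol width in bits
#' @return `list(contextKeys=, ranked=, indices=)`
#' @export
lutForward <- function(subsymbols, order, subsymbolBits)
    .lut_forward(as.integer(subsymbols), as.integer(order),
                 as.integer(subsymbolBits))

#' @rdname lutForward
#' @param tables the `list(contextKeys=, ranked=)` part of [lutForward()]
#' @param indices rank stream
#' @export
lutInverse <- function(tables, indices, order)
    .lut_inverse(as.integer(tables$contextKeys), tables$ranked,
                 as.integer(indices), as.integer(order))

# ---- internal plumbing used by the entropy stage and the optimizer -----

nTransformedStreams <- function(transform)
    switch(transform, NONE = 1L, EQUALITY = 2L, MATCH = 3L, RLE = 2L,
           stop("unknown sequence transform: ", transform))

# Apply a sequence transform; returns the demultiplexed transformed
# subsequences with their bit widths. B and G are fixed at 255 so the
# derived pointer/length streams are 8-bit regardless of the input width.
applySequenceTransform <- function(symbols, symbolBits, transform,
                                   B = 255L, G = 255L) {
    symbols <- as.integer(symbols)
    switch(transform,
        NONE = list(list(name = "main", symbols = symbols, bits = symbolBits)),
        EQUALITY = {
            e <- .eq_encode(symbols)
            list(list(name = "flags", symbols = e$flags, bits = 1L),
                 list(name = "residuals", symbols = e$residuals,
                      bits = symbolBits))
        },
        MATCH = {
            m <- .match_encode(symbols, as.integer(B))
            list(list(name = "pointers", symbols = m$pointers, bits = 8L),
                 list(name = "lengths", symbols = m$lengths, bits = 8L),
                 list(name = "literals", symbols = m$literals,
                      bits = symbolBits))
        },
        RLE = {
            r <- .rle_encode(symbols, as.integer(G))
            list(list(name = "lengths", symbols = r$lengths, bits = 8L),
                 list(name = "values", symbols = r$symbols,
                      bits = symbolBits))
        },
        stop("unknown sequence transform: ", transform))
}

# Invert a sequence transform given the decoded transformed streams (a
# list of integer vectors in layout order) and the original symbol count.
invertSequenceTransform <- function(streams, transform, origN,
                                    B = 255L, G = 255L) {
    out <- switch(transform,
        NONE = streams[[1]],
        EQUALITY = .eq_decode(streams[[1]], streams[[2]]),
        MATCH = .match_decode(streams[[1]], streams[[2]], streams[[3]],
                              as.integer(B)),
        RLE = .rle_decode(streams[[1]], streams[[2]], as.integer(G)),
        stop("unknown sequence transform: ", transform))
    if (length(out) != origN)
        stop(sprintf("corrupt stream: inverse %s transform yielded %d symbols, expected %d",
                     transform, length(out), origN))
    out
}
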
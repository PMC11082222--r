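# Descriptor catalogue. The numbering and subsequence layout are this
# package's own (documented in the methods vignette); symbol widths are
# fixed per stream, chosen from {1,2,4,8,16,32} bits so that every
# subsymbol split factor in {1,2,4,8} either divides the width or is
# consistently invalid for that stream across all access units.

.CATALOGUE <- data.frame(
    name          = c("pos.0", "rlen.0", "mm_count.0", "mm_pos.0",
                      "mm_type.0", "mm_payload.0", "mm_len.0", "pair.0",
                      "flags.0", "ureads.0", "qv.0"),
    descriptorId  = c(0L, 1L, 2L, 3L, 4L, 5L, 5L, 6L, 7L, 8L, 9L),
    subsequenceId = c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L),
    symbolBits    = c(32L, 16L, 16L, 16L, 2L, 4L, 16L, 32L, 1L, 4L, 8L),
    stringsAsFactors = FALSE)

# identifier-token streams: descriptor 10, subsequence = position * 8 + slot
.TOKEN_SLOTS <- c(type = 0L, str = 1L, digit = 2L, width = 3L,
                  delta = 4L, chr = 5L)
.TOKEN_BITS <- c(type = 4L, str = 8L, digit = 32L, width = 8L,
                 delta = 16L, chr = 8L)
.MAX_TOKEN_POSITIONS <- 32L

#' Identifier token-type codes
#'
#' Codes used in the `tok.<position>.type` descriptor subsequences.
#' @format named integer vector
#' @export
TOKEN_TYPES <- c(STRING = 0L, DIGITS = 1L, CHAR = 2L, MATCH = 3L,
                 DELTA = 4L, END = 5L)

#' Symbol width of a named descriptor subsequence
#'
#' Stream names are `"<descriptor>.<subsequence>"` for the fixed catalogue
#' (`pos.0`, `rlen.0`, `mm_count.0`, `mm_pos.0`, `mm_type.0`,
#' `mm_payload.0`, `mm_len.0`, `pair.0`, `flags.0`, `ureads.0`, `qv.0`) and
#' `"tok.<position>.<slot>"` for the identifier-token family.
#'
#' @param name stream name
#' @return integer bit width
#' @export
streamBits <- function(name) {
    i <- match(name, .CATALOGUE$name)
    if (!is.na(i)) return(.CATALOGUE$symbolBits[i])
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    if (length(parts) == 3L && parts[1] == "tok" &&
        parts[3] %in% names(.TOKEN_BITS))
        return(unname(.TOKEN_BITS[parts[3]]))
    stop("unknown descriptor subsequence name: ", name)
}

streamIds <- function(name) {
    i <- match(name, .CATALOGUE$name)
    if (!is.na(i))
        return(c(.CATALOGUE$descriptorId[i], .CATALOGUE$subsequenceId[i]))
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    if (length(parts) == 3L && parts[1] == "tok")
        return(c(10L, as.integer(parts[2]) * 8L +
                      .TOKEN_SLOTS[[parts[3]]]))
    stop("unknown descriptor subsequence name: ", name)
}

newSubsequence <- function(name, symbols) {
    ids <- streamIds(name)
    new("DescriptorSubsequence", descriptorId = ids[1], subsequenceId = ids[2],
        symbols = as.integer(symbols), symbolBits = streamBits(name))
}

# ---- base coding -------------------------------------------------------

.BASES <- c("A", "C", "G", "T", "N")
.BASE_LOOKUP <- local({
    v <- rep.int(-1L, 128L)
    v[utf8ToInt(paste(.BASES, collapse = "")) + 1L] <- 0:4
    v
})
# tie-break rank: lexicographic base order A < C < G < N < T
.BASE_TIE_RANK <- c(0L, 1L, 2L, 4L, 3L)

#' Convert a base string to integer codes (A=0, C=1, G=2, T=3, N=4)
#' @param s base string over ACGTN
#' @return integer vector of codes
#' @export
baseCodes <- function(s) {
    if (!nzchar(s)) return(integer(0))
    v <- .BASE_LOOKUP[utf8ToInt(s) + 1L]
    if (anyNA(v) || min(v) < 0L)
        stop("unknown base in sequence (only A, C, G, T, N are supported)")
    v
}

#' Convert integer base codes back to a base string
#' @param codes integer codes in 0..4
#' @return base string
#' @export
codesToBases <- function(codes) {
    if (!length(codes)) return("")
    if (min(codes) < 0L || max(codes) > 4L) stop("base code outside 0..4")
    paste(.BASES[codes + 1L], collapse = "")
}

# ---- zig-zag mapping for signed descriptor values ----------------------

zigzag <- function(v) ifelse(v >= 0L, 2L * v, -2L * v - 1L)
unzigzag <- function(u) ifelse(u %% 2L == 0L, u %/% 2L, -((u + 1L) %/% 2L))
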
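# Record-level rules: classification into P/N/M/I/U/HM, pre-filtering of
# unsupported alignment features, and position sorting.

#' Classify a record by its alignment properties
#'
#' Classes: P (fully aligned, no mismatches), N (only substitutions by N),
#' M (arbitrary substitutions), I (insertions, deletions or clipping),
#' U (no segment aligned), HM (paired record with exactly one aligned
#' segment). Precedence for aligned records is I > M > N > P.
#'
#' @param rec a [GenomicRecord-class]
#' @return single character, one of `"P","N","M","I","U","HM"`
#' @export
classifyRecord <- function(rec) {
    aligned <- !vapply(rec@alignments, is.null, logical(1))
    if (!any(aligned)) return("U")
    if (!all(aligned)) return("HM")
    kinds <- character(0)
    payloads <- character(0)
    for (al in rec@alignments) {
        kinds <- c(kinds, al$edits$kind)
        payloads <- c(payloads, al$edits$payload[al$edits$kind == "SUBSTITUTION"])
    }
    if (any(kinds %in% c("INSERTION", "DELETION", "SOFTCLIP"))) return("I")
    if (!length(payloads)) return("P")
    if (all(payloads == "N")) return("N")
    "M"
}

#' Drop or normalize record features outside the supported model
#'
#' Half-aligned paired records (class HM) lose their alignment information
#' and become completely unaligned (class U). Paired records whose two
#' mates align to different reference sequences are likewise normalized to
#' class U (the pair descriptor stores a single same-reference position
#' delta). Secondary and supplementary SAM lines are already discarded at
#' [readSamRecords()] before mate joining; optional tags are never read.
#'
#' @param records list of [GenomicRecord-class]
#' @return list of records, same length and order
#' @export
filterUnsupported <- function(records) {
    lapply(records, function(rec) {
        toU <- rec@recordClass == "HM"
        if (!toU && length(rec@segments) == 2L) {
            als <- rec@alignments
            if (!is.null(als[[1]]) && !is.null(als[[2]]) &&
                als[[1]]$referenceId != als[[2]]$referenceId)
                toU <- TRUE
        }
        if (toU) {
            rec@alignments <- vector("list", length(rec@segments))
            rec@recordClass <- "U"
        }
        rec
    })
}

firstAlignedPosition <- function(rec) {
    al <- rec@alignments[[1]]
    if (is.null(al)) NA_integer_ else al$position
}

firstReferenceId <- function(rec) {
    al <- rec@alignments[[1]]
    if (is.null(al)) NA_character_ else al$referenceId
}

#' Sort records by the alignment position of their first segment
#'
#' Stable sort by (reference, position of the first aligned segment);
#' unaligned records keep their relative order and are routed after all
#' aligned records.
#'
#' @param records list of [GenomicRecord-class]
#' @return reordered list
#' @export
sortByPosition <- function(records) {
    refs <- vapply(records, firstReferenceId, character(1))
    pos <- vapply(records, firstAlignedPosition, integer(1))
    unaligned <- is.na(refs)
    aligned <- records[!unaligned]
    o <- order(refs[!unaligned], pos[!unaligned], method = "radix")
    c(aligned[o], records[unaligned])
}

# ---- edit-walk helpers shared by SAM I/O and the descriptor codecs -----

# Number of reference bases consumed by a segment's alignment.
refSpan <- function(rlen, edits) {
    span <- rlen
    for (i in seq_len(nrow(edits))) {
        k <- edits$kind[i]
        if (k == "INSERTION" || k == "SOFTCLIP") span <- span - edits$length[i]
        else if (k == "DELETION") span <- span + edits$length[i]
    }
    span
}

# Reconstruct segment bases from a reference contig string, the 0-based
# alignment position and the edit list (CIGAR order, offsets
# non-decreasing). Returns the base string.
reconstructBases <- function(refStr, position, rlen, edits) {
    pieces <- character(0)
    cursorRead <- 0L
    cursorRef <- position
    for (i in seq_len(nrow(edits))) {
        gap <- edits$readOffset[i] - cursorRead
        if (gap < 0L) stop("corrupt stream: edit offsets decrease")
        if (gap > 0L) {
            pieces <- c(pieces, substr(refStr, cursorRef + 1L, cursorRef + gap))
            cursorRef <- cursorRef + gap
            cursorRead <- cursorRead + gap
        }
        switch(edits$kind[i],
            SUBSTITUTION = {
                pieces <- c(pieces, edits$payload[i])
                cursorRef <- cursorRef + 1L
                cursorRead <- cursorRead + 1L
            },
            INSERTION = {
                pieces <- c(pieces, edits$payload[i])
                cursorRead <- cursorRead + edits$length[i]
            },
            DELETION = {
                cursorRef <- cursorRef + edits$length[i]
            },
            SOFTCLIP = {
                pieces <- c(pieces, edits$payload[i])
                cursorRead <- cursorRead + edits$length[i]
            })
    }
    if (cursorRead < rlen) {
        gap <- rlen - cursorRead
        pieces <- c(pieces, substr(refStr, cursorRef + 1L, cursorRef + gap))
    }
    out <- paste(pieces, collapse = "")
    if (nchar(out) != rlen)
        stop("corrupt stream: reconstructed length mismatch")
    out
}

# Map a segment's aligned bases to reference coordinates: returns
# list(readOffsets=, refPositions=) of 0-based indices for every base that
# consumes both read and reference (match or substitution). Inserted and
# clipped bases are excluded; deletions advance the reference cursor.
alignedBaseMap <- function(position, rlen, edits) {
    ro <- integer(0)
    rp <- integer(0)
    cursorRead <- 0L
    cursorRef <- position
    emit <- function(n) {
        if (n > 0L) {
            ro <<- c(ro, cursorRead + 0L:(n - 1L))
            rp <<- c(rp, cursorRef + 0L:(n - 1L))
            cursorRead <<- cursorRead + n
            cursorRef <<- cursorRef + n
        }
    }
    for (i in seq_len(nrow(edits))) {
        gap <- edits$readOffset[i] - cursorRead
        emit(gap)
        switch(edits$kind[i],
            SUBSTITUTION = emit(1L),
            INSERTION = { cursorRead <- cursorRead + edits$length[i] },
            DELETION = { cursorRef <- cursorRef + edits$length[i] },
            SOFTCLIP = { cursorRead <- cursorRead + edits$length[i] })
    }
    emit(rlen - cursorRead)
    list(readOffsets = ro, refPositions = rp)
}

# Order edits canonically: non-decreasing read offset; at equal offsets
# reference-consuming ops (DELETION) come first, then clips/insertions,
# then substitutions - matching CIGAR emission order.
orderEdits <- function(edits) {
    if (nrow(edits) < 2L) return(edits)
    rank <- match(edits$kind, c("DELETION", "SOFTCLIP", "INSERTION",
                                "SUBSTITUTION"))
    edits[order(edits$readOffset, rank, method = "radix"), , drop = FALSE]
}
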
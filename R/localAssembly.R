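# Local-assembly encoding: a sliding buffer of the most recently coded
# records maintains per-locus base counts; the consensus (per-locus
# plurality vote, ties to the lexicographically smallest base, uncovered
# loci = 'N') serves as the reference for reference-based coding of the
# next record. The decoder reconstructs the identical consensus from the
# records it has already decoded, which guarantees losslessness. Buffers
# never span access units, preserving independent decodability.

#' Build a consensus window from buffered sequences
#'
#' Per-locus plurality vote over all buffered sequences covering the
#' locus; ties are broken toward the lexicographically smallest base
#' (A < C < G < N < T) and loci covered by nothing are filled with 'N'.
#'
#' @param buffer non-empty list of `list(position=, bases=)` with
#'   non-decreasing positions; each entry contributes its bases at
#'   consecutive reference loci from `position`
#' @return `list(start=, bases=, coverage=)`; `coverage` is a 5 x width
#'   count matrix with rows A, C, G, T, N
#' @export
buildLocalConsensus <- function(buffer) {
    if (!length(buffer)) stop("consensus buffer must be non-empty")
    starts <- vapply(buffer, function(b) as.integer(b$position), integer(1))
    lens <- vapply(buffer, function(b) nchar(b$bases), integer(1))
    start <- min(starts)
    width <- max(starts + lens) - start
    counts <- matrix(0L, nrow = 5L, ncol = width,
                     dimnames = list(.BASES, NULL))
    for (b in buffer) {
        codes <- baseCodes(b$bases)
        idx <- (as.integer(b$position) - start) + seq_along(codes)
        counts[cbind(codes + 1L, idx)] <- counts[cbind(codes + 1L, idx)] + 1L
    }
    list(start = start, bases = .consensusFromCounts(counts),
         coverage = counts)
}

# counts: 5 x width matrix in code order A,C,G,T,N -> consensus string
.consensusFromCounts <- function(counts) {
    if (!ncol(counts)) return("")
    # reorder rows lexicographically (A,C,G,N,T) so the first maximum is
    # the lexicographic tie-break winner
    lex <- counts[c(1L, 2L, 3L, 5L, 4L), , drop = FALSE]
    win <- max.col(t(lex), ties.method = "first")
    codes <- c(0L, 1L, 2L, 4L, 3L)[win]
    codes[colSums(counts) == 0L] <- 4L # uncovered -> N
    codesToBases(codes)
}

# Incremental consensus state over one access unit's reference span.
.laState <- function(spanStart, spanWidth, bufferSize) {
    env <- new.env(parent = emptyenv())
    env$counts <- matrix(0L, nrow = 5L, ncol = max(spanWidth, 1L))
    env$start <- spanStart
    env$bufferSize <- bufferSize
    env$queue <- list() # per buffered record: list(loc=, code=)
    env
}

.laAdd <- function(state, refPositions, codes) {
    if (length(refPositions)) {
        idx <- cbind(codes + 1L, refPositions - state$start + 1L)
        state$counts[idx] <- state$counts[idx] + 1L
    }
    state$queue[[length(state$queue) + 1L]] <-
        list(loc = refPositions, code = codes)
    if (length(state$queue) > state$bufferSize) {
        old <- state$queue[[1L]]
        state$queue <- state$queue[-1L]
        if (length(old$loc)) {
            idx <- cbind(old$code + 1L, old$loc - state$start + 1L)
            state$counts[idx] <- state$counts[idx] - 1L
        }
    }
    invisible(state)
}

# Consensus bases for reference positions [from, to) as a string.
.laConsensus <- function(state, from, to) {
    if (to <= from) return("")
    cols <- (from - state$start + 1L):(to - state$start)
    .consensusFromCounts(state$counts[, cols, drop = FALSE])
}

# Reference span bounds of one record (all segments).
.recordSpan <- function(rec) {
    lo <- Inf
    hi <- -Inf
    for (i in seq_along(rec@segments)) {
        al <- rec@alignments[[i]]
        if (is.null(al)) next
        lo <- min(lo, al$position)
        hi <- max(hi, al$position +
                      refSpan(nchar(rec@segments[[i]]$bases), al$edits))
    }
    c(lo, hi)
}

#' Local-assembly encoding of an aligned access unit
#'
#' Each record is encoded exactly as in [encodeReferenceBased()], but
#' against the consensus built from the up-to-`bufferSize` previously
#' encoded records of this access unit: substitutions are recomputed
#' against the consensus (indels and clips keep their original structure),
#' so no external reference is needed for decoding. The first record sees
#' an empty buffer, i.e. an all-'N' consensus, and is carried entirely by
#' substitution payloads. Only aligned (match-op) bases vote.
#'
#' @param au an aligned, position-sorted [AccessUnit-class]
#' @param bufferSize number of recent records in the consensus buffer
#' @param traceConsensus when `TRUE`, attach the per-record consensus
#'   strings as an attribute (for encoder/decoder mirror checks)
#' @return named list of descriptor subsequences
#' @export
encodeLocalAssembly <- function(au, bufferSize = 32L, traceConsensus = FALSE) {
    if (bufferSize < 1L) stop("local-assembly buffer size must be >= 1")
    spans <- vapply(au@records, .recordSpan, numeric(2))
    state <- .laState(as.integer(min(spans[1, ])),
                      as.integer(max(spans[2, ]) - min(spans[1, ])),
                      bufferSize)
    paired <- au@key$paired
    acc <- .newAlignedAcc()
    prevPos <- NA_integer_
    trace <- character(0)
    for (rec in au@records) {
        al1 <- rec@alignments[[1]]
        if (is.null(al1)) stop("local assembly needs aligned records")
        if (is.na(prevPos)) {
            acc$pos[[1L]] <- al1$position
        } else {
            d <- al1$position - prevPos
            if (d < 0L) stop("access unit is not position-sorted")
            acc$pos[[length(acc$pos) + 1L]] <- d
        }
        prevPos <- al1$position
        pend <- list()
        for (i in seq_along(rec@segments)) {
            seg <- rec@segments[[i]]
            al <- rec@alignments[[i]]
            rlen <- nchar(seg$bases)
            acc$rlen[[length(acc$rlen) + 1L]] <- rlen
            acc$flags[[length(acc$flags) + 1L]] <- as.integer(al$reverseStrand)
            map <- alignedBaseMap(al$position, rlen, al$edits)
            readCodes <- baseCodes(seg$bases)
            alignedCodes <- readCodes[map$readOffsets + 1L]
            cons <- .laConsensus(state, al$position,
                                 al$position + refSpan(rlen, al$edits))
            if (traceConsensus) trace <- c(trace, cons)
            consCodes <- baseCodes(cons)
            consAt <- consCodes[map$refPositions - al$position + 1L]
            mis <- which(alignedCodes != consAt)
            structural <- al$edits[al$edits$kind != "SUBSTITUTION", ,
                                   drop = FALSE]
            subs <- if (length(mis))
                data.frame(kind = "SUBSTITUTION",
                           readOffset = map$readOffsets[mis],
                           payload = .BASES[alignedCodes[mis] + 1L],
                           length = 1L, stringsAsFactors = FALSE)
                else .emptyEdits
            .pushEdits(acc, orderEdits(rbind(structural, subs)))
            pend[[i]] <- list(loc = map$refPositions, code = alignedCodes)
        }
        if (paired)
            acc$pair[[length(acc$pair) + 1L]] <-
                zigzag(rec@alignments[[2]]$position - al1$position)
        # the whole record enters the buffer as one unit
        .laAdd(state, unlist(lapply(pend, `[[`, "loc")),
               unlist(lapply(pend, `[[`, "code")))
    }
    out <- .finishStreams(.alignedAccToStreams(acc, paired))
    if (traceConsensus) attr(out, "consensus") <- trace
    out
}

#' @rdname encodeLocalAssembly
#' @param streams descriptor subsequences from [encodeLocalAssembly()]
#' @param key buffer key
#' @param nRecords record count
#' @param qualities,ids see [decodeReferenceBased()]
#' @export
decodeLocalAssembly <- function(streams, key, nRecords, bufferSize = 32L,
                                qualities = NULL, ids = NULL,
                                traceConsensus = FALSE) {
    rd <- .streamReader(streams)
    paired <- key$paired
    # first pass impossible without decoding; the span is discovered
    # incrementally, so the count matrix grows on demand
    state <- NULL
    recs <- vector("list", nRecords)
    prevPos <- NA_integer_
    qi <- 0L
    trace <- character(0)
    for (r in seq_len(nRecords)) {
        st <- .readAlignedRecord(rd, paired, prevPos)
        prevPos <- st$pos[1]
        nseg <- length(st$segs)
        spanHi <- max(vapply(seq_len(nseg), function(i)
            st$pos[i] + refSpan(st$segs[[i]]$rlen, st$segs[[i]]$edits),
            numeric(1)))
        if (is.null(state)) {
            state <- .laState(st$pos[1], as.integer(spanHi - st$pos[1]),
                              bufferSize)
        } else if (spanHi - state$start > ncol(state$counts)) {
            grow <- matrix(0L, nrow = 5L,
                           ncol = as.integer(spanHi - state$start) -
                                  ncol(state$counts))
            state$counts <- cbind(state$counts, grow)
        }
        segments <- vector("list", nseg)
        alignments <- vector("list", nseg)
        pendLoc <- list()
        pendCode <- list()
        for (i in seq_len(nseg)) {
            s <- st$segs[[i]]
            cons <- .laConsensus(state, st$pos[i],
                                 st$pos[i] + refSpan(s$rlen, s$edits))
            if (traceConsensus) trace <- c(trace, cons)
            bases <- reconstructBases(cons, 0L, s$rlen,
                                      .shiftEdits(s$edits))
            qi <- qi + 1L
            segments[[i]] <- list(bases = bases,
                                  qualities = if (is.null(qualities)) ""
                                              else qualities[qi])
            # decoded edit list keeps only the structural ops: the
            # substitutions were measured against the transient consensus
            alignments[[i]] <- list(
                referenceId = key$referenceId, position = st$pos[i],
                reverseStrand = s$strand,
                edits = s$edits[s$edits$kind != "SUBSTITUTION", ,
                                drop = FALSE])
            map <- alignedBaseMap(st$pos[i], s$rlen, s$edits)
            codes <- baseCodes(bases)
            pendLoc[[i]] <- map$refPositions
            pendCode[[i]] <- codes[map$readOffsets + 1L]
        }
        .laAdd(state, unlist(pendLoc), unlist(pendCode))
        recs[[r]] <- new("GenomicRecord",
                         identifier = if (is.null(ids)) sprintf("r%d", r)
                                      else ids[r],
                         segments = segments, alignments = alignments,
                         recordClass = key$recordClass)
    }
    if (traceConsensus) attr(recs, "consensus") <- trace
    recs
}

# The decoder reconstructs against the consensus window, whose coordinate
# origin is the segment's own position; shift edits to window coordinates
# (they are already read-offset based, so nothing changes - helper kept
# for symmetry/clarity).
.shiftEdits <- function(edits) edits
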
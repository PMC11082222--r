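# Encoding of access units into descriptor subsequences and back.
# Reference-based coding stores per record: position (delta-coded),
# segment lengths, strand flags, the edit operations against the
# reference, and (for paired records) the mate's position delta. The
# low-latency strategy stores lengths and verbatim base codes only.

.MM_TYPE <- c(SUBSTITUTION = 0L, INSERTION = 1L, DELETION = 2L,
              SOFTCLIP = 3L)

.alignedStreamNames <- function(paired)
    c("pos.0", "rlen.0", "mm_count.0", "mm_pos.0", "mm_type.0",
      "mm_payload.0", "mm_len.0", "flags.0", if (paired) "pair.0")

# Serialize one segment's edits into the mm accumulators (env `acc` with
# integer-list members). Offsets are delta-coded within the segment.
.pushEdits <- function(acc, edits) {
    acc$mm_count[[length(acc$mm_count) + 1L]] <- nrow(edits)
    prevOff <- 0L
    for (i in seq_len(nrow(edits))) {
        off <- edits$readOffset[i]
        if (off < prevOff) stop("edit offsets decrease within a segment")
        acc$mm_pos[[length(acc$mm_pos) + 1L]] <- off - prevOff
        prevOff <- off
        kind <- edits$kind[i]
        acc$mm_type[[length(acc$mm_type) + 1L]] <- .MM_TYPE[[kind]]
        if (kind == "SUBSTITUTION") {
            acc$mm_payload[[length(acc$mm_payload) + 1L]] <-
                baseCodes(edits$payload[i])
        } else {
            acc$mm_len[[length(acc$mm_len) + 1L]] <- edits$length[i]
            if (kind != "DELETION")
                acc$mm_payload[[length(acc$mm_payload) + 1L]] <-
                    baseCodes(edits$payload[i])
        }
    }
}

.newAlignedAcc <- function() {
    acc <- new.env(parent = emptyenv())
    for (nm in c("pos", "rlen", "mm_count", "mm_pos", "mm_type",
                 "mm_payload", "mm_len", "flags", "pair"))
        acc[[nm]] <- list()
    acc
}

.alignedAccToStreams <- function(acc, paired) {
    out <- list(
        pos.0 = as.integer(unlist(acc$pos)),
        rlen.0 = as.integer(unlist(acc$rlen)),
        mm_count.0 = as.integer(unlist(acc$mm_count)),
        mm_pos.0 = as.integer(unlist(acc$mm_pos)),
        mm_type.0 = as.integer(unlist(acc$mm_type)),
        mm_payload.0 = as.integer(unlist(acc$mm_payload)),
        mm_len.0 = as.integer(unlist(acc$mm_len)),
        flags.0 = as.integer(unlist(acc$flags)))
    if (paired) out$pair.0 <- as.integer(unlist(acc$pair))
    lapply(out, function(s) list(symbols = if (is.null(s)) integer(0) else s,
                                 bits = NULL))
}

.finishStreams <- function(raw) {
    out <- list()
    for (nm in names(raw)) {
        out[[nm]] <- list(symbols = raw[[nm]]$symbols, bits = streamBits(nm))
    }
    out
}

#' Reference-based encoding of an aligned access unit
#'
#' Stores, per record, the alignment position of the first segment (first
#' record absolute, then non-negative deltas), per-segment lengths, strand
#' flags, and the edit operations (type, in-read offset delta, payload
#' base codes, indel/clip lengths) needed to reconstruct each segment from
#' the reference; paired records additionally store the mate's position as
#' a zig-zag-coded delta.
#'
#' @param au an aligned [AccessUnit-class], position-sorted
#' @param reference contig base string the records align to (used for
#'   bounds validation at encode time and for reconstruction at decode
#'   time)
#' @return named list of descriptor subsequences
#'   (`list(symbols=, bits=)` per stream name)
#' @export
encodeReferenceBased <- function(au, reference) {
    paired <- au@key$paired
    acc <- .newAlignedAcc()
    prevPos <- NA_integer_
    refLen <- nchar(reference)
    for (rec in au@records) {
        al1 <- rec@alignments[[1]]
        if (is.null(al1)) stop("reference-based encoding needs aligned records")
        if (is.na(prevPos)) {
            acc$pos[[1L]] <- al1$position
        } else {
            d <- al1$position - prevPos
            if (d < 0L) stop("access unit is not position-sorted")
            acc$pos[[length(acc$pos) + 1L]] <- d
        }
        prevPos <- al1$position
        for (i in seq_along(rec@segments)) {
            seg <- rec@segments[[i]]
            al <- rec@alignments[[i]]
            rlen <- nchar(seg$bases)
            if (al$position + refSpan(rlen, al$edits) > refLen)
                stop("record at position ", al$position,
                     " extends beyond the reference end (", refLen, ")")
            acc$rlen[[length(acc$rlen) + 1L]] <- rlen
            acc$flags[[length(acc$flags) + 1L]] <-
                as.integer(al$reverseStrand)
            .pushEdits(acc, al$edits)
        }
        if (paired)
            acc$pair[[length(acc$pair) + 1L]] <-
                zigzag(rec@alignments[[2]]$position - al1$position)
    }
    .finishStreams(.alignedAccToStreams(acc, paired))
}

# Cursor-based reader over the aligned descriptor streams.
.streamReader <- function(streams) {
    cur <- new.env(parent = emptyenv())
    function(name, n = 1L) {
        if (n == 0L) return(integer(0))
        i <- cur[[name]] %||% 0L
        s <- streams[[name]]$symbols
        if (is.null(s) || i + n > length(s))
            stop("corrupt stream: descriptor subsequence '", name,
                 "' exhausted")
        cur[[name]] <- i + n
        s[(i + 1L):(i + n)]
    }
}

# Decode the structural part (position, lengths, strand, edits, pairing)
# of record `r`; shared by reference-based and local-assembly decoding.
.readAlignedRecord <- function(rd, paired, prevPos) {
    d <- rd("pos.0")
    pos1 <- if (is.na(prevPos)) d else prevPos + d
    nseg <- if (paired) 2L else 1L
    segs <- vector("list", nseg)
    for (i in seq_len(nseg)) {
        rlen <- rd("rlen.0")
        strand <- rd("flags.0") == 1L
        nEdit <- rd("mm_count.0")
        edits <- if (nEdit == 0L) .emptyEdits else {
            off <- 0L
            rows <- vector("list", nEdit)
            for (e in seq_len(nEdit)) {
                off <- off + rd("mm_pos.0")
                ty <- rd("mm_type.0")
                kind <- names(.MM_TYPE)[ty + 1L]
                if (kind == "SUBSTITUTION") {
                    pay <- codesToBases(rd("mm_payload.0"))
                    len <- 1L
                } else {
                    len <- rd("mm_len.0")
                    pay <- if (kind == "DELETION") ""
                           else codesToBases(rd("mm_payload.0", len))
                }
                rows[[e]] <- data.frame(kind = kind, readOffset = off,
                                        payload = pay, length = len,
                                        stringsAsFactors = FALSE)
            }
            do.call(rbind, rows)
        }
        segs[[i]] <- list(rlen = rlen, strand = strand, edits = edits)
    }
    pos2 <- if (paired) pos1 + unzigzag(rd("pair.0")) else NA_integer_
    list(pos = c(pos1, pos2)[seq_len(nseg)], segs = segs)
}

#' @rdname encodeReferenceBased
#' @param streams descriptor subsequences from [encodeReferenceBased()]
#' @param key the access unit's buffer key
#' @param nRecords number of records in the access unit
#' @param qualities optional character vector of per-segment quality
#'   strings (filled by the caller from the qv descriptor); `NULL` leaves
#'   qualities empty
#' @param ids optional identifiers (from the token descriptors)
#' @export
decodeReferenceBased <- function(streams, reference, key, nRecords,
                                 qualities = NULL, ids = NULL) {
    rd <- .streamReader(streams)
    paired <- key$paired
    recs <- vector("list", nRecords)
    prevPos <- NA_integer_
    qi <- 0L
    for (r in seq_len(nRecords)) {
        st <- .readAlignedRecord(rd, paired, prevPos)
        prevPos <- st$pos[1]
        nseg <- length(st$segs)
        segments <- vector("list", nseg)
        alignments <- vector("list", nseg)
        for (i in seq_len(nseg)) {
            s <- st$segs[[i]]
            bases <- reconstructBases(reference, st$pos[i], s$rlen, s$edits)
            qi <- qi + 1L
            segments[[i]] <- list(bases = bases,
                                  qualities = if (is.null(qualities)) ""
                                              else qualities[qi])
            alignments[[i]] <- list(referenceId = key$referenceId,
                                    position = st$pos[i],
                                    reverseStrand = s$strand,
                                    edits = s$edits)
        }
        recs[[r]] <- new("GenomicRecord",
                         identifier = if (is.null(ids)) sprintf("r%d", r)
                                      else ids[r],
                         segments = segments, alignments = alignments,
                         recordClass = key$recordClass)
    }
    recs
}

#' Low-latency encoding of an unaligned access unit
#'
#' Encodes nucleotides verbatim: per-segment lengths plus the concatenated
#' base codes. No positional descriptors are produced.
#'
#' @param au a class-U [AccessUnit-class]
#' @return named list of descriptor subsequences
#' @export
encodeLowLatency <- function(au) {
    rlen <- list()
    codes <- list()
    for (rec in au@records) {
        if (rec@recordClass != "U" ||
            any(!vapply(rec@alignments, is.null, logical(1))))
            stop("low-latency encoding applies to class-U records only")
        for (seg in rec@segments) {
            rlen[[length(rlen) + 1L]] <- nchar(seg$bases)
            codes[[length(codes) + 1L]] <- baseCodes(seg$bases)
        }
    }
    .finishStreams(list(
        rlen.0 = list(symbols = as.integer(unlist(rlen))),
        ureads.0 = list(symbols = as.integer(unlist(codes)))))
}

#' @rdname encodeLowLatency
#' @param streams descriptor subsequences from [encodeLowLatency()]
#' @param key buffer key
#' @param nRecords record count
#' @param qualities,ids see [decodeReferenceBased()]
#' @export
decodeLowLatency <- function(streams, key, nRecords, qualities = NULL,
                             ids = NULL) {
    rd <- .streamReader(streams)
    nseg <- if (key$paired) 2L else 1L
    recs <- vector("list", nRecords)
    qi <- 0L
    for (r in seq_len(nRecords)) {
        segments <- vector("list", nseg)
        for (i in seq_len(nseg)) {
            rlen <- rd("rlen.0")
            bases <- codesToBases(rd("ureads.0", rlen))
            qi <- qi + 1L
            segments[[i]] <- list(bases = bases,
                                  qualities = if (is.null(qualities)) ""
                                              else qualities[qi])
        }
        recs[[r]] <- new("GenomicRecord",
                         identifier = if (is.null(ids)) sprintf("r%d", r)
                                      else ids[r],
                         segments = segments,
                         alignments = vector("list", nseg),
                         recordClass = "U")
    }
    recs
}

#' Verbatim quality-value descriptor
#'
#' One symbol per base, value = ASCII code - 33. In discard mode nothing
#' is emitted and the decoder restores a configured placeholder.
#'
#' @param au an [AccessUnit-class]
#' @param mode `"verbatim"` or `"discard"`
#' @return named list with the `qv.0` stream (empty list in discard mode)
#' @export
encodeQualityVerbatim <- function(au, mode = c("verbatim", "discard")) {
    mode <- match.arg(mode)
    if (mode == "discard") return(list())
    syms <- list()
    for (rec in au@records)
        for (seg in rec@segments) {
            if (!nzchar(seg$qualities))
                stop("verbatim quality coding needs qualities on every ",
                     "segment; use mode = \"discard\" for data without them")
            v <- utf8ToInt(seg$qualities) - 33L
            if (min(v) < 0L || max(v) > 93L)
                stop("quality character outside the printable Phred+33 range")
            syms[[length(syms) + 1L]] <- v
        }
    .finishStreams(list(qv.0 = list(symbols = as.integer(unlist(syms)))))
}

# Split the flat qv stream back into per-segment quality strings using the
# decoded segment lengths (in segment order).
.qualitiesFromStream <- function(streams, segLengths, qualityMode,
                                 placeholder) {
    if (qualityMode == "discard" || is.null(streams[["qv.0"]]))
        return(vapply(segLengths, function(L) strrep(placeholder, L),
                      character(1)))
    syms <- streams[["qv.0"]]$symbols
    if (length(syms) != sum(segLengths))
        stop("corrupt stream: quality symbol count mismatch")
    ends <- cumsum(segLengths)
    starts <- ends - segLengths + 1L
    vapply(seq_along(segLengths), function(i)
        intToUtf8(syms[starts[i]:ends[i]] + 33L), character(1))
}
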
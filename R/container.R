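# Container serialization ("GLC1" format, version 1). Original byte
# layout, deliberately simple: little-endian fixed-width integers,
# length-prefixed strings, a deduplicated parameter-set table (at most 256
# entries) and independently decodable access-unit blocks, each protected
# by a CRC32 over its compressed payload. Decoding needs no external
# information except the reference FASTA for reference-based blocks.

.wU8 <- function(con, v) writeBin(as.integer(v), con, size = 1L)
.wU16 <- function(con, v) writeBin(as.integer(v), con, size = 2L,
                                   endian = "little")
.wU32 <- function(con, v) {
    v <- as.numeric(v)
    if (v >= 2^31) v <- v - 2^32
    writeBin(as.integer(v), con, size = 4L, endian = "little")
}
.wStr <- function(con, s, sizeBytes = 1L) {
    b <- charToRaw(s)
    if (sizeBytes == 1L) .wU8(con, length(b)) else .wU16(con, length(b))
    writeBin(b, con)
}

.rU8 <- function(con) readBin(con, "integer", size = 1L, signed = FALSE)
.rU16 <- function(con) readBin(con, "integer", size = 2L, signed = FALSE,
                               endian = "little")
.rU32 <- function(con) {
    v <- readBin(con, "integer", size = 4L, endian = "little")
    if (!length(v)) stop("container truncated")
    if (v < 0) v + 2^32 else as.numeric(v)
}
.rStr <- function(con, sizeBytes = 1L) {
    n <- if (sizeBytes == 1L) .rU8(con) else .rU16(con)
    rawToChar(readBin(con, "raw", n = n))
}

.QMODES <- c("verbatim", "discard")
.SUFFIX_STYLES <- c("none", "slash", "space")
.AU_CLASS_CODES <- c("P", "N", "M", "I", "U")

.writePset <- function(con, ps) {
    .wU8(con, ps@id)
    .wU16(con, length(ps@configs))
    for (nm in names(ps@configs)) {
        cfg <- ps@configs[[nm]]
        .wStr(con, nm)
        .wU8(con, match(cfg$transform, SEQ_TRANSFORMS) - 1L)
        .wU16(con, cfg$B)
        .wU16(con, cfg$G)
        .wU8(con, length(cfg$streams))
        for (s in cfg$streams) {
            .wU8(con, s$order)
            .wU8(con, s$split)
            .wU8(con, as.integer(isTRUE(s$lut)))
            .wU8(con, match(s$binarization, BINARIZATIONS) - 1L)
        }
    }
}

.readPset <- function(con) {
    id <- .rU8(con)
    n <- .rU16(con)
    configs <- list()
    for (i in seq_len(n)) {
        nm <- .rStr(con)
        transform <- SEQ_TRANSFORMS[.rU8(con) + 1L]
        B <- .rU16(con)
        G <- .rU16(con)
        k <- .rU8(con)
        streams <- vector("list", k)
        for (j in seq_len(k)) {
            streams[[j]] <- list(order = .rU8(con), split = .rU8(con),
                                 lut = .rU8(con) == 1L,
                                 binarization = BINARIZATIONS[.rU8(con) + 1L])
        }
        configs[[nm]] <- list(transform = transform, B = B, G = G,
                              streams = streams)
    }
    new("ParameterSet", id = id, configs = configs)
}

#' Write a container to disk
#'
#' The byte layout is deterministic: writing, parsing and re-writing a
#' container produces identical bytes.
#'
#' @param container a [CodecContainer-class]
#' @param path output file
#' @return invisibly, the number of bytes written
#' @export
writeContainer <- function(container, path) {
    if (length(container@parameterSets) > 256L)
        stop("a container permits at most 256 parameter sets (got ",
             length(container@parameterSets), ")")
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw("GLC1"), con)
    .wU8(con, 1L) # version
    hdr <- container@header
    .wU8(con, as.integer(isTRUE(hdr$paired)))
    .wU8(con, match(hdr$qualityMode, .QMODES) - 1L)
    .wU8(con, utf8ToInt(hdr$qualityPlaceholder))
    .wU8(con, match(hdr$idSuffixStyle, .SUFFIX_STYLES) - 1L)
    .wU16(con, hdr$localBufferSize)
    .wU16(con, length(hdr$references))
    for (nm in names(hdr$references)) {
        .wStr(con, nm, sizeBytes = 2L)
        .wU32(con, hdr$references[[nm]])
    }
    .wU16(con, length(container@parameterSets))
    for (ps in container@parameterSets) .writePset(con, ps)
    .wU32(con, length(container@accessUnits))
    for (blk in container@accessUnits) {
        .wU8(con, match(blk$key$recordClass, .AU_CLASS_CODES) - 1L)
        .wU8(con, as.integer(isTRUE(blk$key$paired)))
        refIdx <- if (is.na(blk$key$referenceId)) 0xFFFFL
                  else match(blk$key$referenceId, names(hdr$references)) - 1L
        .wU16(con, refIdx)
        .wU8(con, match(blk$mode, AU_MODES) - 1L)
        .wU8(con, blk$psetId)
        .wU32(con, blk$nRecords)
        .wU32(con, blk$startPosition)
        .wU16(con, length(blk$streams))
        payload <- raw(0)
        for (nm in names(blk$streams)) {
            .wStr(con, nm)
            s <- blk$streams[[nm]]
            .wU32(con, s$origN)
            .wU8(con, length(s$trStreams))
            for (tr in s$trStreams) {
                .wU32(con, tr$n)
                .wU32(con, length(tr$data))
                writeBin(tr$data, con)
                payload <- c(payload, tr$data)
            }
        }
        .wU32(con, .crc32(payload))
    }
    writeBin(charToRaw("GEND"), con)
    invisible(file.size(path))
}

#' Read a container from disk
#'
#' Streaming parse with per-block CRC verification; any access unit is
#' decodable given only the header, the parameter-set table and its own
#' block.
#'
#' @param path container file written by [writeContainer()]
#' @return a [CodecContainer-class]
#' @export
readContainer <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readBin(con, "raw", 4L)
    if (!identical(rawToChar(magic), "GLC1"))
        stop("not a GLC1 container (bad magic)")
    version <- .rU8(con)
    if (!identical(version, 1L))
        stop("unsupported container version: ", version)
    hdr <- list(paired = .rU8(con) == 1L,
                qualityMode = .QMODES[.rU8(con) + 1L],
                qualityPlaceholder = intToUtf8(.rU8(con)),
                idSuffixStyle = .SUFFIX_STYLES[.rU8(con) + 1L],
                localBufferSize = .rU16(con))
    nref <- .rU16(con)
    refs <- integer(0)
    refNames <- character(0)
    for (i in seq_len(nref)) {
        refNames <- c(refNames, .rStr(con, sizeBytes = 2L))
        refs <- c(refs, as.integer(.rU32(con)))
    }
    names(refs) <- refNames
    hdr$references <- refs
    nps <- .rU16(con)
    psets <- lapply(seq_len(nps), function(i) .readPset(con))
    nau <- .rU32(con)
    aus <- vector("list", nau)
    for (a in seq_len(nau)) {
        cls <- .AU_CLASS_CODES[.rU8(con) + 1L]
        paired <- .rU8(con) == 1L
        refIdx <- .rU16(con)
        key <- list(recordClass = cls, paired = paired,
                    referenceId = if (refIdx == 0xFFFFL) NA_character_
                                  else refNames[refIdx + 1L])
        mode <- AU_MODES[.rU8(con) + 1L]
        psetId <- .rU8(con)
        nRecords <- as.integer(.rU32(con))
        startPosition <- as.integer(.rU32(con))
        nStreams <- .rU16(con)
        streams <- list()
        payload <- raw(0)
        for (s in seq_len(nStreams)) {
            nm <- .rStr(con)
            origN <- as.integer(.rU32(con))
            k <- .rU8(con)
            trStreams <- vector("list", k)
            for (j in seq_len(k)) {
                n <- as.integer(.rU32(con))
                len <- as.integer(.rU32(con))
                dat <- readBin(con, "raw", len)
                if (length(dat) != len)
                    stop("container truncated inside access unit ", a - 1L)
                trStreams[[j]] <- list(n = n, data = dat)
                payload <- c(payload, dat)
            }
            streams[[nm]] <- list(origN = origN, trStreams = trStreams)
        }
        crc <- .rU32(con)
        if (crc != .crc32(payload))
            stop("checksum failure in access unit ", a - 1L)
        aus[[a]] <- list(key = key, mode = mode, psetId = psetId,
                         nRecords = nRecords, startPosition = startPosition,
                         streams = streams)
    }
    endmark <- readBin(con, "raw", 4L)
    if (!identical(rawToChar(endmark), "GEND"))
        stop("container truncated: end marker missing")
    new("CodecContainer", header = hdr, parameterSets = psets,
        accessUnits = aus)
}
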
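#' @include genocodec-package.R
NULL

RECORD_CLASSES <- c("P", "N", "M", "I", "U", "HM")
EDIT_KINDS <- c("SUBSTITUTION", "INSERTION", "DELETION", "SOFTCLIP")
SEQ_TRANSFORMS <- c("NONE", "EQUALITY", "MATCH", "RLE")
BINARIZATIONS <- c("BINARY", "TRUNCATED_UNARY", "EXP_GOLOMB")

.emptyEdits <- data.frame(kind = character(0), readOffset = integer(0),
                          payload = character(0), length = integer(0),
                          stringsAsFactors = FALSE)

#' GenomicRecord: one (possibly paired) sequencing record
#'
#' Holds a read identifier, one or two segments (bases plus optional
#' Phred+33 qualities), optional per-segment alignments, and the record's
#' alignment class (P, N, M, I, U or HM). Coordinates are 0-based
#' throughout; SAM's 1-based positions are converted at the I/O boundary.
#'
#' @slot identifier read identifier (mate suffixes already stripped)
#' @slot segments list of 1-2 segments, each `list(bases=, qualities=)`;
#'   `qualities` is `""` when absent
#' @slot alignments list parallel to `segments`; each entry `NULL`
#'   (unaligned) or `list(referenceId=, position=, reverseStrand=, edits=)`
#'   where `edits` is a data.frame with columns kind, readOffset, payload,
#'   length (CIGAR-order, offsets non-decreasing)
#' @slot recordClass one of P, N, M, I, U, HM
#' @export
setClass("GenomicRecord",
         representation(identifier = "character", segments = "list",
                        alignments = "list", recordClass = "character"))

setValidity("GenomicRecord", function(object) {
    n <- length(object@segments)
    if (n < 1L || n > 2L) return("a record has 1 or 2 segments")
    if (length(object@alignments) != n)
        return("alignments must parallel segments")
    for (s in object@segments) {
        if (!nzchar(s$bases)) return("segment bases must be non-empty")
        if (nzchar(s$qualities) && nchar(s$qualities) != nchar(s$bases))
            return("qualities must be empty or match the base count")
    }
    if (!(object@recordClass %in% RECORD_CLASSES))
        return("unknown record class")
    TRUE
})

#' Construct a GenomicRecord
#'
#' @param identifier read identifier
#' @param segments list of `list(bases=, qualities=)`
#' @param alignments list parallel to segments (`NULL` entries = unaligned);
#'   defaults to all-unaligned
#' @param recordClass record class; derived with [classifyRecord()] when
#'   missing
#' @return a [GenomicRecord-class] object
#' @export
GenomicRecord <- function(identifier, segments, alignments = NULL,
                          recordClass = NULL) {
    if (is.null(alignments)) alignments <- vector("list", length(segments))
    rec <- new("GenomicRecord", identifier = identifier, segments = segments,
               alignments = alignments,
               recordClass = if (is.null(recordClass)) "U" else recordClass)
    if (is.null(recordClass)) rec@recordClass <- classifyRecord(rec)
    rec
}

setMethod("show", "GenomicRecord", function(object) {
    cat(sprintf("GenomicRecord '%s' class %s, %d segment(s)\n",
                object@identifier, object@recordClass,
                length(object@segments)))
    for (i in seq_along(object@segments)) {
        al <- object@alignments[[i]]
        cat(sprintf("  [%d] %d bp %s\n", i, nchar(object@segments[[i]]$bases),
                    if (is.null(al)) "unaligned"
                    else sprintf("@ %s:%d%s", al$referenceId, al$position,
                                 if (al$reverseStrand) " (-)" else "")))
    }
})

#' AccessUnit: the smallest independently decodable group of records
#'
#' Records in an access unit share a buffer key: record class, pairing
#' status and (for aligned classes) the reference sequence.
#'
#' @slot key `list(recordClass=, paired=, referenceId=)`; `referenceId` is
#'   `NA` exactly for class U
#' @slot records ordered list of [GenomicRecord-class] objects
#' @slot auIndex 0-based emission index
#' @slot startPosition position of the first record (aligned AUs; `NA`
#'   otherwise)
#' @export
setClass("AccessUnit",
         representation(key = "list", records = "list", auIndex = "integer",
                        startPosition = "integer"))

setValidity("AccessUnit", function(object) {
    k <- object@key
    if (!all(c("recordClass", "paired", "referenceId") %in% names(k)))
        return("key needs recordClass, paired, referenceId")
    if (length(object@records) < 1L) return("an access unit holds >= 1 record")
    if (identical(k$recordClass, "U") != is.na(k$referenceId))
        return("referenceId must be NA exactly for class U")
    if (identical(k$recordClass, "HM"))
        return("HM records are filtered before grouping")
    TRUE
})

setMethod("show", "AccessUnit", function(object) {
    cat(sprintf("AccessUnit #%d: %d records, class %s, %s, ref %s\n",
                object@auIndex, length(object@records),
                object@key$recordClass,
                if (object@key$paired) "paired" else "unpaired",
                if (is.na(object@key$referenceId)) "-"
                else object@key$referenceId))
})

#' DescriptorSubsequence: one integer-symbol stream of an access unit
#'
#' @slot descriptorId small integer naming the descriptor
#' @slot subsequenceId small integer naming the subsequence
#' @slot symbols unsigned integer symbols
#' @slot symbolBits declared width; every symbol is `< 2^symbolBits`
#' @export
setClass("DescriptorSubsequence",
         representation(descriptorId = "integer", subsequenceId = "integer",
                        symbols = "integer", symbolBits = "integer"))

setValidity("DescriptorSubsequence", function(object) {
    b <- object@symbolBits
    if (b < 1L || b > 32L) return("symbolBits must be in 1..32")
    if (length(object@symbols)) {
        if (min(object@symbols) < 0L) return("symbols must be non-negative")
        lim <- if (b >= 31L) .Machine$integer.max else bitwShiftL(1L, b) - 1L
        if (max(object@symbols) > lim)
            return(sprintf("symbol exceeds 2^%d - 1", b))
    }
    TRUE
})

setMethod("show", "DescriptorSubsequence", function(object) {
    cat(sprintf("DescriptorSubsequence (%d,%d): %d symbols, %d bits\n",
                object@descriptorId, object@subsequenceId,
                length(object@symbols), object@symbolBits))
})

#' ParameterSet: full transform and entropy configuration
#'
#' One configuration per descriptor subsequence: the symbol-level sequence
#' transform (none / equality / match / run-length with its buffer or guard
#' parameter) and, per transformed subsequence, the coding order, subsymbol
#' split factor, LUT flag and binarization. A container holds at most 256
#' parameter sets.
#'
#' @slot id integer 0-255
#' @slot configs named list (stream name -> `list(transform=, B=, G=,
#'   streams=list of list(order=, split=, lut=, binarization=))`)
#' @export
setClass("ParameterSet",
         representation(id = "integer", configs = "list"))

setValidity("ParameterSet", function(object) {
    if (object@id < 0L || object@id > 255L) return("id must be 0..255")
    for (cfg in object@configs) {
        if (!(cfg$transform %in% SEQ_TRANSFORMS)) return("unknown transform")
        if (length(cfg$streams) != nTransformedStreams(cfg$transform))
            return("wrong transformed-stream count for transform")
    }
    TRUE
})

setMethod("show", "ParameterSet", function(object) {
    cat(sprintf("ParameterSet #%d: %d stream configurations\n", object@id,
                length(object@configs)))
})

#' CodecContainer: a parsed or to-be-written compressed dataset
#'
#' Self-describing: dataset header, deduplicated parameter-set table
#' (at most 256 entries) and one independently decodable block per access
#' unit. Only reference-based blocks need external data (the reference
#' FASTA) to decode.
#'
#' @slot header list: paired, qualityMode, qualityPlaceholder,
#'   idSuffixStyle, localBufferSize, references (named lengths)
#' @slot parameterSets list of [ParameterSet-class]
#' @slot accessUnits list of per-AU blocks (key, mode, psetId, nRecords,
#'   startPosition, streams)
#' @export
setClass("CodecContainer",
         representation(header = "list", parameterSets = "list",
                        accessUnits = "list"))

setMethod("show", "CodecContainer", function(object) {
    cat(sprintf("CodecContainer: %d access unit(s), %d parameter set(s), %d reference(s)\n",
                length(object@accessUnits), length(object@parameterSets),
                length(object@header$references)))
})

# ---- accessors ----

#' @rdname GenomicRecord-class
#' @param x object
#' @export
recordId <- function(x) x@identifier

#' @rdname GenomicRecord-class
#' @export
segments <- function(x) x@segments

#' @rdname GenomicRecord-class
#' @export
alignments <- function(x) x@alignments

#' @rdname GenomicRecord-class
#' @export
recordClass <- function(x) x@recordClass

#' @rdname AccessUnit-class
#' @param x object
#' @export
auKey <- function(x) x@key

#' @rdname AccessUnit-class
#' @export
auRecords <- function(x) x@records

#' @rdname DescriptorSubsequence-class
#' @param x object
#' @export
symbols <- function(x) x@symbols

#' @rdname DescriptorSubsequence-class
#' @export
symbolBits <- function(x) x@symbolBits
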
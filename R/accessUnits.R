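# Regrouping of records into access units. Buffers are keyed by
# (record class, pairing, reference); with 5 aligned classes, 2 pairing
# configurations and n references at most 5*2*n aligned buffers exist, and
# at most 2 unaligned ones. A buffer is flushed as one access unit when it
# reaches the threshold or when input ends.

.bufferKeyOf <- function(rec) {
    cls <- rec@recordClass
    list(recordClass = cls, paired = length(rec@segments) == 2L,
         referenceId = if (cls == "U") NA_character_
                       else firstReferenceId(rec))
}

.keyString <- function(key)
    paste(key$recordClass, if (key$paired) "paired" else "unpaired",
          if (is.na(key$referenceId)) "-" else key$referenceId, sep = "|")

#' Group records into access units
#'
#' Each record is appended to the buffer of its key; a buffer is emitted as
#' an access unit exactly when it reaches `threshold` records, and all
#' non-empty buffers are flushed (in the order their keys first appeared)
#' when input ends. Aligned input must be position-sorted per reference;
#' HM records must have been filtered out beforehand.
#'
#' @param records list of [GenomicRecord-class]
#' @param threshold records per access unit (>= 1); the compressed-size /
#'   random-access trade-off knob
#' @return list of [AccessUnit-class] in emission order
#' @export
groupRecords <- function(records, threshold = 4096L) {
    threshold <- as.integer(threshold)
    if (threshold < 1L) stop("access-unit threshold must be >= 1")
    buffers <- list()
    keyOrder <- character(0)
    out <- list()
    auIndex <- 0L
    emit <- function(ks) {
        b <- buffers[[ks]]
        first <- b$records[[1]]
        au <- new("AccessUnit", key = b$key, records = b$records,
                  auIndex = auIndex,
                  startPosition = if (is.na(b$key$referenceId)) NA_integer_
                                  else firstAlignedPosition(first))
        out[[length(out) + 1L]] <<- au
        auIndex <<- auIndex + 1L
        buffers[[ks]]$records <<- list()
    }
    for (rec in records) {
        if (rec@recordClass == "HM")
            stop("HM records cannot be grouped; run filterUnsupported() first")
        key <- .bufferKeyOf(rec)
        ks <- .keyString(key)
        if (is.null(buffers[[ks]])) {
            buffers[[ks]] <- list(key = key, records = list())
            keyOrder <- c(keyOrder, ks)
        }
        buffers[[ks]]$records[[length(buffers[[ks]]$records) + 1L]] <- rec
        if (length(buffers[[ks]]$records) >= threshold) emit(ks)
    }
    for (ks in keyOrder)
        if (length(buffers[[ks]]$records)) emit(ks)
    out
}

#' Census of buffer keys over a record stream
#'
#' Reports how many records fall into each (class, pairing, reference)
#' buffer key. In most datasets many of the theoretically possible keys
#' stay unused.
#'
#' @param records list of [GenomicRecord-class]
#' @return named integer vector; names are `"class|pairing|reference"`
#' @export
bufferCensus <- function(records) {
    ks <- vapply(records, function(r) .keyString(.bufferKeyOf(r)),
                 character(1))
    if (!length(ks)) return(integer(0))
    tab <- table(ks)
    out <- as.integer(tab)
    names(out) <- names(tab)
    out
}
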
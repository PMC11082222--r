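# End-to-end pipeline: filter -> sort -> group -> encode descriptors ->
# choose parameter sets -> entropy-code each access unit.

AU_MODES <- c("reference", "local", "lowlatency")

#' Encode one access unit into its full descriptor set
#'
#' Combines the sequence-coding strategy (reference-based, local assembly
#' or low latency) with the identifier-token and quality descriptors.
#'
#' @param au an [AccessUnit-class]
#' @param mode `"reference"`, `"local"` or `"lowlatency"`
#' @param reference contig string (reference mode only)
#' @param qualityMode `"verbatim"` or `"discard"`
#' @param localBufferSize consensus buffer size (local mode)
#' @return named list of descriptor subsequences (`list(symbols=, bits=)`)
#' @export
encodeAccessUnit <- function(au, mode, reference = NULL,
                             qualityMode = "verbatim",
                             localBufferSize = 32L) {
    seqDs <- switch(mode,
        reference = encodeReferenceBased(au, reference),
        local = encodeLocalAssembly(au, localBufferSize),
        lowlatency = encodeLowLatency(au),
        stop("unknown encoding mode: ", mode))
    ids <- vapply(au@records, recordId, character(1))
    c(seqDs, serializeTokens(ids), encodeQualityVerbatim(au, qualityMode))
}

#' @rdname encodeAccessUnit
#' @param streams descriptor set from [encodeAccessUnit()]
#' @param key buffer key of the access unit
#' @param nRecords record count
#' @param qualityPlaceholder quality character restored in discard mode
#' @export
decodeAccessUnit <- function(streams, key, nRecords, mode,
                             reference = NULL, qualityMode = "verbatim",
                             qualityPlaceholder = "I",
                             localBufferSize = 32L) {
    ids <- deserializeTokens(streams, nRecords)
    nseg <- if (key$paired) 2L else 1L
    segLengths <- streams[["rlen.0"]]$symbols
    if (length(segLengths) != nRecords * nseg)
        stop("corrupt stream: segment-length count mismatch")
    quals <- .qualitiesFromStream(streams, segLengths, qualityMode,
                                  qualityPlaceholder)
    switch(mode,
        reference = decodeReferenceBased(streams, reference, key, nRecords,
                                         qualities = quals, ids = ids),
        local = decodeLocalAssembly(streams, key, nRecords,
                                    bufferSize = localBufferSize,
                                    qualities = quals, ids = ids),
        lowlatency = decodeLowLatency(streams, key, nRecords,
                                      qualities = quals, ids = ids),
        stop("unknown encoding mode: ", mode))
}

# canonical signature of a stream config / parameter set, for dedup
.cfgSignature <- function(cfg)
    paste(cfg$transform, cfg$B, cfg$G,
          paste(vapply(cfg$streams, function(s)
              paste(s$order, s$split, as.integer(s$lut), s$binarization,
                    sep = ","), character(1)), collapse = ";"),
          sep = "|")

.psetSignature <- function(configs)
    paste(names(configs),
          vapply(configs, .cfgSignature, character(1)),
          sep = "=", collapse = " ")

#' Compress genomic records into a container object
#'
#' Runs the full pipeline: [filterUnsupported()], position sorting of the
#' aligned records, [groupRecords()], per-access-unit descriptor encoding,
#' parameter-set selection and entropy coding.
#'
#' @param records list of [GenomicRecord-class]
#' @param mode `"auto"` picks reference-based coding for aligned records
#'   when a reference is given, local assembly otherwise; unaligned
#'   records always use low-latency coding
#' @param reference optional reference (see [loadReference()])
#' @param auSize access-unit flush threshold
#' @param parameterMode `"global"` (one exhaustively optimized parameter
#'   set from a sample of access units), `"per-au"` (one per access unit,
#'   deduplicated under the 256-set bound) or `"default"` (fixed
#'   configuration, no search)
#' @param qualityMode `"verbatim"` or `"discard"`
#' @param qualityPlaceholder restored quality character in discard mode
#' @param optimizeAUs number of access units sampled by the global
#'   optimizer
#' @param localBufferSize local-assembly consensus buffer
#' @param maxParameterSets container bound on distinct parameter sets
#' @return a [CodecContainer-class]
#' @export
gcCompress <- function(records, mode = c("auto", "reference", "local",
                                         "lowlatency"),
                       reference = NULL, auSize = 4096L,
                       parameterMode = c("default", "global", "per-au"),
                       qualityMode = c("verbatim", "discard"),
                       qualityPlaceholder = "I", optimizeAUs = 10L,
                       localBufferSize = 32L, maxParameterSets = 256L) {
    mode <- match.arg(mode)
    parameterMode <- match.arg(parameterMode)
    qualityMode <- match.arg(qualityMode)
    suffixStyle <- attr(records, "idSuffixStyle") %||% "none"
    refs <- if (!is.null(reference)) loadReference(reference) else NULL

    records <- filterUnsupported(records)
    aligned <- vapply(records, function(r) r@recordClass != "U", logical(1))
    ordered <- c(sortByPosition(records[aligned]), records[!aligned])
    aus <- groupRecords(ordered, auSize)

    auMode <- vapply(aus, function(au) {
        if (au@key$recordClass == "U") "lowlatency"
        else if (mode == "lowlatency")
            stop("aligned records cannot use low-latency mode")
        else if (mode == "reference" ||
                 (mode == "auto" && !is.null(refs))) "reference"
        else "local"
    }, character(1))
    dsList <- lapply(seq_along(aus), function(i) {
        au <- aus[[i]]
        refStr <- if (auMode[i] == "reference") {
            if (is.null(refs) || !(au@key$referenceId %in% names(refs)))
                stop("reference-based mode needs the reference FASTA ",
                     "covering '", au@key$referenceId, "'")
            refs[[au@key$referenceId]]
        } else NULL
        encodeAccessUnit(au, auMode[i], refStr, qualityMode,
                         localBufferSize)
    })

    psets <- list()
    auPset <- integer(length(aus))
    if (parameterMode == "default") {
        configs <- list()
        for (ds in dsList)
            for (nm in setdiff(names(ds), names(configs)))
                configs[[nm]] <- defaultStreamConfig()
        psets <- list(new("ParameterSet", id = 0L, configs = configs))
        auPset[] <- 0L
    } else if (parameterMode == "global") {
        sample <- dsList[seq_len(min(optimizeAUs, length(dsList)))]
        opt <- optimizeDataset(list(sample), mode = "global")
        configs <- opt$parameterSet@configs
        for (ds in dsList)
            for (nm in setdiff(names(ds), names(configs)))
                configs[[nm]] <- defaultStreamConfig()
        psets <- list(new("ParameterSet", id = 0L, configs = configs))
        auPset[] <- 0L
    } else { # per-au
        sigs <- character(0)
        for (i in seq_along(dsList)) {
            opt <- optimizeDataset(list(dsList[i]), mode = "global")
            cand <- opt$parameterSet@configs
            sig <- .psetSignature(cand)
            hit <- match(sig, sigs)
            if (!is.na(hit)) {
                auPset[i] <- hit - 1L
            } else if (length(psets) < maxParameterSets) {
                psets[[length(psets) + 1L]] <-
                    new("ParameterSet", id = length(psets), configs = cand)
                sigs <- c(sigs, sig)
                auPset[i] <- length(psets) - 1L
            } else {
                auPset[i] <- .nearestPset(psets, cand, dsList[[i]])
            }
        }
    }

    blocks <- lapply(seq_along(dsList), function(i) {
        cfgSet <- psets[[auPset[i] + 1L]]@configs
        streams <- list()
        for (nm in names(dsList[[i]])) {
            cfg <- cfgSet[[nm]] %||% defaultStreamConfig()
            streams[[nm]] <- compressStream(dsList[[i]][[nm]]$symbols,
                                            dsList[[i]][[nm]]$bits, cfg)
        }
        au <- aus[[i]]
        list(key = au@key, mode = auMode[i], psetId = auPset[i],
             nRecords = length(au@records),
             startPosition = if (is.na(au@startPosition)) 0L
                             else au@startPosition,
             streams = streams)
    })

    # the header lists every referenced contig, with length 0 when only
    # the name is known (local assembly needs no external sequence)
    refNames <- unique(c(names(refs),
                         stats::na.omit(vapply(aus, function(au)
                             au@key$referenceId, character(1)))))
    refTable <- stats::setNames(rep(0L, length(refNames)), refNames)
    if (!is.null(refs)) refTable[names(refs)] <- nchar(refs)
    new("CodecContainer",
        header = list(paired = any(vapply(records, function(r)
                          length(r@segments) == 2L, logical(1))),
                      qualityMode = qualityMode,
                      qualityPlaceholder = qualityPlaceholder,
                      idSuffixStyle = suffixStyle,
                      localBufferSize = as.integer(localBufferSize),
                      references = refTable),
        parameterSets = psets, accessUnits = blocks)
}

# Eviction-to-nearest policy when the parameter-set table is full: reuse
# the existing set agreeing with the candidate configuration on the
# largest raw-symbol mass (ties: lowest id).
.nearestPset <- function(psets, cand, ds) {
    w <- vapply(names(ds), function(nm) length(ds[[nm]]$symbols) *
                    ds[[nm]]$bits / 8, numeric(1))
    score <- vapply(psets, function(ps) {
        sum(w[vapply(names(ds), function(nm) {
            a <- ps@configs[[nm]]
            !is.null(a) && !is.null(cand[[nm]]) &&
                .cfgSignature(a) == .cfgSignature(cand[[nm]])
        }, logical(1))])
    }, numeric(1))
    which.max(score) - 1L
}

#' Decompress a container back into genomic records
#'
#' @param container a [CodecContainer-class] (from [gcCompress()] or
#'   [readContainer()])
#' @param reference reference FASTA; required only when the container
#'   holds reference-based access units
#' @return list of [GenomicRecord-class], access units concatenated in
#'   container order; the recorded identifier-suffix style is attached as
#'   an attribute
#' @export
gcDecompress <- function(container, reference = NULL) {
    hdr <- container@header
    refs <- if (!is.null(reference)) loadReference(reference) else NULL
    out <- list()
    for (blk in container@accessUnits) {
        cfgSet <- container@parameterSets[[blk$psetId + 1L]]@configs
        streams <- list()
        for (nm in names(blk$streams)) {
            cfg <- cfgSet[[nm]] %||% defaultStreamConfig()
            streams[[nm]] <- list(
                symbols = decompressStream(blk$streams[[nm]], streamBits(nm),
                                           cfg),
                bits = streamBits(nm))
        }
        refStr <- if (blk$mode == "reference") {
            if (is.null(refs) || !(blk$key$referenceId %in% names(refs)))
                stop("decoding needs the reference FASTA covering '",
                     blk$key$referenceId, "'")
            refs[[blk$key$referenceId]]
        } else NULL
        out <- c(out, decodeAccessUnit(streams, blk$key, blk$nRecords,
                                       blk$mode, refStr, hdr$qualityMode,
                                       hdr$qualityPlaceholder,
                                       hdr$localBufferSize))
    }
    attr(out, "idSuffixStyle") <- hdr$idSuffixStyle
    out
}
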
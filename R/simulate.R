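# Synthetic FASTQ/SAM generator: the test substrate for the whole
# package. Produces a uniform random reference and reads sampled from it
# with controlled substitution / insertion / deletion / soft-clip rates,
# a choice of quality models (constant, 8-level binned as in patterned
# flow-cell chemistry, full range) and identifier templates with
# incrementing numeric fields (exercising the MATCH/DELTA token coding).
# Fully deterministic for a fixed seed.

#' Generate a uniform random reference contig
#'
#' @param length contig length (>= 1)
#' @param seed optional RNG seed
#' @param name contig name
#' @return named character vector of length one (contig string)
#' @export
simulateReference <- function(length, seed = NULL, name = "chrS") {
    if (length < 1L) stop("reference length must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    out <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                 collapse = "")
    stats::setNames(out, name)
}

.QUALITY_BINS <- c(2L, 12L, 18L, 24L, 30L, 35L, 38L, 40L)
.QUALITY_BIN_W <- c(0.01, 0.02, 0.03, 0.05, 0.09, 0.20, 0.30, 0.30)

.simQualities <- function(n, L, model) {
    switch(model,
        constant = rep.int(strrep("I", L), n), # Phred 40
        binned8 = vapply(seq_len(n), function(i)
            intToUtf8(sample(.QUALITY_BINS, L, replace = TRUE,
                             prob = .QUALITY_BIN_W) + 33L), character(1)),
        fullrange = vapply(seq_len(n), function(i)
            intToUtf8(sample(0:41, L, replace = TRUE) + 33L), character(1)),
        stop("unknown quality model: ", model))
}

.simIds <- function(n, pattern) {
    fields <- list(i = seq_len(n),
                   x = 1000L + (seq_len(n) - 1L) %/% 97L,
                   y = 2000L + (seq_len(n) - 1L) %% 97L)
    m <- gregexpr("\\{(i|x|y)\\}", pattern)[[1]]
    used <- if (m[1] == -1L) character(0)
            else substring(pattern, m + 1L, m + attr(m, "match.length") - 2L)
    fmt <- gsub("\\{(i|x|y)\\}", "%d", pattern)
    if (!length(used)) return(rep.int(fmt, n))
    do.call(sprintf, c(list(fmt), fields[used]))
}

.OTHER_BASES <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                     G = c("A", "C", "T"), T = c("A", "C", "G"))

# substitute bases at 0-based offsets `off` within `bases`; returns
# list(bases=, payload=) with the substituted characters
.applySubs <- function(bases, off, toN) {
    b <- strsplit(bases, "", fixed = TRUE)[[1]]
    payload <- character(length(off))
    for (k in seq_along(off)) {
        orig <- b[off[k] + 1L]
        payload[k] <- if (toN[k]) "N"
                      else sample(.OTHER_BASES[[orig]] %||% c("A", "C", "G"),
                                  1L)
        b[off[k] + 1L] <- payload[k]
    }
    list(bases = paste(b, collapse = ""), payload = payload)
}

#' Simulate sequencing reads with truth alignments
#'
#' Reads start uniformly on the reference. Substitutions occur per base at
#' `substitutionRate` (a fraction `nRate` of them writes 'N'); insertion
#' and deletion events occur per read at the given rates with lengths 1-3;
#' `clipRate` adds a random 1-5 base soft clip at one read end. The truth
#' alignments (position, strand, edit list) are attached to every record,
#' so the returned records are directly compressible and also writable as
#' FASTQ ([writeFastqRecords()]) or SAM ([writeSamRecords()]).
#'
#' @param reference named contig vector from [simulateReference()] (or any
#'   [loadReference()] input)
#' @param nReads number of records
#' @param readLength bases per segment
#' @param paired generate mate pairs (insert size ~ N(300, 30), mate 2 on
#'   the reverse strand)
#' @param substitutionRate per-base substitution probability
#' @param insertionRate,deletionRate per-read indel event probabilities
#' @param clipRate per-read soft-clip probability
#' @param nRate fraction of substitutions writing the unknown base N
#' @param qualityModel `"binned8"` (default), `"constant"` or
#'   `"fullrange"`
#' @param idPattern identifier template; `{i}`, `{x}`, `{y}` expand to
#'   incrementing fields
#' @param seed optional RNG seed
#' @return list of [GenomicRecord-class] with truth alignments
#' @export
simulateReads <- function(reference, nReads, readLength = 100L,
                          paired = FALSE, substitutionRate = 0.005,
                          insertionRate = 0, deletionRate = 0,
                          clipRate = 0, nRate = 0,
                          qualityModel = c("binned8", "constant",
                                           "fullrange"),
                          idPattern = "SIM:1:{x}:{y}", seed = NULL) {
    qualityModel <- match.arg(qualityModel)
    if (!is.null(seed)) set.seed(seed)
    refs <- loadReference(reference)
    refName <- names(refs)[1]
    refStr <- refs[[1]]
    refLen <- nchar(refStr)
    margin <- 40L
    if (readLength + margin >= refLen)
        stop("reference too short for the requested read length")
    ids <- .simIds(nReads, idPattern)
    nseg <- if (paired) 2L else 1L
    quals <- .simQualities(nReads * nseg, readLength, qualityModel)
    maxStart <- refLen - readLength - margin
    starts <- sample.int(maxStart, nReads, replace = TRUE) - 1L
    strands <- runif(nReads) < 0.5
    if (paired) {
        insert <- pmax(readLength + 5L,
                       as.integer(round(rnorm(nReads, 300, 30))))
        starts2 <- pmin(starts + insert, refLen - readLength - margin)
    }
    simpleCase <- insertionRate == 0 && deletionRate == 0 && clipRate == 0

    oneSegment <- function(start, strand) {
        if (simpleCase) {
            bases <- substr(refStr, start + 1L, start + readLength)
            nSub <- rbinom(1L, readLength, substitutionRate)
            edits <- .emptyEdits
            if (nSub > 0L) {
                off <- sort(sample.int(readLength, nSub)) - 1L
                toN <- runif(nSub) < nRate
                sub <- .applySubs(bases, off, toN)
                bases <- sub$bases
                edits <- data.frame(kind = "SUBSTITUTION", readOffset = off,
                                    payload = sub$payload, length = 1L,
                                    stringsAsFactors = FALSE)
            }
            return(list(bases = bases,
                        alignment = list(referenceId = refName,
                                         position = start,
                                         reverseStrand = strand,
                                         edits = edits)))
        }
        # general path: decide the clip first, then walk the reference
        # over the aligned portion, injecting events
        clipLen <- if (runif(1) < clipRate) sample.int(5L, 1L) else 0L
        clipAtStart <- clipLen > 0L && runif(1) < 0.5
        alignedLen <- readLength - clipLen
        edits <- list()
        out <- character(alignedLen)
        readOff <- 0L
        refOff <- start
        insAt <- if (runif(1) < insertionRate && alignedLen > 3L)
                     sample.int(alignedLen - 2L, 1L) else -1L
        delAt <- if (runif(1) < deletionRate && alignedLen > 3L)
                     sample.int(alignedLen - 2L, 1L) else -1L
        while (readOff < alignedLen) {
            if (readOff == insAt && readOff > 0L) {
                len <- min(sample.int(3L, 1L), alignedLen - readOff)
                pay <- paste(sample(c("A", "C", "G", "T"), len,
                                    replace = TRUE), collapse = "")
                edits[[length(edits) + 1L]] <- list(
                    kind = "INSERTION", readOffset = readOff, payload = pay,
                    length = len)
                out[(readOff + 1L):(readOff + len)] <-
                    strsplit(pay, "", fixed = TRUE)[[1]]
                readOff <- readOff + len
                insAt <- -1L
                next
            }
            if (readOff == delAt && readOff > 0L) {
                len <- sample.int(3L, 1L)
                edits[[length(edits) + 1L]] <- list(
                    kind = "DELETION", readOffset = readOff, payload = "",
                    length = len)
                refOff <- refOff + len
                delAt <- -1L
                next
            }
            b <- substr(refStr, refOff + 1L, refOff + 1L)
            if (runif(1) < substitutionRate) {
                pay <- if (runif(1) < nRate) "N"
                       else sample(.OTHER_BASES[[b]], 1L)
                edits[[length(edits) + 1L]] <- list(
                    kind = "SUBSTITUTION", readOffset = readOff,
                    payload = pay, length = 1L)
                b <- pay
            }
            out[readOff + 1L] <- b
            readOff <- readOff + 1L
            refOff <- refOff + 1L
        }
        bases <- paste(out, collapse = "")
        if (clipLen > 0L) {
            pay <- paste(sample(c("A", "C", "G", "T"), clipLen,
                                replace = TRUE), collapse = "")
            if (clipAtStart) {
                bases <- paste0(pay, bases)
                edits <- lapply(edits, function(e) {
                    e$readOffset <- e$readOffset + clipLen
                    e
                })
                edits <- c(list(list(kind = "SOFTCLIP", readOffset = 0L,
                                     payload = pay, length = clipLen)),
                           edits)
            } else {
                bases <- paste0(bases, pay)
                edits <- c(edits, list(list(
                    kind = "SOFTCLIP", readOffset = alignedLen,
                    payload = pay, length = clipLen)))
            }
        }
        edits <- if (!length(edits)) .emptyEdits else
            do.call(rbind, lapply(edits, function(e)
                data.frame(kind = e$kind, readOffset = e$readOffset,
                           payload = e$payload, length = e$length,
                           stringsAsFactors = FALSE)))
        list(bases = bases,
             alignment = list(referenceId = refName, position = start,
                              reverseStrand = strand, edits = edits))
    }

    records <- vector("list", nReads)
    for (i in seq_len(nReads)) {
        s1 <- oneSegment(starts[i], strands[i])
        segs <- list(list(bases = s1$bases, qualities = quals[i]))
        als <- list(s1$alignment)
        if (paired) {
            s2 <- oneSegment(starts2[i], !strands[i])
            segs[[2]] <- list(bases = s2$bases,
                              qualities = quals[nReads + i])
            als[[2]] <- s2$alignment
        }
        rec <- new("GenomicRecord", identifier = ids[i], segments = segs,
                   alignments = als, recordClass = "U")
        rec@recordClass <- classifyRecord(rec)
        records[[i]] <- rec
    }
    attr(records, "idSuffixStyle") <- if (paired) "slash" else "none"
    records
}
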
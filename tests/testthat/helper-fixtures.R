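# Shared fixture builders and independent oracles. All fixtures are
# generated in code; no data files.

# Order-free SAM projection of a record list (the pipeline regroups
# records into access units, so byte comparisons are order-insensitive).
samProjection <- function(records, refLengths = NULL) {
    f <- tempfile(fileext = ".sam")
    on.exit(unlink(f))
    writeSamRecords(records, f, refLengths)
    sort(readLines(f)[-seq_len(1L + length(refLengths))])
}

mkEdits <- function(kind = character(0), readOffset = integer(0),
                    payload = character(0), length = integer(0)) {
    data.frame(kind = kind, readOffset = as.integer(readOffset),
               payload = payload, length = as.integer(length),
               stringsAsFactors = FALSE)
}

# aligned single-segment record
mkAligned <- function(id, bases, position, ref = "chrS", edits = mkEdits(),
                      strand = FALSE, qualities = strrep("I", nchar(bases))) {
    GenomicRecord(id, list(list(bases = bases, qualities = qualities)),
                  list(list(referenceId = ref, position = as.integer(position),
                            reverseStrand = strand, edits = edits)))
}

mkUnaligned <- function(id, bases, qualities = strrep("I", nchar(bases))) {
    GenomicRecord(id, list(list(bases = bases, qualities = qualities)))
}

mkAU <- function(records, paired = FALSE, ref = "chrS", class = NULL) {
    cls <- if (is.null(class)) recordClass(records[[1]]) else class
    new("AccessUnit",
        key = list(recordClass = cls, paired = paired,
                   referenceId = if (cls == "U") NA_character_ else ref),
        records = records, auIndex = 0L,
        startPosition = if (cls == "U") NA_integer_
                        else alignments(records[[1]])[[1]]$position)
}

# ---- independent brute-force oracles ----------------------------------

equalityOracle <- function(seq) {
    flags <- integer(length(seq))
    res <- integer(0)
    prev <- 0L
    for (i in seq_along(seq)) {
        if (seq[i] == prev) flags[i] <- 1L
        else {
            flags[i] <- 0L
            res <- c(res, if (seq[i] < prev) seq[i] else seq[i] - 1L)
            prev <- seq[i]
        }
    }
    list(flags = flags, residuals = res)
}

rleRunsOracle <- function(seq) {
    # maximal equal runs by direct scan
    if (!length(seq)) return(list(lengths = integer(0), values = integer(0)))
    r <- rle(seq)
    list(lengths = r$lengths, values = r$values)
}

rleOracle <- function(seq, G) {
    runs <- rleRunsOracle(seq)
    lengths <- integer(0)
    for (L in runs$lengths) {
        n <- (L - 1L) %/% G
        r <- L - n * G
        lengths <- c(lengths, rep.int(G, n), r - 1L)
    }
    list(lengths = lengths, symbols = runs$values)
}

matchOracle <- function(seq, B) {
    ptrs <- integer(0); lens <- integer(0); lits <- integer(0)
    i <- 1L
    n <- length(seq)
    while (i <= n) {
        lo <- max(1L, i - B)
        best <- 0L; bestJ <- NA_integer_
        maxL <- min(B, n - i + 1L)
        for (j in lo:(i - 1L)) {
            if (j >= i) break
            cap <- min(maxL, i - j)
            l <- 0L
            while (l < cap && seq[j + l] == seq[i + l]) l <- l + 1L
            if (l >= 2L && l > best) { best <- l; bestJ <- j }
        }
        if (best >= 2L) {
            ptrs <- c(ptrs, bestJ - lo)
            lens <- c(lens, best)
            i <- i + best
        } else {
            lens <- c(lens, 0L)
            lits <- c(lits, seq[i])
            i <- i + 1L
        }
    }
    list(pointers = ptrs, lengths = lens, literals = lits)
}

# random symbol stream with occasional runs (exercises all transforms)
randomStream <- function(n, bits, runBias = 0.3) {
    lim <- min(2^bits - 1, 2^20)
    v <- sample.int(lim + 1L, n, replace = TRUE) - 1L
    if (n > 1L && runBias > 0) {
        rep_idx <- which(stats::runif(n - 1L) < runBias)
        for (i in rep_idx) v[i + 1L] <- v[i]
    }
    as.integer(v)
}
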
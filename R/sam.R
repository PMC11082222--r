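# SAM text I/O. No installed R package parses SAM *text* (Rsamtools and
# friends read BAM), so the line format is handled here; CIGAR semantics
# follow the SAM v1.6 specification. BAM users convert with `samtools view`
# first. Optional tags are discarded; secondary (0x100) and supplementary
# (0x800) lines are dropped before mate joining.

#' Load a reference FASTA as named contig strings
#'
#' @param reference FASTA path, a `Biostrings::DNAStringSet`, or a named
#'   character vector of contig sequences
#' @return named character vector (upper case)
#' @export
loadReference <- function(reference) {
    if (is.character(reference) && length(reference) == 1L &&
        is.null(names(reference)) && file.exists(reference))
        reference <- Biostrings::readDNAStringSet(reference)
    if (methods::is(reference, "DNAStringSet")) {
        out <- toupper(as.character(reference))
        names(out) <- sub("\\s.*$", "", names(reference))
        return(out)
    }
    if (is.character(reference) && !is.null(names(reference)))
        return(toupper(reference))
    stop("reference must be a FASTA path, DNAStringSet or named character vector")
}

.parseCigar <- function(cigar) {
    if (cigar == "*") return(NULL)
    m <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    if (!length(m) || sum(nchar(m)) != nchar(cigar))
        stop("malformed CIGAR: ", cigar)
    list(len = as.integer(sub("[MIDNSHP=X]$", "", m)),
         op = substring(m, nchar(m), nchar(m)))
}

# Build the edit list for one aligned SAM line. Substitutions are derived
# by comparing the read to the reference (MD tags are discarded with all
# other tags); M/=/X ops therefore require the reference.
.samEdits <- function(bases, cigar, pos0, refStr) {
    ops <- .parseCigar(cigar)
    edits <- list()
    cursorRead <- 0L
    cursorRef <- pos0
    for (i in seq_along(ops$op)) {
        op <- ops$op[i]
        len <- ops$len[i]
        if (op %in% c("M", "=", "X")) {
            if (is.null(refStr))
                stop("CIGAR match ops need the reference to derive substitutions; ",
                     "supply a reference FASTA")
            readPart <- substr(bases, cursorRead + 1L, cursorRead + len)
            refPart <- substr(refStr, cursorRef + 1L, cursorRef + len)
            if (nchar(refPart) < len)
                stop("alignment extends beyond the reference end")
            if (readPart != refPart) {
                rb <- strsplit(readPart, "", fixed = TRUE)[[1]]
                fb <- strsplit(refPart, "", fixed = TRUE)[[1]]
                mis <- which(rb != fb)
                for (k in mis)
                    edits[[length(edits) + 1L]] <- list(
                        kind = "SUBSTITUTION",
                        readOffset = cursorRead + k - 1L,
                        payload = rb[k], length = 1L)
            }
            cursorRead <- cursorRead + len
            cursorRef <- cursorRef + len
        } else if (op == "I") {
            edits[[length(edits) + 1L]] <- list(
                kind = "INSERTION", readOffset = cursorRead,
                payload = substr(bases, cursorRead + 1L, cursorRead + len),
                length = len)
            cursorRead <- cursorRead + len
        } else if (op == "D") {
            edits[[length(edits) + 1L]] <- list(
                kind = "DELETION", readOffset = cursorRead, payload = "",
                length = len)
            cursorRef <- cursorRef + len
        } else if (op == "S") {
            edits[[length(edits) + 1L]] <- list(
                kind = "SOFTCLIP", readOffset = cursorRead,
                payload = substr(bases, cursorRead + 1L, cursorRead + len),
                length = len)
            cursorRead <- cursorRead + len
        } else if (op == "H") {
            warning("hard-clipped bases (CIGAR H) are dropped")
        } else {
            stop("unsupported CIGAR operation '", op, "'")
        }
    }
    if (cursorRead != nchar(bases))
        stop("CIGAR does not span the read: ", cigar)
    if (!length(edits)) return(.emptyEdits)
    do.call(rbind, lapply(edits, function(e)
        data.frame(kind = e$kind, readOffset = e$readOffset,
                   payload = e$payload, length = e$length,
                   stringsAsFactors = FALSE)))
}

#' Read SAM text into genomic records
#'
#' The input must be sorted (grouped) by record identifier so that mates
#' can be joined in one pass; an identifier that reappears after a
#' different one raises an error. SAM's 1-based positions become 0-based.
#' Substitution edits are derived by comparing the read to the reference;
#' without a reference, lines whose CIGAR contains match ops raise.
#'
#' @param path SAM text file
#' @param reference optional reference (see [loadReference()])
#' @return list of [GenomicRecord-class]
#' @export
readSamRecords <- function(path, reference = NULL) {
    refs <- if (!is.null(reference)) loadReference(reference) else NULL
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "@")]
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(list())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    qname <- vapply(fields, `[`, character(1), 1L)
    flag <- as.integer(vapply(fields, `[`, character(1), 2L))
    keep <- bitwAnd(flag, bitwOr(0x100L, 0x800L)) == 0L
    fields <- fields[keep]
    qname <- qname[keep]
    flag <- flag[keep]
    if (!length(fields)) return(list())
    runs <- rle(qname)
    if (anyDuplicated(runs$values))
        stop("SAM input is not sorted by record identifier: '",
             runs$values[anyDuplicated(runs$values)],
             "' appears in separate groups; sort by name first")
    oneSegment <- function(f) {
        fl <- as.integer(f[2])
        bases <- toupper(f[10])
        baseCodes(bases) # validates the alphabet
        qual <- if (f[11] == "*") "" else f[11]
        seg <- list(bases = bases, qualities = qual)
        if (bitwAnd(fl, 0x4L) != 0L || f[3] == "*")
            return(list(segment = seg, alignment = NULL, flag = fl))
        pos0 <- as.integer(f[4]) - 1L
        refStr <- if (!is.null(refs)) {
            if (!(f[3] %in% names(refs)))
                stop("reference sequence '", f[3], "' not in the FASTA")
            refs[[f[3]]]
        } else NULL
        al <- list(referenceId = f[3], position = pos0,
                   reverseStrand = bitwAnd(fl, 0x10L) != 0L,
                   edits = .samEdits(bases, f[6], pos0, refStr))
        list(segment = seg, alignment = al, flag = fl)
    }
    records <- vector("list", length(runs$values))
    idx <- cumsum(runs$lengths)
    start <- idx - runs$lengths + 1L
    for (g in seq_along(runs$values)) {
        grp <- fields[start[g]:idx[g]]
        segs <- lapply(grp, oneSegment)
        if (length(segs) == 1L) {
            s <- segs[[1]]
            rec <- new("GenomicRecord", identifier = runs$values[g],
                       segments = list(s$segment),
                       alignments = list(s$alignment), recordClass = "U")
        } else if (length(segs) == 2L) {
            firstFlag <- vapply(segs, function(s)
                bitwAnd(s$flag, 0x40L) != 0L, logical(1))
            if (sum(firstFlag) == 1L && firstFlag[2]) segs <- rev(segs)
            rec <- new("GenomicRecord", identifier = runs$values[g],
                       segments = lapply(segs, `[[`, "segment"),
                       alignments = lapply(segs, `[[`, "alignment"),
                       recordClass = "U")
        } else {
            stop("more than two primary lines share identifier '",
                 runs$values[g], "'")
        }
        rec@recordClass <- classifyRecord(rec)
        records[[g]] <- rec
    }
    records
}

.cigarFromEdits <- function(rlen, edits) {
    if (!nrow(edits)) return(paste0(rlen, "M"))
    ops <- character(0)
    lens <- integer(0)
    push <- function(op, n) {
        if (n <= 0L) return()
        if (length(ops) && ops[length(ops)] == op) {
            lens[length(lens)] <<- lens[length(lens)] + n
        } else {
            ops <<- c(ops, op)
            lens <<- c(lens, n)
        }
    }
    cursorRead <- 0L
    for (i in seq_len(nrow(edits))) {
        gap <- edits$readOffset[i] - cursorRead
        push("M", gap)
        cursorRead <- cursorRead + gap
        switch(edits$kind[i],
            SUBSTITUTION = { push("M", 1L); cursorRead <- cursorRead + 1L },
            INSERTION = { push("I", edits$length[i])
                          cursorRead <- cursorRead + edits$length[i] },
            DELETION = push("D", edits$length[i]),
            SOFTCLIP = { push("S", edits$length[i])
                         cursorRead <- cursorRead + edits$length[i] })
    }
    push("M", rlen - cursorRead)
    paste0(lens, ops, collapse = "")
}

#' Write genomic records as SAM text
#'
#' Emits a minimal header (`@HD`, `@SQ` from `refLengths`) and one line per
#' segment. Normalizations applied by design: MAPQ is 255, TLEN is 0,
#' optional tags are absent, and substitutions are implicit in `M` ops.
#'
#' @param records list of [GenomicRecord-class]
#' @param path output file
#' @param refLengths named integer vector of reference lengths (for `@SQ`)
#' @return invisibly, the number of lines written
#' @export
writeSamRecords <- function(records, path, refLengths = NULL) {
    hdr <- "@HD\tVN:1.6\tSO:unknown"
    if (!is.null(refLengths))
        hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", names(refLengths),
                              as.integer(refLengths)))
    lines <- character(0)
    for (rec in records) {
        nseg <- length(rec@segments)
        for (i in seq_len(nseg)) {
            seg <- rec@segments[[i]]
            al <- rec@alignments[[i]]
            mate <- if (nseg == 2L) rec@alignments[[3L - i]] else NULL
            fl <- 0L
            if (nseg == 2L)
                fl <- bitwOr(fl, bitwOr(0x1L, if (i == 1L) 0x40L else 0x80L))
            if (is.null(al)) fl <- bitwOr(fl, 0x4L)
            else if (al$reverseStrand) fl <- bitwOr(fl, 0x10L)
            if (nseg == 2L) {
                if (is.null(mate)) fl <- bitwOr(fl, 0x8L)
                else if (mate$reverseStrand) fl <- bitwOr(fl, 0x20L)
            }
            rname <- if (is.null(al)) "*" else al$referenceId
            pos <- if (is.null(al)) 0L else al$position + 1L
            cig <- if (is.null(al)) "*"
                   else .cigarFromEdits(nchar(seg$bases), al$edits)
            rnext <- if (nseg == 2L && !is.null(mate)) "=" else "*"
            pnext <- if (nseg == 2L && !is.null(mate)) mate$position + 1L else 0L
            qual <- if (nzchar(seg$qualities)) seg$qualities else "*"
            lines <- c(lines, paste(rec@identifier, fl, rname, pos, 255L,
                                    cig, rnext, pnext, 0L, seg$bases, qual,
                                    sep = "\t"))
        }
    }
    writeLines(c(hdr, lines), path)
    invisible(length(lines))
}
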
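# FASTQ I/O. Parsing is delegated to Biostrings; this layer adds mate
# pairing, identifier-suffix normalization and the 4-line writer used for
# byte-identical round trips.

.detectSuffixStyle <- function(id1, id2) {
    if (endsWith(id1, "/1") && endsWith(id2, "/2")) return("slash")
    t1 <- strsplit(id1, " ", fixed = TRUE)[[1]]
    t2 <- strsplit(id2, " ", fixed = TRUE)[[1]]
    if (length(t1) == 2L && length(t2) == 2L && t1[1] == t2[1] &&
        t1[2] == "1" && t2[2] == "2") return("space")
    if (id1 == id2) return("none")
    NA_character_
}

.stripSuffix <- function(id, style) {
    switch(style,
        none = id,
        slash = sub("/[12]$", "", id),
        space = sub(" [12]$", "", id))
}

#' Apply a recorded mate-suffix style to a bare identifier
#' @param id identifier without mate suffix
#' @param mate 1 or 2
#' @param style `"none"`, `"slash"` or `"space"`
#' @return decorated identifier
#' @export
applySuffix <- function(id, mate, style) {
    switch(style,
        none = id,
        slash = paste0(id, "/", mate),
        space = paste0(id, " ", mate))
}

.readOneFastq <- function(path) {
    out <- tryCatch(
        suppressWarnings({
            qs <- Biostrings::readQualityScaledDNAStringSet(path)
            list(ids = names(qs),
                 bases = unname(as.character(qs)),
                 quals = unname(as.character(Biostrings::quality(qs))))
        }),
        error = function(e) {
            # locate the offending quartet for a line-numbered message
            lines <- readLines(path, warn = FALSE)
            n <- length(lines)
            bad <- if (n %% 4L != 0L) (n %/% 4L) * 4L + 1L else {
                at <- which(!startsWith(lines[seq(1L, n, by = 4L)], "@"))
                plus <- which(!startsWith(lines[seq(3L, n, by = 4L)], "+"))
                if (length(at)) (at[1] - 1L) * 4L + 1L
                else if (length(plus)) (plus[1] - 1L) * 4L + 3L
                else 1L
            }
            stop(sprintf("malformed FASTQ quartet near line %d of %s: %s",
                         bad, path, conditionMessage(e)), call. = FALSE)
        })
    out
}

#' Read FASTQ into genomic records
#'
#' Single-file input yields unpaired class-U records. With two files the
#' mates are paired positionally (record i of file 1 with record i of file
#' 2); the identifier is taken from the first mate with a recognized
#' trailing mate suffix (`"/1"`/`"/2"` or `" 1"`/`" 2"`) stripped. The
#' detected suffix style is attached as `attr(, "idSuffixStyle")` so that
#' decompression can regenerate it.
#'
#' @param path FASTQ file (first mate)
#' @param path2 optional second-mate FASTQ file
#' @return list of [GenomicRecord-class] (class U, no alignments)
#' @export
readFastqRecords <- function(path, path2 = NULL) {
    f1 <- .readOneFastq(path)
    if (is.null(path2)) {
        recs <- lapply(seq_along(f1$ids), function(i)
            new("GenomicRecord", identifier = f1$ids[i],
                segments = list(list(bases = f1$bases[i],
                                     qualities = f1$quals[i])),
                alignments = list(NULL), recordClass = "U"))
        attr(recs, "idSuffixStyle") <- "none"
        return(recs)
    }
    f2 <- .readOneFastq(path2)
    if (length(f1$ids) != length(f2$ids))
        stop(sprintf("mate-count mismatch: %d records in %s, %d in %s",
                     length(f1$ids), path, length(f2$ids), path2))
    if (!length(f1$ids)) {
        recs <- list()
        attr(recs, "idSuffixStyle") <- "none"
        return(recs)
    }
    style <- .detectSuffixStyle(f1$ids[1], f2$ids[1])
    if (is.na(style))
        stop("pairing error: mate identifiers differ beyond a recognized ",
             "'/1','/2' or ' 1',' 2' suffix: ", f1$ids[1], " vs ", f2$ids[1])
    recs <- lapply(seq_along(f1$ids), function(i)
        new("GenomicRecord",
            identifier = .stripSuffix(f1$ids[i], style),
            segments = list(list(bases = f1$bases[i], qualities = f1$quals[i]),
                            list(bases = f2$bases[i], qualities = f2$quals[i])),
            alignments = list(NULL, NULL), recordClass = "U"))
    attr(recs, "idSuffixStyle") <- style
    recs
}

#' Write genomic records as 4-line FASTQ
#'
#' Paired records are written as two synchronized files with the recorded
#' mate-suffix style re-applied. Records without stored qualities receive
#' the placeholder character.
#'
#' @param records list of [GenomicRecord-class]
#' @param path output FASTQ (first mate)
#' @param path2 second-mate output (required when records are paired)
#' @param suffixStyle mate-suffix style to regenerate (`"none"`, `"slash"`,
#'   `"space"`); defaults to the records' `idSuffixStyle` attribute
#' @param qualityPlaceholder character used when a segment has no qualities
#' @return invisibly, the number of records written
#' @export
writeFastqRecords <- function(records, path, path2 = NULL,
                              suffixStyle = NULL, qualityPlaceholder = "I") {
    if (is.null(suffixStyle))
        suffixStyle <- attr(records, "idSuffixStyle") %||% "none"
    paired <- length(records) > 0L && length(records[[1]]@segments) == 2L
    if (paired && is.null(path2))
        stop("paired records need a second output file")
    segLines <- function(mate, p) {
        lines <- character(4L * length(records))
        for (i in seq_along(records)) {
            rec <- records[[i]]
            seg <- rec@segments[[mate]]
            q <- seg$qualities
            if (!nzchar(q))
                q <- strrep(qualityPlaceholder, nchar(seg$bases))
            id <- if (paired) applySuffix(rec@identifier, mate, suffixStyle)
                  else rec@identifier
            lines[4L * i - 3L] <- paste0("@", id)
            lines[4L * i - 2L] <- seg$bases
            lines[4L * i - 1L] <- "+"
            lines[4L * i] <- q
        }
        writeLines(lines, p)
    }
    segLines(1L, path)
    if (paired) segLines(2L, path2)
    invisible(length(records))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
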
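# FASTQ/SAM I/O, record classification, filtering and sorting.

test_that("a FASTQ quartet maps onto a class-U record", {
    f <- tempfile(fileext = ".fastq")
    writeLines(c("@r1", "ACGT", "+", "!!!!"), f)
    recs <- readFastqRecords(f)
    expect_length(recs, 1L)
    expect_equal(recordId(recs[[1]]), "r1")
    expect_equal(segments(recs[[1]])[[1]]$bases, "ACGT")
    expect_equal(segments(recs[[1]])[[1]]$qualities, "!!!!")
    expect_equal(recordClass(recs[[1]]), "U")
    expect_null(alignments(recs[[1]])[[1]])
})

test_that("empty FASTQ yields an empty stream", {
    f <- tempfile(fileext = ".fastq")
    file.create(f)
    expect_length(readFastqRecords(f), 0L)
})

test_that("malformed quartets raise a line-numbered parse error", {
    f <- tempfile(fileext = ".fastq")
    writeLines(c("@r1", "ACGT", "+", "!!!!", "@r2", "ACGT"), f)
    expect_error(readFastqRecords(f), "line 5")
})

test_that("paired FASTQ merges mates and strips the suffix style", {
    ref <- simulateReference(3000, seed = 11)
    recs <- simulateReads(ref, 100, readLength = 50, paired = TRUE,
                          seed = 12)
    urecs <- lapply(recs, function(r) {
        r@alignments <- vector("list", 2L)
        r@recordClass <- "U"
        r
    })
    f1 <- tempfile(); f2 <- tempfile()
    writeFastqRecords(urecs, f1, f2, suffixStyle = "slash")
    # independent oracle: record count = line count / 4
    expect_equal(length(readLines(f1)) / 4, 100)
    back <- readFastqRecords(f1, f2)
    expect_length(back, 100L)
    expect_true(all(vapply(back, function(r) length(segments(r)) == 2L,
                           logical(1))))
    expect_equal(attr(back, "idSuffixStyle"), "slash")
    expect_equal(vapply(back, recordId, character(1)),
                 vapply(urecs, recordId, character(1)))
    # byte-identical writer round trip
    g1 <- tempfile(); g2 <- tempfile()
    writeFastqRecords(back, g1, g2)
    expect_identical(readLines(g1), readLines(f1))
    expect_identical(readLines(g2), readLines(f2))
    # mate-count mismatch
    f3 <- tempfile()
    writeLines(readLines(f2)[1:4], f3)
    expect_error(readFastqRecords(f1, f3), "mate-count mismatch")
})

test_that("SAM lines transcode with reference-derived substitutions", {
    ref <- c(chr1 = paste0(strrep("T", 9), "ACGT", strrep("T", 10)))
    sam <- c("@HD\tVN:1.6",
             "@SQ\tSN:chr1\tLN:23",
             "p1\t0\tchr1\t10\t60\t4M\t*\t0\t0\tACGT\tIIII",
             "p2\t0\tchr1\t10\t60\t4M\t*\t0\t0\tANGT\tIIII",
             "p3\t0\tchr1\t10\t60\t2S2M\t*\t0\t0\tGGAC\tIIII")
    f <- tempfile(fileext = ".sam")
    writeLines(sam, f)
    recs <- readSamRecords(f, ref)
    expect_length(recs, 3L)
    al <- alignments(recs[[1]])[[1]]
    expect_equal(al$position, 9L) # SAM POS 10 -> 0-based 9
    expect_equal(nrow(al$edits), 0L)
    expect_equal(recordClass(recs[[1]]), "P")
    ed2 <- alignments(recs[[2]])[[1]]$edits
    expect_equal(ed2$kind, "SUBSTITUTION")
    expect_equal(ed2$readOffset, 1L)
    expect_equal(ed2$payload, "N")
    expect_equal(recordClass(recs[[2]]), "N")
    ed3 <- alignments(recs[[3]])[[1]]$edits
    expect_equal(ed3$kind[1], "SOFTCLIP")
    expect_equal(recordClass(recs[[3]]), "I")
    # 1-based -> 0-based -> 1-based is the identity
    g <- tempfile(fileext = ".sam")
    writeSamRecords(recs, g, c(chr1 = 23L))
    pos <- as.integer(vapply(strsplit(readLines(g)[-(1:2)], "\t"), `[`,
                             character(1), 4L))
    expect_equal(pos, rep(10L, 3)) # p3's clip does not consume reference
    # mismatch reconstruction without a reference raises
    expect_error(readSamRecords(f, reference = NULL), "reference")
})

test_that("secondary/supplementary lines and unsorted input are rejected", {
    ref <- c(chr1 = strrep("A", 50))
    sam <- c("@SQ\tSN:chr1\tLN:50",
             "r1\t0\tchr1\t1\t60\t4M\t*\t0\t0\tAAAA\tIIII",
             "r1\t256\tchr1\t9\t60\t4M\t*\t0\t0\tAAAA\tIIII",
             "r2\t2048\tchr1\t9\t60\t4M\t*\t0\t0\tAAAA\tIIII")
    f <- tempfile(); writeLines(sam, f)
    recs <- readSamRecords(f, ref)
    expect_length(recs, 1L) # flags 0x100/0x800 discarded before joining
    expect_equal(recordId(recs[[1]]), "r1")
    bad <- c("@SQ\tSN:chr1\tLN:50",
             "r1\t0\tchr1\t1\t60\t4M\t*\t0\t0\tAAAA\tIIII",
             "r2\t0\tchr1\t1\t60\t4M\t*\t0\t0\tAAAA\tIIII",
             "r1\t0\tchr1\t9\t60\t4M\t*\t0\t0\tAAAA\tIIII")
    writeLines(bad, f)
    expect_error(readSamRecords(f, ref), "not sorted")
})

test_that("classification follows the I > M > N > P precedence", {
    expect_equal(recordClass(mkUnaligned("u", "ACGT")), "U")
    expect_equal(recordClass(mkAligned("p", "ACGT", 0)), "P")
    nrec <- mkAligned("n", "ANGT", 0,
                      edits = mkEdits("SUBSTITUTION", 1L, "N", 1L))
    expect_equal(recordClass(nrec), "N")
    mrec <- mkAligned("m", "ANGA", 0,
                      edits = mkEdits(rep("SUBSTITUTION", 2), c(1L, 3L),
                                      c("N", "G"), c(1L, 1L)))
    expect_equal(recordClass(mrec), "M")
    irec <- mkAligned("i", "ACGT", 0,
                      edits = mkEdits(c("SUBSTITUTION", "INSERTION"),
                                      c(1L, 2L), c("N", "G"), c(1L, 1L)))
    expect_equal(recordClass(irec), "I")
    # classification is pure
    expect_equal(classifyRecord(mrec), classifyRecord(mrec))
    # half-mapped pair
    hm <- GenomicRecord("h", list(list(bases = "AC", qualities = "II"),
                                  list(bases = "GT", qualities = "II")),
                        list(list(referenceId = "chr1", position = 0L,
                                  reverseStrand = FALSE, edits = mkEdits()),
                             NULL))
    expect_equal(recordClass(hm), "HM")
})

test_that("filterUnsupported converts HM records to unaligned", {
    hm <- GenomicRecord("h", list(list(bases = "AC", qualities = "II"),
                                  list(bases = "GT", qualities = "II")),
                        list(list(referenceId = "chr1", position = 0L,
                                  reverseStrand = FALSE, edits = mkEdits()),
                             NULL))
    p <- mkAligned("p", "ACGT", 5)
    out <- filterUnsupported(list(hm, p))
    expect_equal(recordClass(out[[1]]), "U")
    expect_true(all(vapply(alignments(out[[1]]), is.null, logical(1))))
    expect_identical(out[[2]], p) # pass-through
    expect_length(out, 2L) # count preserved
})

test_that("position sort is stable, grouped by reference, unaligned last", {
    r5 <- mkAligned("a", "AC", 5); r2 <- mkAligned("b", "AC", 2)
    r9 <- mkAligned("c", "AC", 9)
    s <- sortByPosition(list(r5, r2, r9))
    expect_equal(vapply(s, function(r) alignments(r)[[1]]$position,
                        integer(1)), c(2L, 5L, 9L))
    # equal positions keep input order
    e1 <- mkAligned("e1", "AC", 4); e2 <- mkAligned("e2", "AC", 4)
    s2 <- sortByPosition(list(e1, e2))
    expect_equal(vapply(s2, recordId, character(1)), c("e1", "e2"))
    # mixed references group by reference then position; unaligned last
    x1 <- mkAligned("x1", "AC", 7, ref = "chr2")
    x2 <- mkAligned("x2", "AC", 1, ref = "chr1")
    u <- mkUnaligned("u", "AC")
    s3 <- sortByPosition(list(u, x1, x2))
    expect_equal(vapply(s3, recordId, character(1)), c("x2", "x1", "u"))
})
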
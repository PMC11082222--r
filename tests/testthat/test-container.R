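# Container serialization: determinism, structural round trips,
# corruption detection, and the 256-parameter-set bound.

emptyContainer <- function() {
    new("CodecContainer",
        header = list(paired = FALSE, qualityMode = "verbatim",
                      qualityPlaceholder = "I", idSuffixStyle = "none",
                      localBufferSize = 32L, references = integer(0)),
        parameterSets = list(), accessUnits = list())
}

test_that("an empty dataset serializes to a fixed-size header", {
    p1 <- tempfile(); p2 <- tempfile()
    writeContainer(emptyContainer(), p1)
    writeContainer(emptyContainer(), p2)
    expect_identical(readBin(p1, "raw", 1e4), readBin(p2, "raw", 1e4))
    back <- readContainer(p1)
    expect_length(back@accessUnits, 0L)
    expect_length(back@parameterSets, 0L)
})

test_that("parse-then-rewrite reproduces a container byte-identically", {
    ref <- simulateReference(4000, seed = 71)
    recs <- simulateReads(ref, 150, readLength = 60,
                          substitutionRate = 0.01, seed = 72)
    ctr <- gcCompress(recs, mode = "reference", reference = ref,
                      auSize = 50L, parameterMode = "default")
    p1 <- tempfile(); p2 <- tempfile()
    writeContainer(ctr, p1)
    writeContainer(readContainer(p1), p2)
    expect_identical(readBin(p1, "raw", 1e7), readBin(p2, "raw", 1e7))
    # structural identity
    back <- readContainer(p1)
    expect_equal(length(back@accessUnits), length(ctr@accessUnits))
    expect_equal(back@header$references, ctr@header$references)
    expect_equal(back@parameterSets[[1]]@configs,
                 ctr@parameterSets[[1]]@configs)
})

test_that("more than 256 parameter sets is a hard error before writing", {
    ctr <- emptyContainer()
    ctr@parameterSets <- lapply(0:256, function(i)
        new("ParameterSet", id = i %% 256L,
            configs = list(`qv.0` = genocodec:::defaultStreamConfig())))
    p <- tempfile()
    expect_error(writeContainer(ctr, p), "256 parameter sets")
    expect_false(file.exists(p))
})

test_that("corruption is detected: magic, truncation, checksum", {
    ref <- simulateReference(2000, seed = 73)
    recs <- simulateReads(ref, 40, readLength = 40, seed = 74)
    ctr <- gcCompress(recs, mode = "reference", reference = ref,
                      parameterMode = "default")
    p <- tempfile()
    writeContainer(ctr, p)
    bytes <- readBin(p, "raw", file.size(p))
    flip <- function(b, i) { b[i] <- xor(b[i], as.raw(1)); b }
    bad1 <- tempfile(); writeBin(flip(bytes, 1L), bad1)
    expect_error(readContainer(bad1), "magic")
    bad2 <- tempfile(); writeBin(bytes[1:(length(bytes) - 30L)], bad2)
    expect_error(readContainer(bad2), "truncat")
    # flip one payload byte inside the (single) access unit
    bad3 <- tempfile()
    writeBin(flip(bytes, length(bytes) - 200L), bad3)
    expect_error(readContainer(bad3), "checksum|truncat")
})

test_that("an access unit decodes from its block alone (random access)", {
    ref <- simulateReference(4000, seed = 75)
    recs <- simulateReads(ref, 120, readLength = 50, seed = 76)
    ctr <- gcCompress(recs, mode = "reference", reference = ref,
                      auSize = 30L, parameterMode = "default")
    expect_gt(length(ctr@accessUnits), 1L)
    solo <- ctr
    solo@accessUnits <- ctr@accessUnits[2]
    out <- gcDecompress(solo, reference = ref)
    expect_length(out, ctr@accessUnits[[2]]$nRecords)
})

test_that("the full pipeline is lossless for FASTQ and filtered SAM", {
    ref <- simulateReference(6000, seed = 77)
    recs <- simulateReads(ref, 200, readLength = 70,
                          substitutionRate = 0.01, insertionRate = 0.1,
                          deletionRate = 0.1, clipRate = 0.1, nRate = 0.1,
                          seed = 78)
    refLen <- stats::setNames(nchar(ref), names(ref))
    for (m in c("reference", "local")) {
        ctr <- gcCompress(recs, mode = m,
                          reference = if (m == "reference") ref else NULL,
                          auSize = 64L, parameterMode = "default")
        out <- gcDecompress(ctr,
                            reference = if (m == "reference") ref else NULL)
        expect_identical(samProjection(out, refLen),
                         samProjection(filterUnsupported(recs), refLen),
                         label = m)
    }
    # FASTQ path: byte-identical modulo regrouping order
    f <- tempfile()
    u <- lapply(recs, function(r) {
        r@alignments <- vector("list", 1L); r@recordClass <- "U"; r
    })
    writeFastqRecords(u, f)
    rb <- readFastqRecords(f)
    out <- gcDecompress(gcCompress(rb, parameterMode = "default"))
    g <- tempfile()
    writeFastqRecords(out, g)
    expect_identical(readLines(g), readLines(f)) # one class-U AU: same order
})
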
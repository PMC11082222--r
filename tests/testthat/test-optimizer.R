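# Exhaustive parameter search, loss table and global selection.

test_that("minSize equals a shuffled brute-force enumeration", {
    set.seed(81)
    for (case in 1:4) {
        bits <- sample(c(4L, 8L), 1)
        x <- randomStream(sample(50:200, 1), bits, runBias = 0.5)
        t <- sample(genocodec:::SEQ_TRANSFORMS, 1)
        got <- minSize(x, bits, t)
        # independent enumeration in shuffled order
        streams <- genocodec:::applySequenceTransform(x, bits, t)
        total <- 0
        for (st in streams) {
            cfgs <- validEntropyConfigs(st$bits,
                                        maxSubsymbols(st$symbols, st$bits))
            cfgs <- cfgs[sample(nrow(cfgs)), ]
            sizes <- vapply(seq_len(nrow(cfgs)), function(k)
                length(genocodec:::compressTransformedStream(
                    st$symbols, st$bits, as.list(cfgs[k, ]))) +
                genocodec:::STREAM_OVERHEAD_BYTES, numeric(1))
            total <- total + min(sizes)
        }
        expect_equal(got$bytes, total)
    }
})

test_that("run-length wins on constant streams; empty streams cost overhead", {
    x <- rep(7L, 1000)
    expect_lt(minSize(x, 8L, "RLE")$bytes, minSize(x, 8L, "NONE")$bytes)
    # empty subsequence: every parameter combination costs the same
    e <- minSize(integer(0), 8L, "NONE", returnAll = TRUE)
    expect_true(all(e$allSizes[[1]]$bytes == e$allSizes[[1]]$bytes[1]))
})

test_that("uniform random bytes are essentially incompressible", {
    set.seed(82)
    x <- sample(0:255, 2000, replace = TRUE)
    best <- min(vapply(genocodec:::SEQ_TRANSFORMS, function(t)
        minSize(x, 8L, t)$bytes, numeric(1)))
    expect_gte(best, 0.95 * 2000)
})

test_that("totalMinSize is additive and monotone over sampled AUs", {
    set.seed(83)
    aus <- lapply(1:3, function(i)
        list(`qv.0` = list(symbols = randomStream(300, 8, 0.5), bits = 8L)))
    one <- totalMinSize(aus[1], "qv.0", "NONE")
    expect_equal(one$bytes, minSize(aus[[1]][["qv.0"]]$symbols, 8L,
                                    "NONE")$bytes)
    all3 <- totalMinSize(aus, "qv.0", "NONE")
    expect_equal(all3$bytes,
                 sum(vapply(aus, function(a)
                     minSize(a[["qv.0"]]$symbols, 8L, "NONE")$bytes,
                     numeric(1))))
    expect_gte(totalMinSize(aus, "qv.0", "NONE")$bytes,
               totalMinSize(aus[1:2], "qv.0", "NONE")$bytes)
})

test_that("loss factors follow the printed equations", {
    # hand-built two-file table: t1 sizes (10, 15), t2 sizes (12, 10)
    total <- array(NA_real_, dim = c(1L, 2L, 2L),
                   dimnames = list("s", c("t1", "t2"), NULL))
    total["s", "t1", ] <- c(10, 15)
    total["s", "t2", ] <- c(12, 10)
    lt <- lossFromTotals(total)
    expect_equal(lt$loss["s", "t1", ], c(1.0, 1.5))
    expect_equal(lt$loss["s", "t2", ], c(1.2, 1.0))
    expect_equal(unname(lt$meanLoss["s", ]), c(1.25, 1.1))
    expect_equal(unname(lt$tBest["s"]), "t2")
})

test_that("loss is >= 1 with exactly one optimum per file", {
    set.seed(84)
    files <- lapply(1:2, function(f)
        lapply(1:2, function(i)
            list(`qv.0` = list(symbols = randomStream(200, 8, 0.6),
                               bits = 8L),
                 `flags.0` = list(symbols = randomStream(150, 1),
                                  bits = 1L))))
    lt <- buildLossTable(files)
    expect_true(all(lt$loss >= 1))
    for (s in lt$streams)
        for (fi in 1:2)
            expect_equal(sum(lt$loss[s, , fi] == 1), 1)
    # single file: tBest attains mean loss 1
    lt1 <- buildLossTable(files[1])
    for (s in lt1$streams)
        expect_equal(unname(lt1$meanLoss[s, lt1$tBest[[s]]]), 1)
})

test_that("remaining parameters are chosen by mode with cheap tie-breaks", {
    tpl <- function(order, lut = FALSE)
        list(list(order = order, split = 1L, lut = lut,
                  binarization = "BINARY"))
    expect_equal(selectRemainingParams(list(tpl(2L), tpl(2L), tpl(2L))),
                 list(list(order = 2L, split = 1L, lut = FALSE,
                           binarization = "BINARY")))
    expect_equal(selectRemainingParams(list(tpl(0L), tpl(0L),
                                            tpl(1L)))[[1]]$order, 0L)
    tie <- selectRemainingParams(list(tpl(0L, lut = TRUE), tpl(0L)))
    expect_false(tie[[1]]$lut) # NONE before LUT on ties
    expect_error(selectRemainingParams(list()), "no parameter")
})

test_that("global mode yields exactly one configuration per subsequence", {
    set.seed(85)
    ref <- simulateReference(8000, seed = 85)
    files <- lapply(1:2, function(f) {
        recs <- simulateReads(ref, 200, readLength = 40,
                              substitutionRate = 0.01, seed = 85 + f)
        aus <- groupRecords(sortByPosition(recs), 50L)
        lapply(aus[seq_len(min(4, length(aus)))], function(au)
            encodeAccessUnit(au, "reference", ref[[1]]))
    })
    opt <- optimizeDataset(files, mode = "global", report = TRUE)
    allStreams <- unique(unlist(lapply(files, function(f)
        unlist(lapply(f, names)))))
    expect_setequal(names(opt$parameterSet@configs), allStreams)
    # progress report is non-increasing from worst to best
    for (s in unique(opt$report$subsequence)) {
        v <- opt$report$bytes[opt$report$subsequence == s]
        expect_true(all(diff(v) <= 0))
    }
})

test_that("per-AU optimization is never worse than the global choice", {
    set.seed(86)
    ref <- simulateReference(8000, seed = 86)
    recs <- simulateReads(ref, 400, readLength = 40,
                          substitutionRate = 0.01, seed = 87)
    aus <- groupRecords(sortByPosition(recs), 80L)
    ds <- lapply(aus, function(au) encodeAccessUnit(au, "reference",
                                                    ref[[1]]))
    cmp <- compareParameterModes(ds)
    expect_lte(cmp$perAuBytes, cmp$globalBytes)
})
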
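# Binarizations and the context-adaptive arithmetic coder.

test_that("binarizations produce the documented prefix-free patterns", {
    expect_equal(binarize(5, "BINARY", nBits = 4), c(0L, 1L, 0L, 1L))
    expect_equal(binarize(3, "TRUNCATED_UNARY", maxValue = 5),
                 c(1L, 1L, 1L, 0L))
    # at the maximum the trailing zero is truncated
    expect_equal(binarize(5, "TRUNCATED_UNARY", maxValue = 5), rep(1L, 5))
    expect_equal(binarize(0, "EXP_GOLOMB"), 1L)
    expect_equal(binarize(1, "EXP_GOLOMB"), c(0L, 1L, 0L))
    expect_equal(binarize(2, "EXP_GOLOMB"), c(0L, 1L, 1L))
    expect_error(binarize(16, "BINARY", nBits = 4), "fit")
    expect_error(binarize(6, "TRUNCATED_UNARY", maxValue = 5), "exceeds")
})

test_that("debinarize inverts binarize for every kind", {
    for (v in c(0:17, 100, 4095)) {
        expect_equal(debinarize(binarize(v, "BINARY", nBits = 13),
                                "BINARY", nBits = 13)$value, v)
        expect_equal(debinarize(binarize(v, "TRUNCATED_UNARY",
                                         maxValue = 5000),
                                "TRUNCATED_UNARY", maxValue = 5000)$value, v)
        eg <- binarize(v, "EXP_GOLOMB")
        d <- debinarize(eg, "EXP_GOLOMB")
        expect_equal(d$value, v)
        expect_equal(d$consumed, length(eg)) # prefix-free: consumes exactly
    }
})

test_that("arithmetic coding round-trips bins and is deterministic", {
    set.seed(1)
    bits <- as.integer(runif(5000) < 0.3)
    ctx <- sample(0:7, 5000, replace = TRUE)
    enc <- cabacEncode(bits, ctx)
    expect_identical(cabacDecode(enc, length(bits), ctx), bits)
    expect_identical(cabacEncode(bits, ctx), enc) # no hidden randomness
    expect_identical(cabacDecode(cabacEncode(integer(0)), 0L), integer(0))
})

test_that("compressed size approaches the Shannon bound on skewed bins", {
    set.seed(42)
    p <- 0.02
    bits <- as.integer(runif(10000) < p)
    enc <- cabacEncode(bits)
    H <- -(p * log2(p) + (1 - p) * log2(1 - p))
    bound <- length(bits) * H / 8
    expect_lt(length(enc), bound * 1.15 + 16)
})

test_that("adaptive contexts drive a deterministic pattern to near zero", {
    bits <- rep_len(c(1L, 0L), 4000)
    # order-1-style context: the previous bin value
    ctx <- c(0L, bits[-length(bits)])
    enc <- cabacEncode(bits, ctx)
    expect_lt(length(enc), 4000 / 8 * 0.05 + 16)
    expect_identical(cabacDecode(enc, length(bits), ctx), bits)
})

test_that("full entropy path round-trips across the configuration space", {
    set.seed(7)
    for (bits in c(1L, 2L, 4L, 8L, 16L, 32L)) {
        x <- randomStream(200, bits, runBias = 0.4)
        cfgs <- validEntropyConfigs(bits, maxSubsymbols(x, bits))
        expect_gt(nrow(cfgs), 0)
        for (k in seq_len(nrow(cfgs))) {
            cfg <- as.list(cfgs[k, ])
            blk <- genocodec:::compressTransformedStream(x, bits, cfg)
            y <- genocodec:::decompressTransformedStream(blk, length(x),
                                                         bits, cfg)
            expect_identical(y, x)
        }
    }
})

test_that("invalid combinations are excluded from the search space", {
    cfgs <- validEntropyConfigs(4L, c(`1` = 15L, `2` = 3L, `4` = NA, `8` = NA))
    expect_true(all(cfgs$split %in% c(1L, 2L, 4L)))
    expect_true(all(4L %% cfgs$split == 0L))
    # LUT only for subsymbols of <= 8 bits
    cfgs32 <- validEntropyConfigs(32L, maxSubsymbols(c(70000L), 32L))
    expect_true(all(!cfgs32$lut | 32L %/% cfgs32$split <= 8L))
    # truncated unary gated on the observed maximum
    expect_false(any(cfgs32$binarization == "TRUNCATED_UNARY" &
                     cfgs32$split == 1L))
})

test_that("tampering with a compressed block is detected or changes length", {
    x <- randomStream(300, 8)
    cfg <- list(order = 1L, split = 1L, lut = FALSE,
                binarization = "EXP_GOLOMB")
    blk <- genocodec:::compressTransformedStream(x, 8L, cfg)
    bad <- blk[-length(blk)] # truncate
    expect_error(genocodec:::decompressTransformedStream(bad, length(x) + 500,
                                                         8L, cfg),
                 "corrupt|premature|prefix")
})
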
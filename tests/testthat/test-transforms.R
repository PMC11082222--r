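# Sequence transforms, subsymbol splitting and the LUT transform:
# worked examples, brute-force oracles and round-trip bijectivity.

test_that("equality transform follows the flag/residual formulas", {
    e <- equalityEncode(c(0, 0, 3, 3, 2))
    expect_equal(e$flags, c(1L, 1L, 0L, 1L, 0L))
    expect_equal(e$residuals, c(2L, 2L))
    expect_equal(equalityEncode(integer(0)),
                 list(flags = integer(0), residuals = integer(0)))
    # the symbol before the first is 0, so an all-equal nonzero stream
    # still pays one residual
    e2 <- equalityEncode(c(5, 5, 5))
    expect_equal(e2$flags, c(0L, 1L, 1L))
    expect_equal(e2$residuals, 4L)
    for (case in 1:25) {
        set.seed(case)
        x <- randomStream(sample(0:200, 1), sample(c(1, 4, 8, 16), 1))
        e <- equalityEncode(x)
        expect_identical(e, equalityOracle(x))
        expect_identical(equalityDecode(e$flags, e$residuals), x)
        expect_equal(length(e$residuals) + sum(e$flags), length(x))
    }
    expect_error(equalityDecode(c(0L, 1L), integer(0)), "residual count")
})

test_that("match transform is greedy with matches confined to the buffer", {
    m <- matchEncode(c(1, 2, 3, 1, 2, 3), B = 4)
    expect_equal(m$pointers, 0L)
    expect_equal(m$lengths, c(0L, 0L, 0L, 3L))
    expect_equal(m$literals, c(1L, 2L, 3L))
    d <- matchEncode(c(5, 6, 7, 8), B = 8) # all distinct
    expect_equal(d$lengths, rep(0L, 4))
    expect_equal(d$literals, c(5L, 6L, 7L, 8L))
    expect_equal(matchEncode(integer(0), B = 4),
                 list(pointers = integer(0), lengths = integer(0),
                      literals = integer(0)))
    for (case in 1:25) {
        set.seed(100 + case)
        B <- sample(c(2L, 4L, 16L, 255L), 1)
        x <- randomStream(sample(0:300, 1), sample(c(2, 4, 8), 1),
                          runBias = 0.5)
        m <- matchEncode(x, B)
        expect_identical(m, matchOracle(x, B))
        expect_identical(matchDecode(m$pointers, m$lengths, m$literals, B), x)
        # decoded length accounting
        expect_equal(sum(m$lengths[m$lengths > 0]) + sum(m$lengths == 0),
                     length(x))
    }
    expect_error(matchDecode(5L, 3L, integer(0), 4L), "exceeds buffer")
})

test_that("run-length transform uses the guard decomposition 0 < r <= G", {
    r <- rleEncode(c(7, 7, 7, 7, 7, 2), G = 4)
    expect_equal(r$lengths, c(4L, 0L, 0L))
    expect_equal(r$symbols, c(7L, 2L))
    expect_equal(rleEncode(9, G = 100), list(lengths = 0L, symbols = 9L))
    # run of exactly n*G decomposes with r = G
    expect_equal(rleEncode(c(3, 3), G = 1), list(lengths = c(1L, 0L),
                                                 symbols = 3L))
    for (case in 1:25) {
        set.seed(200 + case)
        G <- sample(c(1L, 2L, 4L, 255L), 1)
        x <- randomStream(sample(0:300, 1), sample(c(1, 4, 8), 1),
                          runBias = 0.7)
        r <- rleEncode(x, G)
        expect_identical(r[c("lengths", "symbols")],
                         rleOracle(x, G)[c("lengths", "symbols")])
        expect_identical(rleDecode(r$lengths, r$symbols, G), x)
    }
    expect_error(rleDecode(c(4L, 4L), 7L, 4L), "dangling guard")
})

test_that("subsymbol splitting is big-endian and invertible", {
    expect_equal(splitSubsymbols(strtoi("101011", base = 2), 6L, 2L),
                 c(strtoi("101", base = 2), strtoi("011", base = 2)))
    x <- randomStream(100, 16)
    expect_identical(splitSubsymbols(x, 16L, 1L), x)
    for (bits in c(2L, 4L, 8L, 16L, 32L))
        for (f in c(1L, 2L, 4L, 8L)) {
            if (bits %% f != 0L) next
            y <- randomStream(50, min(bits, 20))
            expect_identical(mergeSubsymbols(splitSubsymbols(y, bits, f),
                                             bits, f), y)
        }
    expect_error(splitSubsymbols(1L, 6L, 4L), "divide")
})

test_that("LUT transform ranks by context-conditioned frequency", {
    lf <- lutForward(c(2, 2, 2, 1), 1, 2)
    expect_equal(lf$indices, c(0L, 0L, 0L, 1L))
    # context 0 (stream start) saw only 2; context 2 saw {2:2, 1:1}
    expect_equal(lf$contextKeys, c(0L, 2L))
    expect_equal(lf$ranked[[1]], 2L)
    expect_equal(lf$ranked[[2]], c(2L, 1L))
    expect_equal(lutForward(rep(3L, 10), 1, 2)$indices, rep(0L, 10))
    for (case in 1:20) {
        set.seed(300 + case)
        ord <- sample(1:2, 1)
        bits <- sample(c(1L, 2L, 4L, 8L), 1)
        x <- randomStream(sample(0:400, 1), bits, runBias = 0.4)
        lf <- lutForward(x, ord, bits)
        expect_identical(lutInverse(lf[c("contextKeys", "ranked")],
                                    lf$indices, ord), x)
        # never increases the alphabet
        if (length(x))
            expect_lte(max(lf$indices), max(x))
    }
    expect_error(lutInverse(list(contextKeys = 0L, ranked = list(0L)),
                            5L, 1), "outside table")
})

test_that("frequency ties rank the smaller subsymbol first", {
    # context 0 sees values 0, 1 and 3 once each: a three-way tie
    lf <- lutForward(c(0, 1, 0, 3), 1, 2)
    k <- match(0L, lf$contextKeys)
    expect_equal(lf$ranked[[k]], c(0L, 1L, 3L))
    expect_equal(lf$indices, c(0L, 1L, 0L, 2L))
})
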
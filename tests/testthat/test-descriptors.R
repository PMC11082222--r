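# Descriptor coding: reference-based, local assembly, low latency,
# identifier tokens, verbatim qualities.

refFixture <- function(len = 60, seed = 41) simulateReference(len, seed)[[1]]

test_that("reference-based coding emits delta positions and edit streams", {
    ref <- paste0(strrep("A", 9), "CGTT", strrep("A", 20))
    r1 <- mkAligned("r1", "CGTT", 9)
    au <- mkAU(list(r1))
    ds <- encodeReferenceBased(au, ref)
    expect_equal(ds[["pos.0"]]$symbols, 9L)
    expect_equal(ds[["rlen.0"]]$symbols, 4L)
    expect_equal(ds[["mm_count.0"]]$symbols, 0L)
    expect_length(ds[["mm_pos.0"]]$symbols, 0L)
    expect_length(ds[["mm_payload.0"]]$symbols, 0L)
    # two records: delta-coded positions
    r2 <- mkAligned("r2", "TAAA", 12)
    au2 <- mkAU(list(r1, r2))
    expect_equal(encodeReferenceBased(au2, ref)[["pos.0"]]$symbols,
                 c(9L, 3L))
    # N-substitution record
    rn <- mkAligned("rn", "CNTT", 9,
                    edits = mkEdits("SUBSTITUTION", 1L, "N", 1L),
                    qualities = "IIII")
    dn <- encodeReferenceBased(mkAU(list(rn), class = "N"), ref)
    expect_equal(dn[["mm_count.0"]]$symbols, 1L)
    expect_equal(dn[["mm_pos.0"]]$symbols, 1L)
    expect_equal(dn[["mm_type.0"]]$symbols, 0L)
    expect_equal(dn[["mm_payload.0"]]$symbols, 4L) # N = code 4
    # sort violation and reference overrun raise
    expect_error(encodeReferenceBased(mkAU(list(r2, r1)), ref),
                 "not position-sorted")
    expect_error(encodeReferenceBased(
        mkAU(list(mkAligned("x", "ACGT", 31))), ref), "beyond the reference")
})

test_that("reference-based decode is the exact inverse", {
    set.seed(42)
    ref <- refFixture(400)
    recs <- simulateReads(c(chrS = ref), 60, readLength = 50,
                          substitutionRate = 0.05, nRate = 0.1,
                          insertionRate = 0.3, deletionRate = 0.3,
                          clipRate = 0.3, seed = 43)
    for (cls in unique(vapply(recs, recordClass, character(1)))) {
        sub <- sortByPosition(Filter(function(r) recordClass(r) == cls,
                                     recs))
        au <- mkAU(sub, class = cls)
        ds <- encodeReferenceBased(au, ref)
        back <- decodeReferenceBased(ds, ref, au@key, length(sub),
                                     ids = vapply(sub, recordId,
                                                  character(1)))
        for (i in seq_along(sub)) {
            expect_equal(segments(back[[i]])[[1]]$bases,
                         segments(sub[[i]])[[1]]$bases)
            expect_equal(alignments(back[[i]])[[1]]$position,
                         alignments(sub[[i]])[[1]]$position)
            expect_equal(alignments(back[[i]])[[1]]$edits,
                         alignments(sub[[i]])[[1]]$edits,
                         ignore_attr = TRUE)
        }
    }
    # truncated mismatch stream is a corruption error
    sub <- sortByPosition(Filter(function(r) recordClass(r) != "P", recs))
    au <- mkAU(sub, class = recordClass(sub[[1]]))
    ds <- encodeReferenceBased(au, ref)
    ds[["mm_pos.0"]]$symbols <- ds[["mm_pos.0"]]$symbols[1]
    expect_error(decodeReferenceBased(ds, ref, au@key, length(sub)),
                 "exhausted")
})

test_that("consensus is a per-locus plurality vote with lexicographic ties", {
    one <- buildLocalConsensus(list(list(position = 0, bases = "ACGT")))
    expect_equal(one$bases, "ACGT")
    maj <- buildLocalConsensus(list(list(position = 0, bases = "AAAA"),
                                    list(position = 0, bases = "AATA"),
                                    list(position = 0, bases = "AATA")))
    expect_equal(maj$bases, "AATA")
    # tie A vs C -> A
    tie <- buildLocalConsensus(list(list(position = 0, bases = "A"),
                                    list(position = 0, bases = "C")))
    expect_equal(tie$bases, "A")
    # uncovered loci fill with N
    gap <- buildLocalConsensus(list(list(position = 0, bases = "AC"),
                                    list(position = 4, bases = "GT")))
    expect_equal(gap$bases, "ACNNGT")
    expect_equal(unname(colSums(gap$coverage)), c(1L, 1L, 0L, 0L, 1L, 1L))
    expect_error(buildLocalConsensus(list()), "non-empty")
})

test_that("local assembly encodes the first record verbatim via substitutions", {
    r1 <- mkAligned("r1", "ACGT", 5)
    ds <- encodeLocalAssembly(mkAU(list(r1)), bufferSize = 4L)
    # empty buffer -> all-N consensus -> every base is a substitution
    expect_equal(ds[["mm_count.0"]]$symbols, 4L)
    expect_equal(ds[["mm_payload.0"]]$symbols, baseCodes("ACGT"))
})

test_that("overlapping identical reads encode mismatch-free after the first", {
    reads <- lapply(1:10, function(i) mkAligned(paste0("r", i), "ACGTACGT",
                                                7))
    ds <- encodeLocalAssembly(mkAU(reads), bufferSize = 32L)
    counts <- ds[["mm_count.0"]]$symbols
    expect_equal(counts[1], 8L)
    expect_equal(counts[-1], rep(0L, 9))
})

test_that("local assembly round-trips and mirrors the consensus exactly", {
    set.seed(51)
    ref <- refFixture(300, seed = 52)
    recs <- simulateReads(c(chrS = ref), 120, readLength = 40,
                          substitutionRate = 0.03, insertionRate = 0.2,
                          deletionRate = 0.2, clipRate = 0.2, seed = 53)
    for (cls in unique(vapply(recs, recordClass, character(1)))) {
        sub <- sortByPosition(Filter(function(r) recordClass(r) == cls,
                                     recs))
        au <- mkAU(sub, class = cls)
        ds <- encodeLocalAssembly(au, bufferSize = 8L,
                                  traceConsensus = TRUE)
        back <- decodeLocalAssembly(ds, au@key, length(sub), bufferSize = 8L,
                                    ids = vapply(sub, recordId, character(1)),
                                    traceConsensus = TRUE)
        # encoder and decoder consensus sequences are identical per record
        expect_identical(attr(back, "consensus"), attr(ds, "consensus"))
        expect_identical(
            vapply(back, function(r) segments(r)[[1]]$bases, character(1)),
            vapply(sub, function(r) segments(r)[[1]]$bases, character(1)))
        expect_identical(
            vapply(back, function(r) alignments(r)[[1]]$position, integer(1)),
            vapply(sub, function(r) alignments(r)[[1]]$position, integer(1)))
    }
})

test_that("low-latency coding stores lengths plus verbatim base codes", {
    rec <- mkUnaligned("u1", "ACGTN")
    ds <- encodeLowLatency(mkAU(list(rec)))
    expect_equal(ds[["rlen.0"]]$symbols, 5L)
    expect_equal(ds[["ureads.0"]]$symbols, 0:4)
    expect_false("pos.0" %in% names(ds))
    back <- decodeLowLatency(ds, list(recordClass = "U", paired = FALSE,
                                      referenceId = NA_character_), 1L)
    expect_equal(segments(back[[1]])[[1]]$bases, "ACGTN")
    expect_error(encodeLowLatency(mkAU(list(mkAligned("a", "AC", 1)),
                                       class = "U")),
                 "class-U")
})

test_that("identifier tokenization follows the digit/string/char rules", {
    t1 <- tokenizeIdentifier("read_0042")
    expect_equal(vapply(t1, `[[`, character(1), "kind"),
                 c("STRING", "DIGITS", "END"))
    expect_equal(t1[[1]]$value, "read_")
    expect_equal(t1[[2]]$value, 42L)
    expect_equal(t1[[2]]$width, 4L)
    expect_equal(vapply(tokenizeIdentifier("1"), `[[`, character(1), "kind"),
                 c("DIGITS", "END"))
    expect_equal(vapply(tokenizeIdentifier("A"), `[[`, character(1), "kind"),
                 c("CHAR", "END"))
    expect_error(tokenizeIdentifier(""), "non-empty")
    expect_error(tokenizeIdentifier("aéb"), "printable|invalid")
})

test_that("delta coding substitutes MATCH and DELTA tokens", {
    d <- deltaTokenize(tokenizeIdentifier("r_2"), tokenizeIdentifier("r_1"))
    expect_equal(vapply(d, `[[`, character(1), "kind"),
                 c("MATCH", "DELTA", "END"))
    expect_equal(d[[2]]$value, 1L)
    lit <- deltaTokenize(tokenizeIdentifier("r_2"), NULL)
    expect_equal(vapply(lit, `[[`, character(1), "kind"),
                 c("STRING", "DIGITS", "END"))
    d2 <- deltaTokenize(tokenizeIdentifier("s_9"), tokenizeIdentifier("r_9"))
    expect_equal(vapply(d2, `[[`, character(1), "kind"),
                 c("STRING", "MATCH", "END"))
})

test_that("token streams serialize per position and round-trip", {
    s <- serializeTokens(c("r1", "r2", "r3"))
    # "r" is a single non-digit, hence a CHAR token; matched thereafter
    expect_equal(s[["tok.0.type"]]$symbols,
                 unname(c(genocodec::TOKEN_TYPES["CHAR"],
                          genocodec::TOKEN_TYPES["MATCH"],
                          genocodec::TOKEN_TYPES["MATCH"])))
    expect_equal(s[["tok.1.type"]]$symbols,
                 unname(c(genocodec::TOKEN_TYPES["DIGITS"],
                          genocodec::TOKEN_TYPES["DELTA"],
                          genocodec::TOKEN_TYPES["DELTA"])))
    expect_equal(s[["tok.1.delta"]]$symbols, c(2L, 2L)) # zig-zag of +1
    expect_identical(deserializeTokens(s, 3L), c("r1", "r2", "r3"))
    same <- serializeTokens(rep("abc:007", 4))
    expect_equal(same[["tok.0.type"]]$symbols[-1],
                 rep(unname(genocodec::TOKEN_TYPES["MATCH"]), 3))
    set.seed(61)
    ids <- sprintf("SIM:%d:%04d:x%s", sample(1:3, 30, TRUE),
                   sample(0:9999, 30), sample(letters, 30, TRUE))
    expect_identical(deserializeTokens(serializeTokens(ids), length(ids)),
                     ids)
})

test_that("prefix-plus-counter identifiers code as pure MATCH/DELTA", {
    ids <- sprintf("FLOW:1:%05d", 1:50)
    s <- serializeTokens(ids)
    types <- c(s[["tok.0.type"]]$symbols[-1], s[["tok.1.type"]]$symbols[-1],
               s[["tok.2.type"]]$symbols[-1])
    expect_true(all(types %in% genocodec::TOKEN_TYPES[c("MATCH", "DELTA")]))
})

test_that("verbatim qualities are offset ASCII codes", {
    au <- mkAU(list(mkUnaligned("q", "ACGT", "!!!!")))
    expect_equal(encodeQualityVerbatim(au)[["qv.0"]]$symbols, rep(0L, 4))
    au2 <- mkAU(list(mkUnaligned("q", "ACGT", "IIII")))
    expect_equal(encodeQualityVerbatim(au2)[["qv.0"]]$symbols, rep(40L, 4))
    expect_length(encodeQualityVerbatim(au2, "discard"), 0L)
})
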
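# Exhaustive search over the entropy-coding parameter space and the
# loss / argmin selection of global parameter sets. The search is
# separable: entropy parameters (coding order, split factor, LUT flag,
# binarization) are chosen per transformed descriptor subsequence, so the
# cross-product minimum equals the sum of per-stream minima; the sequence
# transform is compared via the printed loss equations afterwards.

#' Smallest compressed size of a descriptor subsequence under a fixed
#' sequence transform
#'
#' Applies the transform, then exhaustively compresses every demultiplexed
#' transformed subsequence under every valid remaining-parameter
#' combination and returns the minimal total byte count (all streams
#' summed, including the fixed per-stream container overhead of
#' `STREAM_OVERHEAD_BYTES`) together with the argmin parameters. Ties are
#' broken by enumeration order (see [validEntropyConfigs()]).
#'
#' @param symbols integer symbol vector
#' @param bits symbol width
#' @param transform one of `"NONE"`, `"EQUALITY"`, `"MATCH"`, `"RLE"`
#' @param B,G match-buffer and run-length guard parameters
#' @param returnAll also return every explored size per stream
#' @return `list(bytes=, params=, allSizes=)`; `params` is the
#'   per-transformed-stream entropy configuration list
#' @export
minSize <- function(symbols, bits, transform, B = 255L, G = 255L,
                    returnAll = FALSE) {
    tr <- applySequenceTransform(symbols, bits, transform, B, G)
    total <- 0
    params <- vector("list", length(tr))
    allSizes <- if (returnAll) vector("list", length(tr)) else NULL
    for (i in seq_along(tr)) {
        st <- tr[[i]]
        cfgs <- validEntropyConfigs(st$bits,
                                    maxSubsymbols(st$symbols, st$bits))
        # sizes for the whole enumeration in one batched call
        sizes <- .gc_enumerate_sizes(as.integer(st$symbols),
                                     as.integer(st$bits), cfgs$order,
                                     cfgs$split, cfgs$lut,
                                     match(cfgs$binarization,
                                           BINARIZATIONS) - 1L) +
                 STREAM_OVERHEAD_BYTES
        best <- which.min(sizes) # first minimum = enumeration-order tie-break
        total <- total + sizes[best]
        params[[i]] <- list(order = cfgs$order[best],
                            split = cfgs$split[best], lut = cfgs$lut[best],
                            binarization = cfgs$binarization[best])
        if (returnAll) {
            rownames(cfgs) <- NULL
            allSizes[[i]] <- cbind(cfgs, bytes = sizes)
        }
    }
    list(bytes = total, params = params, allSizes = allSizes)
}

#' Total minimal size of a descriptor subsequence over a file's sampled
#' access units
#'
#' Sums [minSize()] over (up to) the first ten access units sampled from a
#' file; an access unit lacking the subsequence contributes the cost of an
#' empty stream.
#'
#' @param auSample list of descriptor sets (named lists of
#'   `list(symbols=, bits=)`), one per sampled access unit
#' @param streamName descriptor subsequence name
#' @param transform sequence transform
#' @param B,G transform parameters
#' @return `list(bytes=, perAU=)`; `perAU` holds each access unit's
#'   [minSize()] result
#' @export
totalMinSize <- function(auSample, streamName, transform, B = 255L,
                         G = 255L) {
    perAU <- lapply(auSample, function(ds) {
        s <- ds[[streamName]]
        if (is.null(s)) s <- list(symbols = integer(0),
                                  bits = streamBits(streamName))
        minSize(s$symbols, s$bits, transform, B, G)
    })
    list(bytes = sum(vapply(perAU, `[[`, numeric(1), "bytes")),
         perAU = perAU)
}

#' Loss table over files, transforms and descriptor subsequences
#'
#' For every descriptor subsequence s, sequence transform t and file f
#' computes `totalMinSize(s,t,f)`, the loss factor
#' `loss(s,t,f) = totalMinSize(s,t,f) / min_j totalMinSize(s,j,f)` and the
#' mean loss over files. The loss is always >= 1, with equality exactly
#' for a file's optimal transform.
#'
#' @param files list of files; each file is a list of sampled
#'   descriptor sets (one per access unit)
#' @param B,G transform parameters
#' @return list with `total` and `loss` arrays
#'   (subsequence x transform x file), the `meanLoss` matrix, the chosen
#'   `tBest` per subsequence, and the per-(s,t,f,AU) argmin `params`
#' @export
buildLossTable <- function(files, B = 255L, G = 255L) {
    streams <- sort(unique(unlist(lapply(files, function(f)
        unlist(lapply(f, names))))))
    nT <- length(SEQ_TRANSFORMS)
    total <- array(NA_real_, dim = c(length(streams), nT, length(files)),
                   dimnames = list(streams, SEQ_TRANSFORMS, NULL))
    params <- list()
    for (fi in seq_along(files))
        for (s in streams)
            for (t in SEQ_TRANSFORMS) {
                tm <- totalMinSize(files[[fi]], s, t, B, G)
                total[s, t, fi] <- tm$bytes
                params[[paste(s, t, fi, sep = "\r")]] <-
                    lapply(tm$perAU, `[[`, "params")
            }
    c(list(streams = streams, total = total, params = params),
      lossFromTotals(total))
}

#' Loss factors and transform choice from total sizes
#'
#' Applies the loss equations to a precomputed
#' (subsequence x transform x file) array of total minimal sizes:
#' `loss(s,t,f) = total(s,t,f) / min_j total(s,j,f)`, the mean loss over
#' files, and `tBest(s) = argmin_t meanLoss(s,t)` (ties to the earliest
#' transform).
#'
#' @param total numeric array, dims subsequence x transform x file
#' @return `list(loss=, meanLoss=, tBest=)`
#' @export
lossFromTotals <- function(total) {
    loss <- total
    for (fi in seq_len(dim(total)[3])) {
        mins <- apply(total[, , fi, drop = FALSE], 1L, min)
        loss[, , fi] <- total[, , fi] / mins
    }
    meanLoss <- apply(loss, c(1L, 2L), mean)
    tBest <- apply(meanLoss, 1L, function(v)
        colnames(total)[which.min(v)]) # first minimum on ties
    list(loss = loss, meanLoss = meanLoss, tBest = tBest)
}

#' Select the globally best sequence transform per descriptor subsequence
#'
#' The argmin of the mean loss over files; ties resolve to the earliest
#' transform in enumeration order (NONE, EQUALITY, MATCH, RLE).
#'
#' @param lossTable result of [buildLossTable()]
#' @return named character vector, one transform per subsequence
#' @export
selectGlobalTransform <- function(lossTable) lossTable$tBest

#' Select the remaining entropy parameters by majority vote
#'
#' Given the multiset of best per-access-unit solutions for a fixed
#' (subsequence, transform), chooses each field's most frequent value.
#' Ties break toward the cheaper option: lower coding order, smaller split
#' factor, no LUT before LUT, and BINARY < TRUNCATED_UNARY < EXP_GOLOMB.
#'
#' @param tuples non-empty list of per-transformed-stream parameter lists
#'   (each as returned in `minSize()$params`)
#' @return one per-transformed-stream parameter list
#' @export
selectRemainingParams <- function(tuples) {
    if (!length(tuples)) stop("no parameter tuples to vote over")
    nStreams <- length(tuples[[1]])
    pref <- list(order = c(0L, 1L, 2L), split = c(1L, 2L, 4L, 8L),
                 lut = c(FALSE, TRUE), binarization = BINARIZATIONS)
    lapply(seq_len(nStreams), function(i) {
        out <- list()
        for (field in names(pref)) {
            vals <- vapply(tuples, function(tp) as.character(tp[[i]][[field]]),
                           character(1))
            tab <- table(vals)
            winners <- names(tab)[tab == max(tab)]
            pick <- as.character(pref[[field]])
            pick <- pick[pick %in% winners][1]
            out[[field]] <- if (field == "lut") pick == "TRUE"
                            else if (field == "binarization") pick
                            else as.integer(pick)
        }
        out
    })
}

#' Exhaustive parameter optimization over sampled access units
#'
#' Global mode reproduces the analytical selection procedure: per
#' descriptor subsequence the loss table picks the transform with the
#' smallest mean loss over files, and the remaining entropy parameters are
#' the most frequent values among the per-access-unit best solutions for
#' that transform. The result is a single [ParameterSet-class] with
#' exactly one configuration per descriptor subsequence. Per-AU mode
#' returns one optimized parameter set per access unit instead.
#'
#' @param files list of files, each a list of descriptor sets (one per
#'   sampled access unit; at most the first ten are customarily used)
#' @param mode `"global"` or `"per-au"`
#' @param B,G transform parameters
#' @param report also build an optimization-progress report (per
#'   subsequence: explored total sizes for the chosen transform, sorted
#'   from worst to best, normalized to the worst)
#' @return global mode: `list(parameterSet=, lossTable=, report=)`;
#'   per-AU mode: `list(parameterSets=, bytes=)` with one entry per access
#'   unit (files concatenated)
#' @export
optimizeDataset <- function(files, mode = c("global", "per-au"), B = 255L,
                            G = 255L, report = FALSE) {
    mode <- match.arg(mode)
    if (mode == "per-au") {
        aus <- do.call(c, files)
        psets <- lapply(aus, function(ds) {
            configs <- list()
            bytes <- 0
            for (nm in names(ds)) {
                per <- lapply(SEQ_TRANSFORMS, function(t)
                    minSize(ds[[nm]]$symbols, ds[[nm]]$bits, t, B, G))
                sizes <- vapply(per, `[[`, numeric(1), "bytes")
                best <- which.min(sizes)
                configs[[nm]] <- list(transform = SEQ_TRANSFORMS[best],
                                      B = B, G = G,
                                      streams = per[[best]]$params)
                bytes <- bytes + sizes[best]
            }
            list(configs = configs, bytes = bytes)
        })
        return(list(
            parameterSets = lapply(psets, `[[`, "configs"),
            bytes = sum(vapply(psets, `[[`, numeric(1), "bytes"))))
    }
    lt <- buildLossTable(files, B, G)
    configs <- list()
    for (s in lt$streams) {
        t <- lt$tBest[[s]]
        tuples <- list()
        for (fi in seq_along(files))
            tuples <- c(tuples, lt$params[[paste(s, t, fi, sep = "\r")]])
        configs[[s]] <- list(transform = t, B = B, G = G,
                             streams = selectRemainingParams(tuples))
    }
    rep <- NULL
    if (report) rep <- .progressReport(files, lt, B, G)
    list(parameterSet = new("ParameterSet", id = 0L, configs = configs),
         lossTable = lt, report = rep)
}

# Optimization-progress report: for each subsequence and its chosen
# transform, the explored sizes are re-measured with each entropy
# configuration applied uniformly to all transformed streams (a
# well-defined slice of the full cross product), summed over all sampled
# access units and sorted from worst to best.
.progressReport <- function(files, lt, B, G) {
    out <- list()
    for (s in lt$streams) {
        t <- lt$tBest[[s]]
        sizeByCfg <- NULL
        for (f in files)
            for (ds in f) {
                str <- ds[[s]]
                if (is.null(str)) str <- list(symbols = integer(0),
                                              bits = streamBits(s))
                ms <- minSize(str$symbols, str$bits, t, B, G,
                              returnAll = TRUE)
                tot <- Reduce(function(a, b) {
                    m <- merge(a, b,
                               by = c("order", "split", "lut", "binarization"))
                    m$bytes <- m$bytes.x + m$bytes.y
                    m[c("order", "split", "lut", "binarization", "bytes")]
                }, ms$allSizes)
                sizeByCfg <- if (is.null(sizeByCfg)) tot else {
                    m <- merge(sizeByCfg, tot,
                               by = c("order", "split", "lut", "binarization"))
                    m$bytes <- m$bytes.x + m$bytes.y
                    m[c("order", "split", "lut", "binarization", "bytes")]
                }
            }
        sizes <- sort(sizeByCfg$bytes, decreasing = TRUE)
        out[[s]] <- data.frame(
            subsequence = s, transform = t, rank = seq_along(sizes),
            bytes = sizes,
            normalized = if (length(sizes)) sizes / sizes[1] else numeric(0))
    }
    do.call(rbind, out)
}

#' Compare one global parameter set against per-access-unit optimization
#'
#' Measures the total compressed size of the sampled access units (i) with
#' each access unit's individually optimal parameters and (ii) with the
#' single globally selected parameter set, using identical size
#' accounting, and reports the relative increase of the global approach.
#'
#' @param dsList list of descriptor sets, one per access unit
#' @param B,G transform parameters
#' @return `list(perAuBytes=, globalBytes=, gapPercent=, parameterSet=)`
#' @export
compareParameterModes <- function(dsList, B = 255L, G = 255L) {
    perAu <- optimizeDataset(list(dsList), mode = "per-au", B = B, G = G)
    glob <- optimizeDataset(list(dsList), mode = "global", B = B, G = G)
    configs <- glob$parameterSet@configs
    globalBytes <- 0
    for (ds in dsList)
        for (nm in names(ds)) {
            cfg <- configs[[nm]] %||% defaultStreamConfig()
            blk <- compressStream(ds[[nm]]$symbols, ds[[nm]]$bits, cfg)
            globalBytes <- globalBytes +
                sum(vapply(blk$trStreams, function(tr)
                    length(tr$data) + STREAM_OVERHEAD_BYTES, numeric(1)))
        }
    list(perAuBytes = perAu$bytes, globalBytes = globalBytes,
         gapPercent = 100 * (globalBytes - perAu$bytes) / perAu$bytes,
         parameterSet = glob$parameterSet)
}
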
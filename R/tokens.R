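# Read-identifier coding: identifiers are cut into tokens, compared token
# by token with the previous identifier (match / delta substitution), and
# serialized into per-token-position descriptor subsequences.

.token <- function(kind, value = NULL, width = 0L)
    list(kind = kind, value = value, width = as.integer(width))

#' Tokenize a read identifier
#'
#' Maximal digit runs of up to 9 digits become `DIGITS(value, width)`
#' tokens (the width preserves leading zeros; longer runs fall back to
#' `STRING` to stay within 32-bit values); maximal non-digit runs of
#' length > 1 become `STRING` tokens and single non-digits `CHAR` tokens.
#' The list is terminated by an `END` token.
#'
#' @param id non-empty printable-ASCII identifier
#' @return list of tokens `list(kind=, value=, width=)`
#' @export
tokenizeIdentifier <- function(id) {
    if (!nzchar(id)) stop("identifier must be non-empty")
    if (grepl("[^\x20-\x7E]", id))
        stop("identifier contains non-printable characters")
    runs <- regmatches(id, gregexpr("[0-9]+|[^0-9]+", id))[[1]]
    toks <- lapply(runs, function(r) {
        if (grepl("^[0-9]", r)) {
            if (nchar(r) > 9L) .token("STRING", r)
            else .token("DIGITS", as.integer(r), nchar(r))
        } else if (nchar(r) == 1L) {
            .token("CHAR", r)
        } else {
            .token("STRING", r)
        }
    })
    c(toks, list(.token("END")))
}

.sameToken <- function(a, b)
    a$kind == b$kind && identical(a$width, b$width) &&
    identical(a$value, b$value)

#' Delta-code a token list against the previous identifier's tokens
#'
#' Position-wise comparison with the previous identifier's *literal*
#' tokens: identical tokens become `MATCH`; two `DIGITS` tokens of equal
#' width whose difference fits 15 bits become `DELTA`; anything else stays
#' literal, as do all positions beyond the shorter list and the closing
#' `END`.
#'
#' @param current literal token list of the current identifier
#' @param previous literal token list of the previous identifier, or `NULL`
#' @return token list with `MATCH`/`DELTA` substitutions applied
#' @export
deltaTokenize <- function(current, previous = NULL) {
    if (is.null(previous)) return(current)
    out <- current
    for (p in seq_along(current)) {
        if (p > length(previous)) break
        cur <- current[[p]]
        prev <- previous[[p]]
        if (cur$kind == "END") break
        if (.sameToken(cur, prev)) {
            out[[p]] <- .token("MATCH")
        } else if (cur$kind == "DIGITS" && prev$kind == "DIGITS" &&
                   cur$width == prev$width &&
                   abs(cur$value - prev$value) < 32768L) {
            out[[p]] <- .token("DELTA", cur$value - prev$value)
        }
    }
    out
}

#' Serialize an access unit's identifiers into token descriptor streams
#'
#' For each token position, one subsequence of token-type codes plus
#' per-type value subsequences: string bytes (0-terminated), digit values
#' and widths, zig-zag-mapped deltas, and character codes.
#'
#' @param ids character vector of identifiers (one per record)
#' @return named list of `list(symbols=, bits=)` keyed by stream name
#'   (`tok.<position>.<slot>`)
#' @export
serializeTokens <- function(ids) {
    lits <- lapply(ids, tokenizeIdentifier)
    maxPos <- if (length(lits)) max(vapply(lits, length, integer(1))) else 0L
    if (maxPos > .MAX_TOKEN_POSITIONS)
        stop(sprintf(
            "identifier needs %d token positions (limit %d); use verbatim identifiers instead",
            maxPos, .MAX_TOKEN_POSITIONS))
    acc <- new.env(parent = emptyenv())
    push <- function(name, v) {
        cur <- acc[[name]]
        if (is.null(cur)) cur <- list()
        cur[[length(cur) + 1L]] <- v
        acc[[name]] <- cur
    }
    prev <- NULL
    for (r in seq_along(lits)) {
        toks <- deltaTokenize(lits[[r]], prev)
        for (p in seq_along(toks)) {
            t <- toks[[p]]
            pre <- paste0("tok.", p - 1L, ".")
            push(paste0(pre, "type"), TOKEN_TYPES[[t$kind]])
            switch(t$kind,
                STRING = push(paste0(pre, "str"),
                              c(utf8ToInt(t$value), 0L)),
                DIGITS = {
                    push(paste0(pre, "digit"), t$value)
                    push(paste0(pre, "width"), t$width)
                },
                CHAR = push(paste0(pre, "chr"), utf8ToInt(t$value)),
                DELTA = push(paste0(pre, "delta"), zigzag(t$value)))
        }
        prev <- lits[[r]]
    }
    out <- list()
    for (name in sort(names(acc))) {
        out[[name]] <- list(symbols = as.integer(unlist(acc[[name]])),
                            bits = streamBits(name))
    }
    out
}

#' Reconstruct identifiers from token descriptor streams
#'
#' @param streams named list as produced by [serializeTokens()] (symbols
#'   only are used)
#' @param nRecords number of identifiers to reconstruct
#' @return character vector of identifiers
#' @export
deserializeTokens <- function(streams, nRecords) {
    cursors <- new.env(parent = emptyenv())
    nextSym <- function(name) {
        i <- cursors[[name]] %||% 0L
        s <- streams[[name]]$symbols
        if (is.null(s) || i + 1L > length(s))
            stop("corrupt stream: token subsequence '", name, "' exhausted")
        cursors[[name]] <- i + 1L
        s[[i + 1L]]
    }
    readString <- function(name) {
        chars <- integer(0)
        repeat {
            v <- nextSym(name)
            if (v == 0L) break
            chars <- c(chars, v)
        }
        intToUtf8(chars)
    }
    typeNames <- names(TOKEN_TYPES)
    ids <- character(nRecords)
    prev <- NULL
    for (r in seq_len(nRecords)) {
        toks <- list()
        p <- 0L
        repeat {
            pre <- paste0("tok.", p, ".")
            kind <- typeNames[nextSym(paste0(pre, "type")) + 1L]
            tok <- switch(kind,
                STRING = .token("STRING", readString(paste0(pre, "str"))),
                DIGITS = {
                    v <- nextSym(paste0(pre, "digit"))
                    w <- nextSym(paste0(pre, "width"))
                    .token("DIGITS", v, w)
                },
                CHAR = .token("CHAR", intToUtf8(nextSym(paste0(pre, "chr")))),
                MATCH = {
                    if (is.null(prev) || p + 1L > length(prev))
                        stop("corrupt stream: MATCH token without predecessor")
                    prev[[p + 1L]]
                },
                DELTA = {
                    if (is.null(prev) || p + 1L > length(prev) ||
                        prev[[p + 1L]]$kind != "DIGITS")
                        stop("corrupt stream: DELTA token without DIGITS predecessor")
                    d <- unzigzag(nextSym(paste0(pre, "delta")))
                    .token("DIGITS", prev[[p + 1L]]$value + d,
                           prev[[p + 1L]]$width)
                },
                END = .token("END"))
            toks[[p + 1L]] <- tok
            p <- p + 1L
            if (tok$kind == "END") break
        }
        pieces <- vapply(toks, function(t) switch(t$kind,
            STRING = t$value,
            DIGITS = formatC(t$value, width = t$width, flag = "0",
                             format = "d"),
            CHAR = t$value,
            END = ""), character(1))
        ids[r] <- paste(pieces, collapse = "")
        prev <- toks
    }
    ids
}
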
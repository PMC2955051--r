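# --- maximal repeat enumeration -------------------------------------------

# Encode sequences as one integer text: A,C,G,T -> 1..4; every N and every
# inter-sequence sentinel gets its own unique code so repeats cannot span
# them, and sequence boundaries act as per-sequence unique letters.
.encodeText <- function(seqs) {
    base <- c(A = 1L, C = 2L, G = 3L, T = 4L)
    pieces <- vector("list", 2L * length(seqs))
    nextCode <- 5L
    offsets <- integer(length(seqs))
    pos <- 0L
    for (i in seq_along(seqs)) {
        offsets[i] <- pos
        ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
        v <- unname(base[ch])
        isN <- is.na(v)
        if (any(isN)) {
            v[isN] <- seq.int(nextCode, length.out = sum(isN))
            nextCode <- nextCode + sum(isN)
        }
        pieces[[2L * i - 1L]] <- v
        pieces[[2L * i]] <- nextCode   # sentinel after sequence i
        nextCode <- nextCode + 1L
        pos <- pos + length(v) + 1L
    }
    list(text = unlist(pieces, use.names = FALSE), offsets = offsets,
         concat = paste0(paste(seqs, collapse = "#"), "#"))
}

# raw enumeration over a set of character sequences; returns list(word,
# len, occ = data.frame(mr, seq, start, end)) with 0-based coordinates.
.mrEnumerateRaw <- function(seqs) {
    enc <- .encodeText(seqs)
    res <- mr_enumerate_cpp(as.integer(enc$text))
    m <- length(res$len)
    if (m == 0L)
        return(list(word = character(), len = integer(),
                    occ = data.frame(mr = integer(), seq = integer(),
                                     start = integer(), end = integer())))
    nocc <- lengths(res$occ)
    pos <- unlist(res$occ, use.names = FALSE)
    mr <- rep.int(seq_len(m), nocc)
    seq <- findInterval(pos, enc$offsets)
    start <- pos - enc$offsets[seq]
    len <- as.integer(res$len)
    word <- substring(enc$concat, pos + 1L, pos + len[mr])
    # one word per MR; all occurrences of an MR share the word by construction
    words <- character(m)
    words[mr[!duplicated(mr)]] <- word[!duplicated(mr)]
    list(word = words, len = len,
         occ = data.frame(mr = mr, seq = seq, start = start,
                          end = start + len[mr]))
}

# canonical order of the working list L: decreasing length, decreasing
# occurrence count, lexicographic word, then first occurrence (seq, start).
.mrOrder <- function(word, len, occ) {
    nocc <- tabulate(occ$mr, nbins = length(word))
    o <- order(occ$seq, occ$start)
    firstRow <- o[!duplicated(occ$mr[o])]
    fseq <- fstart <- rep.int(.Machine$integer.max, length(word))
    fseq[occ$mr[firstRow]] <- occ$seq[firstRow]
    fstart[occ$mr[firstRow]] <- occ$start[firstRow]
    order(-len, -nocc, word, fseq, fstart, method = "radix")
}

.newMRList <- function(word, len, occ, strand = NULL) {
    if (!is.null(strand)) occ$strand <- strand
    if (is.null(occ$strand)) occ$strand <- rep("+", nrow(occ))
    perm <- .mrOrder(word, len, occ)
    rank <- integer(length(perm)); rank[perm] <- seq_along(perm)
    occ$mr <- rank[occ$mr]
    occ <- occ[order(occ$mr, occ$seq, occ$start), , drop = FALSE]
    rownames(occ) <- NULL
    support <- vapply(split(occ$seq, occ$mr),
                      function(s) length(unique(s)), 1L)
    sup <- integer(length(perm))
    sup[as.integer(names(support))] <- as.integer(support)
    new("MaximalRepeatList", word = word[perm], mrLength = len[perm],
        support = sup, occurrences = occ)
}

# keeps any extra columns of occ (e.g. strand) aligned through the filter
.filterMRSupport <- function(word, len, occ, minSupport) {
    keep <- which(vapply(split(occ$seq, factor(occ$mr, seq_along(word))),
                         function(s) length(unique(s)), 1L) >= minSupport)
    sel <- occ$mr %in% keep
    occ <- occ[sel, , drop = FALSE]
    newId <- integer(length(word)); newId[keep] <- seq_along(keep)
    occ$mr <- newId[occ$mr]
    list(word = word[keep], len = len[keep], occ = occ, keep = keep)
}

#' Enumerate all maximal repeats of a family
#'
#' Indexes the family with a generalized suffix array (unique sentinel per
#' sequence boundary) and reports every exact maximal repeat with its full
#' occurrence list, restricted to repeats present in at least
#' \code{minSupport} distinct sequences. With \code{includeReverse}, the
#' reverse-complemented sequences are indexed too; a repeat and its reverse
#' complement are merged under the lexicographically smaller canonical
#' word, occurrences of the complement being recorded on strand \code{"-"}
#' (a perfect-palindrome word is counted once, on strand \code{"+"}).
#' Repeats containing N are never reported (N breaks exactness).
#'
#' @param family a named \code{DNAStringSet} or character vector.
#' @param minSupport minimum number of distinct sequences (>= 1).
#' @param includeReverse also index the reverse strand.
#' @return a \code{\linkS4class{MaximalRepeatList}}.
#' @examples
#' enumerateMaximalRepeats(asFamily(c(s = "ACGTACGT")))
#' @export
enumerateMaximalRepeats <- function(family, minSupport = 1L,
                                    includeReverse = FALSE) {
    seqs <- .famChar(family)
    n <- length(seqs)
    stopifnot(minSupport >= 1L, minSupport <= n)
    if (!includeReverse) {
        raw <- .mrEnumerateRaw(seqs)
        f <- .filterMRSupport(raw$word, raw$len, raw$occ, minSupport)
        return(.newMRList(f$word, f$len, f$occ))
    }
    aug <- c(seqs, revComp(seqs))
    raw <- .mrEnumerateRaw(aug)
    lens <- nchar(seqs)
    occ <- raw$occ
    onRC <- occ$seq > n
    oseq <- ifelse(onRC, occ$seq - n, occ$seq)
    start <- ifelse(onRC, lens[oseq] - occ$end, occ$start)
    end <- ifelse(onRC, lens[oseq] - occ$start, occ$end)
    occ <- data.frame(mr = occ$mr, seq = oseq, start = start, end = end,
                      strand = ifelse(onRC, "-", "+"))
    rc <- revComp(raw$word)
    keepMR <- raw$word <= rc
    palin <- raw$word == rc
    sel <- keepMR[occ$mr] & !(palin[occ$mr] & occ$strand == "-")
    occ <- occ[sel, , drop = FALSE]
    keep <- which(keepMR)
    newId <- integer(length(raw$word)); newId[keep] <- seq_along(keep)
    occ$mr <- newId[occ$mr]
    f <- .filterMRSupport(raw$word[keep], raw$len[keep], occ, minSupport)
    .newMRList(f$word, f$len, f$occ)
}

#' Definitional maximal-repeat enumeration (test oracle)
#'
#' Enumerates maximal repeats by brute force directly from the definition:
#' every repeated substring is checked for two occurrences with distinct
#' left letters and two with distinct right letters, sequence boundaries
#' acting as unique sentinels. Cubic-time; refuses families above
#' \code{maxTotal} nt. Intended for validating
#' \code{\link{enumerateMaximalRepeats}} on small inputs.
#'
#' @inheritParams enumerateMaximalRepeats
#' @param maxTotal refuse inputs whose cumulated length exceeds this.
#' @return a \code{\linkS4class{MaximalRepeatList}}.
#' @export
bruteForceMaximalRepeats <- function(family, minSupport = 1L,
                                     includeReverse = FALSE,
                                     maxTotal = 2000L) {
    seqs <- .famChar(family)
    n <- length(seqs)
    if (sum(nchar(seqs)) > maxTotal)
        stop("input too large for the brute-force oracle")
    work <- if (includeReverse) c(seqs, revComp(seqs)) else seqs
    slen <- nchar(work)
    words <- character(); wlens <- integer()
    occL <- list()
    k <- 0L
    repeat {
        k <- k + 1L
        if (k > max(slen)) break
        os <- do.call(rbind, lapply(seq_along(work), function(i) {
            if (slen[i] < k) return(NULL)
            st <- seq_len(slen[i] - k + 1L)
            data.frame(seq = i, start = st,
                       w = substring(work[i], st, st + k - 1L))
        }))
        os <- os[!grepl("N", os$w, fixed = TRUE), , drop = FALSE]
        if (is.null(os) || nrow(os) == 0L) break
        tab <- table(os$w)
        rep_w <- names(tab)[tab >= 2L]
        if (length(rep_w) == 0L) break
        os <- os[os$w %in% rep_w, , drop = FALSE]
        for (w in sort(rep_w)) {
            oo <- os[os$w == w, , drop = FALSE]
            left <- ifelse(oo$start == 1L, paste0("<L", oo$seq, ">"),
                           substring(work[oo$seq], oo$start - 1L, oo$start - 1L))
            rend <- oo$start + k - 1L
            right <- ifelse(rend == slen[oo$seq], paste0("<R", oo$seq, ">"),
                            substring(work[oo$seq], rend + 1L, rend + 1L))
            if (length(unique(left)) >= 2L && length(unique(right)) >= 2L) {
                words <- c(words, w); wlens <- c(wlens, k)
                occL[[length(occL) + 1L]] <-
                    data.frame(mr = length(words), seq = oo$seq,
                               start = oo$start - 1L, end = oo$start - 1L + k)
            }
        }
    }
    if (length(words) == 0L)
        return(.newMRList(character(), integer(),
                          data.frame(mr = integer(), seq = integer(),
                                     start = integer(), end = integer())))
    occ <- do.call(rbind, occL)
    if (!includeReverse) {
        f <- .filterMRSupport(words, wlens, occ, minSupport)
        return(.newMRList(f$word, f$len, f$occ))
    }
    lens <- nchar(seqs)
    onRC <- occ$seq > n
    oseq <- ifelse(onRC, occ$seq - n, occ$seq)
    occ2 <- data.frame(mr = occ$mr, seq = oseq,
                       start = ifelse(onRC, lens[oseq] - occ$end, occ$start),
                       end = ifelse(onRC, lens[oseq] - occ$start, occ$end),
                       strand = ifelse(onRC, "-", "+"))
    rc <- revComp(words)
    keepMR <- words <= rc
    palin <- words == rc
    sel <- keepMR[occ2$mr] & !(palin[occ2$mr] & occ2$strand == "-")
    occ2 <- occ2[sel, , drop = FALSE]
    keep <- which(keepMR)
    newId <- integer(length(words)); newId[keep] <- seq_along(keep)
    occ2$mr <- newId[occ2$mr]
    f <- .filterMRSupport(words[keep], wlens[keep], occ2, minSupport)
    .newMRList(f$word, f$len, f$occ)
}

#' Remove occurrences overlapping a set of intervals
#'
#' Implements the partition-condition pruning: every MR occurrence sharing
#' at least one position with any of the given intervals (strand-agnostic)
#' is removed, and MRs whose remaining support falls below
#' \code{minSupport} are dropped. The canonical sort order of the list is
#' re-established.
#'
#' @param mrl a \code{\linkS4class{MaximalRepeatList}}.
#' @param intervals data.frame with columns \code{seq}, \code{start},
#'   \code{end} (0-based half-open).
#' @param minSupport drop MRs with fewer distinct supporting sequences.
#' @return a pruned \code{\linkS4class{MaximalRepeatList}}.
#' @export
pruneOccurrences <- function(mrl, intervals, minSupport = 1L) {
    occ <- mrl@occurrences
    if (nrow(occ) && NROW(intervals)) {
        drop <- rep(FALSE, nrow(occ))
        for (s in unique(intervals$seq)) {
            iv <- intervals[intervals$seq == s, , drop = FALSE]
            rows <- which(occ$seq == s)
            if (!length(rows)) next
            hit <- IRanges::overlapsAny(
                IRanges::IRanges(occ$start[rows] + 1L, occ$end[rows]),
                IRanges::IRanges(iv$start + 1L, iv$end))
            drop[rows[hit]] <- TRUE
        }
        occ <- occ[!drop, , drop = FALSE]
    }
    word <- mrl@word; len <- mrl@mrLength
    f <- .filterMRSupport(word, len, occ[c("mr", "seq", "start", "end")],
                          minSupport)
    strand <- occ$strand[occ$mr %in% f$keep]
    .newMRList(f$word, f$len, f$occ, strand = strand)
}

# --- accessors -------------------------------------------------------------

#' @describeIn MaximalRepeatList number of maximal repeats.
#' @param x a \code{MaximalRepeatList}.
#' @export
setMethod("length", "MaximalRepeatList", function(x) length(x@word))

#' Summary table of maximal repeats
#'
#' @param x a \code{\linkS4class{MaximalRepeatList}}.
#' @param ... unused.
#' @return data.frame with word, length, occurrence count and support.
#' @rdname moduleTable
#' @export
setMethod("moduleTable", "MaximalRepeatList", function(x, ...) {
    data.frame(word = x@word, length = x@mrLength,
               occurrences = tabulate(x@occurrences$mr, length(x@word)),
               support = x@support)
})

#' Occurrence tables
#'
#' User-facing occurrence coordinates are 1-based and inclusive.
#'
#' @param x a \code{MaximalRepeatList} or \code{ModuleCatalog}.
#' @param ... unused.
#' @return a data.frame of occurrences.
#' @rdname occurrenceTable
#' @export
setMethod("occurrenceTable", "MaximalRepeatList", function(x, ...) {
    occ <- x@occurrences
    data.frame(word = x@word[occ$mr], seq = occ$seq,
               start = occ$start + 1L, end = occ$end, strand = occ$strand)
})

setMethod("show", "MaximalRepeatList", function(object) {
    cat(sprintf("MaximalRepeatList with %d repeats, %d occurrences\n",
                length(object@word), nrow(object@occurrences)))
    if (length(object@word)) {
        h <- utils::head(moduleTable(object), 5L)
        print(h)
        if (length(object@word) > 5L) cat("...\n")
    }
})
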
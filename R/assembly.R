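# --- flexible repeat assembly ---------------------------------------------
#
# Greedy seed-and-extend construction of flexible repeats from maximal
# repeats. A seed (the largest remaining MR) is paired with a further MR
# when, on at least MinSequences sequences, occurrences A x B (or B x A)
# exist whose spacers x satisfy the length condition
# |x| <= |A| * Maxratio/100 and, pairwise across sequences, the distance
# condition e(x, y) <= min(b_x, b_y). Pairs are vertices of a
# compatibility graph; a clique covering MinSequences distinct sequences
# certifies the flexible repeat.

#' Levenshtein edit distance
#'
#' Unit-cost edit distance between words (substitution, insertion,
#' deletion all cost 1). Vectorized elementwise with recycling.
#'
#' @param x,y character vectors.
#' @return integer vector of distances.
#' @examples
#' editDistance("", "ACG")      # 3
#' editDistance("GATT", "GTAT") # 2
#' @export
editDistance <- function(x, y) {
    n <- max(length(x), length(y))
    x <- rep_len(as.character(x), n)
    y <- rep_len(as.character(y), n)
    as.integer(diag(utils::adist(x, y, partial = FALSE)))
}

# edit distance matrix between all pairs of a character vector
.editDistMatrix <- function(x) utils::adist(x, x)

#' Collect spacer-constrained pair candidates
#'
#' For every seed occurrence A, finds the occurrences B of a candidate MR
#' on the same sequence such that A x B (orientation \code{"+"}) or
#' B x A (orientation \code{"-"}) is a subword of the sequence and the
#' spacer x has length at most |A| * maxratio/100, |A| being the seed
#' occurrence's span. The spacer may be empty.
#'
#' @param seedOcc data.frame of seed occurrences with columns \code{seq},
#'   \code{start}, \code{end} (0-based half-open).
#' @param nextOcc data.frame of candidate MR occurrences, same columns.
#' @param family the sequence family (named \code{DNAStringSet} or
#'   character).
#' @param maxratio percentage in (0, 100] bounding spacer length.
#' @return data.frame of pair candidates: \code{seedRow}, \code{nextRow},
#'   \code{seq}, \code{orientation}, \code{spacer}, \code{b} (size of the
#'   candidate occurrence), \code{start}, \code{end} (combined span).
#' @export
collectPairs <- function(seedOcc, nextOcc, family, maxratio = 100) {
    stopifnot(maxratio > 0, maxratio <= 100)
    seqs <- .famChar(family)
    out <- list()
    for (r in seq_len(nrow(seedOcc))) {
        s <- seedOcc$seq[r]; st <- seedOcc$start[r]; en <- seedOcc$end[r]
        w <- floor((en - st) * maxratio / 100)
        same <- which(nextOcc$seq == s)
        # A x B : B to the right of A
        ax <- same[nextOcc$start[same] >= en & nextOcc$start[same] <= en + w]
        for (j in ax) out[[length(out) + 1L]] <- data.frame(
            seedRow = r, nextRow = j, seq = s, orientation = "+",
            spacer = substr(seqs[s], en + 1L, nextOcc$start[j]),
            b = nextOcc$end[j] - nextOcc$start[j],
            start = st, end = nextOcc$end[j])
        # B x A : B to the left of A
        bx <- same[nextOcc$end[same] <= st & nextOcc$end[same] >= st - w]
        for (j in bx) out[[length(out) + 1L]] <- data.frame(
            seedRow = r, nextRow = j, seq = s, orientation = "-",
            spacer = substr(seqs[s], nextOcc$end[j] + 1L, st),
            b = nextOcc$end[j] - nextOcc$start[j],
            start = nextOcc$start[j], end = en)
    }
    if (!length(out))
        return(data.frame(seedRow = integer(), nextRow = integer(),
                          seq = integer(), orientation = character(),
                          spacer = character(), b = integer(),
                          start = integer(), end = integer()))
    do.call(rbind, out)
}

#' Build the spacer-compatibility graph GB
#'
#' Vertices are pair candidates; an undirected edge joins two candidates of
#' the same orientation whose spacers x, y satisfy
#' e(x, y) <= min(b_x, b_y).
#'
#' @param pairs data.frame from \code{\link{collectPairs}}.
#' @return list with elements \code{pairs} and \code{adj} (logical
#'   adjacency matrix, FALSE diagonal).
#' @export
buildCompatibilityGraph <- function(pairs) {
    n <- nrow(pairs)
    adj <- matrix(FALSE, n, n)
    if (n > 1L) {
        d <- .editDistMatrix(pairs$spacer)
        bmin <- outer(pairs$b, pairs$b, pmin)
        sameOri <- outer(pairs$orientation, pairs$orientation, "==")
        adj <- d <= bmin & sameOri
        diag(adj) <- FALSE
    }
    list(pairs = pairs, adj = adj)
}

# greedy clique heuristic: keep vertices whose closed neighbourhood covers
# >= minSeq distinct sequences, then iteratively add the highest-degree
# vertex of the remaining graph that stays adjacent to all chosen vertices
# (ties by lowest sequence index, then position). Vertices sharing a seed
# or candidate occurrence with a chosen vertex, or overlapping a chosen
# combined span on the same sequence, are not addable.
.greedyCliqueOri <- function(pairs, adj, verts, minSeq) {
    if (!length(verts)) return(NULL)
    covers <- vapply(verts, function(i) {
        nb <- c(i, verts[adj[i, verts]])
        length(unique(pairs$seq[nb]))
    }, 1L)
    verts <- verts[covers >= minSeq]
    if (!length(verts)) return(NULL)
    chosen <- integer()
    rem <- verts
    while (length(rem)) {
        deg <- vapply(rem, function(i) sum(adj[i, rem]), 1L)
        o <- order(-deg, pairs$seq[rem], pairs$start[rem])
        pick <- rem[o[1L]]
        chosen <- c(chosen, pick)
        ok <- vapply(rem, function(i) {
            if (i == pick) return(FALSE)
            if (!all(adj[i, chosen])) return(FALSE)
            if (pairs$seedRow[i] %in% pairs$seedRow[chosen]) return(FALSE)
            if (pairs$nextRow[i] %in% pairs$nextRow[chosen]) return(FALSE)
            sameSeq <- chosen[pairs$seq[chosen] == pairs$seq[i]]
            !any(pairs$start[sameSeq] < pairs$end[i] &
                 pairs$end[sameSeq] > pairs$start[i])
        }, TRUE)
        rem <- rem[ok]
    }
    if (length(unique(pairs$seq[chosen])) >= minSeq) chosen else NULL
}

#' Find a support clique in the compatibility graph
#'
#' Heuristic clique search as used during assembly: vertices connected to
#' at least \code{minSequences} vertices of distinct sequences are kept,
#' then vertices of highest degree in the remaining graph are added
#' greedily while mutual adjacency holds. Orientations are searched
#' separately (\code{"+"} first); there is no guarantee of finding an
#' existing clique (heuristic contract).
#'
#' @param graph list from \code{\link{buildCompatibilityGraph}}.
#' @param minSequences minimum number of distinct sequences the clique
#'   must cover (composite repeats require at least 2).
#' @return integer vector of row indices into \code{graph$pairs}, or
#'   \code{NULL}.
#' @export
findSupportClique <- function(graph, minSequences) {
    pairs <- graph$pairs
    minSeq <- max(2L, minSequences)
    for (ori in c("+", "-")) {
        verts <- which(pairs$orientation == ori)
        cl <- .greedyCliqueOri(pairs, graph$adj, verts, minSeq)
        if (!is.null(cl)) return(sort(cl))
    }
    NULL
}

# --- working-list machinery -----------------------------------------------

# internal active list: list(word, len, occ = data.frame(mr, seq, start,
# end, strand), rank = L order == seq_along(word))
.lstFromMRL <- function(mrl) {
    list(word = mrl@word, len = mrl@mrLength, occ = mrl@occurrences)
}

.lstToMRL <- function(lst) {
    f <- .filterMRSupport(lst$word, lst$len, lst$occ, 1L)
    .newMRList(f$word, f$len, f$occ)
}

# per-sequence lookup of occurrence rows sorted by start and by end
.lstIndex <- function(lst) {
    occ <- lst$occ
    rows <- seq_len(nrow(occ))
    bySeq <- split(rows, occ$seq)
    lapply(bySeq, function(rr) {
        os <- rr[order(occ$start[rr])]
        oe <- rr[order(occ$end[rr])]
        list(byStart = os, starts = occ$start[os],
             byEnd = oe, ends = occ$end[oe])
    })
}

# all candidate (flexOcc, occRow) pairs within spacer range of the flex
# occurrences; returns df flexRow, row, orientation, spacerStart, spacerEnd
.candidateRows <- function(flexOcc, lst, idx, maxratio) {
    out <- vector("list", 2L * nrow(flexOcc))
    k <- 0L
    for (r in seq_len(nrow(flexOcc))) {
        s <- as.character(flexOcc$seq[r])
        ix <- idx[[s]]
        if (is.null(ix)) next
        st <- flexOcc$start[r]; en <- flexOcc$end[r]
        w <- floor((en - st) * maxratio / 100)
        lo <- findInterval(en - 0.5, ix$starts) + 1L
        hi <- findInterval(en + w + 0.5, ix$starts)
        if (hi >= lo) {
            rows <- ix$byStart[lo:hi]
            k <- k + 1L
            out[[k]] <- data.frame(flexRow = r, row = rows, orientation = "+",
                                   spacerStart = en,
                                   spacerEnd = lst$occ$start[rows])
        }
        lo <- findInterval(st - w - 0.5, ix$ends) + 1L
        hi <- findInterval(st + 0.5, ix$ends)
        if (hi >= lo) {
            rows <- ix$byEnd[lo:hi]
            k <- k + 1L
            out[[k]] <- data.frame(flexRow = r, row = rows, orientation = "-",
                                   spacerStart = lst$occ$end[rows],
                                   spacerEnd = st)
        }
    }
    if (k == 0L)
        return(data.frame(flexRow = integer(), row = integer(),
                          orientation = character(), spacerStart = integer(),
                          spacerEnd = integer()))
    do.call(rbind, out[seq_len(k)])
}

# core of Algorithm 2 given precomputed candidates for one Next MR
.tryNext <- function(cand, lst, flexOcc, minSeq, seqs) {
    b <- lst$len[lst$occ$mr[cand$row[1L]]]
    spacer <- substr(seqs[lst$occ$seq[cand$row]],
                     cand$spacerStart + 1L, cand$spacerEnd)
    pairs <- data.frame(
        seedRow = cand$flexRow, nextRow = cand$row,
        seq = lst$occ$seq[cand$row], orientation = cand$orientation,
        spacer = spacer, b = b,
        start = ifelse(cand$orientation == "+",
                       flexOcc$start[cand$flexRow], lst$occ$start[cand$row]),
        end = ifelse(cand$orientation == "+",
                     lst$occ$end[cand$row], flexOcc$end[cand$flexRow]))
    gb <- buildCompatibilityGraph(pairs)
    cl <- findSupportClique(gb, minSeq)
    if (is.null(cl)) return(NULL)
    pairs[cl, , drop = FALSE]
}

#' Search the working list for a pairable maximal repeat (Algorithm 2)
#'
#' Scans the sorted working list from \code{startIndex} and returns the
#' first MR (largest, then most occurrences) for which a clique of
#' spacer-compatible associations with the seed covers at least
#' \code{minSequences} distinct sequences.
#'
#' @param L a \code{\linkS4class{MaximalRepeatList}} (the working list).
#' @param seed data.frame of seed occurrences (\code{seq}, \code{start},
#'   \code{end}, 0-based half-open).
#' @param startIndex first index of \code{L} to consider.
#' @param minSequences support requirement for the clique.
#' @param maxratio spacer length bound, percent of the seed span.
#' @param family the sequence family.
#' @return list with \code{nextIndex} (index into \code{L} or \code{NA}),
#'   \code{clique} (data.frame of the chosen pair candidates or
#'   \code{NULL}) and \code{ok}.
#' @export
buildPair <- function(L, seed, startIndex, minSequences, maxratio, family) {
    lst <- .lstFromMRL(L)
    res <- .buildPairLst(lst, seed, startIndex, minSequences, maxratio,
                         .famChar(family), .lstIndex(lst))
    if (is.null(res)) list(nextIndex = NA_integer_, clique = NULL, ok = FALSE)
    else list(nextIndex = res$next_mr, clique = res$clique, ok = TRUE)
}

.buildPairLst <- function(lst, flexOcc, startIndex, minSeq, maxratio,
                          seqs, idx) {
    cand <- .candidateRows(flexOcc, lst, idx, maxratio)
    if (!nrow(cand)) return(NULL)
    cand$mr <- lst$occ$mr[cand$row]
    cand <- cand[cand$mr >= startIndex & lst$occ$strand[cand$row] == "+", ,
                 drop = FALSE]
    if (!nrow(cand)) return(NULL)
    effMin <- max(2L, minSeq)
    for (m in sort(unique(cand$mr))) {
        sub <- cand[cand$mr == m, , drop = FALSE]
        # quick support screen per orientation
        okOri <- FALSE
        for (ori in c("+", "-")) {
            so <- sub[sub$orientation == ori, , drop = FALSE]
            if (length(unique(lst$occ$seq[so$row])) >= effMin) okOri <- TRUE
        }
        if (!okOri) next
        cl <- .tryNext(sub, lst, flexOcc, minSeq, seqs)
        if (!is.null(cl)) return(list(next_mr = m, clique = cl))
    }
    NULL
}

# --- Algorithm 1 -----------------------------------------------------------

.emptyFlex <- function() list(parts = character(), partLens = integer(),
                              junctionAdded = character(),
                              occ = NULL, spacers = list())

# merge a clique into the flexible repeat, returning the extended repeat
.extendFlex <- function(flex, nextWord, nextLen, clique, lst) {
    ori <- clique$orientation[1L]
    newOcc <- data.frame(seq = clique$seq, start = clique$start,
                         end = clique$end)
    spacers <- vector("list", nrow(clique))
    for (i in seq_len(nrow(clique))) {
        old <- flex$spacers[[clique$seedRow[i]]]
        spacers[[i]] <- if (ori == "+") c(old, clique$spacer[i])
                        else c(clique$spacer[i], old)
    }
    if (ori == "+") {
        flex$parts <- c(flex$parts, nextWord)
        flex$partLens <- c(flex$partLens, nextLen)
        flex$junctionAdded <- c(flex$junctionAdded, "R")
    } else {
        flex$parts <- c(nextWord, flex$parts)
        flex$partLens <- c(nextLen, flex$partLens)
        flex$junctionAdded <- c("L", flex$junctionAdded)
    }
    flex$occ <- newOcc
    flex$spacers <- spacers
    flex
}

# occurrence keys for consumption bookkeeping
.occKey <- function(occ, rows = seq_len(nrow(occ))) {
    paste(occ$seq[rows], occ$start[rows], occ$end[rows], occ$strand[rows])
}

.dropRows <- function(lst, rows) {
    if (!length(rows)) return(lst)
    lst$occ <- lst$occ[-rows, , drop = FALSE]
    rownames(lst$occ) <- NULL
    lst
}

#' Build one module from the working list (Algorithm 1)
#'
#' Considers seeds in decreasing order of size; on the first seed with a
#' qualifying pair, consumes the paired occurrences and repeatedly extends
#' the flexible repeat left or right until no further pair qualifies. The
#' result is a module when every retained occurrence spans at least
#' \code{minSizeModule} nt. When no seed pairs at all, a lone MR meeting
#' the size and support conditions is emitted as a single-MR module.
#'
#' @param L a \code{\linkS4class{MaximalRepeatList}}.
#' @param minSequences support requirement at this detection round.
#' @param minSizeModule minimum occurrence span of a module, nt.
#' @param maxratio spacer length bound, percent.
#' @param family the sequence family.
#' @param reserved MR words withheld from seeding or joining new modules
#'   (used to reserve parts of accepted modules for the truncated pass).
#' @param skipSeeds seed words already known not to pair at this support
#'   level (memoisation; occurrence removal cannot make them pairable).
#' @param pairSearch run the seed-and-extend pair search.
#' @param allowSingle emit a single-MR module when no seed pairs.
#' @return list with \code{module} (internal flexible-repeat structure or
#'   \code{NULL}), \code{L} (the pruned working list), \code{status}
#'   (\code{"module"}, \code{"undersize"} or \code{"none"}),
#'   \code{failedSeeds}, and \code{consumed} (occurrence keys removed).
#' @export
buildModules <- function(L, minSequences, minSizeModule, maxratio, family,
                         reserved = character(), skipSeeds = character(),
                         pairSearch = TRUE, allowSingle = TRUE) {
    seqs <- .famChar(family)
    lst <- .lstFromMRL(L)
    # occurrences of reserved words are invisible to assembly (kept for the
    # reverse/truncated passes, which search the sequences directly)
    if (length(reserved)) {
        resMr <- which(lst$word %in% reserved)
        if (length(resMr))
            lst <- .dropRows(lst, which(lst$occ$mr %in% resMr))
    }
    m <- length(lst$word)
    consumed <- character()
    failed <- character()
    shields <- list()
    idx <- .lstIndex(lst)
    sup <- integer(m)
    bySeq <- split(lst$occ$seq, factor(lst$occ$mr, seq_len(m)))
    sup[seq_len(m)] <- vapply(bySeq, function(s) length(unique(s)), 1L)
    flex <- NULL
    i <- 0L
    while (pairSearch && i < m && is.null(flex)) {
        i <- i + 1L
        if (lst$word[i] %in% skipSeeds) next
        if (sup[i] < max(2L, minSequences)) next
        seedRows <- which(lst$occ$mr == i & lst$occ$strand == "+")
        if (!length(seedRows)) next
        seedOcc <- data.frame(seq = lst$occ$seq[seedRows],
                              start = lst$occ$start[seedRows],
                              end = lst$occ$end[seedRows])
        res <- .buildPairLst(lst, seedOcc, i + 1L, minSequences, maxratio,
                             seqs, idx)
        if (is.null(res)) {
            failed <- c(failed, lst$word[i])
            # a module-sized seed that cannot pair shields its loci:
            # occurrences of other repeats nested in (or straddling) them
            # are withheld, so sub-word chains cannot fragment a
            # conserved core that may still pair, single out, or serve
            # the truncated pass at a lower support level
            if (lst$len[i] >= minSizeModule) {
                ov <- rep(FALSE, nrow(lst$occ))
                for (r in seq_len(nrow(seedOcc)))
                    ov <- ov | (lst$occ$seq == seedOcc$seq[r] &
                                lst$occ$start < seedOcc$end[r] &
                                lst$occ$end > seedOcc$start[r])
                drop <- which(ov & lst$occ$mr != i)
                if (length(drop)) {
                    lst <- .dropRows(lst, drop)
                    idx <- .lstIndex(lst)
                }
                shields[[length(shields) + 1L]] <-
                    list(word = lst$word[i], intervals = seedOcc)
            }
            next
        }
        # found (Seed, Next): discard the paired occurrences of Seed from L
        flex <- list(parts = lst$word[i], partLens = lst$len[i],
                     junctionAdded = character(),
                     occ = seedOcc, spacers = rep(list(character()),
                                                  nrow(seedOcc)))
        usedSeed <- seedRows[res$clique$seedRow]
        consumed <- c(consumed, .occKey(lst$occ, usedSeed))
        flex <- .extendFlex(flex, lst$word[res$next_mr],
                            lst$len[res$next_mr], res$clique, lst)
        usedNext <- res$clique$nextRow
        consumed <- c(consumed, .occKey(lst$occ, usedNext))
        lst <- .dropRows(lst, unique(c(usedSeed, usedNext)))
        # extension loop: enlarge left or right until no pair qualifies
        repeat {
            idx <- .lstIndex(lst)
            res <- .buildPairLst(lst, flex$occ, 1L, minSequences, maxratio,
                                 seqs, idx)
            if (is.null(res)) break
            flex <- .extendFlex(flex, lst$word[res$next_mr],
                                lst$len[res$next_mr], res$clique, lst)
            usedNext <- res$clique$nextRow
            consumed <- c(consumed, .occKey(lst$occ, usedNext))
            lst <- .dropRows(lst, unique(usedNext))
        }
    }
    if (!is.null(flex)) {
        spans <- flex$occ$end - flex$occ$start
        if (min(spans) >= minSizeModule)
            return(list(module = flex, L = .lstToMRL(lst),
                        status = "module", failedSeeds = failed,
                        consumed = consumed, shields = shields))
        return(list(module = NULL, L = .lstToMRL(lst), status = "undersize",
                    failedSeeds = failed, consumed = consumed,
                    shields = shields))
    }
    # no seed paired: emit a qualifying single-MR module, if any
    if (allowSingle) for (j in seq_len(m)) {
        if (lst$len[j] < minSizeModule) next
        rows <- which(lst$occ$mr == j & lst$occ$strand == "+")
        # keep a non-overlapping subset, left to right (self-overlapping
        # occurrences arise in tandem/homopolymer contexts)
        rows <- rows[order(lst$occ$seq[rows], lst$occ$start[rows])]
        keep <- logical(length(rows)); lastEnd <- -1L; lastSeq <- -1L
        for (k in seq_along(rows)) {
            r <- rows[k]
            if (lst$occ$seq[r] != lastSeq || lst$occ$start[r] >= lastEnd) {
                keep[k] <- TRUE
                lastSeq <- lst$occ$seq[r]; lastEnd <- lst$occ$end[r]
            }
        }
        rows <- rows[keep]
        if (length(unique(lst$occ$seq[rows])) < minSequences) next
        flex <- list(parts = lst$word[j], partLens = lst$len[j],
                     junctionAdded = character(),
                     occ = data.frame(seq = lst$occ$seq[rows],
                                      start = lst$occ$start[rows],
                                      end = lst$occ$end[rows]),
                     spacers = rep(list(character()), length(rows)))
        consumed <- c(consumed, .occKey(lst$occ, rows))
        lst <- .dropRows(lst, rows)
        return(list(module = flex, L = .lstToMRL(lst), status = "module",
                    failedSeeds = failed, consumed = consumed,
                    shields = shields))
    }
    list(module = NULL, L = .lstToMRL(lst), status = "none",
         failedSeeds = failed, consumed = consumed, shields = shields)
}
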
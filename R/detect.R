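# --- module detection ------------------------------------------------------

# all exact (possibly overlapping) 0-based match starts of word in one seq
.matchWord <- function(word, seqchar) {
    if (nchar(word) > nchar(seqchar)) return(integer())
    m <- Biostrings::matchPattern(word, Biostrings::DNAString(seqchar))
    as.integer(Biostrings::start(m)) - 1L
}

.emptyOccDf <- function() data.frame(
    module = integer(), seq = integer(), start = integer(), end = integer(),
    strand = character(), kind = character(), fraction = numeric(),
    conserved = character())

.overlapsCovered <- function(seq, start, end, covered) {
    if (!NROW(covered)) return(FALSE)
    any(covered$seq == seq & covered$start < end & covered$end > start)
}

# remove occurrence rows of an MRList by key (seq start end strand)
.removeKeys <- function(mrl, keys) {
    if (!length(keys)) return(mrl)
    occ <- mrl@occurrences
    keep <- !(.occKey(occ) %in% keys)
    f <- .filterMRSupport(mrl@word, mrl@mrLength, occ[keep, , drop = FALSE], 1L)
    .newMRList(f$word, f$len, f$occ)
}

# While a repeat of at least part scale (length >= minSizeModule/2) is
# pending — its support is below the current detection level — fragments
# shorter than half its length may not claim its loci at this level:
# chance matches elsewhere can prop a sub-word chain up to full support
# and fragment a conserved core before its true support level is
# reached. Returns the level view with such fragment occurrences
# removed.
.shieldPendingCores <- function(view, cur, level, minSizeModule) {
    pOcc <- cur@occurrences
    pLen <- cur@mrLength
    pend <- which(cur@support < level & pLen >= minSizeModule / 2)
    if (!length(pend)) return(view)
    rows <- which(pOcc$mr %in% pend)
    if (!length(rows)) return(view)
    occ <- view@occurrences
    lenOcc <- view@mrLength[occ$mr]
    drop <- rep(FALSE, nrow(occ))
    for (r in rows) {
        lim <- pLen[pOcc$mr[r]] / 2
        drop <- drop | (occ$seq == pOcc$seq[r] &
                        occ$start < pOcc$end[r] &
                        occ$end > pOcc$start[r] & lenOcc < lim)
    }
    if (!any(drop)) return(view)
    f <- .filterMRSupport(view@word, view@mrLength,
                          occ[!drop, , drop = FALSE], 1L)
    .newMRList(f$word, f$len, f$occ)
}

# remove occurrences overlapping shielded intervals, except those of the
# shielding word itself
.removeOverlapExcept <- function(mrl, intervals, word) {
    occ <- mrl@occurrences
    if (!nrow(occ) || !NROW(intervals)) return(mrl)
    ov <- rep(FALSE, nrow(occ))
    for (r in seq_len(nrow(intervals)))
        ov <- ov | (occ$seq == intervals$seq[r] &
                    occ$start < intervals$end[r] &
                    occ$end > intervals$start[r])
    keep <- !(ov & mrl@word[occ$mr] != word)
    f <- .filterMRSupport(mrl@word, mrl@mrLength, occ[keep, , drop = FALSE],
                          1L)
    .newMRList(f$word, f$len, f$occ)
}

# allowed spacer-length windows per junction: observed min/max among the
# module's direct occurrences, widened by ceiling(maxratio/100 * smaller
# flanking part)
.spacerWindows <- function(mod, maxratio) {
    P <- length(mod$parts)
    if (P < 2L) return(list())
    lapply(seq_len(P - 1L), function(j) {
        lens <- nchar(mod$spacerSets[[j]])
        s <- ceiling(maxratio / 100 * min(mod$partLengths[j],
                                          mod$partLengths[j + 1L]))
        c(max(0L, min(lens) - s), max(lens) + s)
    })
}

# chain matcher used by the reverse and truncated searches.
# parts/partLens: composition to match left-to-right; windows: list of
# c(lo, hi) spacer-length bounds per junction; distCheck: NULL or
# function(j, spacer) -> logical; anchor: part index that must be present
# (requireAll = FALSE allows contiguous partial chains around the anchor).
.chainSearch <- function(parts, partLens, windows, distCheck, seqs,
                         covered, anchor = 1L, requireAll = TRUE) {
    P <- length(parts)
    hits <- list()
    for (s in seq_along(seqs)) {
        matches <- lapply(parts, function(p) {
            st <- .matchWord(p, seqs[s])
            st[!vapply(st, function(x)
                .overlapsCovered(s, x, x + nchar(p), covered), TRUE)]
        })
        for (a in sort(matches[[anchor]])) {
            aEnd <- a + partLens[anchor]
            if (.overlapsCovered(s, a, aEnd, covered)) next
            lo <- anchor; hi <- anchor
            span <- c(a, aEnd)
            ok <- TRUE
            # extend right
            j <- anchor
            while (j < P) {
                win <- windows[[j]]
                cands <- matches[[j + 1L]]
                cands <- cands[cands - span[2L] >= win[1L] &
                               cands - span[2L] <= win[2L]]
                if (!is.null(distCheck) && length(cands))
                    cands <- cands[vapply(cands, function(cs) distCheck(
                        j, substr(seqs[s], span[2L] + 1L, cs)), TRUE)]
                if (!length(cands)) { if (requireAll) ok <- FALSE; break }
                nxt <- min(cands)
                span[2L] <- nxt + partLens[j + 1L]
                hi <- j + 1L
                j <- j + 1L
            }
            # extend left
            j <- anchor
            while (ok && j > 1L) {
                win <- windows[[j - 1L]]
                cands <- matches[[j - 1L]]
                ends <- cands + partLens[j - 1L]
                keep <- span[1L] - ends >= win[1L] & span[1L] - ends <= win[2L]
                cands <- cands[keep]; ends <- ends[keep]
                if (!is.null(distCheck) && length(cands))
                    keep2 <- vapply(seq_along(cands), function(k) distCheck(
                        j - 1L, substr(seqs[s], ends[k] + 1L, span[1L])), TRUE)
                else keep2 <- rep(TRUE, length(cands))
                cands <- cands[keep2]
                if (!length(cands)) { if (requireAll) ok <- FALSE; break }
                nxt <- max(cands)
                span[1L] <- nxt
                lo <- j - 1L
                j <- j - 1L
            }
            if (!ok) next
            if (.overlapsCovered(s, span[1L], span[2L], covered)) next
            hits[[length(hits) + 1L]] <- data.frame(
                seq = s, start = span[1L], end = span[2L],
                lo = lo, hi = hi)
            covered <- rbind(covered, data.frame(
                seq = s, start = span[1L], end = span[2L]))
        }
    }
    if (!length(hits)) return(NULL)
    do.call(rbind, hits)
}

# internal reverse-occurrence search on explicit covered intervals
.reverseOccIntern <- function(mod, seqs, covered, maxratio) {
    P <- length(mod$parts)
    partsRC <- rev(revComp(mod$parts))
    lensRC <- rev(mod$partLengths)
    win <- .spacerWindows(mod, maxratio)
    winRC <- if (P >= 2L) lapply(seq_len(P - 1L), function(k) win[[P - k]])
             else list()
    distCheck <- if (P >= 2L) function(k, x) {
        j <- P - k  # original junction index
        lim <- min(mod$partLengths[j], mod$partLengths[j + 1L])
        any(editDistance(rep(revComp(x), length(mod$spacerSets[[j]])),
                         mod$spacerSets[[j]]) <= lim)
    } else NULL
    res <- .chainSearch(partsRC, lensRC, winRC, distCheck, seqs, covered,
                        anchor = 1L, requireAll = TRUE)
    if (is.null(res)) return(.emptyOccDf())
    data.frame(module = mod$id, seq = res$seq, start = res$start,
               end = res$end, strand = "-", kind = "reverse", fraction = 1,
               conserved = paste(seq_len(P), collapse = ","))
}

# internal truncated search (direct and, if enabled, reverse orientation)
.truncatedOccIntern <- function(mod, seqs, covered, maxratio, reverse) {
    P <- length(mod$parts)
    total <- sum(mod$partLengths)
    largest <- which.max(mod$partLengths)
    win <- .spacerWindows(mod, maxratio)
    out <- .emptyOccDf()
    res <- .chainSearch(mod$parts, mod$partLengths, win, NULL, seqs,
                        covered, anchor = largest, requireAll = FALSE)
    if (!is.null(res)) {
        for (r in seq_len(nrow(res))) {
            present <- res$lo[r]:res$hi[r]
            frac <- sum(mod$partLengths[present]) / total
            out <- rbind(out, data.frame(
                module = mod$id, seq = res$seq[r], start = res$start[r],
                end = res$end[r], strand = "+",
                kind = if (frac == 1) "direct" else "truncated_direct",
                fraction = frac,
                conserved = paste(present, collapse = ",")))
        }
        covered <- rbind(covered, res[c("seq", "start", "end")])
    }
    if (reverse) {
        partsRC <- rev(revComp(mod$parts))
        lensRC <- rev(mod$partLengths)
        winRC <- if (P >= 2L) lapply(seq_len(P - 1L),
                                     function(k) win[[P - k]]) else list()
        anchorRC <- P - largest + 1L
        res <- .chainSearch(partsRC, lensRC, winRC, NULL, seqs, covered,
                            anchor = anchorRC, requireAll = FALSE)
        if (!is.null(res)) {
            for (r in seq_len(nrow(res))) {
                presentRC <- res$lo[r]:res$hi[r]
                present <- sort(P - presentRC + 1L)  # original part indices
                frac <- sum(mod$partLengths[present]) / total
                out <- rbind(out, data.frame(
                    module = mod$id, seq = res$seq[r], start = res$start[r],
                    end = res$end[r], strand = "-",
                    kind = if (frac == 1) "reverse" else "truncated_reverse",
                    fraction = frac,
                    conserved = paste(present, collapse = ",")))
            }
        }
    }
    out
}

.modFromFlex <- function(flex, id) {
    P <- length(flex$parts)
    spacerSets <- if (P >= 2L)
        lapply(seq_len(P - 1L), function(j)
            vapply(flex$spacers, function(sp) sp[j], ""))
    else list()
    list(id = id, parts = flex$parts, partLengths = flex$partLens,
         totalMRLength = sum(flex$partLens),
         supportAtDiscovery = NA_integer_,
         junctionAdded = flex$junctionAdded,
         spacerSets = spacerSets, spacers = flex$spacers)
}

#' Detect all modules of a family
#'
#' Runs the full detection loop: maximal repeats are enumerated, then
#' modules are assembled greedily at decreasing support levels
#' (MinSequences from n down to 1, or a fixed user value), each accepted
#' module pruning the working list of overlapping occurrences so that
#' module occurrences never overlap (partition condition). With
#' \code{reverse}, each module's reverse-complemented, order-reversed
#' composition is searched immediately after acceptance and reverse
#' occurrences count toward its support. With \code{truncated}, partial
#' occurrences retaining the module's largest MR are added in a second
#' step once all complete modules are placed.
#'
#' @param family named \code{DNAStringSet} or character vector.
#' @param minSizeModule minimum occurrence span in nt; default is the
#'   data-driven rule of \code{\link{defaultMinSizeModule}}.
#' @param maxratio spacer length bound, percent of the seed span, in
#'   (0, 100].
#' @param minSequences fixed support level; default sweeps n down to 1.
#' @param reverse search for reverse (palindromic) module occurrences.
#' @param truncated search for truncated module occurrences.
#' @param verbose log seed/extension decisions.
#' @return a \code{\linkS4class{ModuleCatalog}}.
#' @export
detectModules <- function(family, minSizeModule = NULL, maxratio = 100,
                          minSequences = NULL, reverse = FALSE,
                          truncated = FALSE, verbose = FALSE) {
    seqs <- .famChar(family)
    n <- length(seqs)
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_len(n))
    stopifnot(maxratio > 0, maxratio <= 100)
    if (is.null(minSizeModule)) minSizeModule <- defaultMinSizeModule(seqs)
    stopifnot(minSizeModule >= 1)
    if (!is.null(minSequences))
        stopifnot(minSequences >= 1, minSequences <= n)
    params <- list(minSizeModule = as.integer(minSizeModule),
                   maxratio = maxratio,
                   minSequences = if (is.null(minSequences)) NA_integer_
                                  else as.integer(minSequences),
                   reverse = reverse, truncated = truncated)
    mkCatalog <- function(mods, occ) {
        occ <- occ[order(occ$seq, occ$start), , drop = FALSE]
        rownames(occ) <- NULL
        new("ModuleCatalog", modules = mods, occurrences = occ,
            seqnames = ids, seqlengths = nchar(seqs), params = params)
    }
    if (minSizeModule > max(nchar(seqs))) {
        warning("MinSizeModule exceeds every sequence length; ",
                "no module can exist")
        return(mkCatalog(list(), .emptyOccDf()))
    }
    cur <- enumerateMaximalRepeats(seqs, minSupport = 1L,
                                   includeReverse = FALSE)
    covered <- data.frame(seq = integer(), start = integer(),
                          end = integer())
    mods <- list()
    occAll <- .emptyOccDf()
    reserved <- character()
    levels <- if (is.null(minSequences)) rev(seq_len(n)) else minSequences
    # accept a built flexible repeat as the next module: number it, search
    # its reverse form if asked, record occurrences and prune the lists
    view <- NULL; level <- NA_integer_
    accept <- function(flex) {
        id <- length(mods) + 1L
        mod <- .modFromFlex(flex, id)
        occNew <- data.frame(
            module = id, seq = flex$occ$seq, start = flex$occ$start,
            end = flex$occ$end, strand = "+", kind = "direct",
            fraction = 1,
            conserved = paste(seq_along(flex$parts), collapse = ","))
        coveredNow <- rbind(covered, occNew[c("seq", "start", "end")])
        if (reverse) {
            rv <- .reverseOccIntern(mod, seqs, coveredNow, maxratio)
            occNew <- rbind(occNew, rv)
        }
        mod$supportAtDiscovery <- length(unique(occNew$seq))
        if (verbose)
            message(sprintf("level %d: module %d (%s), %d occurrence(s)",
                            level, id, paste(mod$parts, collapse = "|"),
                            nrow(occNew)))
        mods[[id]] <<- mod
        occAll <<- rbind(occAll, occNew)
        covered <<- rbind(covered, occNew[c("seq", "start", "end")])
        spans <- occNew[c("seq", "start", "end")]
        cur <<- pruneOccurrences(cur, spans, 1L)
        view <<- pruneOccurrences(view, spans, max(1L, level))
        if (truncated) {
            # shield every sequence match of the module's parts (and
            # their reverse complements when the reverse search is on):
            # leftover copies of the parts are reserved for the
            # second-step truncated pass instead of seeding new modules
            anchors <- mod$parts[mod$partLengths >= minSizeModule / 2]
            words <- unique(c(anchors, if (reverse) revComp(anchors)))
            ivs <- list()
            for (p in words) for (s in seq_along(seqs)) {
                st <- .matchWord(p, seqs[s])
                if (length(st))
                    ivs[[length(ivs) + 1L]] <- data.frame(
                        seq = s, start = st, end = st + nchar(p))
            }
            if (length(ivs)) {
                shield <- do.call(rbind, ivs)
                cur <<- pruneOccurrences(cur, shield, 1L)
                view <<- pruneOccurrences(view, shield, max(1L, level))
            }
        }
    }
    for (level in levels) {
        view <- pruneOccurrences(cur, NULL, minSupport = level)
        view <- .shieldPendingCores(view, cur, level, minSizeModule)
        failed <- character()
        # phase 1: seed-and-extend pair search; an undersize chain ends
        # it (Algorithm 1 returns the empty set then). phase 2: lone MRs
        # meeting the size and support conditions at this level are
        # emitted before the level is left.
        phase <- 1L
        repeat {
            res <- buildModules(view, level, minSizeModule, maxratio, seqs,
                                reserved = reserved, skipSeeds = failed,
                                pairSearch = phase == 1L,
                                allowSingle = phase == 2L)
            failed <- union(failed, res$failedSeeds)
            cur <- .removeKeys(cur, res$consumed)
            for (sh in res$shields)
                cur <- .removeOverlapExcept(cur, sh$intervals, sh$word)
            view <- res$L
            if (res$status %in% c("none", "undersize")) {
                if (phase == 1L) { phase <- 2L; next }
                break
            }
            accept(res$module)
        }
    }
    if (truncated) {
        for (mod in mods) {
            tr <- .truncatedOccIntern(mod, seqs, covered, maxratio, reverse)
            if (nrow(tr)) {
                occAll <- rbind(occAll, tr)
                covered <- rbind(covered, tr[c("seq", "start", "end")])
            }
        }
    }
    mkCatalog(mods, occAll)
}

#' Reverse occurrences of a module
#'
#' Searches uncovered regions for the module's reverse form: the
#' reverse-complemented MRs in reversed order, spacers re-checked against
#' the module's own observed spacers (edit distance at most the smaller
#' flanking part).
#'
#' @param module module id in \code{catalog}.
#' @param family the sequence family.
#' @param catalog a \code{\linkS4class{ModuleCatalog}}.
#' @return data.frame of reverse occurrences (0-based half-open), possibly
#'   empty.
#' @export
findReverseOccurrences <- function(module, family, catalog) {
    mod <- catalog@modules[[module]]
    occ <- catalog@occurrences
    .reverseOccIntern(mod, .famChar(family), occ[c("seq", "start", "end")],
                      catalog@params$maxratio)
}

#' Truncated occurrences of a module
#'
#' Searches uncovered regions for partial occurrences that retain the
#' module's largest MR, attaching the other MRs in their original relative
#' order within the observed spacer-length bounds. The conserved fraction
#' is the summed length of present MRs over the module's total MR length.
#'
#' @inheritParams findReverseOccurrences
#' @return data.frame of truncated occurrences, possibly empty.
#' @export
findTruncatedOccurrences <- function(module, family, catalog) {
    mod <- catalog@modules[[module]]
    occ <- catalog@occurrences
    .truncatedOccIntern(mod, .famChar(family),
                        occ[c("seq", "start", "end")],
                        catalog@params$maxratio, catalog@params$reverse)
}

# --- catalog accessors -----------------------------------------------------

#' @describeIn nModules number of modules in a catalog.
#' @param x a \code{ModuleCatalog}.
#' @export
setMethod("nModules", "ModuleCatalog", function(x) length(x@modules))

#' @rdname moduleTable
#' @export
setMethod("moduleTable", "ModuleCatalog", function(x, ...) {
    if (!length(x@modules))
        return(data.frame(module = integer(), parts = character(),
                          totalMRLength = integer(), support = integer(),
                          occurrences = integer()))
    data.frame(
        module = vapply(x@modules, function(m) m$id, 1L),
        parts = vapply(x@modules, function(m)
            paste(m$parts, collapse = "|"), ""),
        totalMRLength = vapply(x@modules, function(m) m$totalMRLength, 1L),
        support = vapply(x@modules, function(m) m$supportAtDiscovery, 1L),
        occurrences = vapply(x@modules, function(m)
            sum(x@occurrences$module == m$id), 1L))
})

#' @rdname occurrenceTable
#' @export
setMethod("occurrenceTable", "ModuleCatalog", function(x, ...) {
    occ <- x@occurrences
    data.frame(sequence_id = x@seqnames[occ$seq], module = occ$module,
               start = occ$start + 1L, end = occ$end, strand = occ$strand,
               kind = occ$kind, fraction = occ$fraction)
})

#' Per-sequence module composition table
#'
#' The mandatory output of the pipeline: one row per module occurrence,
#' 1-based inclusive coordinates, ordered by sequence then position.
#'
#' @param catalog a \code{\linkS4class{ModuleCatalog}}.
#' @return data.frame with columns \code{sequence_id}, \code{module_id},
#'   \code{start}, \code{end}, \code{kind}, \code{conserved_fraction}.
#' @export
compositionTable <- function(catalog) {
    occ <- catalog@occurrences
    out <- data.frame(sequence_id = catalog@seqnames[occ$seq],
                      module_id = occ$module, start = occ$start + 1L,
                      end = occ$end, kind = occ$kind,
                      conserved_fraction = occ$fraction)
    out <- out[order(occ$seq, occ$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

setMethod("show", "ModuleCatalog", function(object) {
    cat(sprintf("ModuleCatalog: %d module(s), %d occurrence(s), %d sequence(s)\n",
                length(object@modules), nrow(object@occurrences),
                length(object@seqnames)))
    if (length(object@modules)) print(utils::head(moduleTable(object), 8L))
})

# --- legality verifier -----------------------------------------------------

#' Verify module legality conditions
#'
#' Post-hoc check of every emitted module: complete occurrences must
#' reproduce the sequence exactly from parts and spacers; at every
#' junction the spacers of the direct occurrences must satisfy the
#' pairwise distance condition (edit distance at most the size of the MR
#' added at that junction) and the length condition under
#' \code{maxratio}; and all catalog occurrences must be pairwise disjoint
#' (partition condition).
#'
#' @param catalog a \code{\linkS4class{ModuleCatalog}}.
#' @param family the sequence family it was computed from.
#' @return \code{TRUE}, or a character vector describing violations.
#' @export
verifyCatalog <- function(catalog, family) {
    seqs <- .famChar(family)
    occ <- catalog@occurrences
    bad <- character()
    r <- catalog@params$maxratio
    for (s in unique(occ$seq)) {
        o <- occ[occ$seq == s, , drop = FALSE]
        o <- o[order(o$start), , drop = FALSE]
        if (nrow(o) > 1L && any(o$start[-1L] < o$end[-nrow(o)]))
            bad <- c(bad, sprintf("overlap on sequence %d", s))
    }
    for (mod in catalog@modules) {
        P <- length(mod$parts)
        dir <- occ[occ$module == mod$id & occ$kind == "direct", ,
                   drop = FALSE]
        # exactness of direct occurrences recorded at assembly time
        for (k in seq_along(mod$spacers)) {
            pieces <- character(2L * P - 1L)
            pieces[seq(1L, 2L * P - 1L, by = 2L)] <- mod$parts
            if (P > 1L)
                pieces[seq(2L, 2L * P - 2L, by = 2L)] <- mod$spacers[[k]]
            stext <- paste(pieces, collapse = "")
            found <- FALSE
            for (j in seq_len(nrow(dir))) {
                if (substr(seqs[dir$seq[j]], dir$start[j] + 1L,
                           dir$end[j]) == stext) { found <- TRUE; break }
            }
            if (!found)
                bad <- c(bad, sprintf(
                    "module %d: assembled occurrence %d not found verbatim",
                    mod$id, k))
        }
        if (P < 2L) next
        for (j in seq_len(P - 1L)) {
            sp <- mod$spacerSets[[j]]
            b <- if (mod$junctionAdded[j] == "R") mod$partLengths[j + 1L]
                 else mod$partLengths[j]
            d <- .editDistMatrix(sp)
            if (any(d > b))
                bad <- c(bad, sprintf(
                    "module %d junction %d: distance condition violated",
                    mod$id, j))
        }
        # length condition: spacer at most maxratio% of the seed-side span
        for (k in seq_along(mod$spacers)) {
            sp <- mod$spacers[[k]]
            cum <- c(0, cumsum(mod$partLengths[-P] + nchar(sp)))
            span <- sum(mod$partLengths) + sum(nchar(sp))
            for (j in seq_len(P - 1L)) {
                leftSpan <- sum(mod$partLengths[1:j]) +
                    sum(nchar(sp[seq_len(j - 1L)]))
                rightSpan <- span - leftSpan - nchar(sp[j])
                seedSide <- if (mod$junctionAdded[j] == "R") leftSpan
                            else rightSpan
                if (nchar(sp[j]) > floor(seedSide * r / 100))
                    bad <- c(bad, sprintf(
                        "module %d junction %d: length condition violated",
                        mod$id, j))
            }
        }
        # truncated occurrences must retain the largest MR
        tr <- occ[occ$module == mod$id &
                  startsWith(occ$kind, "truncated"), , drop = FALSE]
        if (nrow(tr)) {
            largest <- which.max(mod$partLengths)
            has <- vapply(strsplit(tr$conserved, ","), function(p)
                as.character(largest) %in% p, TRUE)
            if (!all(has))
                bad <- c(bad, sprintf(
                    "module %d: truncated occurrence lacking largest MR",
                    mod$id))
        }
    }
    if (length(bad)) bad else TRUE
}
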
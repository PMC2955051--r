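# --- synthetic TE families with planted module architectures --------------

# run code under a temporary RNG state seeded deterministically
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

.randSeq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = "")

#' Define a planted module architecture
#'
#' Describes a consensus made of module blocks, each an ordered set of
#' exact parts (the maximal repeats the method should recover) joined by
#' short per-copy spacers, with long fully diverged regions between
#' blocks. Per-copy events rearrange individual copies: \code{delete}
#' removes a block, \code{duplicate} repeats it in tandem, \code{invert}
#' reverse-complements it, \code{truncate} drops its final part (creating
#' a truncated module occurrence).
#'
#' Part sequences are drawn at random and must be mutually dissimilar
#' (pairwise edit distance above half the longest part); architectures
#' violating this are rejected.
#'
#' @param blockSpec list of integer vectors: part lengths of each block,
#'   e.g. \code{list(c(20, 10), 25)}.
#' @param events list of lists with fields \code{copy}, \code{block},
#'   \code{type} in \code{c("delete", "duplicate", "invert", "truncate")}.
#' @param intraSpacer integer range of within-block spacer lengths;
#'   capped below the smallest part so the distance condition always
#'   holds among copies.
#' @param interSpacer integer range of between-block diverged region
#'   lengths; must exceed the largest block span so blocks stay separate
#'   modules.
#' @param partSeqs optional list of character vectors giving the part
#'   sequences explicitly (checked for dissimilarity).
#' @param seed RNG seed for drawing part sequences.
#' @return an object of class \code{PlantedArchitecture}.
#' @export
plantedArchitecture <- function(blockSpec, events = list(),
                                intraSpacer = c(4L, 8L),
                                interSpacer = NULL, partSeqs = NULL,
                                seed = 1L) {
    stopifnot(length(blockSpec) >= 1L)
    blockSpec <- lapply(blockSpec, as.integer)
    minPart <- min(unlist(blockSpec))
    maxPart <- max(unlist(blockSpec))
    intraSpacer <- c(max(0L, intraSpacer[1L]),
                     min(intraSpacer[2L], minPart - 1L))
    if (intraSpacer[2L] < intraSpacer[1L]) intraSpacer[2L] <- intraSpacer[1L]
    maxBlockSpan <- max(vapply(blockSpec, function(b)
        sum(b) + (length(b) - 1L) * intraSpacer[2L], 1L))
    if (is.null(interSpacer))
        interSpacer <- c(ceiling(1.3 * maxBlockSpan),
                         ceiling(1.8 * maxBlockSpan))
    if (interSpacer[1L] <= maxBlockSpan)
        stop("interSpacer must exceed the largest block span")
    for (ev in events)
        stopifnot(ev$type %in% c("delete", "duplicate", "invert",
                                 "truncate"),
                  ev$block >= 1L, ev$block <= length(blockSpec))
    for (ev in events)
        if (ev$type == "truncate" && length(blockSpec[[ev$block]]) < 2L)
            stop("cannot truncate a single-part block")
    drawParts <- function() lapply(blockSpec, function(b)
        vapply(b, .randSeq, ""))
    checkParts <- function(ps) {
        flat <- unlist(ps)
        if (length(flat) < 2L) return(TRUE)
        d <- utils::adist(flat, flat)
        lim <- outer(nchar(flat), nchar(flat), pmin) / 2
        if (!all(d[upper.tri(d)] > lim[upper.tri(lim)])) return(FALSE)
        # no part may contain another (or its reverse complement)
        for (i in seq_along(flat)) for (j in seq_along(flat)) {
            if (i == j) next
            if (grepl(flat[i], flat[j], fixed = TRUE) ||
                grepl(revComp(flat[i]), flat[j], fixed = TRUE))
                return(FALSE)
        }
        TRUE
    }
    if (!is.null(partSeqs)) {
        partSeqs <- lapply(partSeqs, toupper)
        stopifnot(identical(lapply(partSeqs, nchar), blockSpec))
        if (!checkParts(partSeqs))
            stop("infeasible architecture: block parts too similar")
    } else {
        partSeqs <- .withSeed(seed, {
            ps <- NULL
            for (try in 1:50) {
                cand <- drawParts()
                if (checkParts(cand)) { ps <- cand; break }
            }
            ps
        })
        if (is.null(partSeqs))
            stop("infeasible architecture: could not draw dissimilar parts")
    }
    structure(list(blockSpec = blockSpec, partSeqs = partSeqs,
                   events = events, intraSpacer = intraSpacer,
                   interSpacer = interSpacer, seed = seed),
              class = "PlantedArchitecture")
}

#' Generate a synthetic family realizing a planted architecture
#'
#' Every copy carries the architecture's blocks in order, separated by
#' independently drawn diverged spacer regions, with the per-copy events
#' applied. Within-block spacers are drawn independently per copy (a
#' saturated-divergence regime), so the planted parts are exactly the
#' conserved words the method should assemble. Generation is
#' seed-deterministic.
#'
#' @param arch a \code{\link{plantedArchitecture}}.
#' @param nCopies number of copies (>= 2).
#' @param seed RNG seed (defaults to the architecture's).
#' @return list with \code{family} (named \code{DNAStringSet}) and
#'   \code{truth}: a data.frame recording every planted block instance
#'   (\code{copy}, \code{block}, \code{start}, \code{end} 1-based
#'   inclusive, NA when deleted, \code{strand}, \code{event}).
#' @export
generateFamily <- function(arch, nCopies, seed = arch$seed) {
    stopifnot(inherits(arch, "PlantedArchitecture"), nCopies >= 2L)
    # decouple the copy-realisation stream from the part-drawing stream
    # (same numeric seed must not replay the architecture's draws)
    seed <- (as.integer(seed) %% 1000000L) * 2011L + 104729L
    nB <- length(arch$blockSpec)
    evFor <- function(copy, block) {
        for (ev in arch$events)
            if (ev$copy == copy && ev$block == block) return(ev$type)
        "none"
    }
    .withSeed(seed, {
        seqs <- character(nCopies)
        truth <- list()
        for (cp in seq_len(nCopies)) {
            pieces <- character()
            pos <- 0L
            addPiece <- function(x) {
                pieces[length(pieces) + 1L] <<- x
                pos <<- pos + nchar(x)
            }
            rspacer <- function(rng) .randSeq(
                rng[1L] + sample.int(rng[2L] - rng[1L] + 1L, 1L) - 1L)
            blockText <- function(b) {
                parts <- arch$partSeqs[[b]]
                sp <- vapply(seq_len(length(parts) - 1L), function(i)
                    rspacer(arch$intraSpacer), "")
                if (length(parts) == 1L) return(parts)
                paste0(paste0(parts[-length(parts)], sp, collapse = ""),
                       parts[length(parts)])
            }
            addPiece(rspacer(arch$interSpacer))  # left flank
            for (b in seq_len(nB)) {
                ev <- evFor(cp, b)
                if (ev == "delete") {
                    truth[[length(truth) + 1L]] <- data.frame(
                        copy = cp, block = b, start = NA_integer_,
                        end = NA_integer_, strand = NA_character_,
                        event = "delete")
                } else if (ev == "truncate") {
                    parts <- arch$partSeqs[[b]]
                    keep <- parts[-length(parts)]
                    txt <- if (length(keep) == 1L) keep else {
                        sp <- vapply(seq_len(length(keep) - 1L), function(i)
                            rspacer(arch$intraSpacer), "")
                        paste0(paste0(keep[-length(keep)], sp,
                                      collapse = ""), keep[length(keep)])
                    }
                    truth[[length(truth) + 1L]] <- data.frame(
                        copy = cp, block = b, start = pos + 1L,
                        end = pos + nchar(txt), strand = "+",
                        event = "truncate")
                    addPiece(txt)
                } else if (ev == "invert") {
                    txt <- revComp(blockText(b))
                    truth[[length(truth) + 1L]] <- data.frame(
                        copy = cp, block = b, start = pos + 1L,
                        end = pos + nchar(txt), strand = "-",
                        event = "invert")
                    addPiece(txt)
                } else if (ev == "duplicate") {
                    for (rep_i in 1:2) {
                        txt <- blockText(b)
                        truth[[length(truth) + 1L]] <- data.frame(
                            copy = cp, block = b, start = pos + 1L,
                            end = pos + nchar(txt), strand = "+",
                            event = "duplicate")
                        addPiece(txt)
                        if (rep_i == 1L) addPiece(rspacer(arch$intraSpacer))
                    }
                } else {
                    txt <- blockText(b)
                    truth[[length(truth) + 1L]] <- data.frame(
                        copy = cp, block = b, start = pos + 1L,
                        end = pos + nchar(txt), strand = "+",
                        event = "none")
                    addPiece(txt)
                }
                addPiece(rspacer(arch$interSpacer))
            }
            seqs[cp] <- paste(pieces, collapse = "")
        }
        names(seqs) <- sprintf("copy%02d", seq_len(nCopies))
        list(family = asFamily(seqs), truth = do.call(rbind, truth))
    })
}
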
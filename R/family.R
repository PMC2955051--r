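#' Read a transposable-element family from a FASTA file
#'
#' Loads a multi-FASTA file into a named \code{DNAStringSet}, the container
#' used throughout the package for a sequence family. Record order is
#' preserved, sequences are upper-cased, and the alphabet is restricted to
#' A, C, G, T and N.
#'
#' @param path path to a FASTA file (wrapped or unwrapped lines).
#' @return a named \code{\link[Biostrings]{DNAStringSet}}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgtACGT"), fa)
#' readFamily(fa)
#' @export
readFamily <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    seqs <- tryCatch(
        Biostrings::readBStringSet(path),
        error = function(e) stop("not a FASTA file: ", conditionMessage(e)))
    if (length(seqs) == 0L) stop("no sequences in ", path)
    # keep only the first whitespace-delimited token of each header
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    asFamily(as.character(seqs), names(seqs))
}

#' Assemble a family from character sequences
#'
#' Validates identifiers and alphabet and returns the family container.
#'
#' @param seqs character vector of nucleotide sequences.
#' @param ids character vector of unique, non-empty identifiers.
#' @return a named \code{DNAStringSet}.
#' @export
asFamily <- function(seqs, ids = names(seqs)) {
    if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
        stop("every sequence needs a non-empty identifier")
    if (anyDuplicated(ids))
        stop("duplicate identifier: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    seqs <- toupper(as.character(seqs))
    if (any(!nzchar(seqs))) stop("zero-length sequence: ",
                                 ids[!nzchar(seqs)][1L])
    bad <- regexpr("[^ACGTN]", seqs)
    if (any(bad > 0L)) {
        i <- which(bad > 0L)[1L]
        stop(sprintf("invalid alphabet in record '%s' at position %d ('%s')",
                     ids[i], bad[i], substr(seqs[i], bad[i], bad[i])))
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    out
}

#' Write a family to FASTA
#'
#' @param family a named \code{DNAStringSet} (see \code{\link{readFamily}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFamily <- function(family, path) {
    Biostrings::writeXStringSet(family, path, width = 70L)
    invisible(path)
}

# family as plain character vector (cached upper-case on load)
.famChar <- function(family) {
    if (is.character(family)) return(family)
    as.character(family)
}

#' Reverse complement of a nucleotide string
#'
#' Character-level wrapper around \code{Biostrings::reverseComplement};
#' N maps to N. An involution: applying it twice returns the input.
#'
#' @param s nucleotide string(s) over A, C, G, T, N.
#' @return character vector of the same length.
#' @examples
#' revComp("AAC")   # "GTT"
#' @export
revComp <- function(s) {
    s <- toupper(s)
    if (any(grepl("[^ACGTN]", s))) stop("invalid alphabet")
    out <- character(length(s))
    nz <- nzchar(s)
    if (any(nz))
        out[nz] <- as.character(
            Biostrings::reverseComplement(Biostrings::DNAStringSet(s[nz])))
    out
}

#' Data-driven default for MinSizeModule
#'
#' The default minimum module size is the smallest word length x such that
#' some word of size x over A, C, G, T is absent from the family: i.e. the
#' smallest x for which the number of distinct x-mers observed on the
#' direct strand is strictly below 4^x. Windows containing N are ignored.
#'
#' @param family a named \code{DNAStringSet} or character vector.
#' @return a positive integer.
#' @examples
#' defaultMinSizeModule(asFamily(c(a = "ACGTACGT")))  # 2
#' @export
defaultMinSizeModule <- function(family) {
    seqs <- .famChar(family)
    if (length(seqs) == 0L) stop("empty family")
    k <- 0L
    repeat {
        k <- k + 1L
        seen <- unique(unlist(lapply(seqs, function(s) {
            n <- nchar(s)
            if (n < k) return(character())
            st <- seq_len(n - k + 1L)
            w <- substring(s, st, st + k - 1L)
            w[!grepl("N", w, fixed = TRUE)]
        }), use.names = FALSE))
        if (length(seen) < 4^k) return(k)
    }
}
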
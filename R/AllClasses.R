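#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib TEmodules, .registration = TRUE
NULL

#' Maximal repeats of a sequence family
#'
#' Ordered list of exact maximal repeats (MRs) with their occurrence table.
#' A word is a maximal repeat when it has at least two occurrences whose
#' left flanking letters differ and whose right flanking letters differ,
#' sequence boundaries acting as per-sequence unique sentinel letters.
#' Entries are sorted by decreasing length, then decreasing occurrence
#' count, then lexicographic word, then first occurrence.
#'
#' @slot word character vector of MR words.
#' @slot mrLength integer vector, word lengths in nt.
#' @slot support integer vector, number of distinct sequences carrying each
#'   MR (direct or reverse occurrences combined).
#' @slot occurrences data.frame with columns \code{mr} (index into
#'   \code{word}), \code{seq} (sequence index), \code{start}, \code{end}
#'   (0-based, half-open), \code{strand} (\code{"+"} or \code{"-"}).
#'
#' @export
setClass("MaximalRepeatList",
    representation(word = "character", mrLength = "integer",
                   support = "integer", occurrences = "data.frame"))

setValidity("MaximalRepeatList", function(object) {
    occ <- object@occurrences
    msg <- character()
    if (length(object@word) != length(object@mrLength) ||
        length(object@word) != length(object@support))
        msg <- c(msg, "parallel slot lengths differ")
    if (nrow(occ) &&
        (any(occ$mr < 1L) || any(occ$mr > length(object@word))))
        msg <- c(msg, "occurrence table references unknown MR")
    if (nrow(occ) && any(occ$end - occ$start != object@mrLength[occ$mr]))
        msg <- c(msg, "occurrence width differs from MR length")
    if (length(msg)) msg else TRUE
})

#' Catalog of detected modules
#'
#' The result of module detection: a set of modules (ordered chains of
#' maximal repeats) and their non-overlapping occurrences across the
#' family. Occurrence kinds are \code{direct}, \code{reverse},
#' \code{truncated_direct} and \code{truncated_reverse}; a truncated
#' occurrence carries a conserved fraction strictly below 1 (conserved MR
#' length over the module's total MR length).
#'
#' @slot modules list; one entry per module with elements \code{id},
#'   \code{parts} (MR words 5'-3'), \code{partLengths},
#'   \code{totalMRLength}, \code{supportAtDiscovery},
#'   \code{spacerSets} (per-junction character vectors of the spacers
#'   observed among direct occurrences).
#' @slot occurrences data.frame with columns \code{module}, \code{seq},
#'   \code{start}, \code{end} (0-based half-open), \code{strand},
#'   \code{kind}, \code{fraction}.
#' @slot seqnames character, sequence identifiers in input order.
#' @slot seqlengths integer, sequence lengths in nt.
#' @slot params list, resolved detection parameters.
#'
#' @export
setClass("ModuleCatalog",
    representation(modules = "list", occurrences = "data.frame",
                   seqnames = "character", seqlengths = "integer",
                   params = "list"))

setValidity("ModuleCatalog", function(object) {
    occ <- object@occurrences
    msg <- character()
    if (nrow(occ)) {
        if (any(occ$start < 0L) ||
            any(occ$end > object@seqlengths[occ$seq]))
            msg <- c(msg, "occurrence outside sequence bounds")
        if (any(occ$fraction <= 0) || any(occ$fraction > 1))
            msg <- c(msg, "conserved fraction must be in (0, 1]")
        full <- occ$kind %in% c("direct", "reverse")
        if (any(occ$fraction[full] != 1))
            msg <- c(msg, "complete occurrences must have fraction 1")
        # partition condition: occurrences are pairwise disjoint
        for (s in unique(occ$seq)) {
            o <- occ[occ$seq == s, , drop = FALSE]
            o <- o[order(o$start), , drop = FALSE]
            if (nrow(o) > 1L && any(o$start[-1L] < o$end[-nrow(o)]))
                msg <- c(msg, "module occurrences overlap")
        }
    }
    if (length(msg)) unique(msg) else TRUE
})

#' Hierarchical classification of sequences
#'
#' Binary merge tree from Ward hierarchical agglomerative clustering of
#' modular profiles. \code{merge} and \code{height} follow the
#' \code{\link[stats]{hclust}} convention (negative entries are leaves);
#' heights are the Ward loss-of-inertia values at each merge.
#'
#' @slot merge integer matrix (n-1 rows, 2 columns).
#' @slot height numeric, merge heights.
#' @slot labels character, leaf labels in input order.
#' @slot order integer, a leaf ordering compatible with the dendrogram.
#'
#' @export
setClass("ClusterTree",
    representation(merge = "matrix", height = "numeric",
                   labels = "character", order = "integer"))

setValidity("ClusterTree", function(object) {
    n <- length(object@labels)
    if (n >= 2L && nrow(object@merge) != n - 1L)
        return("merge matrix must have n - 1 rows")
    if (nrow(object@merge) != length(object@height))
        return("heights and merges differ in length")
    TRUE
})
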
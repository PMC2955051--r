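# --- modular profile clustering -------------------------------------------

#' Module incidence matrix
#'
#' One row per sequence. Without the reverse option there is one counter
#' per module; with it, three attributes per module: the direct counter
#' \code{Mi}, the reverse counter \code{rMi} and the total
#' \code{Mi|rMi}. A complete occurrence contributes 1 to its counter; a
#' truncated occurrence contributes its conserved fraction.
#'
#' @param catalog a \code{\linkS4class{ModuleCatalog}}.
#' @param reverseOption three attributes per module (defaults to the
#'   catalog's reverse setting).
#' @param truncatedOption include truncated fractional contributions
#'   (defaults to the catalog's truncated setting).
#' @return numeric matrix, rownames = sequence ids.
#' @export
buildIncidenceMatrix <- function(catalog,
                                 reverseOption = catalog@params$reverse,
                                 truncatedOption = catalog@params$truncated) {
    n <- length(catalog@seqnames)
    m <- length(catalog@modules)
    occ <- catalog@occurrences
    if (!truncatedOption)
        occ <- occ[!startsWith(occ$kind, "truncated"), , drop = FALSE]
    if (m == 0L) {
        mat <- matrix(0, n, 0)
        rownames(mat) <- catalog@seqnames
        return(mat)
    }
    direct <- matrix(0, n, m)
    revm <- matrix(0, n, m)
    for (r in seq_len(nrow(occ))) {
        w <- occ$fraction[r]
        if (occ$kind[r] %in% c("direct", "truncated_direct"))
            direct[occ$seq[r], occ$module[r]] <-
                direct[occ$seq[r], occ$module[r]] + w
        else
            revm[occ$seq[r], occ$module[r]] <-
                revm[occ$seq[r], occ$module[r]] + w
    }
    if (!reverseOption) {
        mat <- direct + revm
        colnames(mat) <- paste0("M", seq_len(m))
    } else {
        mat <- matrix(0, n, 3L * m)
        cn <- character(3L * m)
        for (i in seq_len(m)) {
            mat[, 3L * i - 2L] <- direct[, i]
            mat[, 3L * i - 1L] <- revm[, i]
            mat[, 3L * i] <- direct[, i] + revm[, i]
            cn[(3L * i - 2L):(3L * i)] <-
                paste0(c("M", "rM", "M|rM"), i)
        }
        colnames(mat) <- cn
    }
    rownames(mat) <- catalog@seqnames
    mat
}

#' Ward loss of inertia between two profiles
#'
#' Delta(x, y) = 1/(2n) * sum_i (x_i - y_i)^2, where n is the number of
#' sequences (all singleton clusters carry weight 1/n).
#'
#' @param x,y equal-length numeric attribute vectors.
#' @param n number of sequences in the family.
#' @return non-negative numeric.
#' @examples
#' wardDelta(c(1, 0), c(0, 1), 2)  # 0.5
#' @export
wardDelta <- function(x, y, n) {
    if (length(x) != length(y)) stop("attribute vectors differ in length")
    sum((x - y)^2) / (2 * n)
}

#' Ward hierarchical agglomerative clustering
#'
#' Starts from singleton clusters of weight 1/n, repeatedly merges the
#' pair with minimal Delta and updates distances with the Lance-Williams
#' recurrence
#' Delta(x u y, z) = ((n_x + n_z) Delta(x,z) + (n_y + n_z) Delta(y,z)
#' - n_z Delta(x,y)) / (n_x + n_y + n_z), weights adding on merge. Ties
#' are broken toward the pair whose sorted smallest leaf indices are
#' lowest.
#'
#' @param mat incidence matrix (rows = sequences), see
#'   \code{\link{buildIncidenceMatrix}}.
#' @return a \code{\linkS4class{ClusterTree}}.
#' @export
hacWard <- function(mat) {
    n <- nrow(mat)
    labels <- rownames(mat)
    if (is.null(labels)) labels <- paste0("seq", seq_len(n))
    if (n == 1L)
        return(new("ClusterTree",
                   merge = matrix(integer(), 0L, 2L), height = numeric(),
                   labels = labels, order = 1L))
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        D[i, j] <- D[j, i] <- wardDelta(mat[i, ], mat[j, ], n)
    w <- rep(1 / n, n)              # cluster weights
    code <- -seq_len(n)             # hclust codes (negative = leaf)
    minLeaf <- seq_len(n)           # smallest leaf index per cluster
    active <- rep(TRUE, n)
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    for (step in seq_len(n - 1L)) {
        best <- NULL
        for (i in which(active)) for (j in which(active)) {
            if (j <= i) next
            key <- c(D[i, j], sort(c(minLeaf[i], minLeaf[j])))
            if (is.null(best) ||
                key[1L] < best$key[1L] - 1e-15 ||
                (abs(key[1L] - best$key[1L]) <= 1e-15 &&
                 (key[2L] < best$key[2L] ||
                  (key[2L] == best$key[2L] && key[3L] < best$key[3L]))))
                best <- list(i = i, j = j, key = key)
        }
        i <- best$i; j <- best$j
        height[step] <- D[i, j]
        merge[step, ] <- c(code[i], code[j])
        for (z in which(active)) {
            if (z == i || z == j) next
            D[i, z] <- D[z, i] <-
                ((w[i] + w[z]) * D[i, z] + (w[j] + w[z]) * D[j, z] -
                 w[z] * D[i, j]) / (w[i] + w[j] + w[z])
        }
        w[i] <- w[i] + w[j]
        code[i] <- step
        minLeaf[i] <- min(minLeaf[i], minLeaf[j])
        active[j] <- FALSE
    }
    ord <- integer(0)
    walk <- function(k) {
        if (k < 0L) ord <<- c(ord, -k)
        else { walk(merge[k, 1L]); walk(merge[k, 2L]) }
    }
    walk(n - 1L)
    new("ClusterTree", merge = merge, height = height, labels = labels,
        order = ord)
}

#' @describeIn ClusterTree convert to a \code{stats::hclust} object.
#' @param x a \code{ClusterTree}.
#' @export
setMethod("asHclust", "ClusterTree", function(x) {
    structure(list(merge = x@merge, height = x@height, order = x@order,
                   labels = x@labels, method = "ward",
                   call = match.call(), dist.method = "ward.delta"),
              class = "hclust")
})

setMethod("show", "ClusterTree", function(object) {
    cat(sprintf("ClusterTree over %d sequence(s)\n", length(object@labels)))
    if (length(object@height))
        cat(sprintf("  merge heights: %s\n",
                    paste(signif(object@height, 4), collapse = ", ")))
})

# --- Newick serialization --------------------------------------------------

.newickLabel <- function(x) gsub("[ ():,;\\[\\]']", "_", x)

#' Write a cluster tree in Newick format
#'
#' Branch lengths are differences of merge heights (leaves at height 0),
#' so two leaves merging at height h are written \code{(a:h,b:h);}.
#'
#' @param tree a \code{\linkS4class{ClusterTree}}.
#' @param path optional output file.
#' @return the Newick string, invisibly if \code{path} is given.
#' @export
writeNewick <- function(tree, path = NULL) {
    fmt <- function(x) sprintf("%.10g", x)
    labs <- .newickLabel(tree@labels)
    rec <- function(k) {
        h <- tree@height[k]
        child <- function(c) {
            if (c < 0L) paste0(labs[-c], ":", fmt(h))
            else paste0(rec(c), ":", fmt(h - tree@height[c]))
        }
        paste0("(", child(tree@merge[k, 1L]), ",",
               child(tree@merge[k, 2L]), ")")
    }
    s <- if (length(tree@labels) == 1L) paste0(labs[1L], ";")
         else paste0(rec(nrow(tree@merge)), ";")
    if (!is.null(path)) {
        writeLines(s, path)
        return(invisible(s))
    }
    s
}
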
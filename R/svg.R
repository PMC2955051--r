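# --- SVG rendering of the segmentation ------------------------------------

.svgPalette <- c("#4878a8", "#b85450", "#7aa661", "#8e6fae", "#c8963e",
                 "#5aa0a8", "#a85a88", "#8a8a4a", "#6a6a6a", "#b07850")

# deterministic texture per module id: one of 8 pattern styles crossed
# with a colour cycle
.svgPatternDef <- function(mid) {
    col <- .svgPalette[((mid - 1L) %/% 8L) %% length(.svgPalette) + 1L]
    style <- (mid - 1L) %% 8L
    id <- sprintf("pat%d", mid)
    body <- switch(as.character(style),
        "0" = sprintf('<rect width="6" height="6" fill="%s"/>', col),
        "1" = sprintf(paste0('<rect width="6" height="6" fill="white"/>',
            '<path d="M0,6 L6,0" stroke="%s" stroke-width="1.6"/>'), col),
        "2" = sprintf(paste0('<rect width="6" height="6" fill="white"/>',
            '<path d="M0,0 L6,6" stroke="%s" stroke-width="1.6"/>'), col),
        "3" = sprintf(paste0('<rect width="6" height="6" fill="white"/>',
            '<circle cx="3" cy="3" r="1.4" fill="%s"/>'), col),
        "4" = sprintf(paste0('<rect width="6" height="6" fill="white"/>',
            '<rect y="2" width="6" height="2" fill="%s"/>'), col),
        "5" = sprintf(paste0('<rect width="6" height="6" fill="white"/>',
            '<rect x="2" width="2" height="6" fill="%s"/>'), col),
        "6" = sprintf(paste0('<rect width="6" height="6" fill="white"/>',
            '<path d="M0,6 L6,0 M0,0 L6,6" stroke="%s" ',
            'stroke-width="1"/>'), col),
        "7" = sprintf(paste0('<rect width="6" height="6" fill="%s"/>',
            '<rect x="0" y="0" width="3" height="3" fill="white"/>'), col))
    sprintf(paste0('<pattern id="%s" width="6" height="6" ',
                   'patternUnits="userSpaceOnUse">%s</pattern>'), id, body)
}

.fmt2 <- function(x) sprintf("%.2f", x)

#' Render the segmentation and classification as SVG
#'
#' Draws the classification tree on the left and, aligned with its
#' leaves, one track per sequence with module occurrences as textured
#' boxes scaled by nucleotide length. Uncovered stretches show as a thin
#' baseline. Reverse occurrences carry a triangle marker; truncated
#' occurrences are drawn as crossed boxes. A legend maps textures to
#' module ids. SVG 1.1, static, deterministic.
#'
#' @param catalog a \code{\linkS4class{ModuleCatalog}}.
#' @param tree a \code{\linkS4class{ClusterTree}} over the same
#'   sequences, or \code{NULL} for input order without a tree panel.
#' @param path output file.
#' @param width canvas width in px.
#' @return \code{path}, invisibly.
#' @export
renderSVG <- function(catalog, tree, path, width = 1000) {
    n <- length(catalog@seqnames)
    if (!is.null(tree) &&
        !identical(sort(tree@labels), sort(catalog@seqnames)))
        stop("catalog and tree cover different sequence sets")
    leafOrder <- if (is.null(tree)) seq_len(n)
                 else match(tree@labels[tree@order], catalog@seqnames)
    rowH <- 26; topM <- 30; leftM <- 15
    treeW <- if (is.null(tree)) 0 else 220
    labelW <- 95
    trackX <- leftM + treeW + labelW
    trackW <- width - trackX - 20
    maxLen <- max(catalog@seqlengths)
    scale <- trackW / maxLen
    yOf <- function(rank) topM + (rank - 0.5) * rowH
    rankOf <- integer(n); rankOf[leafOrder] <- seq_len(n)
    occ <- catalog@occurrences
    mids <- if (length(catalog@modules))
        vapply(catalog@modules, function(m) m$id, 1L) else integer()

    out <- c(sprintf(paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
        '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
        'width="%d" height="%d">'), as.integer(width),
        as.integer(topM + n * rowH + 40 + 22 * ceiling(length(mids) / 8))),
        "<defs>", vapply(mids, .svgPatternDef, ""), "</defs>")

    # classification tree (right-angled dendrogram, heights to the left)
    if (!is.null(tree) && n >= 2L) {
        maxH <- max(tree@height, 1e-12)
        xOf <- function(h) leftM + treeW - 12 - (h / maxH) * (treeW - 24)
        pos <- matrix(0, n - 1L + n, 2L)  # x, y per cluster code
        getPos <- function(code) {
            if (code < 0L) c(leftM + treeW - 12,
                             yOf(rankOf[match(tree@labels[-code],
                                              catalog@seqnames)]))
            else pos[code, ]
        }
        for (k in seq_len(nrow(tree@merge))) {
            p1 <- getPos(tree@merge[k, 1L])
            p2 <- getPos(tree@merge[k, 2L])
            xp <- xOf(tree@height[k])
            out <- c(out, sprintf(
                '<path class="tree" fill="none" stroke="black" d="M%s,%s H%s V%s H%s"/>',
                .fmt2(p1[1L]), .fmt2(p1[2L]), .fmt2(xp), .fmt2(p2[2L]),
                .fmt2(p2[1L])))
            pos[k, ] <- c(xp, (p1[2L] + p2[2L]) / 2)
        }
    }

    for (r in seq_len(n)) {
        s <- leafOrder[r]
        y <- yOf(r)
        out <- c(out, sprintf(
            '<text x="%s" y="%s" font-size="11" font-family="monospace">%s</text>',
            .fmt2(leftM + treeW + 4), .fmt2(y + 4), catalog@seqnames[s]))
        out <- c(out, sprintf(
            '<line class="baseline" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#888" stroke-width="1"/>',
            .fmt2(trackX), .fmt2(y),
            .fmt2(trackX + catalog@seqlengths[s] * scale), .fmt2(y)))
    }

    if (nrow(occ)) for (i in seq_len(nrow(occ))) {
        s <- occ$seq[i]
        y <- yOf(rankOf[s])
        x0 <- trackX + occ$start[i] * scale
        w <- (occ$end[i] - occ$start[i]) * scale
        boxY <- y - 7
        rect <- sprintf(paste0('<rect class="occ %s" x="%s" y="%s" ',
            'width="%s" height="14" fill="url(#pat%d)" stroke="black" ',
            'stroke-width="0.6"/>'), occ$kind[i], .fmt2(x0), .fmt2(boxY),
            .fmt2(w), occ$module[i])
        if (startsWith(occ$kind[i], "truncated")) {
            cross <- sprintf(paste0(
                '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="0.8"/>',
                '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="0.8"/>'),
                .fmt2(x0), .fmt2(boxY), .fmt2(x0 + w), .fmt2(boxY + 14),
                .fmt2(x0), .fmt2(boxY + 14), .fmt2(x0 + w), .fmt2(boxY))
            rect <- sprintf('<g class="crossed">%s%s</g>', rect, cross)
        }
        out <- c(out, rect)
        if (occ$kind[i] %in% c("reverse", "truncated_reverse"))
            out <- c(out, sprintf(
                '<polygon class="marker-reverse" points="%s,%s %s,%s %s,%s" fill="black"/>',
                .fmt2(x0 + w / 2 - 4), .fmt2(boxY - 2),
                .fmt2(x0 + w / 2 + 4), .fmt2(boxY - 2),
                .fmt2(x0 + w / 2), .fmt2(boxY - 8)))
        out <- c(out, sprintf(
            '<text x="%s" y="%s" font-size="8" text-anchor="middle">%d</text>',
            .fmt2(x0 + w / 2), .fmt2(boxY - 10), occ$module[i]))
    }

    # legend
    ly <- topM + n * rowH + 24
    for (j in seq_along(mids)) {
        lx <- leftM + ((j - 1L) %% 8L) * 110
        yy <- ly + ((j - 1L) %/% 8L) * 22
        out <- c(out, sprintf(paste0(
            '<rect class="legend" x="%s" y="%s" width="18" height="12" ',
            'fill="url(#pat%d)" stroke="black" stroke-width="0.5"/>',
            '<text x="%s" y="%s" font-size="11">M%d</text>'),
            .fmt2(lx), .fmt2(yy), mids[j], .fmt2(lx + 24), .fmt2(yy + 10),
            mids[j]))
    }
    out <- c(out, "</svg>")
    writeLines(out, path, sep = "\n")
    invisible(path)
}
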
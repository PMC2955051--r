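# --- end-to-end pipeline ---------------------------------------------------

#' Run the full analysis pipeline
#'
#' Reads (or accepts) a family, detects modules, clusters the sequences
#' on their modular profiles and writes one to three output files plus a
#' machine-readable run manifest:
#' \itemize{
#'   \item \code{<prefix>_modules.tsv} — mandatory composition list;
#'   \item \code{<prefix>_tree.nwk} — Newick classification (unless
#'     \code{cluster = FALSE});
#'   \item \code{<prefix>_graph.svg} — graphical segmentation (unless
#'     \code{svg = FALSE});
#'   \item \code{<prefix>_manifest.json} — all resolved parameters;
#'     re-running from it reproduces the outputs byte for byte.
#' }
#'
#' @param input path to a FASTA file, or a family object
#'   (named \code{DNAStringSet}/character).
#' @param outPrefix output path prefix.
#' @inheritParams detectModules
#' @param cluster write the Newick classification.
#' @param svg write the SVG rendering.
#' @return invisibly, a list with \code{catalog}, \code{tree},
#'   \code{matrix} and \code{files}.
#' @export
runPipeline <- function(input, outPrefix, minSizeModule = NULL,
                        maxratio = 100, minSequences = NULL,
                        reverse = FALSE, truncated = FALSE,
                        cluster = TRUE, svg = TRUE, verbose = FALSE) {
    if (!(maxratio > 0 && maxratio <= 100))
        stop("parameter error: Maxratio must be in (0, 100]")
    if (!is.null(minSizeModule) && minSizeModule < 1)
        stop("parameter error: MinSizeModule must be >= 1")
    inputPath <- NULL
    family <- if (is.character(input) && length(input) == 1L &&
                  is.null(names(input)) && file.exists(input)) {
        inputPath <- input
        readFamily(input)
    } else if (is.character(input)) asFamily(input) else input
    n <- length(family)
    if (!is.null(minSequences) && (minSequences < 1 || minSequences > n))
        stop("parameter error: MinSequences must be in [1, n]")
    resolvedMsm <- if (is.null(minSizeModule))
        defaultMinSizeModule(family) else as.integer(minSizeModule)
    if (verbose && is.null(minSizeModule))
        message("MinSizeModule resolved to ", resolvedMsm,
                " (smallest absent word size)")
    catalog <- detectModules(family, minSizeModule = resolvedMsm,
                             maxratio = maxratio,
                             minSequences = minSequences,
                             reverse = reverse, truncated = truncated,
                             verbose = verbose)
    files <- character()
    comp <- compositionTable(catalog)
    compFile <- paste0(outPrefix, "_modules.tsv")
    utils::write.table(comp, compFile, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    files <- c(composition = compFile)
    tree <- NULL; mat <- NULL
    if (cluster) {
        mat <- buildIncidenceMatrix(catalog)
        tree <- hacWard(mat)
        nwkFile <- paste0(outPrefix, "_tree.nwk")
        writeNewick(tree, nwkFile)
        files <- c(files, newick = nwkFile)
    }
    if (svg) {
        svgFile <- paste0(outPrefix, "_graph.svg")
        renderSVG(catalog, tree, svgFile)
        files <- c(files, svg = svgFile)
    }
    manifest <- list(
        input = if (is.null(inputPath)) "<in-memory>" else inputPath,
        sequences = names(family), n = n,
        minSizeModule = resolvedMsm,
        minSizeModuleAuto = is.null(minSizeModule),
        maxratio = maxratio,
        minSequences = if (is.null(minSequences)) "sweep"
                       else minSequences,
        reverse = reverse, truncated = truncated,
        cluster = cluster, svg = svg,
        outPrefix = outPrefix,
        outputs = as.list(files),
        package = as.character(utils::packageVersion("TEmodules")))
    manFile <- paste0(outPrefix, "_manifest.json")
    jsonlite::write_json(manifest, manFile, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    files <- c(files, manifest = manFile)
    invisible(list(catalog = catalog, tree = tree, matrix = mat,
                   files = files))
}

#' Re-run a pipeline from its manifest
#'
#' @param manifestPath path to a \code{*_manifest.json} written by
#'   \code{\link{runPipeline}}.
#' @param outPrefix optional new output prefix (defaults to the one in
#'   the manifest).
#' @return see \code{\link{runPipeline}}.
#' @export
runFromManifest <- function(manifestPath, outPrefix = NULL) {
    m <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
    if (identical(m$input, "<in-memory>"))
        stop("manifest records an in-memory family; re-run needs a file")
    runPipeline(m$input,
                outPrefix = if (is.null(outPrefix)) m$outPrefix
                            else outPrefix,
                minSizeModule = if (isTRUE(m$minSizeModuleAuto)) NULL
                                else m$minSizeModule,
                maxratio = m$maxratio,
                minSequences = if (identical(m$minSequences, "sweep")) NULL
                               else m$minSequences,
                reverse = m$reverse, truncated = m$truncated,
                cluster = m$cluster, svg = m$svg)
}
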
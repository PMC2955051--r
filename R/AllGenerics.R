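#' @rdname occurrenceTable
#' @export
setGeneric("occurrenceTable", function(x, ...) standardGeneric("occurrenceTable"))

#' @rdname moduleTable
#' @export
setGeneric("moduleTable", function(x, ...) standardGeneric("moduleTable"))

#' @rdname nModules
#' @export
setGeneric("nModules", function(x) standardGeneric("nModules"))

#' @rdname asHclust
#' @export
setGeneric("asHclust", function(x) standardGeneric("asHclust"))
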
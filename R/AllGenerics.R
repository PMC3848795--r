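#' Accessor generics
#'
#' Accessors for the package's S4 containers: `proteins()` returns the
#' protein ids of an object, `functionTerms()` the function universe,
#' `nFunctions()` its size `m`, `annotationList()` the protein-to-terms list,
#' `edgeTable()` the explicit edge data.frame, `scoreTable()` the similarity
#' score data.frame, `explicitNetwork()` / `enrichmentK()` the channels and
#' `k` of an enriched network, `predictionTable()` / `fallbackQueries()` the
#' content of a prediction set, and `metricsTable()` / `sparseSummary()` the
#' evaluation results.
#'
#' @param x an object of one of the package's classes.
#' @param ... unused.
#' @return see the individual method descriptions.
#' @name accessors
#' @aliases proteins functionTerms nFunctions annotationList edgeTable
#'   scoreTable explicitNetwork enrichmentK predictionTable fallbackQueries
#'   metricsTable sparseSummary
NULL

#' @rdname accessors
#' @export
setGeneric("proteins", function(x, ...) standardGeneric("proteins"))

#' @rdname accessors
#' @export
setGeneric("functionTerms", function(x, ...) standardGeneric("functionTerms"))

#' @rdname accessors
#' @export
setGeneric("nFunctions", function(x, ...) standardGeneric("nFunctions"))

#' @rdname accessors
#' @export
setGeneric("annotationList", function(x, ...) standardGeneric("annotationList"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x, ...) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("scoreTable", function(x, ...) standardGeneric("scoreTable"))

#' @rdname accessors
#' @export
setGeneric("explicitNetwork", function(x, ...) standardGeneric("explicitNetwork"))

#' @rdname accessors
#' @export
setGeneric("enrichmentK", function(x, ...) standardGeneric("enrichmentK"))

#' @rdname accessors
#' @export
setGeneric("predictionTable", function(x, ...) standardGeneric("predictionTable"))

#' @rdname accessors
#' @export
setGeneric("fallbackQueries", function(x, ...) standardGeneric("fallbackQueries"))

#' @rdname accessors
#' @export
setGeneric("metricsTable", function(x, ...) standardGeneric("metricsTable"))

#' @rdname accessors
#' @export
setGeneric("sparseSummary", function(x, ...) standardGeneric("sparseSummary"))

#' Per-protein neighbourhoods
#'
#' `explicitNeighbors()` returns the explicit (interaction) neighbours of a
#' protein as a data.frame (`neighbor`, `weight`); `implicitNeighbors()`
#' returns its implicit (similarity-inferred) neighbours as a data.frame
#' (`neighbor`, `score`), sorted by descending score.
#'
#' @param x an [ExplicitNetwork-class] or [EnrichedNetwork-class].
#' @param protein a single protein id.
#' @return a data.frame; empty when the protein has no neighbours in that
#'   channel.
#' @name neighbors
NULL

#' @rdname neighbors
#' @export
setGeneric("explicitNeighbors",
           function(x, protein) standardGeneric("explicitNeighbors"))

#' @rdname neighbors
#' @export
setGeneric("implicitNeighbors",
           function(x, protein) standardGeneric("implicitNeighbors"))
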
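## Accessor and show methods for the S4 containers.

#' @rdname accessors
setMethod("proteins", "AnnotationSet", function(x, ...) names(x@annotations))

#' @rdname accessors
setMethod("proteins", "ExplicitNetwork", function(x, ...) x@proteins)

#' @rdname accessors
setMethod("proteins", "SimilarityTable", function(x, ...) x@proteins)

#' @rdname accessors
setMethod("proteins", "EnrichedNetwork", function(x, ...) x@proteins)

#' @rdname accessors
setMethod("functionTerms", "AnnotationSet", function(x, ...) x@terms)

#' @rdname accessors
setMethod("functionTerms", "FunctionPredictions", function(x, ...) x@terms)

#' @rdname accessors
setMethod("nFunctions", "AnnotationSet", function(x, ...) length(x@terms))

#' @rdname accessors
setMethod("annotationList", "AnnotationSet", function(x, ...) x@annotations)

#' @rdname accessors
setMethod("edgeTable", "ExplicitNetwork", function(x, ...) x@edges)

#' @rdname accessors
setMethod("edgeTable", "EnrichedNetwork", function(x, ...) x@explicit@edges)

#' @rdname accessors
setMethod("scoreTable", "SimilarityTable", function(x, ...) x@scores)

#' @rdname accessors
setMethod("explicitNetwork", "EnrichedNetwork", function(x, ...) x@explicit)

#' @rdname accessors
setMethod("enrichmentK", "EnrichedNetwork", function(x, ...) x@k)

#' @rdname accessors
setMethod("predictionTable", "FunctionPredictions", function(x, ...) x@table)

#' @rdname accessors
setMethod("fallbackQueries", "FunctionPredictions", function(x, ...) x@fallback)

#' @rdname accessors
setMethod("metricsTable", "RankMetrics", function(x, ...) x@table)

#' @rdname accessors
setMethod("sparseSummary", "SparseExperimentReport", function(x, ...) x@summary)

#' @rdname neighbors
setMethod("explicitNeighbors", "ExplicitNetwork", function(x, protein) {
  stopifnot(length(protein) == 1L)
  ed <- x@edges
  hit <- ed$protein_a == protein | ed$protein_b == protein
  ed <- ed[hit, , drop = FALSE]
  nb <- ifelse(ed$protein_a == protein, ed$protein_b, ed$protein_a)
  out <- data.frame(neighbor = nb, weight = ed$weight,
                    stringsAsFactors = FALSE)
  out <- out[order(out$neighbor), , drop = FALSE]
  rownames(out) <- NULL
  out
})

#' @rdname neighbors
setMethod("explicitNeighbors", "EnrichedNetwork", function(x, protein) {
  explicitNeighbors(x@explicit, protein)
})

#' @rdname neighbors
setMethod("implicitNeighbors", "EnrichedNetwork", function(x, protein) {
  stopifnot(length(protein) == 1L)
  il <- x@implicit[[protein]]
  if (is.null(il))
    il <- data.frame(neighbor = character(), score = numeric(),
                     stringsAsFactors = FALSE)
  il
})

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet: %d proteins, %d function terms (m)\n",
              length(object@annotations), length(object@terms)))
  if (length(object@annotations))
    cat(sprintf("  mean functions/protein: %.2f\n",
                mean(lengths(object@annotations))))
})

setMethod("show", "ExplicitNetwork", function(object) {
  cat(sprintf("ExplicitNetwork: %d proteins, %d undirected weighted edges\n",
              length(object@proteins), nrow(object@edges)))
})

setMethod("show", "SimilarityTable", function(object) {
  cat(sprintf("SimilarityTable: %d proteins, %d directed scored pairs\n",
              length(object@proteins), nrow(object@scores)))
})

setMethod("show", "OntologyTable", function(object) {
  cat(sprintf("OntologyTable: %d child-parent links, %d terms\n",
              nrow(object@links),
              length(unique(unlist(object@links, use.names = FALSE)))))
})

setMethod("show", "EnrichedNetwork", function(object) {
  cat(sprintf(paste0("EnrichedNetwork: %d proteins, k = %g\n",
                     "  explicit edges: %d | implicit edges: %d\n"),
              length(object@proteins), object@k,
              nrow(object@explicit@edges),
              sum(vapply(object@implicit, nrow, 0L))))
})

setMethod("show", "GibbsConfig", function(object) {
  cat(sprintf(paste0("GibbsConfig: lambda = %g, burn-in B = %d, samples ",
                     "S = %d\n  seed = %d, mode = %s, fallback prior = %s\n"),
              object@lambda, object@burnIn, object@samples, object@seed,
              object@updateMode, object@fallbackPrior))
})

setMethod("show", "FunctionPredictions", function(object) {
  nq <- length(unique(object@table$protein))
  cat(sprintf("FunctionPredictions: %d queries ranked over %d functions\n",
              nq, length(object@terms)))
  if (length(object@fallback))
    cat(sprintf("  %d fallback-prior prediction(s)\n", length(object@fallback)))
})

setMethod("show", "RankMetrics", function(object) {
  cat(sprintf("RankMetrics over %d queries\n", object@nQueries))
  print(object@table, row.names = FALSE)
})

setMethod("show", "SparseExperimentReport", function(object) {
  cat(sprintf("SparseExperimentReport: fractions %s, %d repeats\n",
              paste(object@fractions, collapse = ", "),
              ncol(object@seeds)))
  print(object@summary, row.names = FALSE)
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(paste0("SynthConfig: n = %d proteins, m = %d functions, ",
                     "%d-%d labels/protein\n  pIn = %g, pOut = %g, ",
                     "simSignal = %g, simNoise = %g (shape %g), seed = %d\n"),
              object@nProteins, object@mFunctions,
              object@labelsPerProtein[1], object@labelsPerProtein[2],
              object@pIn, object@pOut, object@simSignal, object@simNoise,
              object@simDispersion, object@seed))
})

#' Plot a sparse-labelling report
#'
#' Draws mean TP/FP ratio against the annotated fraction, one line per rank.
#'
#' @param x a [SparseExperimentReport-class].
#' @param y unused.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the plotted matrix (fractions x ranks).
#' @export
setMethod("plot", signature(x = "SparseExperimentReport", y = "missing"),
          function(x, y, ...) {
  sm <- x@summary
  ranks <- sort(unique(sm$rank))
  mat <- sapply(ranks, function(r) sm$meanRatio[sm$rank == r])
  mat <- matrix(mat, nrow = length(x@fractions))
  graphics::matplot(x@fractions, mat, type = "b", pch = 19,
                    xlab = "annotated fraction", ylab = "mean TP/FP ratio",
                    ...)
  graphics::legend("topleft", legend = paste("rank", ranks),
                   col = seq_along(ranks), lty = seq_along(ranks), bty = "n")
  invisible(mat)
})
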
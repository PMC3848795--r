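## Baseline predictors: majority voting over explicit neighbours and the
## sequence-similarity kNN that ignores the PPI network.

.ranked_prediction <- function(query, counts, terms, fallback) {
  o <- order(-counts, seq_along(counts))
  total <- sum(counts)
  support <- if (total > 0) counts[o] / total else counts[o]
  data.frame(protein = query, rank = seq_along(terms), term = terms[o],
             support = support, stringsAsFactors = FALSE)
}

#' Majority voting over explicit neighbours
#'
#' Ranks candidate functions of each query by the weighted count of their
#' occurrences among the query's labelled immediate interaction partners
#' (edge weights multiply the votes; unit weights give the classic
#' neighbourhood-counting method). Ties break by ascending function index.
#' Queries with no labelled neighbour get the fallback prior and are
#' flagged. Support fractions are normalized vote shares.
#'
#' @param net an [ExplicitNetwork-class].
#' @param ann an [AnnotationSet-class] of labelled proteins; defines the
#'   function universe.
#' @param queries character vector of query ids (must be network vertices).
#' @param fallbackPrior `"frequency"` or `"uniform"`.
#' @return a [FunctionPredictions-class].
#' @export
majorityPredict <- function(net, ann, queries,
                            fallbackPrior = c("frequency", "uniform")) {
  stopifnot(is(net, "ExplicitNetwork"), is(ann, "AnnotationSet"))
  fallbackPrior <- match.arg(fallbackPrior)
  queries <- sort(unique(as.character(queries)))
  if (!length(queries)) stop("no query proteins")
  bad <- setdiff(queries, net@proteins)
  if (length(bad))
    stop(sprintf("query protein(s) not in the network: %s",
                 paste(head(bad, 3), collapse = ", ")))
  terms <- ann@terms
  m <- length(terms)
  prior <- .label_prior(ann@annotations, terms, fallbackPrior)
  fb <- character()
  tabs <- vector("list", length(queries))
  for (j in seq_along(queries)) {
    q <- queries[j]
    el <- explicitNeighbors(net, q)
    counts <- setNames(numeric(m), terms)
    for (i in seq_len(nrow(el))) {
      lb <- ann@annotations[[el$neighbor[i]]]
      if (!is.null(lb)) counts[lb] <- counts[lb] + el$weight[i]
    }
    if (sum(counts) == 0) {
      counts[] <- prior
      fb <- c(fb, q)
    }
    tabs[[j]] <- .ranked_prediction(q, counts, terms, FALSE)
  }
  new("FunctionPredictions", table = do.call(rbind, tabs), fallback = fb,
      terms = terms)
}

#' Sequence-similarity k-nearest-neighbour prediction
#'
#' For each query, selects the `k` labelled proteins with the highest
#' (positive) similarity score to the query -- ties at the k-th rank break
#' by ascending protein id -- and ranks functions by similarity-weighted
#' votes, ties by ascending function index. The PPI network plays no role.
#' Queries with no positively-similar labelled protein get the fallback
#' prior and are flagged.
#'
#' @param sim a [SimilarityTable-class].
#' @param ann an [AnnotationSet-class] of labelled proteins.
#' @param queries character vector of query ids.
#' @param k number of labelled nearest neighbours (>= 1; default 5).
#' @param fallbackPrior `"frequency"` or `"uniform"`.
#' @return a [FunctionPredictions-class].
#' @export
blastKnnPredict <- function(sim, ann, queries, k = 5,
                            fallbackPrior = c("frequency", "uniform")) {
  stopifnot(is(sim, "SimilarityTable"), is(ann, "AnnotationSet"))
  if (k < 1) stop("k must be >= 1")
  fallbackPrior <- match.arg(fallbackPrior)
  queries <- sort(unique(as.character(queries)))
  if (!length(queries)) stop("no query proteins")
  terms <- ann@terms
  m <- length(terms)
  labelled <- names(ann@annotations)
  prior <- .label_prior(ann@annotations, terms, fallbackPrior)
  sc <- sim@scores
  sc <- sc[sc$subject %in% labelled, , drop = FALSE]
  byQuery <- split(sc, sc$query)
  fb <- character()
  tabs <- vector("list", length(queries))
  for (j in seq_along(queries)) {
    q <- queries[j]
    d <- byQuery[[q]]
    counts <- setNames(numeric(m), terms)
    if (!is.null(d) && nrow(d)) {
      d <- d[d$subject != q, , drop = FALSE]
      d <- d[head(order(-d$score, d$subject), k), , drop = FALSE]
      for (i in seq_len(nrow(d)))
        counts[ann@annotations[[d$subject[i]]]] <-
          counts[ann@annotations[[d$subject[i]]]] + d$score[i]
    }
    if (sum(counts) == 0) {
      counts[] <- prior
      fb <- c(fb, q)
    }
    tabs[[j]] <- .ranked_prediction(q, counts, terms, FALSE)
  }
  new("FunctionPredictions", table = do.call(rbind, tabs), fallback = fb,
      terms = terms)
}
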
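## Building the enriched network: per-protein similarity vectors, top-k
## implicit neighbour selection, and the two-channel EnrichedNetwork.

#' Similarity vector of one protein
#'
#' Returns the similarity scores s(x, i) between `x` and every other protein
#' of `universe`. Pairs absent from the table score 0, and `x` itself is
#' excluded (self-similarity is not considered).
#'
#' @param sim a [SimilarityTable-class].
#' @param x a single protein id; must be in `universe`.
#' @param universe character vector of protein ids.
#' @return named numeric vector over `sort(universe)` minus `x`.
#' @export
similarityVector <- function(sim, x, universe) {
  stopifnot(is(sim, "SimilarityTable"), length(x) == 1L)
  universe <- sort(unique(as.character(universe)))
  if (!x %in% universe) stop(sprintf("protein '%s' is not in the universe", x))
  others <- setdiff(universe, x)
  s <- setNames(numeric(length(others)), others)
  sc <- sim@scores
  sc <- sc[sc$query == x & sc$subject %in% others, , drop = FALSE]
  s[sc$subject] <- sc$score
  s
}

#' Top-k implicit neighbours of every protein
#'
#' For each protein of `universe`, selects its `k` highest-scoring
#' similarity partners (fewer when fewer positive scores exist; zero-score
#' partners are never selected). Ties at the k-th rank break by ascending
#' neighbour id, so the selection is deterministic. `k = 0` yields empty
#' lists for every protein -- the un-enriched ("Origin") configuration.
#'
#' Selection is directed from the query's perspective: protein x's implicit
#' neighbourhood is exactly its own top-k; appearing in someone else's top-k
#' adds nothing, unless `reciprocal = TRUE`, which unions incoming
#' selections in as the undirected alternative (lists may then exceed `k`).
#'
#' @param sim a [SimilarityTable-class].
#' @param universe protein ids to build lists for; neighbours outside the
#'   universe are ignored.
#' @param k number of implicit neighbours per protein (>= 0).
#' @param reciprocal also add incoming top-k selections (default `FALSE`).
#' @return named list over `sort(universe)`; each element a data.frame
#'   (`neighbor`, `score`) sorted by descending score, ties by ascending id.
#' @export
topKImplicit <- function(sim, universe, k, reciprocal = FALSE) {
  stopifnot(is(sim, "SimilarityTable"))
  if (k < 0) stop("k must be non-negative")
  universe <- sort(unique(as.character(universe)))
  empty <- data.frame(neighbor = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  lists <- rep(list(empty), length(universe))
  names(lists) <- universe
  if (k > 0 && nrow(sim@scores)) {
    sc <- sim@scores
    sc <- sc[sc$query %in% universe & sc$subject %in% universe, , drop = FALSE]
    for (d in split(sc, sc$query)) {
      o <- order(-d$score, d$subject)
      d <- d[head(o, k), , drop = FALSE]
      lists[[d$query[1]]] <- data.frame(neighbor = d$subject, score = d$score,
                                        stringsAsFactors = FALSE)
    }
    if (reciprocal) {
      inc <- do.call(rbind, lapply(names(lists), function(x) {
        il <- lists[[x]]
        if (!nrow(il)) return(NULL)
        data.frame(query = il$neighbor, subject = x, score = il$score,
                   stringsAsFactors = FALSE)
      }))
      if (!is.null(inc)) for (d in split(inc, inc$query)) {
        both <- rbind(lists[[d$query[1]]],
                      data.frame(neighbor = d$subject, score = d$score,
                                 stringsAsFactors = FALSE))
        both <- both[!duplicated(both$neighbor), , drop = FALSE]
        both <- both[order(-both$score, both$neighbor), , drop = FALSE]
        rownames(both) <- NULL
        lists[[d$query[1]]] <- both
      }
    }
  }
  lists
}

#' Enrich a PPI network with implicit similarity edges
#'
#' Builds the two-channel network the collective classifier runs on: the
#' explicit interaction graph is kept untouched, and each protein of the
#' union universe (network plus similarity ids) gets its top-`k` implicit
#' neighbour list. Implicit edges duplicating explicit ones are kept in both
#' channels; the classifier's lambda mixture weighs them.
#'
#' @param net an [ExplicitNetwork-class].
#' @param sim a [SimilarityTable-class].
#' @param k implicit edges per protein (default 5, the recommended value;
#'   0 disables enrichment).
#' @param reciprocal see [topKImplicit()].
#' @return an [EnrichedNetwork-class].
#' @examples
#' net <- ExplicitNetwork(c("A", "B"), c("B", "C"))
#' sim <- SimilarityTable(c("A", "A"), c("C", "B"), c(30, 10))
#' enrichNetwork(net, sim, k = 1)
#' @export
enrichNetwork <- function(net, sim, k = 5, reciprocal = FALSE) {
  stopifnot(is(net, "ExplicitNetwork"), is(sim, "SimilarityTable"))
  if (k < 0) stop("k must be non-negative")
  universe <- sort(unique(c(net@proteins, sim@proteins)))
  implicit <- topKImplicit(sim, universe, k, reciprocal = reciprocal)
  ## reciprocal lists may exceed k; the slot records the requested k, so cap
  ## the class invariant by the realized maximum
  kSlot <- max(k, vapply(implicit, nrow, 0L))
  enet <- new("EnrichedNetwork", explicit = net, implicit = implicit,
              k = kSlot, proteins = universe)
  message(sprintf("enriched network: %d explicit edges, %d implicit edges (k = %g)",
                  nrow(net@edges), sum(vapply(implicit, nrow, 0L)), k))
  enet
}

#' Serialize an enriched network to JSON
#'
#' The JSON document has three sections: `proteins` (the universe), an
#' `explicit` section (edge list with weights) and an `implicit` section
#' (per-protein neighbour/score lists), plus the enrichment `k`. The two
#' channels stay separate in the serialization; `readEnrichedNetwork()`
#' restores the object exactly.
#'
#' @param enet an [EnrichedNetwork-class].
#' @param path output/input path.
#' @return `writeEnrichedNetwork()` returns `path` invisibly;
#'   `readEnrichedNetwork()` an [EnrichedNetwork-class].
#' @export
writeEnrichedNetwork <- function(enet, path) {
  stopifnot(is(enet, "EnrichedNetwork"))
  doc <- list(
    k = enet@k,
    proteins = enet@proteins,
    explicit = list(protein_a = enet@explicit@edges$protein_a,
                    protein_b = enet@explicit@edges$protein_b,
                    weight = enet@explicit@edges$weight),
    implicit = lapply(enet@implicit, function(il)
      list(neighbor = il$neighbor, score = il$score)))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeEnrichedNetwork
#' @export
readEnrichedNetwork <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- ExplicitNetwork(as.character(doc$explicit$protein_a),
                         as.character(doc$explicit$protein_b),
                         as.numeric(doc$explicit$weight),
                         proteins = as.character(doc$proteins))
  implicit <- lapply(doc$implicit, function(il)
    data.frame(neighbor = as.character(il$neighbor),
               score = as.numeric(il$score), stringsAsFactors = FALSE))
  new("EnrichedNetwork", explicit = net, implicit = implicit,
      k = as.numeric(doc$k), proteins = as.character(doc$proteins))
}
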
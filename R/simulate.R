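## Synthetic benchmark generator: planted multi-label annotations, a
## function-homophilous explicit network, and correlated similarity scores.
## Each generator derives its RNG stream deterministically from cfg@seed
## (annotations: seed; edges: seed + 1; similarity: seed + 2) so the three
## outputs are individually and jointly reproducible.

.synth_ids <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(n), seq_len(n))

#' Generate multi-label annotations
#'
#' Every protein gets a uniformly drawn number of functions in the
#' configured range, the functions themselves sampled without replacement
#' from a geometric-decay frequency profile (weight of the j-th function
#' proportional to `freqDecay^(j-1)`; `freqDecay = 1` gives uniform
#' frequencies). The skew exercises frequency-based fallback priors and
#' tie-breaking the way real, unbalanced annotation corpora do.
#'
#' @param cfg a [SynthConfig-class].
#' @return an [AnnotationSet-class] over proteins `P001..` and terms `F1..`.
#' @export
generateAnnotations <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  set.seed(cfg@seed)
  n <- cfg@nProteins; m <- cfg@mFunctions
  prots <- .synth_ids("P", n)
  terms <- .synth_ids("F", m)
  lp <- cfg@labelsPerProtein
  nlab <- if (lp[1] == lp[2]) rep(lp[1], n) else
    sample(seq(lp[1], lp[2]), n, replace = TRUE)
  w <- cfg@freqDecay^(seq_len(m) - 1)
  sets <- lapply(nlab, function(k) sort(sample(terms, k, prob = w)))
  names(sets) <- prots
  new("AnnotationSet", annotations = sets, terms = terms)
}

## upper-triangle pair index plus function-sharing indicator
.pair_grid <- function(ann) {
  prots <- names(ann@annotations)
  n <- length(prots)
  Y <- matrix(0, n, length(ann@terms), dimnames = list(prots, ann@terms))
  for (p in prots) Y[p, ann@annotations[[p]]] <- 1
  share <- tcrossprod(Y) > 0
  idx <- which(upper.tri(share), arr.ind = TRUE)
  list(prots = prots, a = prots[idx[, 1]], b = prots[idx[, 2]],
       share = share[idx])
}

#' Generate a function-homophilous explicit network
#'
#' Samples each unordered protein pair independently: edge probability
#' `pIn` when the two proteins share at least one function, `pOut`
#' otherwise; all edges get weight 1. With `pIn > pOut` this plants the
#' guilt-by-association structure (function-sharing proteins are
#' topologically close) that neighbourhood-based predictors assume.
#'
#' @param ann an [AnnotationSet-class] (typically from
#'   [generateAnnotations()]).
#' @param cfg a [SynthConfig-class].
#' @return an [ExplicitNetwork-class] over all proteins of `ann`.
#' @export
generateExplicitEdges <- function(ann, cfg) {
  stopifnot(is(ann, "AnnotationSet"), is(cfg, "SynthConfig"))
  set.seed(cfg@seed + 1L)
  g <- .pair_grid(ann)
  p <- ifelse(g$share, cfg@pIn, cfg@pOut)
  keep <- runif(length(p)) < p
  ExplicitNetwork(g$a[keep], g$b[keep], proteins = g$prots)
}

#' Generate correlated similarity scores
#'
#' Draws a symmetric score for every unordered pair from a gamma
#' distribution with shape `simDispersion` and mean `simSignal` for
#' function-sharing pairs, `simNoise` otherwise; a dispersion of 0 makes
#' scores exactly equal to their means, and a mean of 0 gives score 0
#' (dropped). Self-scores are zero by construction. Only the ordering and
#' rough magnitude of the scores matter to the enrichment and voting steps,
#' so real BLAST bit scores can be substituted directly.
#'
#' @inheritParams generateExplicitEdges
#' @return a [SimilarityTable-class] with both directions of every positive
#'   pair.
#' @export
generateSimilarity <- function(ann, cfg) {
  stopifnot(is(ann, "AnnotationSet"), is(cfg, "SynthConfig"))
  set.seed(cfg@seed + 2L)
  g <- .pair_grid(ann)
  mu <- ifelse(g$share, cfg@simSignal, cfg@simNoise)
  if (cfg@simDispersion > 0) {
    sc <- numeric(length(mu))
    pos <- mu > 0
    sc[pos] <- rgamma(sum(pos), shape = cfg@simDispersion,
                      rate = cfg@simDispersion / mu[pos])
  } else {
    sc <- mu
  }
  SimilarityTable(c(g$a, g$b), c(g$b, g$a), c(sc, sc), proteins = g$prots)
}

#' Generate a complete synthetic benchmark
#'
#' Convenience wrapper producing annotations, explicit network and
#' similarity table from one configuration.
#'
#' @param cfg a [SynthConfig-class].
#' @return list with elements `annotations`, `network`, `similarity`.
#' @examples
#' d <- generateSyntheticData(synthConfig(nProteins = 30, seed = 7))
#' d$network
#' @export
generateSyntheticData <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  ann <- generateAnnotations(cfg)
  list(annotations = ann,
       network = generateExplicitEdges(ann, cfg),
       similarity = generateSimilarity(ann, cfg))
}

#' Write a synthetic benchmark to the standard input files
#'
#' Writes `<prefix>edges.tsv` (unweighted edge list),
#' `<prefix>similarity.tsv` (query/subject/score) and
#' `<prefix>annotations.tsv` (protein/term), readable back with
#' [readEdgeList()], [readSimilarity()] and [readAnnotations()].
#'
#' @param cfg a [SynthConfig-class].
#' @param prefix output path prefix (directories must exist).
#' @return invisibly, the three file paths.
#' @export
writeSyntheticData <- function(cfg, prefix) {
  d <- generateSyntheticData(cfg)
  paths <- paste0(prefix, c("edges.tsv", "similarity.tsv", "annotations.tsv"))
  ed <- d$network@edges
  write.table(ed[, c("protein_a", "protein_b")], paths[1], sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(d$similarity@scores, paths[2], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  annTab <- data.frame(
    protein = rep(names(d$annotations@annotations),
                  lengths(d$annotations@annotations)),
    term = unlist(d$annotations@annotations, use.names = FALSE))
  write.table(annTab, paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
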
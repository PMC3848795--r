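## Gibbs-sampling collective classification on the two-channel network:
## weighted-voting bootstrap, burn-in and sampling sweeps, per-sweep rank
## vectors and column-mode rank aggregation.
##
## The sampler is vectorized over queries: per sweep, both channels'
## vote sums for all queries are two sparse matrix products. Random draws
## follow a fixed documented order so runs are bit-reproducible: within a
## sweep, one assignment draw per query in ascending protein id order
## (hard-sample mode), then -- in sampling sweeps -- one runif(m) tie-break
## vector per query, again in ascending id order.

#' @importFrom Matrix sparseMatrix
NULL

## sparse n x n adjacency of both channels, rows/cols in sorted protein order
.adjacency <- function(enet) {
  prots <- enet@proteins
  n <- length(prots)
  ed <- enet@explicit@edges
  ia <- match(ed$protein_a, prots); ib <- match(ed$protein_b, prots)
  W <- sparseMatrix(i = c(ia, ib), j = c(ib, ia), x = rep(ed$weight, 2L),
                    dims = c(n, n))
  lens <- vapply(enet@implicit, nrow, 0L)
  if (sum(lens)) {
    qi <- rep(match(names(enet@implicit), prots), lens)
    nb <- unlist(lapply(enet@implicit, `[[`, "neighbor"), use.names = FALSE)
    sc <- unlist(lapply(enet@implicit, `[[`, "score"), use.names = FALSE)
    S <- sparseMatrix(i = qi, j = match(nb, prots), x = sc, dims = c(n, n))
  } else {
    S <- sparseMatrix(i = integer(), j = integer(), x = numeric(),
                      dims = c(n, n))
  }
  list(prots = prots, W = W, S = S)
}

## dense n x m 0/1 label indicator for the annotated proteins present
.indicator <- function(ann, prots, terms) {
  Fm <- matrix(0, length(prots), length(terms),
               dimnames = list(prots, terms))
  lab <- intersect(names(ann@annotations), prots)
  for (p in lab) Fm[p, ann@annotations[[p]]] <- 1
  Fm
}

## fallback prior over `terms` from a list of label sets
.label_prior <- function(sets, terms, mode) {
  m <- length(terms)
  if (mode == "uniform" || !length(sets)) return(rep(1 / m, m))
  cnt <- table(factor(unlist(sets, use.names = FALSE), levels = terms))
  if (sum(cnt) == 0) return(rep(1 / m, m))
  as.numeric(cnt) / sum(cnt)
}

## vectorized weighted vote: rows = queries. Returns the probability matrix
## plus the degenerate-row mask (no assigned neighbour in either channel).
.vote_all <- function(Ws, Ww, Fm, lambda, prior) {
  Ts <- as.matrix(Ws %*% Fm)
  Tw <- as.matrix(Ww %*% Fm)
  Zs <- rowSums(Ts); Zw <- rowSums(Tw)
  P <- matrix(0, nrow(Ts), ncol(Ts))
  both <- Zs > 0 & Zw > 0
  sOnly <- Zs > 0 & Zw == 0
  wOnly <- Zs == 0 & Zw > 0
  none <- Zs == 0 & Zw == 0
  if (any(both))
    P[both, ] <- lambda * Ts[both, , drop = FALSE] / Zs[both] +
      (1 - lambda) * Tw[both, , drop = FALSE] / Zw[both]
  if (any(sOnly)) P[sOnly, ] <- Ts[sOnly, , drop = FALSE] / Zs[sOnly]
  if (any(wOnly)) P[wOnly, ] <- Tw[wOnly, , drop = FALSE] / Zw[wOnly]
  if (any(none)) P[none, ] <- rep(prior, each = sum(none))
  list(P = P, none = none)
}

#' Weighted vote over a protein's assigned neighbours
#'
#' Computes the function distribution of protein `x` by weighted voting over
#' the neighbours that currently carry labels, mixing the two channels:
#'
#' `P_x(j) = lambda * (1/Zs) * sum_i f_ij s_xi + (1-lambda) * (1/Zw) * sum_i f_ij w_xi`
#'
#' where the first sum runs over `x`'s implicit neighbours (similarity
#' scores `s`), the second over its explicit neighbours (interaction weights
#' `w`), `f_ij` is neighbour i's 0/1 indicator for function j (a multi-label
#' neighbour contributes its full weight to every function it carries), and
#' each normalizer `Z` makes its channel's term sum to 1 over functions. A
#' channel with no assigned neighbour is dropped and the other channel's
#' coefficient renormalized to 1; when both channels are empty the result is
#' the fallback prior, flagged via `attr(, "fallback")`.
#'
#' @param x a single protein id.
#' @param net an [EnrichedNetwork-class].
#' @param labels named list mapping each currently assigned protein to its
#'   character vector of functions (annotated labels, or sampled assignments
#'   during the iterative phase). Unassigned neighbours are ignored.
#' @param cfg a [GibbsConfig-class] (supplies `lambda` and the fallback
#'   prior).
#' @param terms the function universe; defaults to the terms seen in
#'   `labels`.
#' @return named numeric vector over `terms` summing to 1, with logical
#'   attribute `"fallback"`.
#' @examples
#' net <- enrichNetwork(ExplicitNetwork(c("X", "X"), c("N1", "N2")),
#'                      SimilarityTable("X", "M1", 10), k = 1)
#' weightedVote("X", net, list(M1 = "F1", N1 = "F1", N2 = "F2"),
#'              gibbsConfig(lambda = 0.5), terms = c("F1", "F2"))
#' @export
weightedVote <- function(x, net, labels, cfg, terms = NULL) {
  stopifnot(is(net, "EnrichedNetwork"), is(cfg, "GibbsConfig"),
            length(x) == 1L)
  if (is.null(terms))
    terms <- sort(unique(unlist(labels, use.names = FALSE)))
  m <- length(terms)
  if (!m) stop("empty function universe")
  ts <- setNames(numeric(m), terms)
  tw <- ts
  il <- implicitNeighbors(net, x)
  for (i in seq_len(nrow(il))) {
    lb <- labels[[il$neighbor[i]]]
    if (!is.null(lb)) ts[lb] <- ts[lb] + il$score[i]
  }
  el <- explicitNeighbors(net, x)
  for (i in seq_len(nrow(el))) {
    lb <- labels[[el$neighbor[i]]]
    if (!is.null(lb)) tw[lb] <- tw[lb] + el$weight[i]
  }
  Zs <- sum(ts); Zw <- sum(tw)
  fb <- FALSE
  if (Zs > 0 && Zw > 0)
    p <- cfg@lambda * ts / Zs + (1 - cfg@lambda) * tw / Zw
  else if (Zs > 0) p <- ts / Zs
  else if (Zw > 0) p <- tw / Zw
  else {
    p <- setNames(.label_prior(labels, terms, cfg@fallbackPrior), terms)
    fb <- TRUE
  }
  attr(p, "fallback") <- fb
  p
}

#' Bootstrap function distributions from labelled neighbours
#'
#' The initialization phase of the collective classifier: every query's
#' distribution is the weighted vote ([weightedVote()]) restricted to its
#' annotated neighbours; unlabelled neighbours contribute nothing here.
#' Queries must not themselves be annotated (hold a query's labels out
#' before calling).
#'
#' @param net an [EnrichedNetwork-class].
#' @param ann an [AnnotationSet-class] of the labelled proteins; its term
#'   universe defines `m`.
#' @param queries character vector of query protein ids (in the network,
#'   disjoint from the annotated set).
#' @param cfg a [GibbsConfig-class].
#' @return numeric matrix (sorted queries x terms), each row summing to 1,
#'   with logical attribute `"fallback"` marking rows that fell back to the
#'   prior (no labelled neighbour in either channel).
#' @export
bootstrapDistributions <- function(net, ann, queries, cfg) {
  stopifnot(is(net, "EnrichedNetwork"), is(ann, "AnnotationSet"),
            is(cfg, "GibbsConfig"))
  queries <- sort(unique(as.character(queries)))
  if (!length(queries)) stop("no query proteins")
  bad <- setdiff(queries, net@proteins)
  if (length(bad))
    stop(sprintf("query protein(s) not in the network: %s",
                 paste(head(bad, 3), collapse = ", ")))
  overlap <- intersect(queries, names(ann@annotations))
  if (length(overlap))
    stop(sprintf("query protein(s) still annotated (hold labels out first): %s",
                 paste(head(overlap, 3), collapse = ", ")))
  terms <- ann@terms
  adj <- .adjacency(net)
  qi <- match(queries, adj$prots)
  Fm <- .indicator(ann, adj$prots, terms)
  prior <- .label_prior(ann@annotations, terms, cfg@fallbackPrior)
  v <- .vote_all(adj$S[qi, , drop = FALSE], adj$W[qi, , drop = FALSE],
                 Fm, cfg@lambda, prior)
  a <- v$P
  dimnames(a) <- list(queries, terms)
  attr(a, "fallback") <- setNames(v$none, queries)
  a
}

#' Sample one function from a distribution
#'
#' Draws a single function index with probability proportional to the
#' entries of `a`. Uses the current RNG state; call `set.seed()` for
#' reproducibility.
#'
#' @param a non-negative numeric vector with positive sum.
#' @return integer index in `1:length(a)`.
#' @export
sampleAssignment <- function(a) {
  if (!is.numeric(a) || !length(a) || anyNA(a) || any(a < 0) || sum(a) <= 0)
    stop("`a` must be a non-negative vector with positive sum")
  sample.int(length(a), 1L, prob = a)
}

#' Rank the functions of a distribution
#'
#' Returns the function indices sorted by descending probability. Equal
#' probabilities are ranked uniformly at random (always consuming
#' `length(a)` uniform draws, so the RNG stream does not depend on the
#' presence of ties).
#'
#' @param a numeric vector of function probabilities.
#' @return integer permutation of `1:length(a)`.
#' @export
rankVector <- function(a) {
  stopifnot(is.numeric(a), length(a) >= 1L, !anyNA(a))
  order(-a, runif(length(a)))
}

#' Aggregate per-sweep rankings into a final ranking
#'
#' Builds the final ranked prediction from the sampling-period rank matrix
#' (one row per sweep, each a permutation of the `m` function indices): the
#' rank-r function is the most frequent entry of column r among functions
#' not already chosen at earlier ranks, ties broken by ascending function
#' index, with support fraction = mode count / number of sweeps. If a
#' column's entries are all already chosen (possible when the sampled
#' rankings are highly concentrated), the smallest-index unchosen function
#' fills the rank with support 0.
#'
#' @param M integer matrix (sweeps x m); every row a permutation of `1:m`.
#' @return list with `index` (integer permutation of `1:m`, the final
#'   ranking) and `support` (numeric in \[0,1\] per rank).
#' @examples
#' aggregateRanks(rbind(c(1, 2), c(1, 2), c(2, 1)))
#' @export
aggregateRanks <- function(M) {
  if (!is.matrix(M) || nrow(M) < 1L) stop("M must be a non-empty matrix")
  m <- ncol(M)
  S <- nrow(M)
  chosen <- integer(m)
  support <- numeric(m)
  for (r in seq_len(m)) {
    col <- M[, r]
    col <- col[!(col %in% chosen[seq_len(r - 1L)])]
    if (!length(col)) {
      chosen[r] <- setdiff(seq_len(m), chosen[seq_len(r - 1L)])[1L]
      support[r] <- 0
    } else {
      tab <- tabulate(col, nbins = m)
      chosen[r] <- which.max(tab)   # ties -> smallest index
      support[r] <- tab[chosen[r]] / S
    }
  }
  list(index = chosen, support = support)
}

#' Gibbs-sampling collective function prediction
#'
#' Runs the full two-phase collective classifier on the enriched network:
#'
#' 1. *Bootstrapping*: every query gets an initial distribution by weighted
#'    voting over its labelled neighbours only.
#' 2. *Burn-in* (`B = cfg@burnIn` sweeps) and *sampling*
#'    (`S = cfg@samples` sweeps): at the start of each sweep every query is
#'    assigned one function sampled from its current distribution
#'    (hard-sample mode; in soft mode neighbours see the full distribution),
#'    then all distributions are recomputed by weighted voting over the
#'    current assignments, annotated labels staying clamped throughout.
#'    During the sampling period the post-update ranking of every query is
#'    recorded (ties ranked uniformly at random).
#' 3. *Rank aggregation*: the S recorded rankings per query are reduced
#'    column-by-column to the final ranking by [aggregateRanks()].
#'
#' Queries with no neighbour in either channel keep the fallback prior and
#' are flagged. The run is bit-reproducible given identical inputs and
#' configuration (`cfg@seed` governs all draws).
#'
#' @inheritParams bootstrapDistributions
#' @return a [FunctionPredictions-class] with all `m` functions ranked per
#'   query and per-rank support fractions.
#' @examples
#' net <- enrichNetwork(ExplicitNetwork(c("Q", "Q"), c("A", "B")),
#'                      SimilarityTable(), k = 0)
#' ann <- AnnotationSet(c("A", "B"), c("F1", "F1"))
#' gibbsPredict(net, ann, "Q", gibbsConfig(burnIn = 2, samples = 10, seed = 1))
#' @export
gibbsPredict <- function(net, ann, queries, cfg) {
  stopifnot(is(net, "EnrichedNetwork"), is(ann, "AnnotationSet"),
            is(cfg, "GibbsConfig"))
  queries <- sort(unique(as.character(queries)))
  if (!length(queries)) stop("no query proteins")
  bad <- setdiff(queries, net@proteins)
  if (length(bad))
    stop(sprintf("query protein(s) not in the network: %s",
                 paste(head(bad, 3), collapse = ", ")))
  overlap <- intersect(queries, names(ann@annotations))
  if (length(overlap))
    stop(sprintf("query protein(s) still annotated (hold labels out first): %s",
                 paste(head(overlap, 3), collapse = ", ")))
  terms <- ann@terms
  m <- length(terms)
  nq <- length(queries)
  adj <- .adjacency(net)
  qi <- match(queries, adj$prots)
  Ws <- adj$S[qi, , drop = FALSE]
  Ww <- adj$W[qi, , drop = FALSE]
  Fm <- .indicator(ann, adj$prots, terms)
  prior <- .label_prior(ann@annotations, terms, cfg@fallbackPrior)
  isolated <- Matrix::rowSums(Ws) == 0 & Matrix::rowSums(Ww) == 0

  set.seed(cfg@seed)
  a <- .vote_all(Ws, Ww, Fm, cfg@lambda, prior)$P
  B <- cfg@burnIn; S <- cfg@samples
  Marr <- array(0L, dim = c(S, m, nq))
  Fcur <- Fm
  hard <- cfg@updateMode == "hard-sample"
  for (it in seq_len(B + S)) {
    if (hard) {
      assign <- integer(nq)
      for (j in seq_len(nq)) assign[j] <- sample.int(m, 1L, prob = a[j, ])
      Fcur[qi, ] <- 0
      Fcur[cbind(qi, assign)] <- 1
    } else {
      Fcur[qi, ] <- a
    }
    a <- .vote_all(Ws, Ww, Fcur, cfg@lambda, prior)$P
    if (it > B)
      for (j in seq_len(nq))
        Marr[it - B, , j] <- order(-a[j, ], runif(m))
  }

  tabs <- vector("list", nq)
  for (j in seq_len(nq)) {
    agg <- aggregateRanks(matrix(Marr[, , j], nrow = S, ncol = m))
    tabs[[j]] <- data.frame(protein = queries[j], rank = seq_len(m),
                            term = terms[agg$index], support = agg$support,
                            stringsAsFactors = FALSE)
  }
  new("FunctionPredictions", table = do.call(rbind, tabs),
      fallback = queries[isolated], terms = terms)
}
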
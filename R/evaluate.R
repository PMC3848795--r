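## Evaluation protocols: rank depth rule, rank-wise TP/FP counting,
## leave-one-out cross validation (bootstrap-only) and sparse-labelling
## experiments.

#' Number of prediction ranks to evaluate
#'
#' The evaluation depth is `floor(mean functions per annotated protein) + 1`:
#' e.g. networks averaging 1.24, 3.96 and 2.58 functions per protein are
#' evaluated at the top 2, 4 and 3 predictions respectively.
#'
#' @param ann a non-empty [AnnotationSet-class].
#' @return integer rank depth.
#' @examples
#' rankDepth(AnnotationSet(list(P1 = "F1", P2 = c("F1", "F2"))))
#' @export
rankDepth <- function(ann) {
  stopifnot(is(ann, "AnnotationSet"))
  if (!length(ann@annotations)) stop("empty annotation set")
  as.integer(floor(mean(lengths(ann@annotations))) + 1L)
}

#' Rank-wise TP/FP counts of a prediction set
#'
#' For each rank `i = 1..depth`, counts the queries whose i-th ranked
#' predicted function is among their true functions (TP_i) versus not
#' (FP_i). Every query is counted at every rank, so a query with fewer than
#' `i` true functions necessarily contributes to FP_i. The ratio TP_i/FP_i
#' is `Inf` when FP_i = 0 and TP_i > 0 (never silently dropped) and `NaN`
#' when both are zero.
#'
#' @param preds a [FunctionPredictions-class]; every query must carry at
#'   least `depth` ranked functions.
#' @param truth an [AnnotationSet-class] containing every query.
#' @param depth number of ranks to evaluate (see [rankDepth()]).
#' @return a [RankMetrics-class].
#' @export
rankTpFp <- function(preds, truth, depth) {
  stopifnot(is(preds, "FunctionPredictions"), is(truth, "AnnotationSet"),
            depth >= 1)
  tb <- preds@table
  queries <- sort(unique(tb$protein))
  if (!length(queries)) stop("no predictions to evaluate")
  missing <- setdiff(queries, names(truth@annotations))
  if (length(missing))
    stop(sprintf("query protein(s) missing from the truth annotations: %s",
                 paste(head(missing, 3), collapse = ", ")))
  nq <- length(queries)
  tp <- integer(depth); fp <- integer(depth)
  for (i in seq_len(depth)) {
    sub <- tb[tb$rank == i, , drop = FALSE]
    if (nrow(sub) < nq)
      stop(sprintf("every query needs >= %d ranked functions", depth))
    at <- setNames(sub$term, sub$protein)
    hit <- vapply(queries, function(q) at[[q]] %in% truth@annotations[[q]],
                  logical(1))
    tp[i] <- sum(hit); fp[i] <- nq - tp[i]
  }
  ratio <- ifelse(fp > 0, tp / fp, ifelse(tp > 0, Inf, NaN))
  new("RankMetrics",
      table = data.frame(rank = seq_len(depth), tp = tp, fp = fp,
                         ratio = ratio),
      nQueries = nq)
}

## bootstrap-only ranked predictions of every labelled protein, each with
## its own labels held out (a protein never being its own neighbour, this is
## one vectorized vote over the full labelled indicator)
.loocv_predictions <- function(net, ann, cfg, method, sim, k) {
  labelled <- intersect(names(ann@annotations), net@proteins)
  if (length(labelled) < 2L) stop("need at least two annotated proteins")
  terms <- ann@terms
  m <- length(terms)
  set.seed(cfg@seed)
  fb <- character()
  tabs <- vector("list", length(labelled))
  if (method == "gibbs") {
    adj <- .adjacency(net)
    qi <- match(labelled, adj$prots)
    Fm <- .indicator(ann, adj$prots, terms)
    cnt <- colSums(Fm)
    v <- .vote_all(adj$S[qi, , drop = FALSE], adj$W[qi, , drop = FALSE],
                   Fm, cfg@lambda, rep(1 / m, m))
    a <- v$P
    for (j in seq_along(labelled)) {
      p <- a[j, ]
      if (v$none[j]) {
        ## leave-x-out fallback prior: term frequencies without x's labels
        p <- if (cfg@fallbackPrior == "uniform") rep(1 / m, m) else {
          cx <- cnt - Fm[qi[j], ]
          if (sum(cx) > 0) cx / sum(cx) else rep(1 / m, m)
        }
        fb <- c(fb, labelled[j])
      }
      o <- rankVector(p)
      tabs[[j]] <- data.frame(protein = labelled[j], rank = seq_len(m),
                              term = terms[o], support = sort(p, decreasing = TRUE),
                              stringsAsFactors = FALSE)
    }
  } else {
    for (j in seq_along(labelled)) {
      x <- labelled[j]
      annX <- new("AnnotationSet",
                  annotations = ann@annotations[setdiff(labelled, x)],
                  terms = terms)
      pr <- if (method == "majority")
        majorityPredict(net@explicit, annX, x, cfg@fallbackPrior)
      else
        blastKnnPredict(sim, annX, x, k = k, fallbackPrior = cfg@fallbackPrior)
      tabs[[j]] <- pr@table
      fb <- c(fb, pr@fallback)
    }
  }
  new("FunctionPredictions", table = do.call(rbind, tabs), fallback = fb,
      terms = terms)
}

#' Leave-one-out cross validation
#'
#' Treats each annotated protein as un-annotated in turn, predicts it from
#' the remaining labels, restores them, and aggregates rank-wise TP/FP at
#' the [rankDepth()] of the annotation set. Because a held-out protein's
#' label vector is never updated after bootstrapping, the iterative
#' classification step is omitted: the collective classifier is evaluated on
#' its bootstrap distribution, ranked with the same seeded random tie-break
#' as the main path (so results are reproducible given `cfg@seed`).
#'
#' @param net an [EnrichedNetwork-class].
#' @param ann an [AnnotationSet-class] (>= 2 annotated proteins in the
#'   network).
#' @param cfg a [GibbsConfig-class].
#' @param method `"gibbs"` (bootstrap weighted voting over both channels),
#'   `"majority"`, or `"blast-knn"`.
#' @param sim a [SimilarityTable-class]; required for `method = "blast-knn"`.
#' @param k neighbour count for `"blast-knn"` (default 5).
#' @return a [RankMetrics-class].
#' @export
loocv <- function(net, ann, cfg, method = c("gibbs", "majority", "blast-knn"),
                  sim = NULL, k = 5) {
  stopifnot(is(net, "EnrichedNetwork"), is(ann, "AnnotationSet"),
            is(cfg, "GibbsConfig"))
  method <- match.arg(method)
  if (method == "blast-knn" && is.null(sim))
    stop("method 'blast-knn' needs a SimilarityTable via `sim`")
  depth <- min(rankDepth(ann), length(ann@terms))
  preds <- .loocv_predictions(net, ann, cfg, method, sim, k)
  rankTpFp(preds, ann, depth)
}

#' Sparse-labelling experiment
#'
#' For each annotated fraction p, repeatedly samples that fraction of the
#' annotated proteins uniformly without replacement as the labelled set,
#' predicts all remaining annotated proteins (for `method = "gibbs"`, with
#' the full collective classifier including burn-in and sampling), and
#' scores the predictions against the held-out truth with rank-wise TP/FP.
#' Split seeds are derived reproducibly from `cfg@seed` and recorded in the
#' report.
#'
#' @param net an [EnrichedNetwork-class].
#' @param ann an [AnnotationSet-class]; only annotated proteins in the
#'   network are split and queried.
#' @param fractions annotated fractions, each strictly in (0,1)
#'   (default 0.1-0.9).
#' @param repeats experiments per fraction (default 10).
#' @param cfg a [GibbsConfig-class].
#' @param method `"gibbs"`, `"majority"`, or `"blast-knn"`.
#' @param sim similarity table for `"blast-knn"`.
#' @param k neighbour count for `"blast-knn"`.
#' @return a [SparseExperimentReport-class].
#' @export
sparseExperiment <- function(net, ann, fractions = seq(0.1, 0.9, by = 0.1),
                             repeats = 10, cfg = gibbsConfig(),
                             method = c("gibbs", "majority", "blast-knn"),
                             sim = NULL, k = 5) {
  stopifnot(is(net, "EnrichedNetwork"), is(ann, "AnnotationSet"),
            is(cfg, "GibbsConfig"))
  method <- match.arg(method)
  if (any(fractions <= 0 | fractions >= 1))
    stop("fractions must lie strictly in (0, 1)")
  if (repeats < 1) stop("repeats must be >= 1")
  if (method == "blast-knn" && is.null(sim))
    stop("method 'blast-knn' needs a SimilarityTable via `sim`")
  pool <- intersect(names(ann@annotations), net@proteins)
  npool <- length(pool)
  depth <- min(rankDepth(ann), length(ann@terms))
  nf <- length(fractions)
  set.seed(cfg@seed)
  seeds <- matrix(sample.int(.Machine$integer.max, nf * repeats), nf, repeats)
  ratios <- array(NA_real_, dim = c(nf, repeats, depth))
  for (fi in seq_len(nf)) {
    nlab <- round(fractions[fi] * npool)
    if (nlab < 1 || npool - nlab < 1)
      stop(sprintf("fraction %.2f yields an empty labelled or query set",
                   fractions[fi]))
    for (r in seq_len(repeats)) {
      set.seed(seeds[fi, r])
      lab <- sample(pool, nlab)
      qs <- setdiff(pool, lab)
      annLab <- new("AnnotationSet", annotations = ann@annotations[
        intersect(names(ann@annotations), lab)], terms = ann@terms)
      cfgR <- initialize(cfg, seed = seeds[fi, r])
      preds <- switch(method,
        gibbs = gibbsPredict(net, annLab, qs, cfgR),
        majority = majorityPredict(net@explicit, annLab, qs,
                                   cfg@fallbackPrior),
        `blast-knn` = blastKnnPredict(sim, annLab, qs, k = k,
                                      fallbackPrior = cfg@fallbackPrior))
      ratios[fi, r, ] <- rankTpFp(preds, ann, depth)@table$ratio
    }
  }
  sm <- expand.grid(rank = seq_len(depth), fraction = fractions)[, 2:1]
  sm$meanRatio <- as.numeric(t(apply(ratios, c(1, 3), mean)))
  sm$sdRatio <- as.numeric(t(apply(ratios, c(1, 3), sd)))
  sm <- sm[order(sm$fraction, sm$rank), , drop = FALSE]
  rownames(sm) <- NULL
  new("SparseExperimentReport", ratios = ratios, seeds = seeds,
      fractions = fractions, summary = sm)
}

#' Subset an annotation set, keeping the function universe
#'
#' @param ann an [AnnotationSet-class].
#' @param proteins ids to keep (intersection is taken).
#' @return an [AnnotationSet-class] over the surviving proteins with the
#'   original term universe.
#' @export
subsetAnnotations <- function(ann, proteins) {
  stopifnot(is(ann, "AnnotationSet"))
  keep <- intersect(names(ann@annotations), as.character(proteins))
  new("AnnotationSet", annotations = ann@annotations[keep], terms = ann@terms)
}
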
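#' @import methods
#' @importFrom stats runif rgamma sd setNames
#' @importFrom utils head read.table write.table
NULL

## ---- AnnotationSet ---------------------------------------------------------

#' Multi-label protein function annotations
#'
#' An `AnnotationSet` maps each annotated protein to its set of function
#' terms (GO ids, FunCat codes, or any opaque labels). The sorted vector of
#' distinct terms defines the function universe of size `m`; a protein's label
#' vector is the 0/1 indicator over that universe. Every annotated protein
#' carries at least one term.
#'
#' @slot annotations named list; each element a character vector of terms.
#' @slot terms sorted character vector of all function terms (the universe).
#'
#' @seealso [AnnotationSet()], [readAnnotations()], [functionTerms()]
#' @export
setClass("AnnotationSet",
         slots = c(annotations = "list", terms = "character"))

setValidity("AnnotationSet", function(object) {
  nm <- names(object@annotations)
  if (length(object@annotations) &&
      (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm)))
    return("annotations must be a uniquely named list of term vectors")
  if (any(grepl("[[:space:]]", nm)))
    return("protein identifiers must not contain whitespace")
  bad <- !vapply(object@annotations, function(x)
    is.character(x) && length(x) >= 1L && all(nzchar(x)) && !anyDuplicated(x),
    logical(1))
  if (any(bad))
    return("every annotated protein needs >= 1 distinct non-empty term")
  used <- unique(unlist(object@annotations, use.names = FALSE))
  if (!all(used %in% object@terms))
    return("term universe must contain every term used in the annotations")
  if (is.unsorted(object@terms) || anyDuplicated(object@terms))
    return("term universe must be sorted and duplicate-free")
  TRUE
})

#' Construct an AnnotationSet
#'
#' @param x either a named list mapping protein id to a character vector of
#'   terms, or a character vector of protein ids (paired with `term`).
#' @param term character vector of function terms, parallel to `x` when `x`
#'   is a vector of protein ids. Duplicate (protein, term) pairs collapse.
#' @param terms optional explicit function universe; must contain every used
#'   term. Supplying a superset keeps `m` fixed across label subsets (e.g.
#'   during sparse-labelling experiments).
#' @return an [AnnotationSet-class] object.
#' @examples
#' ann <- AnnotationSet(c("P1", "P1", "P2"), c("F1", "F2", "F1"))
#' functionTerms(ann)
#' @export
AnnotationSet <- function(x, term = NULL, terms = NULL) {
  if (is.list(x)) {
    lst <- lapply(x, function(v) sort(unique(as.character(v))))
  } else {
    if (is.null(term) || length(term) != length(x))
      stop("`term` must be parallel to the protein id vector")
    lst <- lapply(split(as.character(term), as.character(x)),
                  function(v) sort(unique(v)))
  }
  if (length(lst)) lst <- lst[order(names(lst))]
  if (is.null(terms))
    terms <- sort(unique(as.character(unlist(lst, use.names = FALSE))))
  else
    terms <- sort(unique(as.character(terms)))
  new("AnnotationSet", annotations = lst, terms = terms)
}

## ---- ExplicitNetwork -------------------------------------------------------

#' Explicit (observed) PPI network
#'
#' Undirected weighted interaction graph. Self-loops are dropped (with a
#' warning) and duplicate records for the same unordered pair are merged by
#' maximum weight; weights default to 1 and must be positive. The vertex set
#' may include isolated proteins.
#'
#' @slot edges data.frame with columns `protein_a`, `protein_b`, `weight`;
#'   each row a canonical (`protein_a < protein_b`) unordered pair.
#' @slot proteins sorted character vector of vertex ids.
#'
#' @seealso [ExplicitNetwork()], [readEdgeList()]
#' @export
setClass("ExplicitNetwork",
         slots = c(edges = "data.frame", proteins = "character"))

setValidity("ExplicitNetwork", function(object) {
  ed <- object@edges
  if (!identical(names(ed), c("protein_a", "protein_b", "weight")))
    return("edges must have columns protein_a, protein_b, weight")
  if (any(ed$protein_a == ed$protein_b)) return("self-loops are not allowed")
  if (any(ed$weight <= 0)) return("edge weights must be positive")
  if (any(ed$protein_a > ed$protein_b))
    return("edge endpoints must be in canonical order")
  if (anyDuplicated(paste(ed$protein_a, ed$protein_b)))
    return("at most one edge per unordered pair")
  if (!all(c(ed$protein_a, ed$protein_b) %in% object@proteins))
    return("all edge endpoints must be in the protein set")
  TRUE
})

#' Construct an ExplicitNetwork
#'
#' @param from,to character vectors of interacting protein ids.
#' @param weight positive interaction confidences; defaults to 1 for every
#'   edge when `NULL`.
#' @param proteins optional extra vertex ids (isolated proteins to keep).
#' @return an [ExplicitNetwork-class] object.
#' @export
ExplicitNetwork <- function(from = character(), to = character(),
                            weight = NULL, proteins = NULL) {
  from <- as.character(from); to <- as.character(to)
  if (length(from) != length(to)) stop("`from` and `to` must be parallel")
  if (is.null(weight)) weight <- rep(1, length(from))
  weight <- as.numeric(weight)
  if (length(weight) != length(from)) stop("`weight` must be parallel to edges")
  if (anyNA(weight) || any(weight <= 0)) stop("edge weights must be positive")
  proteins <- c(as.character(proteins), from, to)  # self-loop ids stay vertices
  self <- from == to
  if (any(self)) {
    warning(sprintf("%d self-loop(s) dropped", sum(self)))
    from <- from[!self]; to <- to[!self]; weight <- weight[!self]
  }
  a <- pmin(from, to); b <- pmax(from, to)
  if (length(a)) {
    key <- paste(a, b, sep = "\r")
    w <- tapply(weight, key, max)
    ab <- strsplit(names(w), "\r", fixed = TRUE)
    ed <- data.frame(protein_a = vapply(ab, `[`, "", 1L),
                     protein_b = vapply(ab, `[`, "", 2L),
                     weight = as.numeric(w), stringsAsFactors = FALSE)
    ed <- ed[order(ed$protein_a, ed$protein_b), , drop = FALSE]
    rownames(ed) <- NULL
  } else {
    ed <- data.frame(protein_a = character(), protein_b = character(),
                     weight = numeric(), stringsAsFactors = FALSE)
  }
  prots <- sort(unique(c(a, b, as.character(proteins))))
  new("ExplicitNetwork", edges = ed, proteins = prots)
}

## ---- SimilarityTable -------------------------------------------------------

#' Pairwise sequence-similarity scores
#'
#' Directed scored pairs (query, subject, score), typically BLAST bit scores.
#' Self-similarity is defined to be zero and is therefore never stored;
#' duplicate (query, subject) records (e.g. multiple HSPs) collapse to their
#' maximum score, and zero scores are dropped as equivalent to absent pairs.
#'
#' @slot scores data.frame with columns `query`, `subject`, `score`
#'   (score > 0), sorted by query then subject.
#' @slot proteins sorted character vector of all ids seen on input, kept even
#'   when every record involving an id was dropped.
#'
#' @seealso [SimilarityTable()], [readSimilarity()]
#' @export
setClass("SimilarityTable",
         slots = c(scores = "data.frame", proteins = "character"))

setValidity("SimilarityTable", function(object) {
  sc <- object@scores
  if (!identical(names(sc), c("query", "subject", "score")))
    return("scores must have columns query, subject, score")
  if (any(sc$query == sc$subject)) return("self-similarity must be zero (absent)")
  if (any(sc$score <= 0)) return("stored scores must be positive")
  if (anyDuplicated(paste(sc$query, sc$subject)))
    return("at most one score per (query, subject) pair")
  if (!all(c(sc$query, sc$subject) %in% object@proteins))
    return("all scored ids must be in the protein set")
  TRUE
})

#' Construct a SimilarityTable
#'
#' @param query,subject character vectors of protein ids.
#' @param score non-negative similarity scores (zeros dropped).
#' @param proteins optional extra ids to keep in the protein universe.
#' @return a [SimilarityTable-class] object.
#' @export
SimilarityTable <- function(query = character(), subject = character(),
                            score = numeric(), proteins = NULL) {
  query <- as.character(query); subject <- as.character(subject)
  score <- as.numeric(score)
  if (length(query) != length(subject) || length(query) != length(score))
    stop("query, subject and score must be parallel")
  if (anyNA(score) || any(score < 0)) stop("scores must be non-negative numbers")
  prots <- sort(unique(c(query, subject, as.character(proteins))))
  keep <- query != subject & score > 0
  query <- query[keep]; subject <- subject[keep]; score <- score[keep]
  if (length(query)) {
    key <- paste(query, subject, sep = "\r")
    s <- tapply(score, key, max)
    qs <- strsplit(names(s), "\r", fixed = TRUE)
    sc <- data.frame(query = vapply(qs, `[`, "", 1L),
                     subject = vapply(qs, `[`, "", 2L),
                     score = as.numeric(s), stringsAsFactors = FALSE)
    sc <- sc[order(sc$query, sc$subject), , drop = FALSE]
    rownames(sc) <- NULL
  } else {
    sc <- data.frame(query = character(), subject = character(),
                     score = numeric(), stringsAsFactors = FALSE)
  }
  new("SimilarityTable", scores = sc, proteins = prots)
}

## ---- OntologyTable ---------------------------------------------------------

#' Flat parent-child ontology
#'
#' Child-to-parent links between function terms (a term may have several
#' parents). The link set must be acyclic; this is validated with a DAG check.
#'
#' @slot links data.frame with columns `child`, `parent`.
#' @export
setClass("OntologyTable", slots = c(links = "data.frame"))

setValidity("OntologyTable", function(object) {
  lk <- object@links
  if (!identical(names(lk), c("child", "parent")))
    return("links must have columns child, parent")
  if (nrow(lk)) {
    g <- igraph::graph_from_data_frame(lk, directed = TRUE)
    if (!igraph::is_dag(g)) return("ontology links contain a cycle")
  }
  TRUE
})

#' Construct an OntologyTable
#'
#' @param child,parent parallel character vectors of term ids; each row says
#'   `child` is a direct child of `parent`.
#' @return an [OntologyTable-class] object; errors if the links are cyclic.
#' @export
OntologyTable <- function(child = character(), parent = character()) {
  child <- as.character(child); parent <- as.character(parent)
  if (length(child) != length(parent)) stop("`child` and `parent` must be parallel")
  lk <- unique(data.frame(child = child, parent = parent,
                          stringsAsFactors = FALSE))
  lk <- lk[order(lk$child, lk$parent), , drop = FALSE]
  rownames(lk) <- NULL
  new("OntologyTable", links = lk)
}

## ---- EnrichedNetwork -------------------------------------------------------

#' PPI network enriched with implicit similarity edges
#'
#' Holds the explicit interaction graph together with, for every protein in
#' the (union) vertex set, its list of implicit neighbours: the up-to-k
#' most sequence-similar proteins, with the similarity scores as edge
#' weights. The two channels are stored separately and never merged; dropping
#' the implicit channel recovers the explicit network exactly.
#'
#' @slot explicit the [ExplicitNetwork-class].
#' @slot implicit named list over all proteins; each element a data.frame
#'   (`neighbor`, `score`) of length <= k, positive scores, sorted by
#'   descending score then ascending neighbour id, never containing the
#'   protein itself.
#' @slot k number of implicit edges requested per protein.
#' @slot proteins sorted union of explicit and similarity protein ids.
#' @seealso [enrichNetwork()]
#' @export
setClass("EnrichedNetwork",
         slots = c(explicit = "ExplicitNetwork", implicit = "list",
                   k = "numeric", proteins = "character"))

setValidity("EnrichedNetwork", function(object) {
  if (length(object@k) != 1L || object@k < 0)
    return("k must be a single non-negative number")
  if (!setequal(names(object@implicit), object@proteins))
    return("implicit lists must cover exactly the protein universe")
  if (!all(object@explicit@proteins %in% object@proteins))
    return("protein universe must contain the explicit vertex set")
  for (x in names(object@implicit)) {
    il <- object@implicit[[x]]
    if (!is.data.frame(il) || !identical(names(il), c("neighbor", "score")))
      return("each implicit list must be a (neighbor, score) data.frame")
    if (nrow(il) > object@k) return("implicit lists must have length <= k")
    if (any(il$score <= 0)) return("implicit scores must be positive")
    if (any(il$neighbor == x)) return("implicit self-edges are not allowed")
    if (nrow(il) > 1L) {
      o <- order(-il$score, il$neighbor)
      if (!identical(o, seq_len(nrow(il))))
        return("implicit lists must be sorted by descending score, ties by id")
    }
  }
  TRUE
})

## ---- GibbsConfig -----------------------------------------------------------

#' Configuration of the Gibbs collective classifier
#'
#' @slot lambda mixing weight in (0,1) for the implicit (sequence) channel;
#'   `1 - lambda` weighs the explicit (interaction) channel.
#' @slot burnIn number of burn-in sweeps B (>= 0) discarded for equilibration.
#' @slot samples number of sampling sweeps S (>= 1) whose per-sweep rankings
#'   are recorded and aggregated.
#' @slot seed integer seed controlling every random draw.
#' @slot updateMode `"hard-sample"` (each query carries one sampled function
#'   per sweep, classical Gibbs) or `"soft"` (neighbours see the full current
#'   distribution; relaxation labelling).
#' @slot fallbackPrior `"frequency"` (empirical term frequency among labelled
#'   proteins) or `"uniform"`, used when a protein has no assigned neighbour
#'   in either channel.
#' @seealso [gibbsConfig()]
#' @export
setClass("GibbsConfig",
         slots = c(lambda = "numeric", burnIn = "integer", samples = "integer",
                   seed = "integer", updateMode = "character",
                   fallbackPrior = "character"))

setValidity("GibbsConfig", function(object) {
  if (length(object@lambda) != 1L || object@lambda <= 0 || object@lambda >= 1)
    return("lambda must lie strictly in (0, 1)")
  if (object@burnIn < 0L) return("burnIn must be >= 0")
  if (object@samples < 1L) return("samples must be >= 1")
  if (!object@updateMode %in% c("hard-sample", "soft"))
    return("updateMode must be 'hard-sample' or 'soft'")
  if (!object@fallbackPrior %in% c("frequency", "uniform"))
    return("fallbackPrior must be 'frequency' or 'uniform'")
  TRUE
})

#' Construct a GibbsConfig
#'
#' Defaults are the recommended operating point: `lambda = 0.3`, 20 burn-in
#' and 100 sampling sweeps.
#'
#' @param lambda implicit-channel mixing weight in (0,1).
#' @param burnIn burn-in sweeps (B).
#' @param samples sampling sweeps (S).
#' @param seed integer random seed.
#' @param updateMode `"hard-sample"` or `"soft"`.
#' @param fallbackPrior `"frequency"` or `"uniform"`.
#' @return a [GibbsConfig-class] object.
#' @examples
#' gibbsConfig(seed = 7)
#' @export
gibbsConfig <- function(lambda = 0.3, burnIn = 20L, samples = 100L, seed = 1L,
                        updateMode = c("hard-sample", "soft"),
                        fallbackPrior = c("frequency", "uniform")) {
  new("GibbsConfig", lambda = as.numeric(lambda),
      burnIn = as.integer(burnIn), samples = as.integer(samples),
      seed = as.integer(seed), updateMode = match.arg(updateMode),
      fallbackPrior = match.arg(fallbackPrior))
}

## ---- FunctionPredictions ---------------------------------------------------

#' Ranked multi-label function predictions
#'
#' For each query protein, all `m` functions of the universe ranked from most
#' to least supported, with a per-rank support fraction in [0,1] (for the
#' Gibbs classifier, the fraction of sampling sweeps electing that function
#' at that rank; for the voting baselines, the normalized vote share).
#'
#' @slot table data.frame with columns `protein`, `rank`, `term`, `support`.
#' @slot fallback character vector of query ids whose prediction is the
#'   fallback prior (no usable neighbour evidence).
#' @slot terms the function universe the ranks are over.
#' @export
setClass("FunctionPredictions",
         slots = c(table = "data.frame", fallback = "character",
                   terms = "character"))

setValidity("FunctionPredictions", function(object) {
  tb <- object@table
  if (!identical(names(tb), c("protein", "rank", "term", "support")))
    return("table must have columns protein, rank, term, support")
  if (nrow(tb)) {
    if (any(tb$support < 0 | tb$support > 1))
      return("support fractions must lie in [0, 1]")
    if (!all(tb$term %in% object@terms))
      return("predicted terms must be in the function universe")
    sp <- split(tb, tb$protein)
    ok <- vapply(sp, function(d)
      identical(sort(d$rank), seq_len(nrow(d))) && !anyDuplicated(d$term),
      logical(1))
    if (!all(ok))
      return("each protein needs ranks 1..m with distinct terms")
  }
  TRUE
})

## ---- RankMetrics -----------------------------------------------------------

#' Rank-wise true/false positive counts
#'
#' At rank i, TP_i counts the queries whose i-th ranked predicted function is
#' among their true functions and FP_i the rest, so TP_i + FP_i equals the
#' number of evaluated queries at every rank. The reported performance is the
#' ratio TP_i / FP_i; it is `Inf` when FP_i = 0 and TP_i > 0, and `NaN` when
#' both counts are zero.
#'
#' @slot table data.frame with columns `rank`, `tp`, `fp`, `ratio`.
#' @slot nQueries number of evaluated queries.
#' @export
setClass("RankMetrics",
         slots = c(table = "data.frame", nQueries = "integer"))

setValidity("RankMetrics", function(object) {
  tb <- object@table
  if (!identical(names(tb), c("rank", "tp", "fp", "ratio")))
    return("table must have columns rank, tp, fp, ratio")
  if (nrow(tb) && any(tb$tp + tb$fp != object@nQueries))
    return("tp + fp must equal the number of queries at every rank")
  TRUE
})

## ---- SparseExperimentReport ------------------------------------------------

#' Report of a sparse-labelling experiment
#'
#' Holds the per-(fraction, repeat, rank) TP/FP ratios of a sparsely-labelled
#' evaluation, the seeds used for the label splits, and a per-fraction
#' mean/sd summary.
#'
#' @slot ratios numeric array `[fraction, repeat, rank]` of TP/FP ratios.
#' @slot seeds integer matrix `[fraction, repeat]` of split seeds.
#' @slot fractions the annotated fractions evaluated (strictly in (0,1)).
#' @slot summary data.frame `fraction`, `rank`, `meanRatio`, `sdRatio`.
#' @export
setClass("SparseExperimentReport",
         slots = c(ratios = "array", seeds = "matrix", fractions = "numeric",
                   summary = "data.frame"))

setValidity("SparseExperimentReport", function(object) {
  if (any(object@fractions <= 0 | object@fractions >= 1))
    return("fractions must lie strictly in (0, 1)")
  if (dim(object@ratios)[1] != length(object@fractions))
    return("ratio array must have one slice per fraction")
  if (!identical(dim(object@seeds), dim(object@ratios)[1:2]))
    return("one seed per (fraction, repeat)")
  TRUE
})

## ---- SynthConfig -----------------------------------------------------------

#' Configuration of the synthetic benchmark generator
#'
#' Parameters of a planted-partition style generator emulating the premise of
#' guilt-by-association: proteins sharing a function interact more often
#' (`pIn` vs `pOut`) and have stochastically higher sequence-similarity
#' scores (`simSignal` vs `simNoise`).
#'
#' @slot nProteins number of proteins.
#' @slot mFunctions number of function terms.
#' @slot labelsPerProtein integer range (min, max) of functions per protein.
#' @slot pIn edge probability for function-sharing pairs.
#' @slot pOut edge probability for non-sharing pairs (`pOut <= pIn`).
#' @slot simSignal mean similarity score for function-sharing pairs.
#' @slot simNoise mean similarity score for non-sharing pairs
#'   (`simNoise <= simSignal`).
#' @slot simDispersion gamma shape of the score distribution; 0 makes the
#'   scores exactly equal to their means.
#' @slot freqDecay geometric decay of the term frequency profile in (0,1];
#'   1 gives uniform term frequencies.
#' @slot seed integer seed.
#' @seealso [synthConfig()]
#' @export
setClass("SynthConfig",
         slots = c(nProteins = "integer", mFunctions = "integer",
                   labelsPerProtein = "integer", pIn = "numeric",
                   pOut = "numeric", simSignal = "numeric",
                   simNoise = "numeric", simDispersion = "numeric",
                   freqDecay = "numeric", seed = "integer"))

setValidity("SynthConfig", function(object) {
  if (object@nProteins < 2L) return("need at least two proteins")
  if (object@mFunctions < 1L) return("need at least one function")
  lp <- object@labelsPerProtein
  if (length(lp) != 2L || lp[1] < 1L || lp[2] < lp[1])
    return("labelsPerProtein must be an increasing range with min >= 1")
  if (lp[2] > object@mFunctions)
    return("labelsPerProtein max cannot exceed the number of functions")
  if (object@pOut < 0 || object@pIn > 1 || object@pOut > object@pIn)
    return("need 0 <= pOut <= pIn <= 1")
  if (object@simNoise < 0 || object@simSignal < object@simNoise)
    return("need simSignal >= simNoise >= 0")
  if (object@simDispersion < 0) return("simDispersion must be >= 0")
  if (object@freqDecay <= 0 || object@freqDecay > 1)
    return("freqDecay must lie in (0, 1]")
  TRUE
})

#' Construct a SynthConfig
#'
#' The defaults are the package's reference benchmark: 200 proteins, 5
#' functions, 1-3 functions per protein with a geometric (0.7) frequency
#' skew, strong topological homophily (`pIn = 0.3` vs `pOut = 0.01`) and a
#' strong similarity signal (gamma scores with mean 50 for function-sharing
#' pairs vs 5 otherwise, shape 2).
#'
#' @param nProteins,mFunctions,labelsPerProtein,pIn,pOut,simSignal,simNoise,simDispersion,freqDecay,seed
#'   see [SynthConfig-class].
#' @return a [SynthConfig-class] object.
#' @examples
#' synthConfig(seed = 7)
#' @export
synthConfig <- function(nProteins = 200L, mFunctions = 5L,
                        labelsPerProtein = c(1L, 3L), pIn = 0.3, pOut = 0.01,
                        simSignal = 50, simNoise = 5, simDispersion = 2,
                        freqDecay = 0.7, seed = 1L) {
  new("SynthConfig", nProteins = as.integer(nProteins),
      mFunctions = as.integer(mFunctions),
      labelsPerProtein = as.integer(labelsPerProtein),
      pIn = as.numeric(pIn), pOut = as.numeric(pOut),
      simSignal = as.numeric(simSignal), simNoise = as.numeric(simNoise),
      simDispersion = as.numeric(simDispersion),
      freqDecay = as.numeric(freqDecay), seed = as.integer(seed))
}
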
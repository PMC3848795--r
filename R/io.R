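## Readers/writers for the standard flat-file inputs and outputs, plus the
## informative-term annotation filter and the restrict-to-common step.

.split_fields <- function(lines) strsplit(trimws(lines), "[ \t]+")

#' Read a PPI edge list
#'
#' Parses a whitespace/tab separated edge list with two columns
#' (`protein_a protein_b`) or three (`... weight`). Self-loops are dropped
#' with a warning and duplicate records for an unordered pair are merged by
#' maximum weight; both events are reported with a message.
#'
#' @param path path to the edge-list file.
#' @param hasWeights logical; `NA` (default) infers the presence of a weight
#'   column from the first data row.
#' @return an [ExplicitNetwork-class]; unweighted input gets weight 1.0.
#' @export
readEdgeList <- function(path, hasWeights = NA) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- .split_fields(lines[keep])
  if (!length(fields))
    return(ExplicitNetwork())
  nf <- lengths(fields)
  if (is.na(hasWeights)) hasWeights <- nf[1] == 3L
  want <- if (hasWeights) 3L else 2L
  bad <- which(nf != want)
  if (length(bad))
    stop(sprintf("malformed edge row at line %d: expected %d fields, got %d",
                 lineno[bad[1]], want, nf[bad[1]]))
  from <- vapply(fields, `[`, "", 1L)
  to <- vapply(fields, `[`, "", 2L)
  if (hasWeights) {
    weight <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    if (anyNA(weight))
      stop(sprintf("non-numeric weight at line %d", lineno[which(is.na(weight))[1]]))
    if (any(weight <= 0))
      stop(sprintf("non-positive weight at line %d", lineno[which(weight <= 0)[1]]))
  } else weight <- rep(1, length(from))
  nself <- sum(from == to)
  net <- withCallingHandlers(
    ExplicitNetwork(from, to, weight),
    warning = function(w) invokeRestart("muffleWarning"))
  if (nself)
    warning(sprintf("%d self-loop(s) dropped", nself))
  ndup <- length(from) - nself - nrow(net@edges)
  message(sprintf("read %d edges (%d duplicate record(s) merged, %d self-loop(s) dropped)",
                  nrow(net@edges), ndup, nself))
  net
}

#' Read pairwise sequence-similarity scores
#'
#' Two dialects are supported: `"blast6"`, the 12-column BLAST tabular
#' output (`-outfmt 6`), taking the query and subject ids from columns 1-2
#' and the bit score from column 12; and `"tsv3"`, a plain
#' `query subject score` table. Self-pairs are stored as score zero (i.e.
#' dropped) and duplicate (query, subject) records -- such as multiple HSPs
#' -- collapse to their maximum score.
#'
#' @param path path to the score file.
#' @param dialect `"tsv3"` or `"blast6"`.
#' @return a [SimilarityTable-class]; an empty file yields an empty table.
#' @export
readSimilarity <- function(path, dialect = c("tsv3", "blast6")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- .split_fields(lines[keep])
  if (!length(fields))
    return(SimilarityTable())
  nf <- lengths(fields)
  want <- if (dialect == "blast6") 12L else 3L
  scol <- if (dialect == "blast6") 12L else 3L
  bad <- which(nf != want)
  if (length(bad))
    stop(sprintf("malformed %s row at line %d: expected %d fields, got %d",
                 dialect, lineno[bad[1]], want, nf[bad[1]]))
  query <- vapply(fields, `[`, "", 1L)
  subject <- vapply(fields, `[`, "", 2L)
  score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", scol)))
  if (anyNA(score))
    stop(sprintf("non-numeric score at line %d", lineno[which(is.na(score))[1]]))
  if (any(score < 0))
    stop(sprintf("negative score at line %d", lineno[which(score < 0)[1]]))
  SimilarityTable(query, subject, score)
}

#' Read protein function annotations
#'
#' Parses a two-column `protein term` table, one annotation per row;
#' duplicated rows deduplicate silently. The function universe `m` is the
#' number of distinct terms seen.
#'
#' @param path path to the annotation file.
#' @return an [AnnotationSet-class].
#' @export
readAnnotations <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- .split_fields(lines[keep])
  if (!length(fields))
    stop("empty annotation file: no functions to predict")
  nf <- lengths(fields)
  bad <- which(nf != 2L)
  if (length(bad))
    stop(sprintf("malformed annotation row at line %d: expected 2 fields, got %d",
                 lineno[bad[1]], nf[bad[1]]))
  AnnotationSet(vapply(fields, `[`, "", 1L), vapply(fields, `[`, "", 2L))
}

#' Read a flat parent-child ontology table
#'
#' Parses a two-column `child parent` table of term links; errors if the
#' links contain a cycle.
#'
#' @param path path to the ontology file.
#' @return an [OntologyTable-class].
#' @export
readOntology <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  fields <- .split_fields(lines[keep])
  if (!length(fields)) return(OntologyTable())
  nf <- lengths(fields)
  if (any(nf != 2L))
    stop("malformed ontology row: expected 2 fields per row")
  OntologyTable(vapply(fields, `[`, "", 1L), vapply(fields, `[`, "", 2L))
}

.ancestor_closure <- function(ont) {
  ## term -> character vector of all ancestors (transitive parents)
  lk <- ont@links
  if (!nrow(lk)) return(list())
  parents <- split(lk$parent, lk$child)
  terms <- unique(c(lk$child, lk$parent))
  anc <- list()
  for (t in terms) {
    seen <- character()
    frontier <- parents[[t]]
    while (length(frontier)) {
      frontier <- setdiff(unique(frontier), seen)
      seen <- c(seen, frontier)
      frontier <- unlist(parents[frontier], use.names = FALSE)
    }
    anc[[t]] <- seen
  }
  anc
}

#' Select informative function terms
#'
#' A term is informative when it is annotated by at least `threshold`
#' proteins and none of its direct child terms reaches that threshold, so
#' the selected terms are specific but still well-populated. Counts use
#' direct annotations only by default; set `propagate = TRUE` to first
#' up-propagate every protein's annotations to all ancestor terms
#' (true-path semantics).
#'
#' @param ann an [AnnotationSet-class].
#' @param ont an [OntologyTable-class], or `NULL` to treat all terms as
#'   leaves.
#' @param threshold minimum number of annotating proteins (default 30).
#' @param propagate up-propagate annotations across the ontology before
#'   counting (default `FALSE`).
#' @return sorted character vector of informative terms.
#' @export
informativeTerms <- function(ann, ont = NULL, threshold = 30,
                             propagate = FALSE) {
  stopifnot(is(ann, "AnnotationSet"))
  if (is.null(ont)) ont <- OntologyTable()
  stopifnot(is(ont, "OntologyTable"))
  sets <- ann@annotations
  if (propagate) {
    anc <- .ancestor_closure(ont)
    sets <- lapply(sets, function(ts)
      unique(c(ts, unlist(anc[ts], use.names = FALSE))))
  }
  counts <- table(unlist(sets, use.names = FALSE))
  eligible <- names(counts)[counts >= threshold]
  lk <- ont@links
  ok <- vapply(eligible, function(t) {
    children <- lk$child[lk$parent == t]
    !any(counts[intersect(children, names(counts))] >= threshold)
  }, logical(1))
  sort(eligible[ok])
}

#' Write and read ranked predictions
#'
#' `writePredictions()` writes a tab-separated table with header
#' `protein rank term support`; `readPredictions()` reads it back (also
#' accepting externally produced predictions for comparison). The pair
#' round-trips losslessly.
#'
#' @param preds a [FunctionPredictions-class].
#' @param path output/input path.
#' @return `writePredictions()` returns `path` invisibly;
#'   `readPredictions()` returns a [FunctionPredictions-class] whose
#'   function universe is the set of terms seen.
#' @export
writePredictions <- function(preds, path) {
  stopifnot(is(preds, "FunctionPredictions"))
  write.table(preds@table, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writePredictions
#' @export
readPredictions <- function(path) {
  tb <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "integer", "character",
                                  "numeric"))
  names(tb) <- c("protein", "rank", "term", "support")
  new("FunctionPredictions", table = tb, fallback = character(),
      terms = sort(unique(tb$term)))
}

#' Restrict inputs to their common protein universe
#'
#' Proteins lacking either interaction data or sequence information are
#' removed: the network and similarity table are cut down to the
#' intersection of their protein sets, and the annotations to annotated
#' proteins inside that intersection. A summary of what was dropped is
#' reported with a message.
#'
#' @param net an [ExplicitNetwork-class].
#' @param sim a [SimilarityTable-class].
#' @param ann an [AnnotationSet-class].
#' @return list with elements `network`, `similarity`, `annotations`,
#'   restricted to the common universe (the annotation term universe is
#'   preserved).
#' @export
restrictToCommon <- function(net, sim, ann) {
  stopifnot(is(net, "ExplicitNetwork"), is(sim, "SimilarityTable"),
            is(ann, "AnnotationSet"))
  common <- intersect(net@proteins, sim@proteins)
  ed <- net@edges
  ed <- ed[ed$protein_a %in% common & ed$protein_b %in% common, , drop = FALSE]
  net2 <- ExplicitNetwork(ed$protein_a, ed$protein_b, ed$weight,
                          proteins = common)
  sc <- sim@scores
  sc <- sc[sc$query %in% common & sc$subject %in% common, , drop = FALSE]
  sim2 <- SimilarityTable(sc$query, sc$subject, sc$score, proteins = common)
  keepAnn <- intersect(names(ann@annotations), common)
  ann2 <- new("AnnotationSet", annotations = ann@annotations[keepAnn],
              terms = ann@terms)
  message(sprintf(paste0("restricted to %d common proteins ",
                         "(dropped %d network-only, %d similarity-only, ",
                         "%d annotated without data)"),
                  length(common), length(setdiff(net@proteins, common)),
                  length(setdiff(sim@proteins, common)),
                  length(setdiff(names(ann@annotations), common))))
  list(network = net2, similarity = sim2, annotations = ann2)
}

#' Cross-check identifiers against a FASTA file
#'
#' Sequences are never aligned by this package (similarity scores are an
#' input); a FASTA file is accepted only to verify that protein identifiers
#' match its record names.
#'
#' @param path path to a FASTA file.
#' @param ids character vector of protein ids to check.
#' @return character vector of ids absent from the FASTA headers (empty when
#'   all are present).
#' @export
checkFastaIds <- function(path, ids) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, ">")]
  fastaIds <- vapply(strsplit(sub("^>", "", hdr), "[ \t]"), `[`, "", 1L)
  setdiff(ids, fastaIds)
}
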
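# Fixture builders shared across test files. All randomized fixtures are
# generated under an explicit seed so failures reproduce.

quiet_enrich <- function(...) suppressMessages(enrichNetwork(...))

# 4-node path A(F1)-B(F1)-C(F2)-D(F2), unit weights, no similarity
path_fixture <- function() {
  list(net = quiet_enrich(
         ExplicitNetwork(c("A", "B", "C"), c("B", "C", "D")),
         SimilarityTable(), k = 0),
       ann = AnnotationSet(c("A", "B", "C", "D"), c("F1", "F1", "F2", "F2")))
}

# the worked weighted-voting example: query X with one implicit neighbour
# M1 {F1} (score 10) and explicit neighbours N1 {F1}, N2 {F2} (unit weights)
vote_fixture <- function() {
  net <- quiet_enrich(ExplicitNetwork(c("X", "X"), c("N1", "N2")),
                      SimilarityTable("X", "M1", 10), k = 1)
  list(net = net,
       labels = list(M1 = "F1", N1 = "F1", N2 = "F2"),
       terms = c("F1", "F2"))
}

# random small two-channel fixture with a labelled/unlabelled split;
# queries always have at least one labelled neighbour unless allow_bare
random_fixture <- function(seed, n = NULL, m = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(6:14, 1)
  if (is.null(m)) m <- sample(2:5, 1)
  prots <- sprintf("P%02d", seq_len(n))
  terms <- sprintf("F%d", seq_len(m))
  # random explicit edges
  pairs <- t(combn(prots, 2))
  keep <- runif(nrow(pairs)) < 0.35
  net <- if (any(keep))
    ExplicitNetwork(pairs[keep, 1], pairs[keep, 2],
                    weight = round(runif(sum(keep), 0.5, 3), 2),
                    proteins = prots)
  else ExplicitNetwork(proteins = prots)
  # random directed similarity scores
  ord <- expand.grid(q = prots, s = prots, stringsAsFactors = FALSE)
  ord <- ord[ord$q != ord$s, ]
  hit <- runif(nrow(ord)) < 0.3
  sim <- SimilarityTable(ord$q[hit], ord$s[hit],
                         round(runif(sum(hit), 1, 40), 1), proteins = prots)
  # random multi-label annotations on a subset
  nlab <- sample(seq(3, n - 2), 1)
  lab <- sort(sample(prots, nlab))
  sets <- lapply(lab, function(p) sort(sample(terms, sample(1:min(3, m), 1))))
  names(sets) <- lab
  ann <- AnnotationSet(sets, terms = terms)
  k <- sample(0:4, 1)
  list(net = quiet_enrich(net, sim, k = k), bare = net, sim = sim,
       ann = ann, queries = setdiff(prots, lab), terms = terms, k = k)
}

# independent explicit-only weighted voting: the reference the k = 0
# ("Origin") configuration must reduce to
explicit_only_vote <- function(net, ann, query, prior) {
  terms <- functionTerms(ann)
  counts <- setNames(numeric(length(terms)), terms)
  el <- explicitNeighbors(net, query)
  for (i in seq_len(nrow(el))) {
    lb <- annotationList(ann)[[el$neighbor[i]]]
    if (!is.null(lb)) counts[lb] <- counts[lb] + el$weight[i]
  }
  if (sum(counts) > 0) counts / sum(counts) else prior
}

# brute-force column-mode-with-exclusion rank aggregation
brute_aggregate <- function(M) {
  m <- ncol(M)
  chosen <- integer(0)
  support <- numeric(0)
  for (r in seq_len(m)) {
    vals <- setdiff(M[, r], chosen)
    if (!length(vals)) {
      pick <- setdiff(seq_len(m), chosen)[1]
      supp <- 0
    } else {
      cnt <- vapply(sort(vals), function(v) sum(M[, r] == v), 0L)
      best <- max(cnt)
      pick <- sort(vals)[which(cnt == best)[1]]
      supp <- best / nrow(M)
    }
    chosen <- c(chosen, pick)
    support <- c(support, supp)
  }
  list(index = chosen, support = support)
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
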
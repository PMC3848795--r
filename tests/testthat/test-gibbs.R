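# Weighted voting, Gibbs sweeps, rank vectors and rank aggregation.

test_that("weighted voting mixes the two channels as specified", {
  fx <- vote_fixture()
  cfg <- gibbsConfig(lambda = 0.5)
  # implicit: F1 gets 10/10; explicit: F1 1/2, F2 1/2 -> 0.75 / 0.25
  p <- weightedVote("X", fx$net, fx$labels, cfg, terms = fx$terms)
  expect_equal(as.numeric(p), c(0.75, 0.25))
  expect_false(attr(p, "fallback"))

  # unanimity across both channels puts all mass on the one function
  p1 <- weightedVote("X", fx$net,
                     list(M1 = "F1", N1 = "F1", N2 = "F1"), cfg,
                     terms = fx$terms)
  expect_equal(as.numeric(p1), c(1, 0))

  # degenerate implicit channel: explicit term renormalized to full weight
  net <- quiet_enrich(ExplicitNetwork("X", "N1", weight = 3),
                      SimilarityTable(), k = 0)
  p2 <- weightedVote("X", net, list(N1 = "F2"), gibbsConfig(lambda = 0.3),
                     terms = c("F1", "F2"))
  expect_equal(as.numeric(p2), c(0, 1))

  # a multi-label neighbour adds its full weight to every function it has
  p3 <- weightedVote("X", net, list(N1 = c("F1", "F2")), gibbsConfig(),
                     terms = c("F1", "F2"))
  expect_equal(as.numeric(p3), c(0.5, 0.5))
})

test_that("weighted voting falls back to the prior when evidence is empty", {
  net <- quiet_enrich(ExplicitNetwork("X", "N1"), SimilarityTable(), k = 0)
  # neighbour unlabelled -> frequency prior over the supplied label state
  p <- weightedVote("X", net, list(Z1 = c("F1", "F1p"), Z2 = "F1"),
                    gibbsConfig(), terms = c("F1", "F1p"))
  expect_true(attr(p, "fallback"))
  expect_equal(as.numeric(p), c(2 / 3, 1 / 3))
  pu <- weightedVote("X", net, list(Z1 = "F1"),
                     gibbsConfig(fallbackPrior = "uniform"),
                     terms = c("F1", "F1p"))
  expect_equal(as.numeric(pu), c(0.5, 0.5))
})

test_that("bootstrap equals per-protein weighted voting on labelled state", {
  for (seed in c(2, 5, 9)) {
    fx <- random_fixture(seed)
    cfg <- gibbsConfig(seed = seed)
    a <- bootstrapDistributions(fx$net, fx$ann, fx$queries, cfg)
    labels <- annotationList(fx$ann)
    for (q in fx$queries) {
      p <- weightedVote(q, fx$net, labels, cfg, terms = fx$terms)
      expect_equal(as.numeric(a[q, ]), as.numeric(p), tolerance = 1e-12)
    }
    expect_true(all(abs(rowSums(a) - 1) < 1e-9))
  }
})

test_that("bootstrap rejects queries that still carry labels", {
  fx <- random_fixture(3)
  lab <- proteins(fx$ann)[1]
  expect_error(bootstrapDistributions(fx$net, fx$ann, lab, gibbsConfig()),
               "hold labels out")
})

test_that("queries with no labelled neighbour bootstrap to the flagged prior", {
  net <- quiet_enrich(ExplicitNetwork(c("Q", "U", "L1"), c("U", "L1", "L2")),
                      SimilarityTable(), k = 0)
  ann <- AnnotationSet(c("L1", "L2"), c("F1", "F2"))
  a <- bootstrapDistributions(net, ann, c("Q", "U"), gibbsConfig())
  expect_true(attr(a, "fallback")[["Q"]])   # only neighbour U is unlabelled
  expect_false(attr(a, "fallback")[["U"]])
  expect_equal(as.numeric(a["U", ]), c(1, 0))  # only labelled neighbour: L1 {F1}
})

test_that("assignment sampling follows the distribution deterministically", {
  expect_equal(replicate(25, sampleAssignment(c(1, 0))), rep(1L, 25))

  set.seed(1)
  draws <- replicate(10000, sampleAssignment(c(0.5, 0.5)))
  expect_gte(mean(draws == 1), 0.47)
  expect_lte(mean(draws == 1), 0.53)

  set.seed(99); d1 <- replicate(50, sampleAssignment(c(0.2, 0.5, 0.3)))
  set.seed(99); d2 <- replicate(50, sampleAssignment(c(0.2, 0.5, 0.3)))
  expect_identical(d1, d2)

  expect_error(sampleAssignment(c(0, 0)), "positive sum")
})

test_that("rank vectors argsort with uniform random tie-breaks", {
  set.seed(1)
  expect_equal(rankVector(c(0.2, 0.5, 0.3)), c(2L, 3L, 1L))
  expect_equal(rankVector(1), 1L)

  set.seed(42)
  first <- replicate(1000, rankVector(c(0.5, 0.5))[1])
  expect_gte(mean(first == 1), 0.45)
  expect_lte(mean(first == 1), 0.55)
})

test_that("rank aggregation takes column modes with exclusion", {
  agg <- aggregateRanks(rbind(c(1, 2), c(1, 2), c(2, 1)))
  expect_equal(agg$index, c(1L, 2L))
  expect_equal(agg$support, c(2 / 3, 2 / 3))

  one <- rbind(c(3L, 1L, 2L))
  expect_equal(aggregateRanks(one)$index, c(3L, 1L, 2L))
  expect_equal(aggregateRanks(one)$support, c(1, 1, 1))

  same <- matrix(rep(c(2L, 3L, 1L), each = 5), nrow = 5)
  expect_equal(aggregateRanks(same)$support, c(1, 1, 1))

  # column-1 tie {1,2} -> smaller index; column 2 excludes it
  tie <- rbind(c(1, 2), c(2, 1))
  expect_equal(aggregateRanks(tie)$index, c(1L, 2L))

  expect_error(aggregateRanks(matrix(integer(), 0, 2)), "non-empty")
})

test_that("rank aggregation matches the brute-force oracle", {
  set.seed(7)
  for (i in 1:100) {
    S <- sample(1:20, 1); m <- sample(1:6, 1)
    M <- t(replicate(S, sample(m), simplify = TRUE))
    if (m == 1) M <- matrix(1L, S, 1)
    expect_equal(aggregateRanks(M), brute_aggregate(M))
  }
})

test_that("unanimous neighbourhoods propagate with full support", {
  # two disconnected labelled cliques; query attached only to clique 1 (F1)
  net <- quiet_enrich(
    ExplicitNetwork(c("A1", "A1", "A2", "B1", "B1", "B2", "Q", "Q"),
                    c("A2", "A3", "A3", "B2", "B3", "B3", "A1", "A2")),
    SimilarityTable(), k = 0)
  ann <- AnnotationSet(c("A1", "A2", "A3", "B1", "B2", "B3"),
                       c("F1", "F1", "F1", "F2", "F2", "F2"))
  pr <- gibbsPredict(net, ann, "Q", gibbsConfig(seed = 5))
  tb <- predictionTable(pr)
  expect_equal(tb$term[tb$rank == 1], "F1")
  expect_equal(tb$support[tb$rank == 1], 1.0)
})

test_that("an isolated query is flagged and ranked by the prior", {
  net <- quiet_enrich(ExplicitNetwork("L1", "L2", proteins = c("L1", "L2", "Q")),
                      SimilarityTable(), k = 0)
  ann <- AnnotationSet(c("L1", "L2", "L2"), c("F1", "F1", "F2"))
  pr <- gibbsPredict(net, ann, "Q", gibbsConfig(seed = 2))
  expect_equal(fallbackQueries(pr), "Q")
  tb <- predictionTable(pr)
  expect_equal(tb$term[tb$rank == 1], "F1")  # frequency prior favours F1
})

test_that("a single hard-sample sweep matches a step-by-step trace", {
  # 5-node fixture: labelled L1 {F1}, L2 {F2}; queries Q1, Q2, Q3
  net <- quiet_enrich(
    ExplicitNetwork(c("Q1", "Q1", "Q2", "Q3", "Q3"),
                    c("L1", "Q2", "L2", "L1", "Q1"),
                    weight = c(2, 1, 1, 1, 2)),
    SimilarityTable(c("Q1", "Q2"), c("L2", "Q3"), c(5, 4)), k = 1)
  ann <- AnnotationSet(c("L1", "L2"), c("F1", "F2"))
  cfg <- gibbsConfig(lambda = 0.4, burnIn = 0L, samples = 1L, seed = 31L)
  pr <- gibbsPredict(net, ann, c("Q1", "Q2", "Q3"), cfg)

  # --- independent trace ------------------------------------------------
  terms <- c("F1", "F2")
  labels0 <- list(L1 = "F1", L2 = "F2")
  qs <- c("Q1", "Q2", "Q3")
  boot <- lapply(qs, function(q)
    as.numeric(weightedVote(q, net, labels0, cfg, terms = terms)))
  names(boot) <- qs
  set.seed(31)
  # sweep: one assignment per query in ascending id order
  assign <- vapply(qs, function(q) sample.int(2, 1, prob = boot[[q]]), 0L)
  state <- c(labels0, lapply(assign, function(i) terms[i]))
  a1 <- lapply(qs, function(q)
    as.numeric(weightedVote(q, net, state, cfg, terms = terms)))
  names(a1) <- qs
  # then one runif(m) tie-break vector per query in ascending id order
  ranks <- lapply(qs, function(q) order(-a1[[q]], runif(2)))
  names(ranks) <- qs
  # S = 1: the final ranking is the single recorded rank vector
  tb <- predictionTable(pr)
  for (q in qs)
    expect_equal(tb$term[tb$protein == q][order(tb$rank[tb$protein == q])],
                 terms[ranks[[q]]])
})

test_that("gibbsPredict is bit-reproducible under a fixed seed", {
  fx <- random_fixture(13)
  cfg <- gibbsConfig(burnIn = 3L, samples = 10L, seed = 77L)
  p1 <- gibbsPredict(fx$net, fx$ann, fx$queries, cfg)
  p2 <- gibbsPredict(fx$net, fx$ann, fx$queries, cfg)
  expect_identical(p1, p2)
  # soft mode runs and is reproducible too
  cfgS <- gibbsConfig(burnIn = 3L, samples = 10L, seed = 77L,
                      updateMode = "soft")
  expect_identical(gibbsPredict(fx$net, fx$ann, fx$queries, cfgS),
                   gibbsPredict(fx$net, fx$ann, fx$queries, cfgS))
})

test_that("lambda extremes reduce the bootstrap to one channel", {
  for (seed in c(4, 8)) {
    fx <- random_fixture(seed)
    labels <- annotationList(fx$ann)
    aLo <- bootstrapDistributions(fx$net, fx$ann, fx$queries,
                                  gibbsConfig(lambda = 1e-6))
    aHi <- bootstrapDistributions(fx$net, fx$ann, fx$queries,
                                  gibbsConfig(lambda = 1 - 1e-6))
    prior <- rep(1 / length(fx$terms), length(fx$terms))
    for (q in fx$queries) {
      # explicit-only reference
      pw <- explicit_only_vote(fx$bare, fx$ann, q, prior)
      # implicit-only reference
      il <- implicitNeighbors(fx$net, q)
      ps <- setNames(numeric(length(fx$terms)), fx$terms)
      for (i in seq_len(nrow(il))) {
        lb <- labels[[il$neighbor[i]]]
        if (!is.null(lb)) ps[lb] <- ps[lb] + il$score[i]
      }
      hasS <- sum(ps) > 0; hasW <- sum(pw) > 0 && sum(abs(pw - prior)) > 0
      if (hasS && hasW) {
        expect_equal(as.numeric(aLo[q, ]), as.numeric(pw), tolerance = 1e-5)
        expect_equal(as.numeric(aHi[q, ]), as.numeric(ps / sum(ps)),
                     tolerance = 1e-5)
      }
    }
  }
})

test_that("the Origin configuration equals explicit-only voting exactly", {
  for (seed in 1:10) {
    fx <- random_fixture(seed)
    enet0 <- quiet_enrich(fx$bare, fx$sim, k = 0)
    cfg <- gibbsConfig(lambda = 0.3, fallbackPrior = "uniform")
    a <- bootstrapDistributions(enet0, fx$ann, fx$queries, cfg)
    prior <- rep(1 / length(fx$terms), length(fx$terms))
    for (q in fx$queries)
      expect_identical(as.numeric(a[q, ]),
                       as.numeric(explicit_only_vote(fx$bare, fx$ann, q,
                                                     prior)))
  }
})

test_that("every distribution normalizes, degenerate channels included", {
  for (seed in 1:25) {
    fx <- random_fixture(seed)
    a <- bootstrapDistributions(fx$net, fx$ann, fx$queries,
                                gibbsConfig(seed = seed))
    expect_true(all(abs(rowSums(a) - 1) < 1e-9))
  }
})
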
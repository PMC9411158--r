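test_that("J-score arithmetic and domain", {
  expect_equal(jscore(2, 3, 3), 0.5)
  for (n in c(1, 4, 9)) expect_equal(jscore(n, n, n), 1)
  expect_equal(jscore(0, 5, 7), 0)
  expect_equal(jscore(0, 0, 0), 0)  # both-empty convention
  expect_error(jscore(4, 3, 5), "exceeds")
})

test_that("pair p-value is the hypergeometric overlap tail", {
  expect_equal(pairPValue(2, 2, 2, 10), 1 / 45)
  expect_equal(pairPValue(0, 3, 4, 100), 1)
  expect_equal(pairPValue(1, 2, 2, 4), 5 / 6)
  expect_equal(pairPValue(0, 0, 5, 50), 1)  # empty profile -> 1
})

test_that("pair p-value agrees with a Monte-Carlo overlap null", {
  set.seed(99)
  for (i in 1:20) {
    Nt <- sample(15:40, 1)
    nd1 <- sample(2:8, 1)
    nd2 <- sample(2:8, 1)
    ns <- sample(0:min(nd1, nd2), 1)
    draws <- 1e5
    hits <- vapply(seq_len(draws), function(j) {
      sum(sample.int(Nt, nd2) <= nd1) >= ns
    }, logical(1))
    phat <- mean(hits)
    se <- sqrt(phat * (1 - phat) / draws)
    expect_lt(abs(pairPValue(ns, nd1, nd2, Nt) - phat), 3 * se + 1e-9)
  }
})

test_that("all-pairs enumeration, symmetry and empty-profile handling", {
  sets <- list(A = c("P1", "P2"), B = c("P2", "P3"), C = character(0))
  res <- allPairs(sets, Nt = 10)
  e <- edgeTable(res)
  expect_equal(nrow(e), 3L)
  expect_true(all(e$diseaseA < e$diseaseB))
  # pair with the empty profile: J = 0, p = 1
  eC <- e[e$diseaseB == "C", ]
  expect_true(all(eC$jScore == 0) && all(eC$p == 1))
  # AB overlap
  eAB <- e[e$diseaseA == "A" & e$diseaseB == "B", ]
  expect_equal(eAB$nShared, 1L)
  expect_equal(eAB$jScore, 1 / 3)
  expect_equal(eAB$p, hyperTailOracle(1, 2, 2, 10), tolerance = 1e-12)
  # invariant under input ordering
  res2 <- allPairs(sets[c("C", "B", "A")], Nt = 10)
  expect_identical(edgeTable(res2), e)
  # two profiles -> one edge; fewer is an error
  expect_equal(nrow(edgeTable(allPairs(sets[1:2], Nt = 10))), 1L)
  expect_error(allPairs(sets[1], Nt = 10), "at least 2")
})

test_that("planted comorbid pairs outrank unplanted ones", {
  fix <- accFixture()
  e <- edgeTable(fix$result)
  truth <- fix$world@truth
  key <- paste(e$diseaseA, e$diseaseB)
  pKey <- paste(truth$plantedPairs$disease_a, truth$plantedPairs$disease_b)
  planted <- key %in% pKey
  expect_gt(min(e$jScore[planted]), stats::median(e$jScore[!planted]))
  # every significant edge shares at least one protein
  expect_true(all(e$nShared[e$significant] >= 1))
})

test_that("gene-set queries rank the matching disease first", {
  fix <- accFixture()
  pr <- fix$profiles
  sets <- moaSets(pr)
  target <- names(sets)[which(lengths(sets) > 0)[1]]
  res <- genesetQuery(sets[[target]], pr)
  e <- edgeTable(res)
  expect_equal(e$diseaseB[1], target)
  expect_equal(e$jScore[1], 1)
  # planted module of a disease recovers that disease in the top 3
  mod <- fix$world@truth$modules[["D05"]]
  eM <- edgeTable(genesetQuery(mod, pr))
  expect_true("D05" %in% eM$diseaseB[1:3])
  # disjoint query: all J 0, all p 1
  other <- setdiff(proteinUniverse(fix$world), unique(unlist(sets)))
  eD <- edgeTable(genesetQuery(other[1:10], pr))
  expect_true(all(eD$jScore == 0) && all(eD$p == 1))
  expect_error(genesetQuery("NOT_A_PROTEIN", pr), "empty intersection")
})

test_that("easy-pair score is the normalised drug-set overlap", {
  expect_equal(easyPairScore(c("a", "b"), c("a", "b")), 1)
  expect_equal(easyPairScore(c("a", "b"), c("c", "d")), 0)
  expect_equal(easyPairScore(paste0("x", 1:4),
                             c("x1", "x2", "x3", paste0("y", 1:6))), 0.5)
  expect_error(easyPairScore(character(0), "a"), "empty")
})

test_that("network metrics on hand-checkable graphs", {
  cfg <- comoaConfig()
  tri <- data.frame(diseaseA = c("A", "A", "B"), diseaseB = c("B", "C", "C"),
                    nShared = 1L, jScore = 0.5, p = 0.001, q = 0.001,
                    significant = TRUE)
  rep1 <- networkReport(tri, jCutoffGrid = c(0, 0.4, 0.6), config = cfg,
                        diseases = c("A", "B", "C"))
  expect_equal(rep1$nodes$closeness, rep(1, 3))
  expect_equal(rep1$nodes$betweenness, rep(0, 3))
  expect_equal(rep1$giantFraction, 1)
  # J cutoff 0.6 removes every edge
  expect_equal(rep1$curve$fraction, c(1, 1, 1 / 3))
  expect_true(all(diff(rep1$curve$fraction) <= 0))

  path <- tri[1:2, ]  # A-B, A-C: a path with A in the middle
  rep2 <- networkReport(path, jCutoffGrid = 0, config = cfg,
                        diseases = c("A", "B", "C"))
  nodes <- rep2$nodes
  expect_equal(nodes$closeness[nodes$disease == "A"], 1)
  expect_equal(nodes$closeness[nodes$disease == "B"], 2 / 3)
  expect_equal(nodes$betweenness[nodes$disease == "A"], 1)
  expect_equal(nodes$degree, c(2L, 1L, 1L))

  # empty graph: all zeros
  none <- tri[tri$q > 1, ]
  rep3 <- networkReport(none, jCutoffGrid = 0, config = cfg,
                        diseases = c("A", "B"))
  expect_equal(rep3$giantFraction, 1 / 2)  # two singletons, giant = 1 node
  expect_equal(rep3$nodes$closeness, c(0, 0))
})

test_that("raising the J cutoff never grows the giant component", {
  fix <- accFixture()
  rep_ <- networkReport(fix$result, jCutoffGrid = seq(0, 0.6, by = 0.1),
                        config = fix$cfg)
  expect_true(all(diff(rep_$curve$fraction) <= 1e-12))
})
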
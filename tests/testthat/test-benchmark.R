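test_that("log relative risk and phi score arithmetic", {
  # independence: n_ab = n_a n_b / n_tot
  expect_equal(logRR(20, 50, 10, 100), 0)
  expect_equal(logRR(10, 10, 10, 100), log(10))
  expect_error(logRR(10, 10, 0, 100), "n_ab = 0")

  expect_equal(phiScore(20, 50, 10, 100), 0)
  expect_equal(phiScore(50, 50, 50, 100), 1)
  expect_equal(phiScore(20, 30, 10, 100), 400 / sqrt(3360000),
               tolerance = 1e-12)
  expect_error(phiScore(0, 10, 0, 100), "degenerate")

  # sign agreement on a modest sweep (the full sweep runs in acceptance)
  set.seed(13)
  for (i in 1:200) {
    n_tot <- sample(50:5000, 1)
    n_a <- sample(1:(n_tot - 1), 1)
    n_b <- sample(1:(n_tot - 1), 1)
    n_ab <- sample(1:min(n_a, n_b), 1)
    expect_equal(sign(phiScore(n_a, n_b, n_ab, n_tot)),
                 sign(logRR(n_a, n_b, n_ab, n_tot)))
  }
})

test_that("AUROC: closed cases and agreement with pROC", {
  expect_equal(aucRoc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(aucRoc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(aucRoc(c(0.9, 0.8, 0.2, 0.1), c(1, 0, 1, 0)), 0.75)
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    s <- round(stats::runif(n), 1)  # coarse scores force ties
    l <- stats::runif(n) < 0.4
    if (!any(l) || all(l)) next
    expect_equal(aucRoc(s, l), aucOracle(s, l), tolerance = 1e-12)
    expect_equal(aucRoc(s, l),
                 as.numeric(pROC::auc(pROC::roc(as.numeric(l), s,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("AUPRC by step-wise summation", {
  expect_equal(aucPr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # hand-summed: prec 1 at rec .5; block at 0.2 adds prec 2/3 * dRec .5
  expect_equal(aucPr(c(0.9, 0.8, 0.2, 0.1), c(1, 0, 1, 0)), 0.5 + 1 / 3,
               tolerance = 1e-12)
  expect_error(aucPr(c(1, 2), c(0, 0)), "positive")
})

test_that("benchmark evaluation: joins, labels, exclusions", {
  cfg <- comoaConfig()
  n <- 12
  ids <- sprintf("D%02d", 1:(n + 1))
  edges <- data.frame(
    diseaseA = ids[1], diseaseB = ids[-1],
    nShared = 5L, jScore = seq(0.9, by = -0.05, length.out = n),
    p = 1e-6, q = c(rep(0.01, 6), rep(0.5, 6)),
    significant = c(rep(TRUE, 6), rep(FALSE, 6)),
    stringsAsFactors = FALSE
  )
  # first six clinically comorbid (RR = 4), last six at independence-ish
  clin <- data.frame(
    disease_a = ids[1], disease_b = ids[-1],
    n_a = 1000, n_b = 1000,
    n_ab = c(rep(40, 6), rep(10, 6))
  )
  b <- evaluateComorbidity(edges, clin, nTot = 1e5, config = cfg)
  expect_equal(b$recall, 100)      # all 6 true positives predicted
  expect_equal(b$precision, 100)
  expect_equal(b$auroc, 1)         # J perfectly ordered with labels
  expect_equal(b$auprc, 1)
  expect_equal(b$n_pairs_used, 12L)

  # n_ab = 0 rows are excluded with a warning
  clin2 <- clin
  clin2$n_ab[7] <- 0
  clin2 <- rbind(clin2, data.frame(disease_a = ids[1], disease_b = "OTHER",
                                   n_a = 10, n_b = 10, n_ab = 5))
  expect_warning(b2 <- evaluateComorbidity(edges, clin2, 1e5, cfg),
                 "n_ab = 0")
  expect_equal(b2$n_pairs_used, 11L)  # 12 - zero row; OTHER never joins

  # easy pairs: only near-identical efficacious drug sets are excluded
  eff <- stats::setNames(lapply(seq_len(n + 1), function(i) {
    paste0("d", i, "_", 1:5)  # pairwise disjoint: overlap 0
  }), ids)
  eff[[ids[2]]] <- eff[[ids[1]]]  # pair (D01, D02) overlap 1 > 0.9
  b3 <- evaluateComorbidity(edges, clin, 1e5, cfg, effDrugs = eff)
  expect_equal(b3$n_excluded_easy, 1L)
  expect_equal(b3$n_pairs_used, 11L)
  expect_error(evaluateComorbidity(edges, clin[1:3, ], 1e5, cfg),
               "fewer than 10")
  expect_error(
    evaluateComorbidity(edges, data.frame(disease_a = "ZZ", disease_b = "YY",
                                          n_a = 1, n_b = 1, n_ab = 1),
                        1e5, cfg),
    "no overlapping pairs"
  )
})

test_that("drug permutations are seeded bijections preserving multisets", {
  tm <- list(d1 = c("P1", "P2"), d2 = "P3", d3 = character(0), d4 = "P1")
  p1 <- permuteDrugProtein(tm, 7)
  p2 <- permuteDrugProtein(tm, 7)
  expect_identical(p1, p2)                       # same seed, same result
  expect_identical(names(p1), names(tm))
  expect_setequal(unname(sapply(p1, paste, collapse = ",")),
                  unname(sapply(tm, paste, collapse = ",")))
  # 2-drug map: both identity and swap occur across seeds
  tm2 <- list(a = "P1", b = "P2")
  outcomes <- vapply(1:20, function(s) {
    permuteDrugProtein(tm2, s)$a
  }, character(1))
  expect_setequal(unique(outcomes), c("P1", "P2"))

  m <- matrix(1:12, 4, 3, dimnames = list(paste0("d", 1:4), paste0("D", 1:3)))
  q1 <- permuteDrugDisease(m, 11)
  expect_identical(q1, permuteDrugDisease(m, 11))
  expect_identical(rownames(q1), rownames(m))
  expect_setequal(unname(apply(q1, 1, paste, collapse = ",")),
                  unname(apply(m, 1, paste, collapse = ",")))
  expect_error(permuteDrugDisease(m[1, , drop = FALSE], 1), "at least 2")
})

test_that("permutation summaries report z against the null distribution", {
  w <- generateWorld(worldParams(n_drugs = 60L, n_proteins = 150L,
                                 n_diseases = 8L, module_size = 10L,
                                 targets_per_drug = 10L,
                                 n_planted_pairs = 2L), seed = 2L)
  cfg <- comoaConfig(n_permutations = 5L, rng_seed = 2L)
  ps <- permutationTest(w, cfg, which = "drug_disease")
  expect_setequal(ps$metric, c("cc_logRR", "cc_phi", "recall", "precision",
                               "auroc", "auprc"))
  ok <- !is.na(ps$z)
  expect_equal(ps$z[ok], (ps$observed[ok] - ps$nullMean[ok]) / ps$nullSd[ok],
               tolerance = 1e-12)
  expect_equal(ps$p[ok], normalRightTail(ps$z[ok]), tolerance = 1e-12)
  expect_true(all(ps$nDefined <= 5))
  # deterministic given the seed
  ps2 <- permutationTest(w, cfg, which = "drug_disease")
  expect_identical(ps, ps2)
})
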
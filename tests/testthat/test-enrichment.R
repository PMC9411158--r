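# Build a focal disease "F" with a hand-specified comorbidity ranking and
# per-partner MOA p-values, bypassing inference.
makeEnrichScenario <- function(nPartners, shared) {
  # shared: named list partner -> named numeric vector protein -> p
  partners <- sprintf("C%03d", seq_len(nPartners))
  universe <- c("T1", "T2", "T3", sprintf("U%02d", 1:20))
  sets <- c(list(F = c("T1", "T2")),
            stats::setNames(lapply(partners, function(pt) {
              names(shared[[pt]]) %||% character(0)
            }), partners))
  assoc <- do.call(rbind, lapply(partners, function(pt) {
    pv <- shared[[pt]]
    if (is.null(pv)) return(NULL)
    data.frame(disease = pt, protein = names(pv), n1t = 1L, n2t = 0L,
               rr = Inf, p = unname(pv), q = unname(pv),
               passedTissueFilter = TRUE, stringsAsFactors = FALSE)
  }))
  if (is.null(assoc)) assoc <- comoa:::emptyAssociationTable()
  profiles <- moaProfileSet(sets, universe, associations = assoc)
  edges <- data.frame(
    diseaseA = "F", diseaseB = partners, nShared = 1L, jScore = 0.5,
    p = seq_len(nPartners) * 1e-6, q = seq_len(nPartners) * 1e-5,
    significant = TRUE, stringsAsFactors = FALSE
  )
  result <- new("ComorbidityResult", edges = edges,
                diseases = c("F", partners), universeSize = 23L)
  list(profiles = profiles, result = result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("enrichment weight: natural log, saturation, monotonicity", {
  expect_equal(comoaWeight(1, 0.025), 0)
  expect_equal(comoaWeight(exp(-20), 0.025), 0.5)
  expect_equal(comoaWeight(exp(-40), 0.025), 1)
  expect_equal(comoaWeight(0, 0.025), 1)  # clamped below the floor
  p <- sort(stats::runif(50))
  w <- comoaWeight(p, 0.025)
  expect_true(all(diff(w) <= 0))
  expect_true(all(w >= 0 & w <= 1))
})

test_that("score-to-p uses the unnormalized weight", {
  expect_equal(scoreToP(1, 0.025), exp(-40))
  expect_equal(signif(scoreToP(1, 0.025), 2), 4.2e-18)
  expect_equal(scoreToP(0, 0.025), 1)
  expect_equal(scoreToP(0.5, 0.025), exp(-20))
  # round trip through a single sub-saturation contribution
  p <- exp(-stats::runif(100, 0, 40))
  w <- comoaWeight(p, 0.025)
  sub <- w < 1
  expect_equal(scoreToP(w[sub], 0.025), p[sub], tolerance = 1e-10)
})

test_that("comorbidity enrichment: pooled weighted frequency", {
  # k = 1, one shared protein at the saturated weight -> score 1
  sc1 <- makeEnrichScenario(1, list(C001 = c(T1 = exp(-40))))
  e1 <- comoaEnrich("F", sc1$result, sc1$profiles, comoaConfig())
  expect_equal(e1$score[e1$protein == "T1"], 1)
  expect_equal(e1$impliedP[e1$protein == "T1"], exp(-40))
  expect_true(e1$enriched[e1$protein == "T1"])
  # protein shared by no comorbidity -> score 0
  expect_equal(e1$score[e1$protein == "T2"], 0)
  expect_equal(e1$impliedP[e1$protein == "T2"], 1)

  # k = 100, one saturated contribution -> score exactly at the 0.01 cutoff
  sc2 <- makeEnrichScenario(100, list(C001 = c(T1 = exp(-40))))
  e2 <- comoaEnrich("F", sc2$result, sc2$profiles, comoaConfig())
  expect_equal(e2$score[e2$protein == "T1"], 0.01)
  expect_false(e2$enriched[e2$protein == "T1"])  # cutoff is strict
  expect_equal(attr(e2, "kUsed"), 100L)

  # scores always in [0, 1]; total weight bounded by k
  sc3 <- makeEnrichScenario(4, list(
    C001 = c(T1 = exp(-40), T2 = 1e-3),
    C002 = c(T1 = 1e-9), C003 = c(T1 = exp(-50))
  ))
  e3 <- comoaEnrich("F", sc3$result, sc3$profiles, comoaConfig())
  expect_true(all(e3$score >= 0 & e3$score <= 1))
  expect_true(all(e3$totalWeight <= attr(e3, "kUsed")))
  expect_equal(e3$totalWeight[e3$protein == "T1"],
               1 + comoaWeight(1e-9, 0.025) + 1, tolerance = 1e-12)

  # removing a contributing comorbidity (k held fixed via top_k) never
  # increases any protein's total weight
  cfg3 <- comoaConfig(top_k_comorbid = 3)
  full <- comoaEnrich("F", sc3$result, sc3$profiles, cfg3)
  dropped <- sc3
  dropped$result@edges <- sc3$result@edges[-2, ]  # drop C002 from the top 3
  less <- comoaEnrich("F", dropped$result, dropped$profiles, cfg3)
  m <- match(full$protein, less$protein)
  expect_true(all(less$totalWeight[m] <= full$totalWeight + 1e-12))

  # no significant comorbidity -> empty result with a warning
  sc4 <- makeEnrichScenario(2, list())
  sc4$result@edges$significant <- FALSE
  expect_warning(e4 <- comoaEnrich("F", sc4$result, sc4$profiles,
                                   comoaConfig()), "no significant")
  expect_equal(nrow(e4), 0L)
})

test_that("pathway over-representation over the universe", {
  universe <- sprintf("G%02d", 1:10)
  coll <- list(hit = c("G01", "G03"), miss = c("G09", "G10"))
  attr(coll, "descriptions") <- c(hit = "h", miss = "m")
  res <- pathwayOra(c("G01", "G02"), coll, universe)
  expect_equal(res$p[res$pathway == "hit"], 17 / 45, tolerance = 1e-12)
  expect_equal(res$p[res$pathway == "miss"], 1)
  expect_equal(res$pathway[1], "hit")  # sorted by p
  # a pathway identical to the query is minimal in a larger collection
  coll2 <- c(coll, list(exact = c("G01", "G02")))
  res2 <- pathwayOra(c("G01", "G02"), coll2, universe)
  expect_equal(res2$pathway[1], "exact")
  expect_equal(res2$p[1], 1 / choose(10, 2), tolerance = 1e-12)
  expect_error(pathwayOra(character(0), coll, universe), "empty query")
  expect_equal(nrow(pathwayOra("G01", list(), universe)), 0L)
})

test_that("planted modules dominate pathway rankings on the synthetic world", {
  fix <- accFixture()
  w <- fix$world
  d <- "D03"
  enr <- comoaEnrich(d, fix$result, fix$profiles, fix$cfg)
  top <- head(enr$protein[enr$enriched], 100)
  expect_gt(length(top), 0)
  ora <- pathwayOra(top, w@gmt, proteinUniverse(w))
  ranks <- truthEval(w, pathways = ora)$pathwayRanks
  expect_lt(ranks[[d]], 10)  # own module among the top pathways
})
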
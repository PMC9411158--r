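test_that("score standardisation uses the population sd", {
  z <- standardizeScores(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  # idempotent on an already standardised vector
  expect_equal(standardizeScores(z), z, tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_error(standardizeScores(c(5, 5, 5)), "zero variance")
})

test_that("drug partition is boundary-inclusive at the z cutoff", {
  z <- c(drug1 = 2.0, drug2 = 1.65, drug3 = 1.0)
  part <- partitionDrugs(z, 1.65)
  expect_setequal(part$efficacious, c("drug1", "drug2"))
  expect_setequal(part$rest, "drug3")
  expect_length(partitionDrugs(z, 5)$efficacious, 0)
  expect_length(partitionDrugs(z, -5)$rest, 0)
})

test_that("relative risk follows the zero and infinity conventions", {
  expect_equal(relativeRisk(0, 100, 0, 1995), 0)
  expect_equal(relativeRisk(10, 100, 20, 1995), (10 / 100) / (20 / 1995))
  expect_identical(relativeRisk(5, 100, 0, 1995), Inf)
  expect_error(relativeRisk(1, 0, 1, 10), "N1 = 0")
})

test_that("association p-values agree with the enumeration oracle", {
  expect_equal(moaPValue(2, 2, 0, 8), 1 / 45)
  expect_equal(moaPValue(0, 2, 2, 8), 1)
  expect_equal(moaPValue(1, 2, 1, 8), hyperTailOracle(1, 2, 2, 10))
  set.seed(5)
  for (i in 1:50) {
    N1 <- sample(2:10, 1); N2 <- sample(2:20, 1)
    n1t <- sample(0:N1, 1); n2t <- sample(0:N2, 1)
    expect_equal(moaPValue(n1t, N1, n2t, N2),
                 hyperTailOracle(n1t, n1t + n2t, N1, N1 + N2),
                 tolerance = 1e-12)
  }
})

test_that("tissue filter removes only uniformly-not-detected proteins", {
  expr <- data.frame(
    protein = c("A", "A", "B", "B", "B", "C", "C", "D"),
    tissue = c("t1", "t2", "t1", "t2", "t3", "t1", "t2", "t9"),
    level = c("high", "not detected", rep("not detected", 3),
              "not detected", "not detected", "not detected"),
    reliability = c("approved", "approved", "approved", "approved",
                    "approved", "approved", "uncertain", "approved"),
    stringsAsFactors = FALSE
  )
  cand <- c("A", "B", "C", "D", "E")
  got <- tissueFilter(cand, expr, c("t1", "t2", "t3"))
  expect_true("A" %in% got)        # one detected record -> retained
  expect_false("B" %in% got)       # not detected everywhere, none uncertain
  expect_true("C" %in% got)        # an uncertain record blocks removal
  expect_true("D" %in% got)        # only tested in unrelated tissue
  expect_true("E" %in% got)        # untested anywhere
  # empty tissue set is a no-op; filtering never adds proteins
  expect_identical(tissueFilter(cand, expr, character(0)), cand)
  expect_true(all(got %in% cand))
})

test_that("profile inference on a hand-built world", {
  w <- tinyWorld()
  pr <- inferMoaProfiles(w, comoaConfig())
  # disease X: d1, d2 efficacious (z >= 1.65); P1 bound by both
  a <- associations(pr)
  aX <- a[a$disease == "X", ]
  expect_equal(aX$n1t[aX$protein == "P1"], 2L)
  expect_equal(aX$n2t[aX$protein == "P1"], 0L)
  expect_equal(aX$p[aX$protein == "P1"],
               hyperTailOracle(2, 2, 2, 10), tolerance = 1e-12)
  expect_identical(moaSets(pr)$X, "P1")        # p = 1/45, the only call
  expect_setequal(effDrugs(pr)$X, c("d1", "d2"))
  # deterministic: same inputs -> identical output
  pr2 <- inferMoaProfiles(w, comoaConfig())
  expect_identical(associations(pr), associations(pr2))
  expect_identical(moaSets(pr), moaSets(pr2))
  # rr > 1 iff n1t/N1 > n2t/N2 over all associations
  N1 <- unname(lengths(effDrugs(pr))[a$disease])
  N2 <- nrow(scoreMatrix(w)) - N1
  expect_equal(a$rr > 1, (a$n1t / N1) > (a$n2t / N2))
})

test_that("a world where no drug binds anything gives empty profiles", {
  w <- tinyWorld()
  w@targets <- lapply(w@targets, function(x) character(0))
  pr <- inferMoaProfiles(w, comoaConfig())
  expect_true(all(lengths(moaSets(pr)) == 0))
  expect_equal(nrow(associations(pr)), 0L)
})

test_that("zero-variance indications yield empty profiles with a warning", {
  w <- tinyWorld()
  w@scores[, "Y"] <- 1
  expect_warning(pr <- inferMoaProfiles(w, comoaConfig()), "zero score variance")
  expect_length(moaSets(pr)$Y, 0)
  expect_gt(length(moaSets(pr)$X), 0)
})
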
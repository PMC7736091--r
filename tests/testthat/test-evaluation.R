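refTabs <- referenceCohortTables()

test_that("confusionTable counts exactly and validates labels", {
  ref <- c("a", "a", "b", "b", "b")
  pred <- c("a", "b", "b", "b", "a")
  ct <- confusionTable(ref, pred, classes = c("a", "b"))
  expect_equal(counts(ct), matrix(c(1L, 1L, 1L, 2L), 2, 2,
    dimnames = list(reference = c("a", "b"), predicted = c("a", "b"))))
  expect_equal(tableN(ct), 5)

  perfect <- confusionTable(ref, ref, classes = c("a", "b"))
  expect_equal(sum(counts(perfect)) , sum(diag(counts(perfect))))

  expect_error(confusionTable(character(0), character(0)),
    class = "hipmorph_input")
  expect_error(confusionTable(c("a", "z"), c("a", "a"), classes = c("a", "b")),
    class = "hipmorph_input")
})

test_that("reference cohort tables reproduce their published marginals", {
  tn <- counts(refTabs$tonnis)
  expect_equal(rowSums(tn), c(normal = 163, dysplasia = 85))
  expect_equal(colSums(tn), c(normal = 174, dysplasia = 74))
  expect_equal(tableN(refTabs$tonnis), 248)
  expect_equal(tableN(refTabs$sharp), 248)
  expect_equal(tableN(refTabs$ce3), 248)
  expect_equal(tableN(refTabs$ce2), 248)
})

test_that("diagnostic metrics are exact count ratios", {
  m <- diagnosticMetrics(refTabs$tonnis, positive = "dysplasia")
  expect_equal(m$accuracy, 221 / 248)
  expect_equal(m$sensitivity, 66 / 85)
  expect_equal(m$specificity, 155 / 163)
  expect_equal(m$fpr, 8 / 163)

  allCorrect <- confusionTableFromCounts(rbind(n = c(50, 0), d = c(0, 30)),
    classes = c("n", "d"))
  m2 <- diagnosticMetrics(allCorrect, positive = "d")
  expect_equal(unlist(m2), c(accuracy = 1, sensitivity = 1, specificity = 1,
    fpr = 0))

  noPos <- confusionTableFromCounts(rbind(n = c(50, 0), d = c(0, 0)),
    classes = c("n", "d"))
  err <- tryCatch(diagnosticMetrics(noPos, positive = "d"),
    error = function(e) e)
  expect_s3_class(err, "hipmorph_undefined_metric")
  expect_match(conditionMessage(err), "sensitivity")

  expect_equal(asPercent(66 / 85), 77.6)
})

test_that("multiclass accuracy and per-class recall are trace ratios", {
  expect_equal(multiclassAccuracy(refTabs$ce3), 204 / 248)
  expect_equal(classRecall(refTabs$ce3, "borderline"), 27 / 47)
  ident <- confusionTableFromCounts(diag(c(3L, 4L, 5L)),
    classes = c("a", "b", "c"))
  expect_equal(multiclassAccuracy(ident), 1)
})

test_that("Cohen's kappa matches the closed form and its edge cases", {
  expect_equal(cohenKappa(refTabs$sharp),
    (231 / 248 - (213 * 212 + 35 * 36) / 248^2) /
      (1 - (213 * 212 + 35 * 36) / 248^2))
  expect_equal(round(cohenKappa(refTabs$sharp), 3), 0.721)

  perfect <- confusionTableFromCounts(diag(c(10L, 20L)), classes = c("a", "b"))
  expect_equal(cohenKappa(perfect), 1)

  # independence: counts proportional to the outer product of margins
  indep <- confusionTableFromCounts(outer(c(40L, 60L), c(30L, 70L)) / 100,
    classes = c("a", "b"))
  expect_equal(cohenKappa(indep), 0, tolerance = 1e-12)
})

test_that("exact McNemar reproduces the binomial tail oracle", {
  # oracle: two-sided exact binomial, 2 * sum_{k<=8} C(27,k) / 2^27
  oracle <- 2 * sum(choose(27, 0:8)) / 2^27
  m <- mcnemarTest(refTabs$tonnis)
  expect_equal(m$p, oracle, tolerance = 1e-12)
  expect_equal(m$b, 8); expect_equal(m$c, 19)

  m6 <- mcnemarTest(refTabs$ce2)
  expect_equal(m6$p, 2 * sum(choose(26, 0:6)) / 2^26, tolerance = 1e-12)

  # symmetry in the discordant counts and under transposition
  bal <- confusionTableFromCounts(rbind(a = c(5, 7), b = c(7, 9)),
    classes = c("a", "b"))
  expect_equal(mcnemarTest(bal)$p, 1)
  expect_equal(mcnemarTest(t(counts(refTabs$tonnis)))$p,
    mcnemarTest(refTabs$tonnis)$p)

  none <- confusionTableFromCounts(rbind(a = c(5, 0), b = c(0, 9)),
    classes = c("a", "b"))
  res <- mcnemarTest(none)
  expect_equal(res$p, 1)
  expect_match(res$note, "vacuous")
})

test_that("continuity-corrected McNemar matches the stats implementation", {
  m <- mcnemarTest(refTabs$tonnis, method = "chisq")
  ref <- stats::mcnemar.test(counts(refTabs$tonnis), correct = TRUE)
  expect_equal(m$statistic, unname(ref$statistic))
  expect_equal(m$p, ref$p.value)
})

test_that("Bowker symmetry test matches hand arithmetic and drops empty pairs", {
  b <- bowkerTest(refTabs$ce3)
  expect_equal(b$statistic, 2^2 / 2 + 12^2 / 24 + 10^2 / 18, tolerance = 1e-12)
  expect_equal(b$df, 3L)
  expect_equal(b$p, pchisq(b$statistic, 3, lower.tail = FALSE))

  sym <- confusionTableFromCounts(rbind(c(5, 2, 3), c(2, 6, 1), c(3, 1, 7)),
    classes = c("a", "b", "c"))
  bs <- bowkerTest(sym)
  expect_equal(bs$statistic, 0)
  expect_equal(bs$p, 1)

  # an off-diagonal pair with zero sum drops a degree of freedom
  holey <- confusionTableFromCounts(rbind(c(5, 0, 3), c(0, 6, 1), c(4, 2, 7)),
    classes = c("a", "b", "c"))
  expect_equal(bowkerTest(holey)$df, 2L)

  # cross-check against the stats implementation on all-positive pairs
  set.seed(61)
  cnt <- matrix(rpois(9, 10) + 1L, 3, 3)
  mine <- bowkerTest(confusionTableFromCounts(cnt, classes = c("a", "b", "c")))
  ref <- stats::mcnemar.test(cnt, correct = FALSE)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)

  # a 2 x 2 input delegates to the exact McNemar test
  expect_equal(bowkerTest(refTabs$tonnis)$p, mcnemarTest(refTabs$tonnis)$p)
})

test_that("Pearson correlation wraps the t-test and flags degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearsonR(x, x)$r, 1)
  expect_equal(pearsonR(x, -x)$r, -1)
  expect_error(pearsonR(x, rep(1, 5)), class = "hipmorph_undefined_metric")
  expect_error(pearsonR(1:2, 1:2), class = "hipmorph_input")
})

test_that("Cronbach's alpha behaves across agreement regimes", {
  set.seed(71)
  m1 <- rnorm(200, 40, 5)
  expect_equal(cronbachAlpha(m1, m1), 1)
  expect_gt(cronbachAlpha(m1, m1 + rnorm(200, 0, 0.5)), 0.95)
  expect_lt(abs(cronbachAlpha(m1, rnorm(200, 40, 5))), 0.3)
})
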
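test_that("concordance classification follows the overlap rules", {
  expect_identical(classifyConcordance("left:temporal", "left:temporal"),
                   "concordant")
  expect_identical(
    classifyConcordance("right:frontal",
                        c("right:frontal", "right:occipital")),
    "partially_concordant")
  expect_identical(classifyConcordance("left:frontal", "left:temporal"),
                   "discordant")
  # no hyperperfusion seen at all
  expect_identical(classifyConcordance(character(), "left:temporal"),
                   "discordant")
  # extra predicted areas do not spoil concordance
  expect_identical(
    classifyConcordance(c("left:temporal", "right:parietal"), "left:temporal"),
    "concordant")
  expect_error(classifyConcordance("left:temporal", character()), "non-empty")
})

test_that("concordance classification is permutation invariant", {
  set.seed(71)
  pool <- c("left:temporal", "right:temporal", "left:frontal",
            "right:occipital", "left:insular")
  for (i in 1:25) {
    p <- sample(pool, sample(0:4, 1))
    r <- sample(pool, sample(1:3, 1))
    base <- classifyConcordance(p, r)
    expect_identical(classifyConcordance(sample(p), sample(r)), base)
    # covering the full reference always yields concordance
    expect_identical(classifyConcordance(c(p, r), r), "concordant")
  }
})

test_that("the packaged study table loads and validates", {
  tab <- studyTableFixture()
  expect_identical(nrow(tab), 23L)
  expect_identical(anyDuplicated(tab$patient_id), 0L)
  expect_true(all(lengths(tab$ez_lobes) >= 1))
  # multifocal patients carry more than one lobe
  expect_identical(sum(lengths(tab$ez_lobes) > 1), 3L)
  expect_identical(sum(is.na(tab$injection_time_s)), 1L)
  expect_identical(sum(tab$operated), 6L)
})

test_that("summarizeTable reproduces the per-method label breakdown", {
  tab <- studyTableFixture()

  s <- summarizeTable(tab, "siscom")
  expect_identical(s$n[s$label == "concordant"], 18L)
  expect_identical(s$n[s$label == "discordant"], 4L)
  expect_identical(s$n[s$label == "partially_concordant"], 1L)
  expect_equal(s$pct[s$label == "concordant"], 78.3)
  expect_equal(s$pct[s$label == "discordant"], 17.4)
  expect_equal(s$pct[s$label == "partially_concordant"], 4.3)
  expect_equal(sum(s$pct), 100)

  v <- summarizeTable(tab, "visual")
  expect_identical(v$n[v$label == "concordant"], 13L)
  expect_identical(v$n[v$label == "discordant"], 7L)
  expect_identical(v$n[v$label == "partially_concordant"], 3L)
  expect_equal(v$pct[v$label == "concordant"], 56.5)
  expect_equal(v$pct[v$label == "discordant"], 30.4)
  expect_equal(v$pct[v$label == "partially_concordant"], 13.1)

  one <- tab[5, ]
  s1 <- summarizeTable(one, "visual")
  expect_equal(s1$pct[s1$label == "concordant"], 100)
})

test_that("Cohen's kappa matches closed form and an independent package", {
  expect_equal(cohenKappa(c("a", "b", "a"), c("a", "b", "a")), 1)

  # 2x2 table (20, 5; 10, 15): p_o = 0.7, p_e = 0.5, kappa = 0.40
  a <- rep(c("x", "x", "y", "y"), c(20, 5, 10, 15))
  b <- rep(c("x", "y", "x", "y"), c(20, 5, 10, 15))
  expect_equal(cohenKappa(a, b), 0.40)

  skip_if_not_installed("e1071")
  set.seed(72)
  for (i in 1:10) {
    la <- sample(c("p", "q", "r"), 40, replace = TRUE)
    lb <- sample(c("p", "q", "r"), 40, replace = TRUE)
    lev <- sort(unique(c(la, lb)))
    tabm <- table(factor(la, lev), factor(lb, lev))
    expect_equal(cohenKappa(la, lb), e1071::classAgreement(tabm)$kappa,
                 tolerance = 1e-12)
  }
})

test_that("kappa properties: bounded, degenerate cases handled", {
  set.seed(73)
  for (i in 1:20) {
    la <- sample(c("p", "q"), 30, replace = TRUE)
    lb <- sample(c("p", "q"), 30, replace = TRUE)
    k <- cohenKappa(la, lb)
    expect_gte(k, -1); expect_lte(k, 1)
  }
  expect_equal(cohenKappa(rep("a", 5), rep("a", 5)), 1)
  expect_error(cohenKappa(c("a", "a"), c("a", "b", "b")), "equal length")

  # marginal-matched permutations: kappa ~ 0 in expectation
  set.seed(74)
  la <- rep(c("p", "q"), c(12, 18))
  ks <- replicate(400, cohenKappa(la, sample(la)))
  expect_lt(abs(mean(ks)), 0.05)
})

test_that("McNemar variants match hand computation and stats::mcnemar.test", {
  expect_equal(mcnemarTest(4, 4, "exact")$p.value, 1)
  expect_equal(mcnemarTest(7, 2, "exact")$p.value, 92 / 512)
  expect_equal(mcnemarTest(7, 2, "chi2")$statistic, 25 / 9)
  expect_equal(mcnemarTest(7, 2, "chi2_cc")$statistic, 16 / 9)

  # symmetry in (b, c)
  expect_equal(mcnemarTest(2, 7, "exact")$p.value,
               mcnemarTest(7, 2, "exact")$p.value)
  expect_lte(mcnemarTest(0, 0, "exact")$p.value, 1)
  expect_error(mcnemarTest(0, 0, "chi2"), "b \\+ c")

  m <- matrix(c(10, 7, 2, 11), 2)  # b = 7, c = 2 off-diagonals
  ref <- stats::mcnemar.test(m, correct = FALSE)
  expect_equal(mcnemarTest(7, 2, "chi2")$p.value, unname(ref$p.value))
  refc <- stats::mcnemar.test(m, correct = TRUE)
  expect_equal(mcnemarTest(7, 2, "chi2_cc")$p.value, unname(refc$p.value))
})

test_that("method comparison reports all three dichotomizations", {
  cmp <- compareMethodsMcnemar(studyTableFixture(), "exact")
  expect_identical(nrow(cmp), 3L)
  expect_identical(cmp$b[cmp$rule == "partial_as_discordant"], 7L)
  expect_identical(cmp$c[cmp$rule == "partial_as_discordant"], 2L)
  expect_equal(cmp$p.value[cmp$rule == "partial_as_discordant"], 92 / 512)
  expect_identical(cmp$b[cmp$rule == "partial_as_concordant"], 6L)
  expect_identical(cmp$c[cmp$rule == "partial_as_concordant"], 3L)
  expect_identical(cmp$b[cmp$rule == "partial_excluded"], 6L)
  expect_identical(cmp$c[cmp$rule == "partial_excluded"], 2L)
})

test_that("Mann-Whitney: exact small-sample p equals enumeration", {
  r <- mannWhitney(c(1, 2), c(3, 4))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p.value, 2 / 6)

  # same multiset in both groups: U = nm/2
  r2 <- mannWhitney(c(5, 1, 3), c(3, 1, 5))
  expect_equal(unname(r2$U), 9 / 2)

  set.seed(75)
  x <- runif(5); y <- runif(5)
  ref <- mwEnumerate(x, y)
  r3 <- mannWhitney(x, y)
  expect_equal(unname(r3$U), unname(ref["U"]))
  expect_equal(r3$p.value, unname(ref["p"]))

  expect_error(mannWhitney(numeric(), 1:3), "non-empty")
})

test_that("summary statistics exclude missing values", {
  tab <- studyTableFixture()
  s <- summaryStats(tab$injection_time_s)
  expect_identical(s$n, 22L)
  expect_identical(s$nMissing, 1L)
  expect_equal(s$mean1, 17.8)
  expect_equal(s$sd1, 14.3)
  expect_equal(s$min, 2)
  expect_equal(s$max, 60)

  s2 <- summaryStats(c(2, 2, 2))
  expect_equal(s2$mean, 2); expect_equal(s2$sd, 0)

  expect_equal(summaryStats(1:10)$sd, sqrt(sum((1:10 - 5.5)^2) / 9))
  expect_error(summaryStats(c(NA_real_, NA_real_)), "missing")
  expect_error(summaryStats(c(5, NA)), "at least 2")
})
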
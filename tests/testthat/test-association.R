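# Dichotomization, exact tests, logistic fits and rank correlations.

test_that("root dichotomization follows the published groupings", {
  expect_equal(dichotomizeRoot("UP1", "1", "1"), "1")
  expect_equal(dichotomizeRoot("UP1", "2", "1"), "2<=")   # discordant sides
  expect_equal(dichotomizeRoot("UP1", "2", "3"), "2<=")
  expect_equal(dichotomizeRoot("UP2", "m", "1"), "1")
  expect_equal(dichotomizeRoot("UM2", "3", "1"), "<=2")
  expect_equal(dichotomizeRoot("UM2", "4", "4"), "3<=")
  expect_equal(dichotomizeRoot("LM1", "3", "2"), "3")
  expect_equal(dichotomizeRoot("LM2", "2", "C"), "C")
  expect_equal(dichotomizeRoot("LM2", "C", "C"), "C")
  # missing: absent side, NA, or a combination outside the groupings
  expect_true(is.na(dichotomizeRoot("LM1", "2", "absent")))
  expect_true(is.na(dichotomizeRoot("UP1", NA, "1")))
  expect_true(is.na(dichotomizeRoot("UP1", "1", "4")))
  expect_error(dichotomizeRoot("UP1", "5", "1"), "invalid root code")
  expect_error(dichotomizeRoot("XX1", "1", "1"), "unknown tooth")
})

test_that("contingency tables count the non-missing records", {
  tab <- edarRootCounts()$UP1
  cohort <- expandTable(tab, "UP1")
  expect_identical(genotypeTraitTable(cohort, "UP1"), tab)
  expect_equal(sum(genotypeTraitTable(cohort, "UP1")), nrow(cohort))
  empty <- expandTable(matrix(0L, 3, 2), "UP1")
  expect_equal(sum(genotypeTraitTable(empty, "UP1")), 0)
})

test_that("the exact r x c test agrees with independent oracles", {
  # r x c: stats::fisher.test network algorithm on the five reference tables
  for (tab in edarRootCounts()) {
    ours <- fisherExactRxC(tab)
    expect_equal(ours$p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  # 2 x 2: closed-form hypergeometric probability ordering
  set.seed(404)
  for (k in 1:25) {
    tab <- matrix(rpois(4, 8), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    ks <- max(0, c1 - r2):min(r1, c1)
    pk <- dhyper(ks, r1, r2, c1)
    pObs <- dhyper(tab[1, 1], r1, r2, c1)
    oracle <- sum(pk[pk <= pObs * (1 + 1e-12)])
    expect_equal(fisherExactRxC(tab)$p, oracle, tolerance = 1e-10)
  }
})

test_that("the exact test P is invariant under row and column permutations", {
  set.seed(405)
  for (k in 1:10) {
    tab <- matrix(rpois(6, 10), 3)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisherExactRxC(tab)$p
    expect_equal(fisherExactRxC(tab[sample(3), ])$p, p, tolerance = 1e-10)
    expect_equal(fisherExactRxC(tab[, 2:1])$p, p, tolerance = 1e-10)
    expect_equal(fisherExactRxC(t(tab))$p, p, tolerance = 1e-10)
  }
  # degenerate margin
  expect_equal(fisherExactRxC(matrix(c(0, 0, 3, 4), 2))$p, 1)
})

test_that("logistic fits recover closed forms and true effects", {
  # constant-only design: intercept = logit(mean(y))
  set.seed(11)
  y <- rbinom(400, 1, 0.3)
  fit <- logisticFit(y, data.frame(const = rep(1, 400)))
  expect_equal(fit$coefficients$logOR[1], qlogis(mean(y)), tolerance = 1e-8)
  expect_false(fit$separation)
  expect_error(logisticFit(rep(1, 50), data.frame(x = rnorm(50))), "constant")

  # genotype effect of the published LM2 size recovered at n = 5000
  cohort <- generateCohort(cohortModel(n = 5000), seed = 20)
  lm2 <- rootTraitLogistic(cohort, "LM2")
  est <- lm2$coefficients$logOR[lm2$coefficients$term == "genotype"]
  expect_lt(abs(est - 0.858), 0.1)
  # Wald machinery: chisq = (coef/se)^2, P from chi-square with 1 df
  co <- lm2$coefficients
  expect_equal(co$chisq, (co$logOR / co$se)^2)
  expect_equal(co$p, pchisq(co$chisq, 1, lower.tail = FALSE))

  # perfect separation is flagged by the coefficient-magnitude guard
  ysep <- rep(0:1, each = 30)
  sep <- suppressWarnings(logisticFit(ysep, data.frame(x = ysep * 2 - 1)))
  expect_true(sep$separation)
})

test_that("null logistic fits give small coefficients and uniform-ish P", {
  set.seed(12)
  ps <- numeric(0)
  for (k in 1:80) {
    y <- rbinom(2000, 1, 0.4)
    X <- data.frame(g = sample(0:2, 2000, TRUE), z = rnorm(2000))
    fit <- logisticFit(y, X)
    co <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
    expect_true(all(abs(co$logOR) < 0.2))
    ps <- c(ps, co$p)
  }
  frac <- mean(ps < 0.05)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.12)
})

test_that("spearman matches cor.test and its from-table closed form", {
  set.seed(13)
  expect_equal(spearmanRank(1:10, 1:10)$rho, 1)
  expect_error(spearmanRank(rep(1, 5), 1:5), "constant")
  for (k in 1:60) {
    n <- sample(10:40, 1)
    x <- sample(0:3, n, TRUE)
    y <- sample(0:2, n, TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    ours <- spearmanRank(x, y)$rho
    oracle <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman")$estimate)
    expect_equal(ours, unname(oracle), tolerance = 1e-12)
  }
  # from-table equals rank-then-correlate on the expansion
  set.seed(14)
  for (k in 1:50) {
    tab <- matrix(rpois(6, 6), 3)
    rows <- rep(rep(1:3, 2), as.vector(tab))
    cols <- rep(rep(1:2, each = 3), as.vector(tab))
    if (length(unique(rows)) < 2 || length(unique(cols)) < 2) next
    expect_equal(spearmanFromTable(tab)$rho, spearmanRank(rows, cols)$rho,
                 tolerance = 1e-12)
  }
})

test_that("reference tables reproduce the published correlations that verify", {
  counts <- edarRootCounts()
  expect_equal(round(spearmanFromTable(counts$UP1)$rho, 4), -0.1855)
  expect_equal(round(spearmanFromTable(counts$UP2)$rho, 4), -0.0235)
  expect_equal(round(spearmanFromTable(counts$UM2)$rho, 4), -0.0061)
  expect_equal(round(spearmanFromTable(counts$LM1)$rho, 4), 0.1351)
  # the LM2 value computed from the published dichotomized counts
  expect_equal(round(spearmanFromTable(counts$LM2)$rho, 4), -0.2416)
})

test_that("associationSummary assembles the full battery", {
  cohort <- generateCohort(cohortModel(n = 400), seed = 3)
  res <- associationSummary(cohort)
  expect_setequal(names(res$tables), c("UP1", "UP2", "UM2", "LM1", "LM2"))
  expect_equal(nrow(res$fisher), 5)
  expect_true(all(res$fisher$p >= 0 & res$fisher$p <= 1))
  expect_equal(nrow(res$spearman), 5)
  expect_true(all(abs(res$spearman$rho) <= 1))
  expect_named(res$logistic, c("UP1", "LM1", "LM2"))
})
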
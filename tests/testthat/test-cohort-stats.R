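## Group statistics: demographic table, Welch test, correlation matrix.

test_that("identical groups give t = 0, p = 1 for continuous variables", {
  rec <- recordFixture(8)      # R and MPMS rows have identical demographics
  rec$age <- rep(c(40, 50, 60, 45), 2)
  tab <- compareDemographics(rec)
  ct <- tab[tab$variable %in% c("age", "height", "weight", "bmi"), ]
  expect_true(all(abs(ct$statistic[ct$variable == "age"]) < 1e-12))
  expect_equal(ct$p[ct$variable == "age"], 1)
  expect_true(all(!ct$significant))
})

test_that("Fisher exact p for a perfectly separated 2x2 table matches the
          hypergeometric enumeration oracle", {
  # [[10,0],[0,10]]: enumerate the hypergeometric distribution directly
  probs <- dhyper(0:10, 10, 10, 10)
  pOracle <- sum(probs[probs <= probs[11] + 1e-12])  # two-sided
  expect_equal(pOracle, 2 * choose(20, 10)^-1 * 1, tolerance = 1e-12)
  pF <- fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value
  expect_equal(pF, pOracle, tolerance = 1e-10)
  expect_equal(pF, 1.0825e-05, tolerance = 1e-3)
})

test_that("chi-squared statistic matches its closed form (no continuity
          correction)", {
  tab <- matrix(c(20, 10, 10, 20), 2)
  # closed-form chi^2 of a 2x2 table
  n <- sum(tab)
  stat <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(rowSums(tab), colSums(tab))
  expect_equal(stat, 20 / 3, tolerance = 1e-12)
  ct <- chisq.test(tab, correct = FALSE)
  expect_equal(unname(ct$statistic), stat, tolerance = 1e-12)
  expect_equal(ct$p.value, pchisq(20 / 3, 1, lower.tail = FALSE))
  expect_equal(ct$p.value, 0.0098, tolerance = 1e-2)
})

test_that("cartilage categories empty in both groups are dropped with a
          warning", {
  rec <- recordFixture(8)
  rec$cart_mfc <- rep(c("0-I", "II"), 4)   # III and IV-focal absent
  expect_warning(tab <- compareDemographics(rec), "IV-focal")
  expect_true("cart_mfc" %in% tab$variable)
})

test_that("Welch test handles equal samples, planted shifts, and the
          degenerate zero-variance case", {
  x <- c(1, 2, 3, 4)
  eq <- welchTest(x, x)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  set.seed(100)
  a <- rnorm(120, 0, 1); b <- rnorm(120, 1, 1)
  wt <- welchTest(a, b)
  expect_lt(wt$p, 1e-6)
  # permutation oracle agrees on rejection
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  perm <- replicate(500, {
    idx <- sample(240, 120)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  expect_lt(mean(perm >= obs), 0.01)

  # Welch-Satterthwaite df re-evaluated from the formula
  set.seed(101)
  u <- rnorm(15, sd = 1); v <- rnorm(40, sd = 3)
  wt2 <- welchTest(u, v)
  su <- var(u) / 15; sv <- var(v) / 40
  dfOracle <- (su + sv)^2 / (su^2 / 14 + sv^2 / 39)
  expect_equal(wt2$df, dfOracle, tolerance = 1e-10)
  tOracle <- (mean(u) - mean(v)) / sqrt(su + sv)
  expect_equal(wt2$t, tOracle, tolerance = 1e-10)
  expect_equal(wt2$p, 2 * pt(-abs(tOracle), dfOracle), tolerance = 1e-10)

  degen <- welchTest(c(2, 2, 2), c(2, 2))
  expect_equal(degen$p, 1)
  expect_error(welchTest(1, c(1, 2)), "at least 2")
})

test_that("correlation matrix: identities, masking, and a permutation
          oracle for the p-value", {
  set.seed(7)
  n <- 30
  rec <- recordFixture(n)
  rec$age <- rnorm(n, 50, 10)
  rec$height <- -3 * rec$age + 7          # exact linear relation
  rec$weight <- rnorm(n, 80, 10)
  rec$bmi <- rec$weight / (rec$height / 100)^2
  W <- matrix(rnorm(3 * n), ncol = 3)
  vars <- morphologyVariables(rec, femur = W)
  cm <- correlationMatrix(vars)
  expect_equal(unname(diag(cm$r)), rep(1, ncol(vars)))
  expect_equal(cm$r["age", "height"], -1, tolerance = 1e-12)
  expect_true(all(abs(cm$r[!is.na(cm$r)]) <= 1 + 1e-12))
  expect_true(all(cm$r == t(cm$r), na.rm = TRUE))
  # masking: every unmasked entry has p < 0.05
  off <- row(cm$masked) != col(cm$masked)
  shown <- !is.na(cm$masked) & off
  expect_true(all(cm$p[shown] < 0.05))
  hidden <- is.na(cm$masked) & off & !is.na(cm$p)
  expect_true(all(cm$p[hidden] >= 0.05))

  # permutation oracle for a single pair at n = 10
  set.seed(8)
  x <- rnorm(10); y <- x * 0.8 + rnorm(10, sd = 0.6)
  pObs <- cor.test(x, y)$p.value
  robs <- abs(cor(x, y))
  perm <- replicate(4000, abs(cor(x, sample(y))))
  expect_lt(abs(mean(perm >= robs - 1e-12) - pObs), 0.03)
})

test_that("zero-variance variables are masked with a note", {
  rec <- recordFixture(6)
  vars <- morphologyVariables(rec)
  vars$constant <- 5
  cm <- correlationMatrix(vars)
  expect_true(any(grepl("constant", cm$notes)))
  expect_true(all(is.na(cm$masked["constant", -which(colnames(cm$masked) == "constant")])))
})

test_that("RTT and sex are coded as documented", {
  rec <- recordFixture(4)
  vars <- morphologyVariables(rec)
  expect_identical(vars$rtt, as.integer(rec$group == "R"))
  expect_true(all(vars$sex %in% c(0, 1)))
})
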
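# Damage scoring, stress-vs-score regression and risk classification.

test_that("damage score reproduces the in vitro group totals", {
  counts <- invitro_failure_counts()
  s <- damage_score(counts)
  expect_equal(s, counts$total_score)
  expect_equal(s, c(12, 8.5, 7.5, 4.5, 0))
  expect_equal(damage_score(c(large_aff = 0, small_aff = 0,
                              large_epjf = 0, small_epjf = 0)), 0)
  expect_equal(damage_score(c(large_aff = 4, small_aff = 0,
                              large_epjf = 3, small_epjf = 3)), 8.5)
})

test_that("score validation, bounds and monotonicity", {
  expect_error(damage_score(c(large_aff = -1, small_aff = 0,
                              large_epjf = 0, small_epjf = 0)), "negative")
  set.seed(7)
  for (k in 1:20) {
    n <- sample(1:10, 1)
    # per specimen, large and small failures of one mode are exclusive
    aff <- sample(c("none", "small", "large"), n, replace = TRUE)
    epjf <- sample(c("none", "small", "large"), n, replace = TRUE)
    cnt <- data.frame(large_aff = sum(aff == "large"),
                      small_aff = sum(aff == "small"),
                      large_epjf = sum(epjf == "large"),
                      small_epjf = sum(epjf == "small"))
    s <- damage_score(cnt)
    expect_gte(s, 0); expect_lte(s, 2 * n)
    bump <- cnt; bump$small_aff <- bump$small_aff + 1
    expect_gt(damage_score(bump), s)
  }
})

test_that("risk classification thresholds", {
  expect_equal(classify_risk(12, "axial"), "high")
  expect_equal(classify_risk(4, "axial"), "low")
  expect_equal(classify_risk(8, "axial"), "moderate")
  expect_equal(classify_risk(c(9.5, 5, 7), "circumferential"),
               c("high", "low", "moderate"))
  expect_equal(classify_risk(c(3.5, 3.49), "interface"), c("high", "low"))
  expect_true(is.na(classify_risk(5, "radial")))
  tb <- data.frame(value = c(10, 6), direction = c("axial", "axial"))
  expect_equal(classify_risk(tb)$risk, c("high", "low"))
  expect_error(risk_thresholds(axial_high = 5, axial_low = 6), "high")
})

test_that("constant response yields zero slopes and no significance flags", {
  set.seed(5)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  r <- regress_stress_vs_score(x, rep(2, 20))
  expect_equal(r$slope, rep(0, 3), tolerance = 1e-10)
  expect_false(any(r$significant))
})

test_that("regression recovers a planted linear score-stress relation", {
  # slope 1.0, noise sd 0.1, n = 30; over replicates the recovered slope
  # should lie within 3 standard errors of the truth ~99.7% of the time
  within3 <- 0; signif <- 0
  for (seed in 1:10) {
    set.seed(seed)
    x <- matrix(runif(30, 2, 10), 30, 1, dimnames = list(NULL, "axial"))
    y <- 1.0 * x[, 1] + rnorm(30, 0, 0.1)
    r <- regress_stress_vs_score(x, y)
    fit <- summary(stats::lm(y ~ x[, 1]))$coefficients
    within3 <- within3 + as.integer(abs(r$slope - 1) < 3 * fit[2, 2])
    signif <- signif + as.integer(isTRUE(r$significant))
  }
  expect_gte(within3, 9)
  expect_equal(signif, 10)
})

test_that("p-value matches the closed-form OLS t-test", {
  x <- c(1, 2, 3, 4, 6)
  y <- c(1.1, 1.9, 3.3, 3.8, 6.4)
  r <- regress_stress_vs_score(matrix(x, ncol = 1, dimnames = list(NULL, "x")),
                               y)
  # closed-form simple OLS oracle
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  se <- sqrt(sum(res^2) / (n - 2) / sum((x - mean(x))^2))
  p <- 2 * stats::pt(abs(b / se), df = n - 2, lower.tail = FALSE)
  expect_equal(r$slope, b, tolerance = 1e-12)
  expect_equal(r$intercept, a, tolerance = 1e-12)
  expect_equal(r$p_value, p, tolerance = 1e-12)
})

test_that("regression invariance: rescaling a predictor rescales its slope only", {
  set.seed(13)
  x <- matrix(runif(40, 0, 5), 20, 2, dimnames = list(NULL, c("p1", "p2")))
  y <- 0.8 * x[, 1] + rnorm(20, 0, 0.3)
  r1 <- regress_stress_vs_score(x, y)
  x2 <- x; x2[, 1] <- 10 * x2[, 1]
  r2 <- regress_stress_vs_score(x2, y)
  expect_equal(r2$slope[1], r1$slope[1] / 10, tolerance = 1e-10)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-10)
})

test_that("zero-variance predictors are flagged non-estimable", {
  set.seed(3)
  x <- cbind(const = rep(2, 12), ok = runif(12))
  y <- x[, 2] + rnorm(12, 0, 0.1)
  r <- regress_stress_vs_score(x, y)
  expect_true(is.na(r$slope[1]))
  expect_false(r$significant[1])
  expect_true(r$significant[2])
})

test_that("joint mode and BH correction are available", {
  set.seed(17)
  x <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 * x[, 1] + rnorm(30, 0, 0.5)
  rj <- regress_stress_vs_score(x, y, mode = "joint")
  expect_true(rj$significant[1])
  rbh <- regress_stress_vs_score(x, y, p_adjust = "BH")
  expect_true(all(is.na(rbh$p_value) | rbh$p_value <= 1))
  expect_error(regress_stress_vs_score(x[1:2, ], y[1:2]), "3 specimens")
})
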
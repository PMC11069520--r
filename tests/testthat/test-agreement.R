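test_that("Pearson correlation honours its trivial identities and samples correctly", {
  x <- c(1, 2, 3, 4, 5, 7)
  p <- pearsonWithCI(x, x, n_boot = 200L, seed = 1L)
  expect_equal(p$r, 1)
  expect_equal(p$ci, c(1, 1))
  expect_lt(p$p, 1e-10)
  expect_equal(pearsonWithCI(x, -x, n_boot = 50L, seed = 1L)$r, -1)
  expect_error(pearsonWithCI(x, rep(1, 6)), "variance")

  set.seed(31)
  n <- 1000
  a <- rnorm(n); b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(n)
  pr <- pearsonWithCI(a, b, n_boot = 400L, seed = 2L)
  expect_lt(abs(pr$r - 0.9), 0.03)
  expect_true(pr$ci[1] <= 0.9 && 0.9 <= pr$ci[2])
})

test_that("ICC(2,1) matches a hand-computed ANOVA table to 1e-10 and is sensitive to offsets", {
  x <- c(9, 6, 8, 7, 10, 6)
  y <- c(2, 1, 4, 1, 5, 2)
  # hand ANOVA: mean squares written out from sums, independent of the
  # implementation
  n <- 6; k <- 2
  m <- cbind(x, y)
  grand <- sum(m) / (n * k)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  sse <- sum((m - outer(rowMeans(m), c(1, 1)) -
                rbind(colMeans(m))[rep(1, n), ] + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  handICC <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  fit <- iccWithCI(x, y, n_boot = 100L, seed = 1L)
  expect_equal(fit$icc, handICC, tolerance = 1e-10)

  expect_equal(iccWithCI(x, x, n_boot = 50L, seed = 1L)$icc, 1)
  # absolute-agreement: a constant offset lowers ICC below Pearson r = 1
  off <- iccWithCI(x, x + 2, n_boot = 50L, seed = 1L)
  expect_lt(off$icc, 1)
  expect_error(iccWithCI(rep(3, 6), rep(3, 6)), "degenerate")
})

test_that("MAE matches its identities and the half-normal closed form", {
  x <- c(1, 2, 3, 4)
  expect_identical(maeWithCI(x, x, 50L, 1L)$mae, 0)
  expect_equal(maeWithCI(x, x + c(0.3, -0.3, 0.3, -0.3), 50L, 1L)$mae,
               0.3)
  set.seed(8)
  a <- rnorm(146); b <- a + rnorm(146, 0, 0.02)
  m <- maeWithCI(a, b, 300L, 2L)
  expect_lt(abs(m$mae - 0.02 * sqrt(2 / pi)) / (0.02 * sqrt(2 / pi)), 0.15)
})

test_that("Bland-Altman bias and limits behave on trivial and Gaussian differences", {
  x <- c(1, 2, 3)
  ba0 <- blandAltman(x, x)
  expect_identical(c(ba0$bias, ba0$loa_lower, ba0$loa_upper), c(0, 0, 0))
  bac <- blandAltman(x + 0.5, x)
  expect_equal(bac$bias, 0.5)
  expect_equal(bac$loa_lower, bac$loa_upper)

  set.seed(5)
  a <- rnorm(2000); b <- a + rnorm(2000, 0, 0.1)
  ba <- blandAltman(a, b)
  cover <- mean(ba$differences >= ba$loa_lower &
                  ba$differences <= ba$loa_upper)
  expect_gt(cover, 0.93); expect_lt(cover, 0.97)
})

test_that("bootstrap confidence intervals are reproducible under a seed", {
  set.seed(12); a <- rnorm(60); b <- a + rnorm(60, 0, 0.3)
  r1 <- pearsonWithCI(a, b, 300L, seed = 9L)
  r2 <- pearsonWithCI(a, b, 300L, seed = 9L)
  expect_identical(r1$ci, r2$ci)
  r3 <- pearsonWithCI(a, b, 300L, seed = 10L)
  expect_false(identical(r1$ci, r3$ci))
  i1 <- iccWithCI(a, b, 200L, seed = 4L); i2 <- iccWithCI(a, b, 200L, seed = 4L)
  expect_identical(i1$ci, i2$ci)
})

test_that("grading scores reproduce a hand tally and the accuracy decomposition", {
  # all-correct roster
  rec <- data.frame(item = 1:6,
                    truth = rep(c("real", "synthetic"), 3),
                    stratum = rep(c("normal", "dr"), each = 3),
                    expert1 = rep(c("real", "synthetic"), 3),
                    expert2 = rep(c("real", "synthetic"), 3),
                    expert3 = rep(c("real", "synthetic"), 3))
  sc <- gradingScores(rec)
  expect_true(all(sc$accuracy == 100))
  expect_true(all(sc$sensitivity == 100, na.rm = TRUE))
  expect_true(all(sc$specificity == 100, na.rm = TRUE))

  # constructed 10-item roster with known expert vectors
  truth <- c("real", "real", "real", "real", "synthetic", "synthetic",
             "synthetic", "synthetic", "real", "synthetic")
  e1 <- c("real", "synthetic", "real", "real", "synthetic", "real",
          "synthetic", "synthetic", "synthetic", "synthetic")
  e2 <- c("real", "real", "synthetic", "real", "real", "real",
          "synthetic", "synthetic", "real", "synthetic")
  e3 <- c("synthetic", "real", "real", "real", "synthetic", "synthetic",
          "synthetic", "real", "real", "real")
  rec2 <- data.frame(item = 1:10, truth = truth, expert1 = e1,
                     expert2 = e2, expert3 = e3)
  sc2 <- gradingScores(rec2)
  g <- function(gr, col) sc2[sc2$grader == gr & sc2$scope == "all", col]
  # hand tallies
  expect_equal(g("expert1", "accuracy"), 100 * 7 / 10)
  expect_equal(g("expert1", "sensitivity"), 100 * 3 / 5)
  expect_equal(g("expert1", "specificity"), 100 * 4 / 5)
  maj <- c("real", "real", "real", "real", "synthetic", "real",
           "synthetic", "synthetic", "real", "synthetic")
  expect_equal(g("majority", "accuracy"), 100 * mean(maj == truth))
  # accuracy = (sens * n_real + spec * n_syn) / n
  acc <- g("expert2", "accuracy")
  sens <- g("expert2", "sensitivity"); spec <- g("expert2", "specificity")
  expect_equal(acc, (sens * 5 + spec * 5) / 10)

  expect_error(gradingScores(rec2, experts = c("expert1", "expert2")),
               "odd")
})

test_that("the reader-study design strata are scored with their design counts", {
  set.seed(3)
  strata <- rep(c("normal", "glaucoma", "dr"), times = c(30, 25, 50))
  n <- length(strata)
  rec <- data.frame(item = seq_len(n),
                    truth = sample(c("real", "synthetic"), n, TRUE),
                    stratum = strata,
                    expert1 = sample(c("real", "synthetic"), n, TRUE),
                    expert2 = sample(c("real", "synthetic"), n, TRUE),
                    expert3 = sample(c("real", "synthetic"), n, TRUE))
  sc <- gradingScores(rec)
  expect_identical(sc$n[sc$grader == "majority" & sc$scope == "normal"], 30L)
  expect_identical(sc$n[sc$grader == "majority" & sc$scope == "glaucoma"], 25L)
  expect_identical(sc$n[sc$grader == "majority" & sc$scope == "dr"], 50L)
})

test_that("agreement reports assemble all statistics per metric", {
  set.seed(2)
  a <- data.frame(rt_mm = rnorm(20, 0.22, 0.02),
                  ct_mm = rnorm(20, 0.25, 0.08))
  b <- data.frame(rt_mm = a$rt_mm + rnorm(20, 0, 0.005),
                  ct_mm = a$ct_mm + rnorm(20, 0, 0.02))
  rep <- agreementReport(a, b, metrics = c("rt_mm", "ct_mm"),
                         n_boot = 200L, seed = 3L)
  df <- as.data.frame(rep)
  expect_identical(df$metric, c("rt_mm", "ct_mm"))
  expect_true(all(df$pearson_lo <= df$pearson_r + 1e-9))
  expect_true(all(df$mae >= 0))
  expect_identical(formatPValue(c(1e-5, 0.5)), c("***", "0.500"))
})
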
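# independent sums-of-squares oracle: nested loops, no shared code with the
# implementation
rm_anova_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  ss_c <- 0
  for (j in 1:k) ss_c <- ss_c + n * (mean(m[, j]) - g)^2
  ss_s <- 0
  for (i in 1:n) ss_s <- ss_s + k * (mean(m[i, ]) - g)^2
  ss_t <- 0
  for (i in 1:n) for (j in 1:k) ss_t <- ss_t + (m[i, j] - g)^2
  ((ss_c / (k - 1)) / ((ss_t - ss_c - ss_s) / ((k - 1) * (n - 1))))
}

test_that("rm-ANOVA matches a brute-force oracle and its k = 2 identities", {
  set.seed(81)
  m33 <- matrix(c(3, 5, 4, 6, 7, 8, 2, 4, 9), 3, 3)
  expect_equal(rm_anova_gg(m33)$F, rm_anova_oracle(m33), tolerance = 1e-10)
  for (i in 1:20) {
    m <- matrix(rnorm(20, sd = 3), 5, 4)
    expect_equal(rm_anova_gg(m)$F, rm_anova_oracle(m), tolerance = 1e-10)
  }

  m2 <- matrix(rnorm(24), 12, 2)
  r2 <- rm_anova_gg(m2)
  expect_equal(r2$epsilon_gg, 1)
  tt <- t.test(m2[, 1], m2[, 2], paired = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r2$p_gg, tt$p.value, tolerance = 1e-10)

  expect_error(rm_anova_gg(matrix(1:5, 5, 1)), "at least 2 conditions")
  expect_error(rm_anova_gg(matrix(c(1, NA, 2, 3), 2, 2)), "missing cells")
})

test_that("epsilon stays in its bounds and Bonferroni never undercuts raw p", {
  set.seed(82)
  for (i in 1:25) {
    k <- sample(3:6, 1)
    m <- matrix(rnorm(10 * k), 10, k)
    r <- rm_anova_gg(m)
    expect_gte(r$epsilon_gg, 1 / (k - 1) - 1e-12)
    expect_lte(r$epsilon_gg, 1 + 1e-12)
    expect_true(all(r$pairwise$p_bonferroni >= r$pairwise$p_raw - 1e-15))
    expect_true(all(r$pairwise$p_bonferroni <= 1))
    expect_equal(nrow(r$pairwise), k * (k - 1) / 2)
  }
})

test_that("compound-symmetric nulls keep the GG test near nominal size", {
  set.seed(83)
  n <- 18; k <- 4
  rejections <- 0
  eps_vals <- numeric(400)
  for (i in 1:400) {
    subj <- rnorm(n, 0, 3)
    m <- matrix(subj, n, k) + matrix(rnorm(n * k, 0, 2), n, k)
    r <- rm_anova_gg(m)
    eps_vals[i] <- r$epsilon_gg
    if (r$p_gg < 0.05) rejections <- rejections + 1
  }
  expect_gt(mean(eps_vals), 0.8)
  expect_lte(mean(eps_vals), 1)
  expect_gt(rejections / 400, 0.015)
  expect_lt(rejections / 400, 0.085)
})

test_that("stepwise regression selects planted predictors and reduces to OLS", {
  set.seed(84)
  n <- 40
  x1 <- rnorm(n)
  y1 <- 2 * x1
  f_exact <- stepwise_regression(y1, cbind(x1 = x1))
  expect_equal(f_exact$selected, "x1")
  expect_equal(f_exact$r_squared, 1, tolerance = 1e-12)

  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  y <- 0.75 * X[, 1] + rnorm(n, 0, 0.6)
  f <- stepwise_regression(y, X)
  expect_equal(f$selected[1], "x1")
  expect_equal(unname(f$coefficients["x1"]), 0.75, tolerance = 0.35)

  # thresholds of 1 admit everything: the fit equals a direct full OLS
  f_all <- stepwise_regression(y, X, entry_p = 1, removal_p = 1)
  expect_setequal(f_all$selected, colnames(X))
  lmfit <- summary(lm(y ~ X))
  expect_equal(f_all$r_squared, lmfit$r.squared, tolerance = 1e-10)
  expect_equal(f_all$adj_r_squared, lmfit$adj.r.squared, tolerance = 1e-10)
  expect_lte(f_all$adj_r_squared, f_all$r_squared)

  expect_error(stepwise_regression(y, cbind(a = X[, 1], b = X[, 1]),
                                   entry_p = 1, removal_p = 1),
               "rank-deficient|conditioning")
  expect_error(stepwise_regression(rnorm(4), X), "n >")
})

test_that("pure-noise candidates mostly leave the stepwise model empty", {
  set.seed(85)
  empty <- 0
  for (i in 1:150) {
    y <- rnorm(25)
    X <- matrix(rnorm(25 * 4), 25, 4)
    if (length(stepwise_regression(y, X)$selected) == 0) empty <- empty + 1
  }
  # P(any of 4 independent candidates enters at 0.05) is about 0.19
  expect_gt(empty / 150, 0.6)
  expect_lt(empty / 150, 0.97)
})

test_that("Pearson correlation matches its closed form and cor.test", {
  x <- c(1, 2, 4, 7, 9)
  r1 <- pearson_r(x, -x)
  expect_equal(r1$r, -1)
  expect_equal(r1$p, 0)

  y <- c(1, -1, 0, 1, -1)
  y_orth <- y - mean(y) - sum((y - mean(y)) * (x - mean(x))) /
    sum((x - mean(x))^2) * (x - mean(x))
  expect_lt(abs(pearson_r(x, y_orth)$r), 1e-12)

  set.seed(86)
  a <- rnorm(18); b <- 0.5 * a + rnorm(18)
  ct <- cor.test(a, b)
  pr <- pearson_r(a, b)
  expect_equal(pr$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pr$p, ct$p.value, tolerance = 1e-12)

  expect_error(pearson_r(1:2, 1:2), "n >= 3")
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
})

test_that("sampled correlations concentrate around the generative rho", {
  set.seed(87)
  rho <- -0.6; n <- 18
  rs <- replicate(3000, {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    pearson_r(x, y)$r
  })
  expect_gt(mean(rs), -0.65)
  expect_lt(mean(rs), -0.55)
})

test_that("the normality screen reports a Shapiro-Wilk row per condition", {
  set.seed(88)
  m <- matrix(rnorm(36), 18, 2, dimnames = list(NULL, c("a", "b")))
  ns <- normality_screen(m)
  expect_equal(ns$condition, c("a", "b"))
  expect_true(all(ns$p > 0 & ns$p <= 1))
})
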
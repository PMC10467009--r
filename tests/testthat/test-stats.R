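test_that("manipulation-check regression matches the normal equations", {
  set.seed(71)
  dat <- data.frame(frequency = stats::rnorm(10, 3, 1),
                    concreteness = stats::rnorm(10, 3, 0.8),
                    aoa = stats::rnorm(10, 10, 2),
                    length = sample(4:10, 10, TRUE))
  beta_true <- c(1, -0.5, 0.3, 0.1, -0.2)
  X <- cbind(1, as.matrix(dat))
  dat$rating <- drop(X %*% beta_true) + stats::rnorm(10, 0, 0.3)

  res <- manipulation_check_regression(dat)
  oracle <- solve(t(X) %*% X, t(X) %*% dat$rating)
  expect_equal(unname(res$coefficients), unname(drop(oracle)),
               tolerance = 1e-10)

  # perfect linear dependence on one predictor gives R2 = 1
  dat2 <- dat
  dat2$rating <- dat2$frequency
  expect_equal(manipulation_check_regression(dat2)$r2, 1, tolerance = 1e-12)
})

test_that("regression pre-conditions and rank checks are enforced", {
  set.seed(72)
  dat <- data.frame(frequency = stats::rnorm(30), concreteness = stats::rnorm(30),
                    aoa = stats::rnorm(30), length = 7,
                    rating = sample(1:6, 30, TRUE))
  expect_error(manipulation_check_regression(dat), "length")
  expect_error(manipulation_check_regression(dat[1:8, ]), "at least")
})

test_that("null regressions reject at about the nominal rate", {
  set.seed(73)
  rej <- mean(vapply(1:2000, function(i) {
    dat <- data.frame(frequency = stats::rnorm(60), concreteness = stats::rnorm(60),
                      aoa = stats::rnorm(60), length = stats::rnorm(60),
                      rating = stats::rnorm(60))
    manipulation_check_regression(dat)$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("2x2 within-ANOVA effects equal squared paired-t contrasts", {
  set.seed(74)
  m <- matrix(stats::rnorm(80, mean = rep(c(2, 1.8, 1.2, 1.1), each = 20)),
              nrow = 20)
  res <- rm_anova(m, design = "2x2", factor_names = c("strength", "var"))
  tt_a <- stats::t.test((m[, 1] + m[, 2]) / 2 - (m[, 3] + m[, 4]) / 2)
  tt_i <- stats::t.test(m[, 1] - m[, 2] - m[, 3] + m[, 4])
  expect_equal(res$F[res$effect == "strength"], unname(tt_a$statistic)^2,
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "strength:var"], unname(tt_i$statistic)^2,
               tolerance = 1e-10)
  expect_equal(res$df2, rep(19, 3))

  # identical columns: all effects vanish
  same <- matrix(rep(stats::rnorm(12), 4), ncol = 4)
  expect_equal(rm_anova(same, "2x2")$F, rep(0, 3))
})

test_that("one-way RM-ANOVA matches aov and its epsilon behaves", {
  set.seed(75)
  m <- matrix(stats::rnorm(60, rep(c(0, 0.4, 0.9), each = 20), 1), ncol = 3)
  res <- rm_anova(m, design = "oneway")

  # uncorrected F cross-checked against stats::aov with an Error stratum
  long <- data.frame(y = as.vector(m),
                     cond = factor(rep(1:3, each = 20)),
                     subj = factor(rep(1:20, 3)))
  av <- summary(stats::aov(y ~ cond + Error(subj / cond), data = long))
  f_aov <- av[["Error: subj:cond"]][[1]]["cond", "F value"]
  expect_equal(res$F, f_aov, tolerance = 1e-10)

  # epsilon bounds; exactly 1 at k = 2
  expect_gte(res$epsilon, 1 / 2)
  expect_lte(res$epsilon, 1)
  expect_equal(rm_anova(m[, 1:2], "oneway")$epsilon, 1, tolerance = 1e-12)

  # compound-symmetric population covariance: epsilon near 1
  sigma <- matrix(0.5, 3, 3); diag(sigma) <- 1
  big <- MASS::mvrnorm(4000, c(0, 0, 0), sigma)
  expect_equal(rm_anova(big, "oneway")$epsilon, 1, tolerance = 0.02)
})

test_that("within-subject sums of squares partition the total", {
  set.seed(76)
  m <- matrix(stats::rnorm(48, rep(c(1, 2, 3, 4), each = 12)), ncol = 4)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_total <- sum((m - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  resid <- m - outer(rowMeans(m), rep(1, k)) - outer(rep(1, n), colMeans(m)) +
    grand
  expect_equal(ss_total, ss_subj + ss_cond + sum(resid^2), tolerance = 1e-10)
  # and the package's one-way F is built from exactly these pieces
  res <- rm_anova(m, "oneway")
  expect_equal(res$pes, ss_cond / (ss_cond + sum(resid^2)), tolerance = 1e-12)
})

test_that("t tests match the hand formula and the CI/p duality", {
  x <- c(12.1, 11.4, 13.2, 12.8, 11.9)
  y <- c(11.2, 11.5, 12.4, 12.1, 11.0)
  res <- t_test(x, y, mode = "paired")
  d <- x - y
  t_hand <- mean(d) / (stats::sd(d) / sqrt(5))
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$d_z, mean(d) / stats::sd(d), tolerance = 1e-12)

  expect_error(t_test(x, x, mode = "paired"), "zero variance")

  set.seed(77)
  for (i in 1:20) {
    v <- stats::rnorm(12, mean = stats::runif(1, -0.6, 0.6))
    r <- t_test(v, mu = 0, mode = "one-sample")
    excludes <- r$ci[1] > 0 || r$ci[2] < 0
    expect_equal(excludes, r$p < 0.05)
  }
})

test_that("null t tests and ANOVAs reject at about the nominal rate", {
  set.seed(78)
  rej_t <- mean(vapply(1:2000, function(i) {
    t_test(stats::rnorm(20), stats::rnorm(20), mode = "paired")$p < 0.05
  }, logical(1)))
  expect_gt(rej_t, 0.03); expect_lt(rej_t, 0.07)

  rej_a <- colMeans(t(vapply(1:2000, function(i) {
    rm_anova(matrix(stats::rnorm(48), ncol = 4), "2x2")$p < 0.05
  }, logical(3))))
  expect_true(all(rej_a > 0.03 & rej_a < 0.07))
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, m = 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, m = 3), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.04)), c(0.4, 0.08))
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "m")
})

test_that("sequential scaling fits recover a noiseless linear law exactly", {
  d <- seq(0.3, 2.4, length.out = 30)
  sigma <- 0.09 + 0.18 * d
  fit <- sequential_scaling_fit(d, sigma)
  expect_equal(fit$selected, "linear")
  co <- fit$models$linear$coefficients
  expect_equal(unname(co[1]), 0.09, tolerance = 1e-8)
  expect_equal(unname(co[2]), 0.18, tolerance = 1e-8)
  expect_error(sequential_scaling_fit(d[1:4], sigma[1:4]), "5")
})

test_that("a true quadratic term is detected and R2 never decreases", {
  set.seed(79)
  d <- seq(0.2, 2.2, length.out = 60)
  sigma <- 0.3 + 0.1 * d + 0.25 * d^2 + stats::rnorm(60, 0, 0.01)
  fit <- sequential_scaling_fit(d, sigma)
  expect_equal(fit$selected, "quadratic")
  r2s <- vapply(fit$models, `[[`, numeric(1), "r2")
  expect_true(all(diff(r2s) >= -1e-12))

  # sequential F equals the direct extra-sum-of-squares computation
  m1 <- stats::lm(sigma ~ d)
  m2 <- stats::lm(sigma ~ d + I(d^2))
  rss1 <- sum(stats::resid(m1)^2); rss2 <- sum(stats::resid(m2)^2)
  f_direct <- (rss1 - rss2) / (rss2 / m2$df.residual)
  expect_equal(fit$comparisons$F[1], f_direct, tolerance = 1e-10)
})

test_that("minimum detectable paired effect size solves the power equation", {
  expect_equal(round(min_detectable_dz(72, 0.05, 0.80), 2), 0.33)

  # monotone decreasing in n
  dz <- vapply(c(20, 40, 80, 160), min_detectable_dz, numeric(1))
  expect_true(all(diff(dz) < 0))

  # large-n, 50% power: dz approaches z_{.975}/sqrt(n)
  expect_equal(min_detectable_dz(10000, 0.05, 0.50),
               stats::qnorm(0.975) / sqrt(10000), tolerance = 1e-3)
})
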
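test_that("category probabilities are a proper 6-category distribution", {
  # equal-quantile criteria slice both distributions into sixths at d = 0
  eq <- uvsd_params(0, 1, stats::qnorm((1:5) / 6))
  expect_equal(category_probs(eq, "old"), rep(1 / 6, 6), tolerance = 1e-12)
  expect_equal(category_probs(eq, "new"), rep(1 / 6, 6), tolerance = 1e-12)

  # d at the middle criterion puts half the old mass above it
  p <- uvsd_params(1, 1.7, c(-1, 0, 1, 1.5, 2))
  expect_equal(sum(category_probs(p, "old")[4:6]), 0.5, tolerance = 1e-12)

  set.seed(101)
  for (i in 1:20) {
    pr <- random_uvsd_params()
    for (it in c("old", "new")) {
      probs <- category_probs(pr, it)
      expect_true(all(probs >= 0))
      expect_equal(sum(probs), 1, tolerance = 1e-12)
    }
  }
})

test_that("closed-form probabilities match adaptive quadrature", {
  # spot value: highest-confidence old rate for a strong, wide distribution
  p <- uvsd_params(1.31, 1.42, c(-0.80, 0.16, 0.71, 1.17, 1.87))
  expect_equal(category_probs(p, "old")[6],
               stats::pnorm((1.31 - 1.87) / 1.42),
               tolerance = 1e-12)
  expect_equal(category_probs(p, "old"), quad_probs(1.31, 1.42, p$criteria),
               tolerance = 1e-8)

  set.seed(11)
  for (i in 1:20) {
    pr <- random_uvsd_params()
    expect_equal(category_probs(pr, "old"),
                 quad_probs(pr$d, pr$sigma_o, pr$criteria), tolerance = 1e-8)
    expect_equal(category_probs(pr, "new"),
                 quad_probs(0, 1, pr$criteria), tolerance = 1e-8)
  }
})

test_that("parameter invariants are enforced", {
  expect_error(uvsd_params(1, -0.5, c(-1, 0, 1, 1.5, 2)), "sigma_o")
  expect_error(uvsd_params(1, 1, c(0, -1, 1, 1.5, 2)), "increasing")
  expect_error(uvsd_params(1, 1, c(0, 1, 2)), "5")
})

test_that("operating points behave at the boundaries and in population", {
  expect_equal(operating_points(c(0, 0, 0, 0, 0, 10),
                                c(2, 2, 2, 2, 1, 1))$hit, rep(1, 5))
  # criterion at 0 leaves half the new mass above it
  pop <- operating_points(uvsd_params(1, 1.2, c(0, 0.4, 0.8, 1.2, 1.6)))
  expect_equal(pop$fa[1], 0.5, tolerance = 1e-12)
  pop2 <- operating_points(uvsd_params(1.31, 1.42,
                                       c(-0.80, 0.16, 0.71, 1.17, 1.87)))
  expect_equal(pop2$fa[1], stats::pnorm(0.80), tolerance = 1e-12)
  # monotone non-increasing in the criterion index
  expect_true(all(diff(pop2$hit) <= 0) && all(diff(pop2$fa) <= 0))
  expect_error(operating_points(rep(0, 6), rep(0, 6)), "at least one trial")
})

test_that("log-likelihood matches closed forms and a brute-force oracle", {
  eq <- uvsd_params(0, 1, stats::qnorm((1:5) / 6))
  n <- c(10, 10, 10, 10, 10, 10)
  expect_equal(log_likelihood(eq, n, n), 120 * log(1 / 6), tolerance = 1e-10)

  p <- uvsd_params(1, 1.3, c(-1, -0.5, 0, 0.5, 1))
  n_old <- c(1, 2, 3, 4, 5, 6); n_new <- c(6, 5, 4, 3, 2, 1)
  expect_equal(log_likelihood(p, n_old, n_new),
               brute_loglik(1, 1.3, p$criteria, n_old, n_new),
               tolerance = 1e-10)

  # moving a count out of the most likely category never increases logL
  probs <- category_probs(p, "old")
  hi <- which.max(probs)
  ll_base <- log_likelihood(p, n_old, n_new)
  for (k in setdiff(1:6, hi)) {
    shifted <- n_old
    shifted[hi] <- shifted[hi] - 1
    shifted[k] <- shifted[k] + 1
    expect_lte(log_likelihood(p, shifted, n_new), ll_base + 1e-12)
  }
})

test_that("MLE recovers generating parameters from expected counts", {
  gen <- uvsd_params(1.0, 1.3, c(-1, -0.5, 0.25, 0.9, 1.6))
  n_old <- round(1e5 * category_probs(gen, "old"))
  n_new <- round(1e5 * category_probs(gen, "new"))
  fit <- fit_uvsd(n_old, n_new, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$estimates$d, 1.0, tolerance = 0.03)
  expect_equal(fit$estimates$sigma_o, 1.3, tolerance = 0.03)
  expect_equal(fit$estimates$criteria, gen$criteria, tolerance = 0.03)

  # coarse grid-search oracle: no (d, sigma) grid point beats the MLE
  grid <- expand.grid(d = seq(0.5, 1.5, 0.05), s = seq(0.9, 1.7, 0.05))
  ll_grid <- mapply(function(d, s) {
    log_likelihood(uvsd_params(d, s, fit$estimates$criteria), n_old, n_new)
  }, grid$d, grid$s)
  expect_true(fit$logL >= max(ll_grid) - 1e-6)
})

test_that("identical old and new counts give d = 0, sigma_o = 1", {
  n <- c(10, 12, 8, 9, 11, 10)
  fit <- fit_uvsd(n, n, seed = 2)
  expect_equal(fit$estimates$d, 0, tolerance = 1e-3)
  expect_equal(fit$estimates$sigma_o, 1, tolerance = 1e-3)
})

test_that("degenerate count patterns raise non-identifiability errors", {
  expect_error(fit_uvsd(c(0, 0, 0, 0, 0, 60), c(60, 0, 0, 0, 0, 0)),
               "non-identifiable")
  expect_error(fit_uvsd(c(0, 0, 60, 0, 0, 0), c(0, 0, 60, 0, 0, 0)),
               "single rating category")
  expect_error(fit_uvsd(rep(0, 6), c(1, 2, 3, 0, 0, 0)), "both item types")
})

test_that("fitted logL is at least the generating-parameter logL", {
  set.seed(21)
  for (i in 1:10) {
    gen <- random_uvsd_params()
    cp <- counts_pair(simulate_ratings(gen, 200, seed = 100 + i))
    fit <- fit_uvsd(cp$old, cp$new, n_restarts = 4, seed = i)
    expect_gte(fit$logL, log_likelihood(gen, cp$old, cp$new) - 1e-6)
  }
})

test_that("parameter recovery at realistic trial counts is faithful", {
  # 200 simulated participants, 60 old + 60 new trials each, generating
  # values spread over the empirically plausible range
  set.seed(31)
  gen_d <- stats::runif(200, 0.4, 2.2)
  gen_ls <- stats::rnorm(200, 0.25, 0.2)
  rec <- t(vapply(seq_len(200), function(i) {
    gen <- uvsd_params(gen_d[i], exp(gen_ls[i]), c(-1.1, -0.2, 0.5, 1.1, 1.9))
    cp <- counts_pair(simulate_ratings(gen, 60, seed = 3000 + i))
    f <- fit_uvsd(cp$old, cp$new, n_restarts = 3, seed = i)
    c(f$estimates$d, f$log_sigma_o)
  }, numeric(2)))
  expect_gt(stats::cor(gen_d, rec[, 1]), 0.8)
  med_err <- stats::median(abs(rec[, 2] - gen_ls))
  expect_lt(med_err, 0.25)
})
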
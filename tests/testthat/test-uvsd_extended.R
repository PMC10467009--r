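reference_extended_params <- function() {
  extended_params(mu_nh = -0.19, mu_ol = 1.34, mu_oh = 1.31,
                  sigma_nh = 0.96, sigma_ol = 1.28, sigma_oh = 1.42,
                  criteria = c(-0.80, 0.16, 0.71, 1.17, 1.87))
}

test_that("extended likelihood reduces to closed forms and sums by condition", {
  eqc <- stats::qnorm((1:5) / 6)
  ref <- extended_params(0, 0, 0, 1, 1, 1, eqc)
  n <- rep(10, 6)
  counts <- list(new_low = n, new_high = n, old_low = n, old_high = n)
  expect_equal(extended_log_likelihood(ref, counts), 240 * log(1 / 6),
               tolerance = 1e-10)

  # additivity: equals four single-distribution multinomial terms
  p <- reference_extended_params()
  set.seed(12)
  counts <- lapply(counts, function(x) tabulate(sample(1:6, 60, TRUE), 6))
  parts <- vapply(names(counts), function(cc) {
    m <- switch(cc, new_low = c(0, 1), new_high = c(-0.19, 0.96),
                old_low = c(1.34, 1.28), old_high = c(1.31, 1.42))
    brute_loglik(m[1], m[2], p$criteria, counts[[cc]], rep(0, 6))
  }, numeric(1))
  expect_equal(extended_log_likelihood(p, counts), sum(parts),
               tolerance = 1e-10)
})

test_that("extended likelihood matches the brute-force oracle on big counts", {
  p <- reference_extended_params()
  counts <- lapply(c(new_low = "new_low", new_high = "new_high",
                     old_low = "old_low", old_high = "old_high"),
                   function(cc) round(1e4 * category_probs(p, cc)))
  oracle <- sum(vapply(names(counts), function(cc) {
    m <- switch(cc, new_low = c(0, 1), new_high = c(-0.19, 0.96),
                old_low = c(1.34, 1.28), old_high = c(1.31, 1.42))
    brute_loglik(m[1], m[2], p$criteria, counts[[cc]], rep(0, 6))
  }, numeric(1)))
  expect_equal(extended_log_likelihood(p, counts), oracle, tolerance = 1e-10)
})

test_that("missing conditions are reported by name", {
  counts <- list(new_low = rep(10, 6), old_low = rep(10, 6),
                 old_high = rep(10, 6))
  expect_error(extended_log_likelihood(reference_extended_params(), counts), "new_high")
})

test_that("collapsing the high conditions recovers the standard model", {
  # mu_nh = 0, sigma_nh = 1, old conditions identical -> the extended
  # likelihood equals the standard UVSD likelihood on pooled counts
  crit <- c(-1, -0.4, 0.3, 0.9, 1.7)
  ext <- extended_params(0, 1.2, 1.2, 1, 1.35, 1.35, crit)
  std <- uvsd_params(1.2, 1.35, crit)
  set.seed(13)
  nl <- tabulate(sample(1:6, 50, TRUE), 6); nh <- tabulate(sample(1:6, 50, TRUE), 6)
  ol <- tabulate(sample(1:6, 50, TRUE), 6); oh <- tabulate(sample(1:6, 50, TRUE), 6)
  expect_equal(
    extended_log_likelihood(ext, list(new_low = nl, new_high = nh,
                                      old_low = ol, old_high = oh)),
    log_likelihood(std, ol + oh, nl + nh),
    tolerance = 1e-10)
})

test_that("joint MLE recovers the generating parameters at large N", {
  gen <- reference_extended_params()
  tab <- simulate_ratings(gen, 2e4, seed = 7)
  fit <- fit_extended(counts_quad(tab), seed = 1)
  e <- fit$estimates
  expect_true(fit$converged)
  expect_lt(abs(e$mu_nh - gen$mu_nh), 0.05)
  expect_lt(abs(e$mu_ol - gen$mu_ol), 0.05)
  expect_lt(abs(e$mu_oh - gen$mu_oh), 0.05)
  expect_lt(abs(log(e$sigma_nh) - log(gen$sigma_nh)), 0.05)
  expect_lt(abs(log(e$sigma_ol) - log(gen$sigma_ol)), 0.05)
  expect_lt(abs(log(e$sigma_oh) - log(gen$sigma_oh)), 0.05)
  expect_lt(max(abs(e$criteria - gen$criteria)), 0.05)
})

test_that("swapping the old condition labels permutes the estimates", {
  gen <- reference_extended_params()
  counts <- counts_quad(simulate_ratings(gen, 2000, seed = 19))
  f1 <- fit_extended(counts, n_restarts = 4, seed = 3)
  swapped <- counts
  swapped$old_low <- counts$old_high
  swapped$old_high <- counts$old_low
  f2 <- fit_extended(swapped, n_restarts = 4, seed = 3)
  expect_equal(f2$estimates$mu_oh, f1$estimates$mu_ol, tolerance = 1e-3)
  expect_equal(f2$estimates$mu_ol, f1$estimates$mu_oh, tolerance = 1e-3)
  expect_equal(f2$estimates$sigma_oh, f1$estimates$sigma_ol, tolerance = 1e-3)
})

test_that("a unit new-high SD is recovered without bias at moderate N", {
  # generating sigma_nh = 1, mu_nh = 0: across replicates the fitted
  # log sigma_nh should centre on 0 (mirrors the null check on the
  # new-item variance ratio)
  ls <- vapply(1:60, function(i) {
    gen <- extended_params(0, 1.3, 1.3, 1, 1.25, 1.45,
                           c(-0.8, 0.16, 0.71, 1.17, 1.87))
    tab <- simulate_ratings(gen, 120, seed = 500 + i)
    fit_extended(counts_quad(tab), n_restarts = 3, seed = i)$log_sigma[["nh"]]
  }, numeric(1))
  tt <- stats::t.test(ls)
  expect_gt(tt$p.value, 0.01)
  expect_lt(abs(mean(ls)), 0.06)
})

test_that("discriminability measures are exact mean differences", {
  p <- reference_extended_params()
  dm <- discriminability(p)
  expect_equal(dm$d_high, 1.50, tolerance = 1e-12)
  expect_equal(dm$d_low, 1.34, tolerance = 1e-12)
  z <- extended_params(0, 0, 0, 1, 1, 1, c(-1, -0.5, 0, 0.5, 1))
  expect_equal(discriminability(z), list(d_high = 0, d_low = 0))
})

test_that("thin conditions trigger a warning, not silence", {
  counts <- list(new_low = c(30, 20, 5, 3, 1, 1),
                 new_high = c(0, 0, 60, 0, 0, 0),
                 old_low = c(1, 2, 5, 10, 20, 22),
                 old_high = c(1, 1, 4, 8, 20, 26))
  expect_warning(fit_extended(counts, n_restarts = 2, seed = 1), "new_high")
})
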
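test_that("encoding-variability strengths have the implied moments", {
  # degenerate added strength: O inherits the baseline SD
  s0 <- encoding_variability_strengths(
    encoding_spec(0, 1, 1, 0, 0), n = 1e6, seed = 1)
  expect_equal(stats::sd(s0), 1, tolerance = 0.01)

  # independent components: variances add
  s1 <- encoding_variability_strengths(
    encoding_spec(0, 1, 1, 1, 0), n = 1e6, seed = 2)
  expect_equal(stats::sd(s1), sqrt(2), tolerance = 0.01)

  # negative B-A correlation cancels part of the added variance
  s2 <- encoding_variability_strengths(
    encoding_spec(0, 1, 1, 1, -0.5), n = 1e6, seed = 3)
  expect_equal(stats::var(s2), 1 + 1 + 2 * (-0.5), tolerance = 0.01)

  expect_error(encoding_spec(rho = 1.5), "rho")
})

test_that("simulated ratings are reproducible and match model frequencies", {
  p <- uvsd_params(1, 1.3, c(-1, -0.4, 0.2, 0.9, 1.6))
  t1 <- simulate_ratings(p, 60, seed = 9)
  t2 <- simulate_ratings(p, 60, seed = 9)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 120L)

  big <- simulate_ratings(p, 2e5, seed = 10)
  cp <- counts_pair(big)
  for (it in c("old", "new")) {
    probs <- category_probs(p, it)
    obs <- cp[[it]] / sum(cp[[it]])
    se <- sqrt(probs * (1 - probs) / 2e5)
    expect_true(all(abs(obs - probs) <= 3.5 * se + 1e-12))
  }
})

test_that("factorial experiment emulation has the 2x2 block structure", {
  d1 <- design_spec(experiment = 1, participants = 3, seed = 21)
  tr <- simulate_experiment(d1)
  expect_equal(nrow(tr), 3 * 4 * 120)
  tab <- table(tr$strength_cond, tr$variability_cond, tr$item_type)
  expect_true(all(tab == 3 * 60))
  # deterministic given the design seed
  expect_identical(tr, simulate_experiment(d1))
})

test_that("mixed-list emulation yields 120 study items and 240 test trials", {
  tr <- simulate_experiment(design_spec(experiment = 3, participants = 2,
                                        seed = 22))
  per <- split(tr, tr$participant_id)
  for (pp in per) {
    expect_equal(nrow(pp), 240L)
    expect_equal(sum(pp$item_type == "old"), 120L)  # the studied words
    expect_equal(sum(pp$item_type == "new"), 120L)
    expect_equal(as.vector(table(pp$variability_cond)), c(120L, 120L))
  }
})

test_that("synthetic lexicons hit their moment and correlation targets", {
  lex <- generate_lexicon(1e4, seed = 31)
  tg <- lexicon_targets("high")
  expect_equal(mean(lex$frequency), tg$means[["frequency"]], tolerance = 0.02)
  expect_equal(stats::sd(lex$frequency), tg$sds[["frequency"]],
               tolerance = 0.02)
  expect_equal(stats::cor(lex$frequency, lex$concreteness),
               tg$corr["frequency", "concreteness"], tolerance = 0.03)
  expect_true(all(lex$length >= 4 & lex$length <= 10))

  strong <- generate_lexicon(
    1e4, corr = matrix(c(1, -0.8, 0, -0.8, 1, 0, 0, 0, 1), 3, 3), seed = 32)
  expect_equal(stats::cor(strong$frequency, strong$concreteness), -0.8,
               tolerance = 0.03)

  fixed <- generate_lexicon(100, length_policy = list(type = "fixed", value = 7),
                            seed = 33)
  expect_true(all(fixed$length == 7))

  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(generate_lexicon(10, corr = bad), "positive-definite")
})

test_that("strength-scaling generation is recovered by per-participant fits", {
  # participants with heterogeneous d on an exact linear law: regressing
  # fitted sigma_o on fitted d at large trial counts recovers the law
  law <- scaling_law(0.8, 0.25)
  set.seed(41)
  est <- t(vapply(1:40, function(i) {
    d <- stats::runif(1, 0.4, 2.2)
    gen <- uvsd_params(d, scaling_sigma(law, d), c(-1.1, -0.2, 0.5, 1.1, 1.9))
    cp <- counts_pair(simulate_ratings(gen, 4000, seed = 800 + i))
    f <- fit_uvsd(cp$old, cp$new, n_restarts = 3, seed = i)
    c(f$estimates$d, f$estimates$sigma_o)
  }, numeric(2)))
  co <- stats::coef(stats::lm(est[, 2] ~ est[, 1]))
  expect_lt(abs(co[[2]] - 0.25), 0.03)
  expect_lt(abs(co[[1]] - 0.8), 0.06)
})

test_that("recovery studies summarise bias, RMSE, and correlation", {
  rep_small <- recovery_study(data.frame(d = c(0.8, 1.6),
                                         sigma_o = c(1.1, 1.4)),
                              fit = "standard", reps = 2, n = 40, seed = 5,
                              n_restarts = 2)
  expect_true(all(is.finite(rep_small$summary$bias)))
  expect_setequal(rep_small$summary$parameter, c("d", "sigma_o"))

  # fixed sigma, varying d, large N: recovered sigma shows no trend in d
  grid <- data.frame(d = seq(0.5, 2, length.out = 4), sigma_o = 1.3)
  rs <- recovery_study(grid, fit = "standard", reps = 3, n = 2e4, seed = 6,
                       n_restarts = 3)
  det <- rs$details[rs$details$parameter == "sigma_o", ]
  gen_d <- grid$d[det$grid_row]
  fit <- stats::lm(det$recovered ~ gen_d)
  ci <- stats::confint(fit)["gen_d", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})
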
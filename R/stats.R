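#' Manipulation-check regression
#'
#' Ordinary least squares of recognition confidence ratings on the four
#' item characteristics (word frequency, concreteness, age of acquisition,
#' word length) with an intercept, for one participant x condition (x item
#' type) cell. The overall F test and R-squared quantify how much of the
#' rating variance the manipulated characteristics carry.
#'
#' @param data Data frame with the response and predictor columns.
#' @param predictors Predictor column names.
#' @param response Response column name (default `"rating"`).
#' @return Object of class `regression_result`: list with `coefficients`,
#'   `r2`, `F`, `df1`, `df2`, `p`, `n`.
#' @export
manipulation_check_regression <- function(data,
                                          predictors = c("frequency",
                                                         "concreteness",
                                                         "aoa", "length"),
                                          response = "rating") {
  stopifnot(is.data.frame(data), all(c(response, predictors) %in% names(data)))
  n <- nrow(data)
  p <- length(predictors)
  if (n < p + 6) {
    stop(sprintf("need at least %d rows (6 more than predictors); got %d",
                 p + 6, n), call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(data[, predictors, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient predictors: %s (constant or collinear)",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  fml <- stats::reformulate(predictors, response = response)
  fit <- stats::lm(fml, data = data)
  tss <- sum((data[[response]] - mean(data[[response]]))^2)
  if (tss == 0) {
    stop(sprintf("response '%s' has zero variance", response), call. = FALSE)
  }
  rss <- sum(stats::resid(fit)^2)
  r2 <- 1 - rss / tss
  df1 <- p; df2 <- n - p - 1
  Fstat <- (r2 / df1) / ((1 - r2) / df2)
  structure(list(coefficients = stats::coef(fit),
                 r2 = r2, F = Fstat, df1 = df1, df2 = df2,
                 p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
                 n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS manipulation check: R2 = %.3f, F(%g, %g) = %.2f, p = %.4g\n",
              x$r2, x$df1, x$df2, x$F, x$p))
  invisible(x)
}

# Greenhouse-Geisser epsilon from the conditions' sample covariance matrix:
# double-centre S, then eps = tr(S~)^2 / ((k-1) * sum(S~^2)).
gg_epsilon <- function(mat) {
  S <- stats::cov(mat)
  k <- ncol(S)
  Sc <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
}

#' Repeated-measures ANOVA (within-subjects)
#'
#' Two designs:
#'
#' * `"2x2"`: a 2x2 within-subjects factorial. Columns must be ordered
#'   (A-high/B-high, A-high/B-low, A-low/B-high, A-low/B-low). Each effect
#'   (two main effects and the interaction) is tested on (1, n-1) df; the
#'   effect F equals the squared paired-t statistic of the corresponding
#'   contrast.
#' * `"oneway"`: one within-subjects factor with k levels, with a
#'   Greenhouse-Geisser sphericity correction (epsilon estimated from the
#'   sample covariance of the conditions; both df are multiplied by it).
#'
#' Partial eta squared is `SS_effect / (SS_effect + SS_error)`.
#'
#' @param mat Numeric matrix, participants in rows, conditions in columns.
#' @param design `"2x2"` or `"oneway"`.
#' @param factor_names For `"2x2"`, names of the two factors.
#' @return Data frame with one row per effect: `effect`, `F`, `df1`, `df2`,
#'   `p`, `pes`, `epsilon`.
#' @export
rm_anova <- function(mat, design = c("2x2", "oneway"),
                     factor_names = c("A", "B")) {
  design <- match.arg(design)
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing cells are not allowed (no imputation)", call. = FALSE)
  n <- nrow(mat)
  if (n < 2) stop("need at least 2 participants", call. = FALSE)

  if (design == "2x2") {
    if (ncol(mat) != 4) stop("2x2 design needs exactly 4 columns", call. = FALSE)
    contrasts <- list(c(1, 1, -1, -1) / 2,   # factor A main effect
                      c(1, -1, 1, -1) / 2,   # factor B main effect
                      c(1, -1, -1, 1) / 2)   # interaction
    labels <- c(factor_names[1], factor_names[2],
                paste(factor_names, collapse = ":"))
    rows <- lapply(seq_along(contrasts), function(i) {
      cvals <- drop(mat %*% contrasts[[i]])
      v <- stats::var(cvals)
      tstat <- if (v > 0) mean(cvals) / sqrt(v / n) else 0
      Fstat <- tstat^2
      data.frame(effect = labels[i], F = Fstat, df1 = 1, df2 = n - 1,
                 p = stats::pf(Fstat, 1, n - 1, lower.tail = FALSE),
                 pes = Fstat / (Fstat + (n - 1)), epsilon = NA_real_,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  } else {
    k <- ncol(mat)
    if (k < 2) stop("one-way design needs at least 2 conditions", call. = FALSE)
    grand <- mean(mat)
    ss_cond <- n * sum((colMeans(mat) - grand)^2)
    resid <- mat - outer(rowMeans(mat), rep(1, k)) -
      outer(rep(1, n), colMeans(mat)) + grand
    ss_err <- sum(resid^2)
    eps <- gg_epsilon(mat)
    df1 <- (k - 1) * eps
    df2 <- (n - 1) * (k - 1) * eps
    Fstat <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
    out <- data.frame(effect = "condition", F = Fstat, df1 = df1, df2 = df2,
                      p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
                      pes = ss_cond / (ss_cond + ss_err), epsilon = eps,
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Paired or one-sample t test with effect size
#'
#' Two-sided t test with 95 percent confidence interval and the
#' standardised effect size d_z (mean difference divided by the SD of the
#' differences; for one-sample, mean deviation from `mu` over the sample
#' SD).
#'
#' @param x Numeric vector.
#' @param y Second vector (paired mode).
#' @param mu Null value (one-sample mode).
#' @param mode `"paired"` or `"one-sample"`.
#' @return Object of class `t_result`: `t`, `df`, `p`, `ci` (length 2),
#'   `d_z`, `mean`.
#' @export
t_test <- function(x, y = NULL, mu = 0, mode = c("paired", "one-sample")) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    if (is.null(y) || length(y) != length(x)) {
      stop("paired mode needs 'y' of the same length as 'x'", call. = FALSE)
    }
    diffs <- x - y
  } else {
    diffs <- x - mu
  }
  if (length(diffs) < 2) stop("need n >= 2", call. = FALSE)
  if (stats::sd(diffs) == 0) {
    stop("zero variance of the (differenced) sample; t is undefined",
         call. = FALSE)
  }
  ht <- if (mode == "paired") stats::t.test(x, y, paired = TRUE) else
    stats::t.test(x, mu = mu)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, ci = unname(ht$conf.int),
                 d_z = mean(diffs) / stats::sd(diffs), mean = mean(diffs)),
            class = "t_result")
}

#' @export
print.t_result <- function(x, ...) {
  cat(sprintf("t(%g) = %.3f, p = %.4g, 95%% CI [%.3f, %.3f], d_z = %.3f\n",
              x$df, x$t, x$p, x$ci[1], x$ci[2], x$d_z))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` elementwise, for a family of `m` comparisons.
#'
#' @param p Vector of p values.
#' @param m Family size (>= `length(p)`).
#' @return Adjusted p values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1), m >= length(p))
  pmin(1, m * p)
}

#' Sequential polynomial fits of the strength-scaling curve
#'
#' Fits the three nested scaling models sigma_o = y + b1 d,
#' + b2 d^2, + b3 d^3 to participant-level (d, sigma_o) estimate pairs and
#' compares them sequentially with extra-sum-of-squares F tests. The
#' selected model is the most complex whose added term is significant at
#' `alpha`, otherwise the linear model.
#'
#' @param d Vector of discriminability estimates.
#' @param sigma_o Vector of old-item SD estimates (same length).
#' @param alpha Significance level for the sequential comparisons.
#' @return Object of class `scaling_fit`: list with `models` (per model:
#'   coefficients and R2), `comparisons` (added term, F, df, p), and
#'   `selected` (`"linear"`, `"quadratic"`, or `"cubic"`).
#' @export
sequential_scaling_fit <- function(d, sigma_o, alpha = 0.05) {
  stopifnot(length(d) == length(sigma_o))
  if (length(d) < 5) stop("need at least 5 (d, sigma_o) pairs", call. = FALSE)
  dat <- data.frame(d = d, sigma_o = sigma_o)
  m1 <- stats::lm(sigma_o ~ d, data = dat)
  m2 <- stats::lm(sigma_o ~ d + I(d^2), data = dat)
  m3 <- stats::lm(sigma_o ~ d + I(d^2) + I(d^3), data = dat)
  tss <- sum((sigma_o - mean(sigma_o))^2)
  r2 <- function(m) 1 - sum(stats::resid(m)^2) / tss
  # pairwise extra-sum-of-squares tests: each added term against the
  # residual mean square of the larger model in that comparison
  pair_f <- function(small, big) {
    rss_s <- sum(stats::resid(small)^2)
    rss_b <- sum(stats::resid(big)^2)
    Fstat <- (rss_s - rss_b) / (rss_b / big$df.residual)
    list(F = Fstat,
         p = stats::pf(Fstat, 1, big$df.residual, lower.tail = FALSE),
         df2 = big$df.residual,
         # guard: improvements at numerical-noise level (perfect fits)
         # carry no evidence for the added term
         real = (rss_s - rss_b) > 1e-10 * max(tss, 1e-12))
  }
  c12 <- pair_f(m1, m2); c23 <- pair_f(m2, m3)
  comparisons <- data.frame(
    added_term = c("quadratic", "cubic"),
    F = c(c12$F, c23$F), df1 = c(1, 1), df2 = c(c12$df2, c23$df2),
    p = c(c12$p, c23$p), stringsAsFactors = FALSE)
  sig <- function(cc) isTRUE(is.finite(cc$p) && cc$p < alpha && cc$real)
  selected <- if (sig(c23)) "cubic" else if (sig(c12)) "quadratic" else
    "linear"
  structure(list(models = list(linear = list(coefficients = stats::coef(m1),
                                             r2 = r2(m1)),
                               quadratic = list(coefficients = stats::coef(m2),
                                                r2 = r2(m2)),
                               cubic = list(coefficients = stats::coef(m3),
                                            r2 = r2(m3))),
                 comparisons = comparisons, selected = selected,
                 alpha = alpha),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  co <- x$models$linear$coefficients
  cat(sprintf("Scaling fit: selected %s model; linear sigma_o = %.3f + %.3f d (R2 = %.3f)\n",
              x$selected, co[1], co[2], x$models$linear$r2))
  invisible(x)
}

#' Minimum detectable paired-samples effect size
#'
#' The effect size d_z whose two-sided paired t test at level `alpha`
#' reaches the target power with `n` pairs, from the exact noncentral-t
#' power function at df = n - 1. Monotone decreasing in n; e.g. 72 pairs
#' detect d_z = 0.33 at 80 percent power and alpha = .05.
#'
#' @param n Number of pairs (>= 3).
#' @param alpha Two-sided significance level.
#' @param power Target power, in (0, 1).
#' @return The minimum detectable d_z.
#' @export
min_detectable_dz <- function(n, alpha = 0.05, power = 0.80) {
  stopifnot(n >= 3, alpha > 0, alpha < 1, power > 0, power < 1)
  res <- tryCatch(
    stats::power.t.test(n = n, sig.level = alpha, power = power,
                        type = "paired", alternative = "two.sided", sd = 1),
    error = function(e) stop("power target unattainable for these settings",
                             call. = FALSE))
  res$delta
}
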
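#' UVSD model parameters
#'
#' Parameter record for the unequal-variance signal detection (UVSD) model of
#' recognition confidence ratings. Memory strength is Gaussian on a latent
#' axis: new items are N(0, 1) (the fixed reference), old items are
#' N(d, sigma_o^2). Five strictly increasing decision criteria partition the
#' axis into the six confidence categories of the scale
#' "1 Sure New ... 6 Sure Old".
#'
#' @param d Old-item mean strength (the discriminability parameter); the new
#'   mean is fixed at 0.
#' @param sigma_o Old-item strength standard deviation (> 0); the new SD is
#'   fixed at 1, so `sigma_o` is also the old/new SD ratio.
#' @param criteria Numeric vector of 5 strictly increasing decision criteria
#'   C1 < ... < C5 on the strength axis.
#' @return An object of class `uvsd_params`.
#' @examples
#' uvsd_params(d = 1, sigma_o = 1.3, criteria = c(-1, -0.5, 0.25, 0.9, 1.6))
#' @export
uvsd_params <- function(d, sigma_o, criteria) {
  stopifnot(is.numeric(d), length(d) == 1L, is.finite(d))
  if (!is.numeric(sigma_o) || length(sigma_o) != 1L || !is.finite(sigma_o) ||
      sigma_o <= 0) {
    stop("'sigma_o' must be a single finite value > 0", call. = FALSE)
  }
  check_criteria(criteria)
  structure(list(d = d, sigma_o = sigma_o, criteria = as.numeric(criteria)),
            class = "uvsd_params")
}

check_criteria <- function(criteria) {
  if (!is.numeric(criteria) || length(criteria) != 5L || !all(is.finite(criteria))) {
    stop("'criteria' must be 5 finite values", call. = FALSE)
  }
  if (any(diff(criteria) <= 0)) {
    stop("'criteria' must be strictly increasing (C1 < C2 < ... < C5)",
         call. = FALSE)
  }
  invisible(criteria)
}

#' @export
print.uvsd_params <- function(x, ...) {
  cat("UVSD parameters\n")
  cat(sprintf("  d = %.4f, sigma_o = %.4f (sigma_n fixed at 1)\n", x$d, x$sigma_o))
  cat("  criteria:", paste(sprintf("%.4f", x$criteria), collapse = ", "), "\n")
  invisible(x)
}

# Probability of each rating category for a Gaussian strength distribution
# N(mu, sigma^2) cut at the criteria: P(k) = Phi((C_k - mu)/sigma) -
# Phi((C_{k-1} - mu)/sigma), with C_0 = -Inf, C_6 = +Inf.
cat_probs <- function(mu, sigma, criteria) {
  diff(c(0, stats::pnorm((criteria - mu) / sigma), 1))
}

#' Rating-category probabilities under the UVSD model
#'
#' The six-category multinomial distribution implied by the model for one
#' item type: category k has probability
#' \eqn{\Phi((C_k-\mu)/\sigma) - \Phi((C_{k-1}-\mu)/\sigma)} with
#' \eqn{C_0=-\infty}, \eqn{C_6=+\infty}, where \eqn{(\mu,\sigma)} is (0, 1)
#' for new items and (d, sigma_o) for old items.
#'
#' @param params Model parameters (`uvsd_params` or `uvsd_extended_params`).
#' @param item_type `"old"` or `"new"` (standard model).
#' @param ... Passed to methods.
#' @return Numeric vector of 6 probabilities summing to 1.
#' @export
category_probs <- function(params, ...) UseMethod("category_probs")

#' @rdname category_probs
#' @export
category_probs.uvsd_params <- function(params, item_type = c("old", "new"), ...) {
  item_type <- match.arg(item_type)
  if (item_type == "old") {
    cat_probs(params$d, params$sigma_o, params$criteria)
  } else {
    cat_probs(0, 1, params$criteria)
  }
}

#' ROC operating points (hit and false-alarm rates at each criterion)
#'
#' Cumulative "old"-response rates at confidence criteria i = 1..5:
#' \eqn{H_i = P(rating \ge i+1 | old)}, \eqn{FA_i = P(rating \ge i+1 | new)}.
#' In population mode (model parameters) these are
#' \eqn{H_i = \Phi((d - C_i)/\sigma_o)} and \eqn{FA_i = \Phi(-C_i)};
#' from counts they are empirical proportions.
#'
#' @param x `uvsd_params` (population mode) or a 6-vector of old-item rating
#'   counts (empirical mode; supply `n_new`).
#' @param n_new 6-vector of new-item rating counts (empirical mode).
#' @param ... Unused.
#' @return List with components `hit` and `fa`, each of length 5 and
#'   non-increasing in i.
#' @export
operating_points <- function(x, ...) UseMethod("operating_points")

#' @rdname operating_points
#' @export
operating_points.uvsd_params <- function(x, ...) {
  list(hit = stats::pnorm((x$d - x$criteria) / x$sigma_o),
       fa  = stats::pnorm(-x$criteria))
}

#' @rdname operating_points
#' @export
operating_points.default <- function(x, n_new, ...) {
  n_old <- check_counts(x, "n_old")
  n_new <- check_counts(n_new, "n_new")
  if (sum(n_old) == 0 || sum(n_new) == 0) {
    stop("operating points need at least one trial of each item type",
         call. = FALSE)
  }
  upper_cum <- function(n) rev(cumsum(rev(n)))[2:6] / sum(n)
  list(hit = upper_cum(n_old), fa = upper_cum(n_new))
}

#' Multinomial log-likelihood of rating counts under the UVSD model
#'
#' \eqn{\sum_k n^{old}_k \log p^{old}_k + \sum_k n^{new}_k \log p^{new}_k},
#' the kernel of the product-multinomial likelihood maximised when fitting.
#' Category probabilities are floored at `eps` inside the log so that
#' zero-probability cells with zero counts stay finite.
#'
#' @param params `uvsd_params`.
#' @param n_old,n_new 6-vectors of rating counts for old and new items.
#' @param eps Probability floor (default 1e-10).
#' @return Log-likelihood (<= 0 for any count data).
#' @export
log_likelihood <- function(params, n_old, n_new, eps = 1e-10) {
  stopifnot(inherits(params, "uvsd_params"))
  n_old <- check_counts(n_old, "n_old")
  n_new <- check_counts(n_new, "n_new")
  ll_counts(n_old, params$d, params$sigma_o, params$criteria, eps) +
    ll_counts(n_new, 0, 1, params$criteria, eps)
}

ll_counts <- function(n, mu, sigma, criteria, eps) {
  p <- pmax(cat_probs(mu, sigma, criteria), eps)
  sum(n * log(p))
}

# ---- Fitting ----------------------------------------------------------------

# Internal parameterisation: theta = (d, log sigma_o, C1, log diff(C)).
# The log-increments guarantee strictly ordered criteria for any real theta.
theta_to_params <- function(theta) {
  criteria <- cumsum(c(theta[3], exp(theta[4:7])))
  list(d = theta[1], sigma_o = exp(theta[2]), criteria = criteria)
}

params_to_theta <- function(d, sigma_o, criteria) {
  c(d, log(sigma_o), criteria[1], log(diff(criteria)))
}

# z-ROC based starting values: with half-count-corrected rates, the probit
# identity z(H) = d/sigma + z(FA)/sigma gives d and sigma from an OLS line,
# and FA_i = Phi(-C_i) gives the criteria.
zroc_start <- function(n_sig, n_ref) {
  rate <- function(n) {
    cum <- rev(cumsum(rev(n)))[2:6]
    pmin(pmax(cum, 0.5), sum(n) - 0.5) / sum(n)
  }
  zf <- stats::qnorm(rate(n_ref))
  zh <- stats::qnorm(rate(n_sig))
  slope <- if (stats::var(zf) > 0) stats::cov(zf, zh) / stats::var(zf) else 1
  slope <- min(max(slope, 0.2), 5)
  sigma <- 1 / slope
  d <- (mean(zh) - slope * mean(zf)) * sigma
  crit <- -zf
  # enforce strict ordering for degenerate empirical rates
  crit <- cummax(crit) + 0.05 * (seq_len(5) - 1) * (diff(range(crit)) < 1e-8)
  for (i in 2:5) if (crit[i] <= crit[i - 1]) crit[i] <- crit[i - 1] + 0.05
  list(d = d, sigma_o = sigma, criteria = crit)
}

check_identifiable <- function(n_old, n_new) {
  if (sum(n_old) == 0 || sum(n_new) == 0) {
    stop("both item types must have at least one trial", call. = FALSE)
  }
  occupied <- (n_old + n_new) > 0
  if (sum(occupied) < 2) {
    stop("non-identifiable data: all responses fall in a single rating category",
         call. = FALSE)
  }
  if (sum(n_old > 0) == 1 && sum(n_new > 0) == 1) {
    stop(paste("non-identifiable data: each item type occupies a single rating",
               "category, so d and sigma_o are unbounded (perfect separation)"),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit the UVSD model to rating counts by maximum likelihood
#'
#' Maximises the product-multinomial likelihood of old and new 6-category
#' rating counts over (d, sigma_o, C1..C5). Optimisation is unconstrained in
#' an internal parameterisation (log sigma_o; first criterion plus log
#' increments), multi-started from a z-ROC heuristic plus seeded jittered
#' restarts, and deterministic given `seed`.
#'
#' @param n_old,n_new 6-vectors of rating counts (ratings 1-6) for old and
#'   new items.
#' @param n_restarts Number of optimiser starts (default 10; the first is the
#'   z-ROC heuristic, the rest are jittered).
#' @param seed Integer seed controlling restart jitter.
#' @param eps Probability floor inside the log-likelihood.
#' @param control Passed to [stats::nlminb()].
#' @return An object of class `uvsd_fit`: list with `estimates`
#'   (`uvsd_params`), `logL`, `log_sigma_o`, `converged`, `restarts_used`.
#' @examples
#' p <- uvsd_params(1, 1.3, c(-1, -0.5, 0.25, 0.9, 1.6))
#' n_old <- round(1000 * category_probs(p, "old"))
#' n_new <- round(1000 * category_probs(p, "new"))
#' fit_uvsd(n_old, n_new, seed = 1)
#' @export
fit_uvsd <- function(n_old, n_new, n_restarts = 10, seed = 1, eps = 1e-10,
                     control = list(iter.max = 500, eval.max = 1000)) {
  n_old <- check_counts(n_old, "n_old")
  n_new <- check_counts(n_new, "n_new")
  check_identifiable(n_old, n_new)

  negll <- function(theta) {
    cr <- cumsum(c(theta[3], exp(theta[4:7])))
    -(ll_counts(n_old, theta[1], exp(theta[2]), cr, eps) +
        ll_counts(n_new, 0, 1, cr, eps))
  }

  st <- zroc_start(n_old, n_new)
  theta0 <- params_to_theta(st$d, st$sigma_o, st$criteria)
  best <- run_restarts(negll, theta0, n_restarts, seed)

  pp <- theta_to_params(best$par)
  est <- uvsd_params(pp$d, pp$sigma_o, pp$criteria)
  structure(list(estimates = est,
                 logL = -best$objective,
                 log_sigma_o = log(est$sigma_o),
                 converged = best$converged,
                 restarts_used = n_restarts),
            class = "uvsd_fit")
}

# Shared multi-start driver: first start as given, remaining starts jittered.
run_restarts <- function(negll, theta0, n_restarts, seed,
                         control = list(iter.max = 500, eval.max = 1000)) {
  stopifnot(n_restarts >= 1)
  starts <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(i) {
      if (i == 1) theta0 else theta0 + stats::rnorm(length(theta0), 0, 0.3)
    })
  })
  best <- NULL
  any_converged <- FALSE
  for (s in starts) {
    res <- tryCatch(stats::nlminb(s, negll, control = control),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    if (res$convergence == 0) any_converged <- TRUE
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) {
    stop("optimisation failed from every start; data may be degenerate",
         call. = FALSE)
  }
  best$converged <- any_converged
  if (!any_converged) {
    warning("no optimiser start reported convergence; returning best value found",
            call. = FALSE)
  }
  best
}

#' @export
print.uvsd_fit <- function(x, ...) {
  cat("UVSD maximum-likelihood fit\n")
  print(x$estimates)
  cat(sprintf("  logL = %.4f, log(sigma_o) = %.4f, converged: %s (%d starts)\n",
              x$logL, x$log_sigma_o, x$converged, x$restarts_used))
  invisible(x)
}
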
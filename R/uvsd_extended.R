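#' Four-distribution UVSD parameters for mixed-list designs
#'
#' Extension of the UVSD model for a single study/test block in which both
#' old and new items come in two item-characteristic variability sub-lists
#' (high, low). Each of the four conditions (new-low, new-high, old-low,
#' old-high) has its own Gaussian strength distribution; the new-low
#' distribution is the fixed reference (mean 0, SD 1) and a single set of
#' five decision criteria is shared by all conditions, since every item is
#' judged in the same test phase.
#'
#' @param mu_nh,mu_ol,mu_oh Means of the new-high, old-low, old-high
#'   distributions (new-low mean fixed at 0).
#' @param sigma_nh,sigma_ol,sigma_oh SDs (> 0) of the three free
#'   distributions (new-low SD fixed at 1).
#' @param criteria 5 strictly increasing shared decision criteria.
#' @return Object of class `uvsd_extended_params`.
#' @export
extended_params <- function(mu_nh, mu_ol, mu_oh,
                            sigma_nh, sigma_ol, sigma_oh, criteria) {
  mus <- c(mu_nh, mu_ol, mu_oh)
  sds <- c(sigma_nh, sigma_ol, sigma_oh)
  stopifnot(is.numeric(mus), length(mus) == 3L, all(is.finite(mus)))
  if (!is.numeric(sds) || length(sds) != 3L || !all(is.finite(sds)) ||
      any(sds <= 0)) {
    stop("all standard deviations must be finite and > 0", call. = FALSE)
  }
  check_criteria(criteria)
  structure(list(mu_nh = mu_nh, mu_ol = mu_ol, mu_oh = mu_oh,
                 sigma_nh = sigma_nh, sigma_ol = sigma_ol, sigma_oh = sigma_oh,
                 mu_nl = 0, sigma_nl = 1,
                 criteria = as.numeric(criteria)),
            class = "uvsd_extended_params")
}

#' @export
print.uvsd_extended_params <- function(x, ...) {
  cat("Extended (four-distribution) UVSD parameters\n")
  cat(sprintf("  mu:    nl = 0 (fixed), nh = %.4f, ol = %.4f, oh = %.4f\n",
              x$mu_nh, x$mu_ol, x$mu_oh))
  cat(sprintf("  sigma: nl = 1 (fixed), nh = %.4f, ol = %.4f, oh = %.4f\n",
              x$sigma_nh, x$sigma_ol, x$sigma_oh))
  cat("  criteria:", paste(sprintf("%.4f", x$criteria), collapse = ", "), "\n")
  invisible(x)
}

extended_conditions <- c("new_low", "new_high", "old_low", "old_high")

condition_moments <- function(params, condition) {
  switch(condition,
         new_low  = c(params$mu_nl, params$sigma_nl),
         new_high = c(params$mu_nh, params$sigma_nh),
         old_low  = c(params$mu_ol, params$sigma_ol),
         old_high = c(params$mu_oh, params$sigma_oh),
         stop(sprintf("unknown condition '%s'", condition), call. = FALSE))
}

#' @rdname category_probs
#' @param condition For the extended model, one of `"new_low"`, `"new_high"`,
#'   `"old_low"`, `"old_high"`.
#' @export
category_probs.uvsd_extended_params <- function(params, condition, ...) {
  condition <- match.arg(condition, extended_conditions)
  m <- condition_moments(params, condition)
  cat_probs(m[1], m[2], params$criteria)
}

check_extended_counts <- function(counts) {
  if (!is.list(counts)) {
    stop("'counts' must be a named list of four 6-vectors", call. = FALSE)
  }
  missing <- setdiff(extended_conditions, names(counts))
  if (length(missing)) {
    stop(sprintf("missing condition counts: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  lapply(stats::setNames(extended_conditions, extended_conditions),
         function(cc) check_counts(counts[[cc]], cc))
}

#' Joint log-likelihood of the four-distribution UVSD model
#'
#' Sum of four multinomial log-likelihoods, one per condition, each using its
#' condition's (mu, sigma) and the shared criteria.
#'
#' @param params `uvsd_extended_params`.
#' @param counts Named list with 6-vectors of rating counts for
#'   `new_low`, `new_high`, `old_low`, `old_high`.
#' @param eps Probability floor inside the log.
#' @return Scalar log-likelihood.
#' @export
extended_log_likelihood <- function(params, counts, eps = 1e-10) {
  stopifnot(inherits(params, "uvsd_extended_params"))
  counts <- check_extended_counts(counts)
  sum(vapply(extended_conditions, function(cc) {
    m <- condition_moments(params, cc)
    ll_counts(counts[[cc]], m[1], m[2], params$criteria, eps)
  }, numeric(1)))
}

#' Fit the four-distribution UVSD model
#'
#' Joint maximum-likelihood estimation of the 11 free parameters (3 means,
#' 3 log-scale SDs, 5 ordered shared criteria) from the four conditions'
#' rating counts. Multi-start and deterministic given `seed`, as
#' [fit_uvsd()].
#'
#' @inheritParams extended_log_likelihood
#' @inheritParams fit_uvsd
#' @return Object of class `uvsd_extended_fit`: `estimates`
#'   (`uvsd_extended_params`), `logL`, `log_sigma` (named log-scale SDs),
#'   `converged`, `restarts_used`.
#' @export
fit_extended <- function(counts, n_restarts = 10, seed = 1, eps = 1e-10) {
  counts <- check_extended_counts(counts)
  check_identifiable(counts$old_low + counts$old_high,
                     counts$new_low + counts$new_high)
  thin <- names(counts)[vapply(counts, function(n) sum(n > 0) < 2, logical(1))]
  if (length(thin)) {
    warning(sprintf("condition(s) with fewer than 2 occupied rating categories: %s",
                    paste(thin, collapse = ", ")), call. = FALSE)
  }

  # theta = (mu_nh, mu_ol, mu_oh, log s_nh, log s_ol, log s_oh, C1, log dC 2..5)
  negll <- function(theta) {
    cr <- cumsum(c(theta[7], exp(theta[8:11])))
    -(ll_counts(counts$new_low, 0, 1, cr, eps) +
        ll_counts(counts$new_high, theta[1], exp(theta[4]), cr, eps) +
        ll_counts(counts$old_low, theta[2], exp(theta[5]), cr, eps) +
        ll_counts(counts$old_high, theta[3], exp(theta[6]), cr, eps))
  }

  # Starts: criteria from the reference condition's rates; each free
  # condition's (mu, sigma) from its z-ROC line against new_low.
  ref <- counts$new_low
  if (sum(ref) == 0) ref <- counts$new_high
  st_nh <- zroc_start(counts$new_high, ref)
  st_ol <- zroc_start(counts$old_low, ref)
  st_oh <- zroc_start(counts$old_high, ref)
  theta0 <- c(st_nh$d, st_ol$d, st_oh$d,
              log(c(st_nh$sigma_o, st_ol$sigma_o, st_oh$sigma_o)),
              st_oh$criteria[1], log(diff(st_oh$criteria)))

  best <- run_restarts(negll, theta0, n_restarts, seed)
  th <- best$par
  cr <- cumsum(c(th[7], exp(th[8:11])))
  est <- extended_params(th[1], th[2], th[3],
                         exp(th[4]), exp(th[5]), exp(th[6]), cr)
  structure(list(estimates = est,
                 logL = -best$objective,
                 log_sigma = c(nh = th[4], ol = th[5], oh = th[6]),
                 converged = best$converged,
                 restarts_used = n_restarts),
            class = "uvsd_extended_fit")
}

#' @export
print.uvsd_extended_fit <- function(x, ...) {
  cat("Extended UVSD maximum-likelihood fit\n")
  print(x$estimates)
  cat(sprintf("  logL = %.4f, converged: %s (%d starts)\n",
              x$logL, x$converged, x$restarts_used))
  invisible(x)
}

#' Discriminability measures from extended-model estimates
#'
#' `d_high = mu_oh - mu_nh` and `d_low = mu_ol - mu_nl` (the latter equals
#' `mu_ol` because the new-low mean is fixed at 0): old-new mean strength
#' separation within each variability sub-list.
#'
#' @param params `uvsd_extended_params`.
#' @return List with `d_high` and `d_low`.
#' @export
discriminability <- function(params) {
  stopifnot(inherits(params, "uvsd_extended_params"))
  list(d_high = params$mu_oh - params$mu_nh,
       d_low = params$mu_ol - params$mu_nl)
}
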
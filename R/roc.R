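#' z-ROC points
#'
#' Probit-transformed ROC operating points: `z_fa = qnorm(FA_i)`,
#' `z_h = qnorm(H_i)` at criteria i = 1..5. Under the Gaussian model the
#' population points are exactly linear,
#' \eqn{z_H = d/\sigma_o + (1/\sigma_o) z_{FA}}, so the slope carries the SD
#' ratio \eqn{\sigma_n/\sigma_o}.
#'
#' For empirical counts, rates of exactly 0 or 1 have infinite probit; the
#' `"half-count"` correction replaces cumulative counts of 0 and N by 0.5 and
#' N - 0.5 before forming rates. The correction is descriptive only and is
#' never applied when fitting by maximum likelihood.
#'
#' @param x `uvsd_params` (population mode) or a 6-vector of old-item rating
#'   counts (empirical mode, with `n_new`).
#' @param n_new 6-vector of new-item rating counts (empirical mode).
#' @param correction `"half-count"` (default for counts) or `"none"`.
#' @param ... Unused.
#' @return Object of class `zroc_points`: list with `z_fa`, `z_h`,
#'   `correction_used`.
#' @export
zroc_points <- function(x, ...) UseMethod("zroc_points")

#' @rdname zroc_points
#' @export
zroc_points.uvsd_params <- function(x, ...) {
  # population probits in closed form (z = qnorm of the population rates,
  # but computed directly to avoid the lossy pnorm/qnorm round trip)
  structure(list(z_fa = -x$criteria, z_h = (x$d - x$criteria) / x$sigma_o,
                 correction_used = FALSE),
            class = "zroc_points")
}

#' @rdname zroc_points
#' @export
zroc_points.default <- function(x, n_new,
                                correction = c("half-count", "none"), ...) {
  correction <- match.arg(correction)
  n_old <- check_counts(x, "n_old")
  n_new <- check_counts(n_new, "n_new")
  rate <- function(n) {
    cum <- rev(cumsum(rev(n)))[2:6]
    if (correction == "half-count") cum <- pmin(pmax(cum, 0.5), sum(n) - 0.5)
    cum / sum(n)
  }
  h <- rate(n_old); fa <- rate(n_new)
  if (any(c(h, fa) <= 0) || any(c(h, fa) >= 1)) {
    stop(paste("operating-point rate of exactly 0 or 1; use",
               "correction = \"half-count\" for finite z-ROC points"),
         call. = FALSE)
  }
  structure(list(z_fa = stats::qnorm(fa), z_h = stats::qnorm(h),
                 correction_used = correction == "half-count"),
            class = "zroc_points")
}

#' z-ROC slope and intercept
#'
#' Ordinary least squares of `z_h` on `z_fa` (false-alarm rate on the
#' abscissa, the conventional plotting direction). For population points of
#' a UVSD model the slope equals \eqn{1/\sigma_o} exactly — e.g. the
#' classical slope of about 0.8 corresponds to \eqn{\sigma_o = 1.25}.
#'
#' @param points A `zroc_points` object.
#' @return List with `slope` and `intercept`.
#' @export
zroc_slope <- function(points) {
  stopifnot(inherits(points, "zroc_points"))
  zf <- points$z_fa; zh <- points$z_h
  if (length(unique(zf)) < 2L) {
    stop("z-ROC slope needs at least 2 distinct z(FA) values", call. = FALSE)
  }
  slope <- stats::cov(zf, zh) / stats::var(zf)
  list(slope = slope, intercept = mean(zh) - slope * mean(zf))
}
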
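# Independent oracles and small fixture builders used across test files.

# Category probabilities by adaptive quadrature of the Gaussian density over
# each criterion interval (independent of the closed-form pnorm difference).
quad_probs <- function(mu, sigma, criteria) {
  bounds <- c(-Inf, criteria, Inf)
  vapply(seq_len(6), function(k) {
    stats::integrate(stats::dnorm, bounds[k], bounds[k + 1],
                     mean = mu, sd = sigma, rel.tol = 1e-12)$value
  }, numeric(1))
}

# Term-by-term multinomial log-likelihood with explicit loops.
brute_loglik <- function(d, sigma_o, criteria, n_old, n_new, eps = 1e-10) {
  total <- 0
  for (item in c("old", "new")) {
    mu <- if (item == "old") d else 0
    sg <- if (item == "old") sigma_o else 1
    n <- if (item == "old") n_old else n_new
    bounds <- c(-Inf, criteria, Inf)
    for (k in 1:6) {
      p <- stats::pnorm(bounds[k + 1], mu, sg) - stats::pnorm(bounds[k], mu, sg)
      total <- total + n[k] * log(max(p, eps))
    }
  }
  total
}

# Pull the 6-vector of rating counts out of an aggregate_counts() row set.
get_counts <- function(cnt, sel) {
  i <- which(sel)
  stopifnot(length(i) == 1)
  as.numeric(unlist(cnt[i, paste0("n", 1:6)]))
}

# Counts for both item types from a simulated trial table.
counts_pair <- function(trials) {
  cnt <- aggregate_counts(trials, by = "item_type")
  list(old = get_counts(cnt, cnt$item_type == "old"),
       new = get_counts(cnt, cnt$item_type == "new"))
}

# Four-condition counts list from a mixed-list trial table.
counts_quad <- function(trials) {
  cnt <- aggregate_counts(trials, by = c("variability_cond", "item_type"))
  key <- paste(cnt$item_type, cnt$variability_cond, sep = "_")
  conds <- c("new_low", "new_high", "old_low", "old_high")
  stats::setNames(lapply(conds, function(cc) get_counts(cnt, key == cc)), conds)
}

random_uvsd_params <- function() {
  d <- stats::runif(1, 0, 2.5)
  sigma <- exp(stats::runif(1, -0.5, 0.7))
  c1 <- stats::runif(1, -2, 0)
  criteria <- cumsum(c(c1, stats::runif(4, 0.2, 0.9)))
  uvsd_params(d, sigma, criteria)
}

# A small well-formed trial table for data-model tests.
tiny_trials <- function() {
  data.frame(participant_id = c("p1", "p1", "p2", "p2"),
             experiment = "exp1",
             strength_cond = c("high", "high", "low", "low"),
             variability_cond = c("high", "low", "high", "low"),
             item_type = c("old", "new", "old", "new"),
             rating = c(6L, 1L, 4L, 3L),
             frequency = c(2.5, 3.1, 2.9, 3.3),
             concreteness = c(3.0, 3.2, 2.8, 3.1),
             aoa = c(9.8, 10.4, 11.0, 10.1),
             length = c(5L, 7L, 6L, 7L),
             stringsAsFactors = FALSE)
}
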
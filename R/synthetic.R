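#' Encoding-variability specification
#'
#' The encoding-variability account of the old-item variance effect: every
#' studied item starts from a baseline strength \eqn{B \sim N(\mu_b,
#' \sigma_b^2)} (the new-item distribution) and gains an added strength
#' \eqn{A \sim N(\mu_a, \sigma_a^2)} at study, giving the old-item strength
#' \eqn{O = B + A}. `rho` is the correlation between B and A; a negative
#' value encodes the idea that already-strong items gain less.
#'
#' @param mu_baseline,sigma_baseline Baseline strength mean and SD
#'   (defaults 0 and 1, the new-item reference).
#' @param mu_added,sigma_added Added strength mean and SD.
#' @param rho Correlation between baseline and added strength, in [-1, 1].
#' @return Object of class `encoding_spec`.
#' @export
encoding_spec <- function(mu_baseline = 0, sigma_baseline = 1,
                          mu_added = 1, sigma_added = 0.5, rho = 0) {
  stopifnot(is.finite(mu_baseline), is.finite(mu_added))
  if (sigma_baseline < 0 || sigma_added < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (!is.finite(rho) || abs(rho) > 1) {
    stop("'rho' must be a correlation in [-1, 1]", call. = FALSE)
  }
  structure(list(mu_baseline = mu_baseline, sigma_baseline = sigma_baseline,
                 mu_added = mu_added, sigma_added = sigma_added, rho = rho),
            class = "encoding_spec")
}

# Implied SD of O = B + A.
encoding_sigma_o <- function(spec) {
  with(spec, sqrt(sigma_baseline^2 + sigma_added^2 +
                    2 * rho * sigma_baseline * sigma_added))
}

#' Draw old-item strengths under the encoding-variability account
#'
#' Samples (B, A) from a bivariate normal with correlation `rho` and returns
#' O = B + A.
#'
#' @param spec An [encoding_spec()].
#' @param n Number of items.
#' @param seed Optional integer seed.
#' @return Numeric vector of n strengths.
#' @export
encoding_variability_strengths <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "encoding_spec"), n >= 1)
  with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    b <- spec$mu_baseline + spec$sigma_baseline * z1
    a <- spec$mu_added +
      spec$sigma_added * (spec$rho * z1 + sqrt(1 - spec$rho^2) * z2)
    b + a
  })
}

#' Strength-scaling law
#'
#' Polynomial relation between old-item SD and discriminability:
#' \eqn{\sigma_o = y + b_1 d (+ b_2 d^2 + b_3 d^3)}. The linear form with a
#' small intercept and slope around 0.2 is the empirical regularity the
#' package's curve-fitting analysis targets.
#'
#' @param intercept Intercept y.
#' @param b1,b2,b3 Linear, quadratic, cubic coefficients.
#' @return Object of class `scaling_law`, callable via [scaling_sigma()].
#' @export
scaling_law <- function(intercept, b1, b2 = 0, b3 = 0) {
  stopifnot(is.finite(intercept), is.finite(b1), is.finite(b2), is.finite(b3))
  structure(list(intercept = intercept, b1 = b1, b2 = b2, b3 = b3),
            class = "scaling_law")
}

#' @rdname scaling_law
#' @param law A `scaling_law`.
#' @param d Discriminability value(s).
#' @export
scaling_sigma <- function(law, d) {
  stopifnot(inherits(law, "scaling_law"))
  law$intercept + law$b1 * d + law$b2 * d^2 + law$b3 * d^3
}

rating_from_strength <- function(strength, criteria) {
  findInterval(strength, criteria) + 1L
}

#' Simulate confidence ratings from model parameters
#'
#' Draws each trial's rating from the model-implied 6-category distribution
#' (latent Gaussian strength cut at the criteria). For standard parameters
#' this produces `n` old and `n` new trials; for extended parameters, `n`
#' trials in each of the four conditions.
#'
#' @param params `uvsd_params` or `uvsd_extended_params`.
#' @param n Trials per condition per item type.
#' @param seed Optional integer seed (same seed, same table).
#' @param participant_id Participant label attached to the rows.
#' @return A trial data frame (canonical columns).
#' @export
simulate_ratings <- function(params, n, seed = NULL, participant_id = "p1") {
  UseMethod("simulate_ratings")
}

#' @export
simulate_ratings.uvsd_params <- function(params, n, seed = NULL,
                                         participant_id = "p1") {
  stopifnot(n >= 1)
  with_seed(seed, {
    s_old <- stats::rnorm(n, params$d, params$sigma_o)
    s_new <- stats::rnorm(n, 0, 1)
    data.frame(participant_id = participant_id,
               item_type = rep(c("old", "new"), each = n),
               rating = rating_from_strength(c(s_old, s_new), params$criteria),
               stringsAsFactors = FALSE)
  })
}

#' @export
simulate_ratings.uvsd_extended_params <- function(params, n, seed = NULL,
                                                  participant_id = "p1") {
  stopifnot(n >= 1)
  with_seed(seed, {
    rows <- lapply(extended_conditions, function(cc) {
      m <- condition_moments(params, cc)
      it <- if (grepl("^old", cc)) "old" else "new"
      vc <- if (grepl("high$", cc)) "high" else "low"
      data.frame(participant_id = participant_id,
                 strength_cond = "none",
                 variability_cond = vc, item_type = it,
                 rating = rating_from_strength(stats::rnorm(n, m[1], m[2]),
                                               params$criteria),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Target attribute structure for synthetic lexicons
#'
#' Default word-norm targets for the two item-characteristic variability
#' regimes: high-variability words have wide, inter-correlated frequency /
#' concreteness / age-of-acquisition norms and 4-10 character lengths;
#' low-variability words have tight norms, near-zero correlations, and a
#' fixed 7-character length.
#'
#' @param variability `"high"` or `"low"`.
#' @return List with `means`, `sds`, `corr` (3x3 correlation matrix over
#'   frequency, concreteness, aoa), and `length_policy`.
#' @export
lexicon_targets <- function(variability = c("high", "low")) {
  variability <- match.arg(variability)
  vars <- c("frequency", "concreteness", "aoa")
  if (variability == "high") {
    corr <- matrix(c(1, -0.82, -0.67,
                     -0.82, 1, 0.38,
                     -0.67, 0.38, 1), 3, 3, dimnames = list(vars, vars))
    list(means = c(frequency = 2.94, concreteness = 3.10, aoa = 10.3),
         sds = c(frequency = 0.94, concreteness = 0.87, aoa = 2.4),
         corr = corr,
         length_policy = list(type = "range", min = 4, max = 10))
  } else {
    corr <- matrix(c(1, -0.2, -0.05,
                     -0.2, 1, 0,
                     -0.05, 0, 1), 3, 3, dimnames = list(vars, vars))
    list(means = c(frequency = 2.94, concreteness = 3.10, aoa = 10.3),
         sds = c(frequency = 0.33, concreteness = 0.46, aoa = 0.52),
         corr = corr,
         length_policy = list(type = "fixed", value = 7))
  }
}

#' Generate a synthetic word-attribute lexicon
#'
#' Samples word frequency, concreteness, and age-of-acquisition values with
#' specified means, SDs, and correlation structure, plus character lengths
#' from a length policy. `mode = "gaussian"` uses multivariate normal
#' margins; `mode = "symmetric"` keeps the Gaussian copula but maps margins
#' to a symmetric platykurtic (uniform) shape, for emulating wider,
#' non-Gaussian stimulus pools.
#'
#' @param n_words Number of words.
#' @param means,sds Named targets for frequency, concreteness, aoa.
#' @param corr 3x3 positive-definite correlation matrix (same order).
#' @param mode `"gaussian"` or `"symmetric"`.
#' @param length_policy `list(type = "fixed", value = 7)` or
#'   `list(type = "range", min = 4, max = 10)`.
#' @param seed Optional integer seed.
#' @return Data frame with `word_id`, `frequency`, `concreteness`, `aoa`,
#'   `length`.
#' @export
generate_lexicon <- function(n_words,
                             means = lexicon_targets("high")$means,
                             sds = lexicon_targets("high")$sds,
                             corr = lexicon_targets("high")$corr,
                             mode = c("gaussian", "symmetric"),
                             length_policy = list(type = "range",
                                                  min = 4, max = 10),
                             seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_words >= 1, length(means) == 3, length(sds) == 3, all(sds > 0))
  if (!isSymmetric(unname(corr)) ||
      inherits(try(chol(corr), silent = TRUE), "try-error")) {
    stop("'corr' must be a symmetric positive-definite correlation matrix",
         call. = FALSE)
  }
  with_seed(seed, {
    z <- MASS::mvrnorm(n_words, mu = c(0, 0, 0), Sigma = corr)
    if (mode == "symmetric") {
      # Gaussian copula, uniform margins rescaled to the target mean/SD
      z <- sqrt(3) * (2 * stats::pnorm(z) - 1)
    }
    x <- sweep(sweep(z, 2, sds, `*`), 2, means, `+`)
    len <- switch(length_policy$type,
                  fixed = rep(as.integer(length_policy$value), n_words),
                  range = sample(seq(length_policy$min, length_policy$max),
                                 n_words, replace = TRUE),
                  stop("length_policy$type must be 'fixed' or 'range'",
                       call. = FALSE))
    data.frame(word_id = sprintf("w%06d", seq_len(n_words)),
               frequency = x[, 1], concreteness = x[, 2], aoa = x[, 3],
               length = len, stringsAsFactors = FALSE)
  })
}

# Standardised item index: the direction along which characteristics push
# old-item memory strength (rare, concrete, early-acquired, short words are
# remembered better). Zero-variance attributes drop out.
item_strength_index <- function(items) {
  w <- c(frequency = -1, concreteness = 1, aoa = -1, length = -1)
  idx <- rep(0, nrow(items))
  for (a in names(w)) {
    if (a %in% names(items) && stats::sd(items[[a]]) > 0) {
      idx <- idx + w[[a]] * as.numeric(scale(items[[a]]))
    }
  }
  if (stats::sd(idx) > 0) as.numeric(scale(idx)) else idx
}

#' Population values for the mixed-list (single-block) design emulator
#'
#' Group-level parameter means and between-participant SDs used by
#' [simulate_experiment()] for the four-distribution design, chosen to
#' emulate a typical mixed-list recognition experiment: new-high mean
#' slightly below 0, both old means around 1.3, old SDs above 1 with the
#' high-variability sub-list largest, and new-high SD at 1. Sigma
#' heterogeneity is log-normal; `shared_var` is the proportion of
#' between-participant variance in means (and in log SDs) carried by a
#' common ability (variance) trait, and `rho_dv` the correlation between
#' the two traits, which induces the participant-level d-sigma association.
#'
#' @return Named list of population values.
#' @export
exp3_population <- function() {
  list(mu = c(nh = -0.19, ol = 1.34, oh = 1.31),
       sd_mu = c(nh = 0.28, ol = 0.69, oh = 0.77),
       log_sigma = log(c(nh = 0.96, ol = 1.28, oh = 1.42)),
       sd_log_sigma = log(c(nh = 1.36, ol = 1.31, oh = 1.40)),
       criteria = c(-0.80, 0.16, 0.71, 1.17, 1.87),
       shared_var = 0.85, rho_dv = 0.55)
}

#' Design specification for a simulated recognition experiment
#'
#' Describes one of the three emulated designs. Experiments 1 and 2 are 2x2
#' within-subject factorials (strength high/low x item-characteristic
#' variability high/low), four separate study/test blocks, 60 old + 60 new
#' trials per condition. Experiment 3 is a single study/test block with
#' intermixed high/low variability sub-lists: 120 study items and 240 test
#' trials (60 per condition x item type).
#'
#' Old-item SDs follow either a strength [scaling_law()] applied to the
#' participant-condition d (the strength-scaling hypothesis) or an
#' [encoding_spec()] per variability condition (the encoding-variability
#' hypothesis).
#'
#' @param experiment 1, 2, or 3.
#' @param participants Number of simulated participants.
#' @param trials Trials per condition per item type (default 60).
#' @param d_means Named condition means of d for the strength manipulation
#'   (`high`, `low`).
#' @param scaling A [scaling_law()] mapping each participant-condition d to
#'   sigma_o (ignored when `encoding` is supplied).
#' @param encoding Optional named list of [encoding_spec()] objects
#'   (`high`, `low`) keyed by variability condition.
#' @param criteria Population decision criteria (Experiments 1-2).
#' @param sd_d Between-participant SD of d.
#' @param sd_log_sigma Residual SD of log sigma_o around the scaling law.
#' @param sd_criteria_shift SD of the participant-level common criterion
#'   shift.
#' @param shared_var Proportion of d variance shared across conditions
#'   within a participant (stable memory ability).
#' @param item_r2 Named proportions (`high`, `low`) of latent strength
#'   variance carried by the item-characteristic index in each variability
#'   condition; this is what makes manipulation-check regressions pick up
#'   the manipulation.
#' @param exp3 Population values for the mixed-list design, see
#'   [exp3_population()].
#' @param seed Integer seed recorded in the design and used by
#'   [simulate_experiment()].
#' @return Object of class `design_spec`.
#' @export
design_spec <- function(experiment = 1,
                        participants = 64,
                        trials = 60,
                        d_means = c(high = 1.46, low = 0.92),
                        scaling = scaling_law(1.0, 0.3),
                        encoding = NULL,
                        criteria = c(-1.1, -0.2, 0.5, 1.1, 1.9),
                        sd_d = 0.7,
                        sd_log_sigma = 0.15,
                        sd_criteria_shift = 0.25,
                        shared_var = 0.7,
                        item_r2 = c(high = 0.05, low = 0.005),
                        exp3 = exp3_population(),
                        seed = 1) {
  stopifnot(experiment %in% 1:3, participants >= 1, trials >= 1)
  stopifnot(all(c("high", "low") %in% names(d_means)))
  stopifnot(all(c("high", "low") %in% names(item_r2)),
            all(item_r2 >= 0 & item_r2 < 1))
  check_criteria(criteria)
  if (!is.null(encoding)) {
    stopifnot(is.list(encoding), all(c("high", "low") %in% names(encoding)),
              inherits(encoding$high, "encoding_spec"),
              inherits(encoding$low, "encoding_spec"))
  } else {
    stopifnot(inherits(scaling, "scaling_law"))
  }
  structure(list(experiment = experiment, participants = participants,
                 trials = trials, d_means = d_means, scaling = scaling,
                 encoding = encoding, criteria = criteria, sd_d = sd_d,
                 sd_log_sigma = sd_log_sigma,
                 sd_criteria_shift = sd_criteria_shift,
                 shared_var = shared_var, item_r2 = item_r2, exp3 = exp3,
                 seed = seed),
            class = "design_spec")
}

# Condition-level items with characteristic-linked latent strengths.
# Returns ratings for n old + n new trials.
simulate_condition_trials <- function(n, d, sigma_o, criteria, variability,
                                      r2, lexicon_mode = "gaussian") {
  tg <- lexicon_targets(variability)
  items <- generate_lexicon(2 * n, means = tg$means, sds = tg$sds,
                            corr = tg$corr, mode = lexicon_mode,
                            length_policy = tg$length_policy)
  idx <- item_strength_index(items)
  old <- seq_len(n); new <- n + seq_len(n)
  s_old <- d + sigma_o * (sqrt(r2) * idx[old] +
                            sqrt(1 - r2) * stats::rnorm(n))
  s_new <- 0 + 1 * (sqrt(r2) * idx[new] + sqrt(1 - r2) * stats::rnorm(n))
  out <- items
  out$item_type <- rep(c("old", "new"), each = n)
  out$rating <- rating_from_strength(c(s_old, s_new), criteria)
  out$variability_cond <- variability
  out
}

#' Simulate a whole recognition experiment
#'
#' Generates a long-format trial table under the design's generative
#' hypothesis: participant-level parameters are drawn around the condition
#' means, old-item SDs come from the scaling law (or encoding spec), item
#' characteristics are attached from synthetic lexicons and feed the latent
#' strengths, and ratings are produced by cutting strengths at the
#' participant's criteria. Deterministic given `design$seed`.
#'
#' @param design A [design_spec()].
#' @return Trial data frame with canonical columns (participant_id,
#'   experiment, strength_cond, variability_cond, item_type, rating,
#'   frequency, concreteness, aoa, length).
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  with_seed(design$seed, {
    if (design$experiment %in% c(1, 2)) {
      simulate_factorial(design)
    } else {
      simulate_mixed_list(design)
    }
  })
}

simulate_factorial <- function(design) {
  lexicon_mode <- if (design$experiment == 2) "symmetric" else "gaussian"
  cells <- expand.grid(strength = c("high", "low"),
                       variability = c("high", "low"),
                       stringsAsFactors = FALSE)
  out <- vector("list", design$participants)
  for (p in seq_len(design$participants)) {
    pid <- sprintf("p%03d", p)
    ability <- stats::rnorm(1)
    crit <- design$criteria + stats::rnorm(1, 0, design$sd_criteria_shift)
    rows <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      sc <- cells$strength[i]; vc <- cells$variability[i]
      d <- design$d_means[[sc]] + design$sd_d *
        (sqrt(design$shared_var) * ability +
           sqrt(1 - design$shared_var) * stats::rnorm(1))
      if (!is.null(design$encoding)) {
        sigma <- encoding_sigma_o(design$encoding[[vc]]) *
          exp(stats::rnorm(1, 0, design$sd_log_sigma))
      } else {
        base <- scaling_sigma(design$scaling, d)
        if (base <= 0) {
          stop(sprintf(paste("scaling law yields sigma_o = %.3f <= 0 at",
                             "d = %.3f; adjust the law or the d range"),
                       base, d), call. = FALSE)
        }
        sigma <- base * exp(stats::rnorm(1, 0, design$sd_log_sigma))
      }
      tr <- simulate_condition_trials(design$trials, d, sigma, crit, vc,
                                      design$item_r2[[vc]], lexicon_mode)
      tr$strength_cond <- sc
      rows[[i]] <- tr
    }
    blk <- do.call(rbind, rows)
    blk$participant_id <- pid
    out[[p]] <- blk
  }
  finish_trial_table(do.call(rbind, out), design$experiment)
}

simulate_mixed_list <- function(design) {
  pop <- design$exp3
  w <- pop$shared_var
  out <- vector("list", design$participants)
  for (p in seq_len(design$participants)) {
    pid <- sprintf("p%03d", p)
    traits <- MASS::mvrnorm(1, c(0, 0),
                            matrix(c(1, pop$rho_dv, pop$rho_dv, 1), 2))
    a <- traits[1]; v <- traits[2]
    mix <- function(t) sqrt(w) * t + sqrt(1 - w) * stats::rnorm(1)
    params <- extended_params(
      mu_nh = pop$mu["nh"] + pop$sd_mu["nh"] * stats::rnorm(1),
      mu_ol = pop$mu["ol"] + pop$sd_mu["ol"] * mix(a),
      mu_oh = pop$mu["oh"] + pop$sd_mu["oh"] * mix(a),
      sigma_nh = exp(pop$log_sigma["nh"] +
                       pop$sd_log_sigma["nh"] * stats::rnorm(1)),
      sigma_ol = exp(pop$log_sigma["ol"] + pop$sd_log_sigma["ol"] * mix(v)),
      sigma_oh = exp(pop$log_sigma["oh"] + pop$sd_log_sigma["oh"] * mix(v)),
      criteria = pop$criteria +
        stats::rnorm(1, 0, design$sd_criteria_shift))
    rows <- lapply(c("high", "low"), function(vc) {
      suff <- if (vc == "high") "h" else "l"
      mo <- condition_moments(params, paste0("old_", ifelse(vc == "high",
                                                            "high", "low")))
      mn <- condition_moments(params, paste0("new_", ifelse(vc == "high",
                                                            "high", "low")))
      tg <- lexicon_targets(vc)
      items <- generate_lexicon(2 * design$trials, means = tg$means,
                                sds = tg$sds, corr = tg$corr,
                                length_policy = tg$length_policy)
      idx <- item_strength_index(items)
      r2 <- design$item_r2[[vc]]
      n <- design$trials
      s_old <- mo[1] + mo[2] * (sqrt(r2) * idx[seq_len(n)] +
                                  sqrt(1 - r2) * stats::rnorm(n))
      s_new <- mn[1] + mn[2] * (sqrt(r2) * idx[n + seq_len(n)] +
                                  sqrt(1 - r2) * stats::rnorm(n))
      items$item_type <- rep(c("old", "new"), each = n)
      items$rating <- rating_from_strength(c(s_old, s_new), params$criteria)
      items$variability_cond <- vc
      items
    })
    blk <- do.call(rbind, rows)
    blk$participant_id <- pid
    blk$strength_cond <- "none"
    out[[p]] <- blk
  }
  finish_trial_table(do.call(rbind, out), 3)
}

finish_trial_table <- function(trials, experiment) {
  trials$experiment <- paste0("exp", experiment)
  cols <- c("participant_id", "experiment", "strength_cond",
            "variability_cond", "item_type", "rating",
            "frequency", "concreteness", "aoa", "length")
  trials <- trials[, intersect(cols, names(trials))]
  rownames(trials) <- NULL
  validate_trials(trials)
  trials
}

#' Parameter-recovery study
#'
#' Simulates rating data from each row of a generating-parameter grid,
#' refits the model, and summarises recovery: bias, RMSE, and the
#' correlation between generating and recovered values per parameter.
#'
#' @param grid Data frame of generating parameters. For `fit = "standard"`:
#'   columns `d`, `sigma_o`. For `fit = "extended"`: columns `mu_nh`,
#'   `mu_ol`, `mu_oh`, `sigma_nh`, `sigma_ol`, `sigma_oh`.
#' @param fit `"standard"` or `"extended"`.
#' @param reps Replicates per grid row (>= 2).
#' @param n Trials per condition per item type.
#' @param criteria Criteria used for generation.
#' @param seed Integer seed; replicate r of row g uses a sub-seed, so
#'   results do not depend on execution order.
#' @param n_restarts Optimiser restarts per fit.
#' @return Object of class `recovery_report`: list with `summary` (one row
#'   per parameter: bias, rmse, correlation) and `details` (one row per
#'   simulated dataset).
#' @export
recovery_study <- function(grid, fit = c("standard", "extended"), reps = 10,
                           n = 60, criteria = c(-1.1, -0.2, 0.5, 1.1, 1.9),
                           seed = 1, n_restarts = 5) {
  fit <- match.arg(fit)
  stopifnot(is.data.frame(grid), nrow(grid) >= 1, reps >= 2)
  pars <- if (fit == "standard") c("d", "sigma_o") else
    c("mu_nh", "mu_ol", "mu_oh", "sigma_nh", "sigma_ol", "sigma_oh")
  stopifnot(all(pars %in% names(grid)))

  details <- list()
  for (g in seq_len(nrow(grid))) {
    for (r in seq_len(reps)) {
      s <- sub_seed(seed, sprintf("recovery/%d/%d", g, r))
      if (fit == "standard") {
        gen <- uvsd_params(grid$d[g], grid$sigma_o[g], criteria)
        tab <- simulate_ratings(gen, n, seed = s)
        cnt <- aggregate_counts(tab, by = "item_type")
        f <- fit_uvsd(counts_row(cnt, which(cnt$item_type == "old")),
                      counts_row(cnt, which(cnt$item_type == "new")),
                      n_restarts = n_restarts, seed = s)
        rec <- c(d = f$estimates$d, sigma_o = f$estimates$sigma_o)
      } else {
        gen <- extended_params(grid$mu_nh[g], grid$mu_ol[g], grid$mu_oh[g],
                               grid$sigma_nh[g], grid$sigma_ol[g],
                               grid$sigma_oh[g], criteria)
        tab <- simulate_ratings(gen, n, seed = s)
        cnt <- aggregate_counts(tab, by = c("variability_cond", "item_type"))
        key <- paste(cnt$item_type, cnt$variability_cond, sep = "_")
        counts <- lapply(stats::setNames(extended_conditions,
                                         extended_conditions),
                         function(cc) counts_row(cnt, which(key == cc)))
        f <- fit_extended(counts, n_restarts = n_restarts, seed = s)
        e <- f$estimates
        rec <- c(mu_nh = e$mu_nh, mu_ol = e$mu_ol, mu_oh = e$mu_oh,
                 sigma_nh = e$sigma_nh, sigma_ol = e$sigma_ol,
                 sigma_oh = e$sigma_oh)
      }
      for (pn in pars) {
        details[[length(details) + 1L]] <-
          data.frame(grid_row = g, rep = r, parameter = pn,
                     generating = grid[[pn]][g], recovered = unname(rec[pn]),
                     stringsAsFactors = FALSE)
      }
    }
  }
  details <- do.call(rbind, details)
  summ <- do.call(rbind, lapply(split(details, details$parameter), function(dd) {
    err <- dd$recovered - dd$generating
    corr <- if (stats::sd(dd$generating) > 0 && stats::sd(dd$recovered) > 0) {
      stats::cor(dd$generating, dd$recovered)
    } else NA_real_
    data.frame(parameter = dd$parameter[1], bias = mean(err),
               rmse = sqrt(mean(err^2)), correlation = corr,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, details = details, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery report (seed", x$seed, ")\n")
  print(x$summary, digits = 4)
  invisible(x)
}
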
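#' Analysis configuration
#'
#' Settings for the per-experiment analysis: exclusion thresholds, fitting
#' options, seed, and an optional output directory for the written report.
#'
#' @param experiment 1, 2, or 3 (1 and 2 share the factorial branch).
#' @param extreme_prop A participant is excluded when at least this
#'   proportion of their ratings are the extreme categories 1 or 6
#'   (default 0.90, the operationalisation of "predominantly").
#' @param outlier_sd Outlier multiplier: estimates above the sample mean
#'   plus this many SDs (one-sided, high side; log scale for sigma) flag a
#'   participant (default 3).
#' @param n_restarts Optimiser restarts per fit.
#' @param seed Integer seed for all fitting randomness.
#' @param alpha Significance level used in reports.
#' @param output_dir Optional directory; when given, the report is written
#'   there as tidy CSVs plus a JSON summary and a text narrative.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(experiment = 1, extreme_prop = 0.90,
                            outlier_sd = 3, n_restarts = 10, seed = 1,
                            alpha = 0.05, output_dir = NULL) {
  stopifnot(experiment %in% 1:3,
            extreme_prop > 0, extreme_prop <= 1,
            outlier_sd > 0, n_restarts >= 1)
  structure(list(experiment = experiment, extreme_prop = extreme_prop,
                 outlier_sd = outlier_sd, n_restarts = n_restarts,
                 seed = seed, alpha = alpha, output_dir = output_dir),
            class = "analysis_config")
}

#' Apply participant exclusion rules
#'
#' A participant is excluded when (a) the proportion of their ratings in
#' the extreme categories 1 and 6 is at least `config$extreme_prop`, or
#' (b) any of their d or log sigma estimates exceeds the full-sample mean
#' plus `config$outlier_sd` SDs (computed once, on all participants,
#' one-sided). The log records which rule fired.
#'
#' @param fits Data frame of per-participant estimates with columns
#'   `participant_id` and one or more of `d`, `log_sigma` (several rows per
#'   participant are allowed, e.g. one per condition).
#' @param trials Trial data frame (for the extreme-response rule).
#' @param config An [analysis_config()].
#' @return List with `retained` (participant ids) and `log` (data frame:
#'   participant_id, excluded, rule).
#' @export
apply_exclusions <- function(fits, trials, config = analysis_config()) {
  stopifnot(is.data.frame(fits), "participant_id" %in% names(fits))
  ids <- unique(fits$participant_id)

  extreme <- vapply(ids, function(id) {
    r <- trials$rating[trials$participant_id == id]
    length(r) > 0 && mean(r %in% c(1, 6)) >= config$extreme_prop
  }, logical(1))

  outlier <- rep(FALSE, length(ids))
  for (col in intersect(c("d", "log_sigma"), names(fits))) {
    v <- fits[[col]]
    cut <- mean(v) + config$outlier_sd * stats::sd(v)
    flagged <- unique(fits$participant_id[v > cut])
    outlier <- outlier | ids %in% flagged
  }

  rule <- ifelse(extreme, "extreme responses",
                 ifelse(outlier, "outlying estimates", ""))
  log <- data.frame(participant_id = ids,
                    excluded = extreme | outlier,
                    rule = rule, stringsAsFactors = FALSE)
  list(retained = ids[!log$excluded], log = log)
}

# Per-cell manipulation-check R2; zero-variance predictors (e.g. fixed word
# length in low-variability lists) are left out of that cell's model.
cell_r2 <- function(cell) {
  preds <- c("frequency", "concreteness", "aoa", "length")
  preds <- preds[vapply(preds, function(a) {
    a %in% names(cell) && stats::sd(cell[[a]]) > 0
  }, logical(1))]
  if (!length(preds) || nrow(cell) < length(preds) + 6) return(NA_real_)
  tryCatch(manipulation_check_regression(cell, predictors = preds)$r2,
           error = function(e) NA_real_)
}

#' Run the full per-experiment analysis
#'
#' Executes the analysis sequence appropriate to the design:
#'
#' * Experiments 1-2 (2x2 factorial): four separate UVSD fits per
#'   participant (one per condition); exclusions; per-participant
#'   manipulation-check regressions on old items; 2x2 within-subjects
#'   ANOVAs on d, log sigma_o, and R2; per-condition sequential scaling
#'   fits of sigma_o on d across participants.
#' * Experiment 3 (single mixed block): one four-distribution fit per
#'   participant; exclusions; one-way repeated-measures ANOVA with
#'   Greenhouse-Geisser correction on the three free log sigma parameters;
#'   Bonferroni-corrected pairwise sigma comparisons; one-sample tests of
#'   log sigma_nh against 0 and mu_nh against 0; paired tests of
#'   mu_oh vs mu_ol and d_high vs d_low; within-condition scaling
#'   regressions; manipulation checks split by item type x variability.
#'
#' Condition means of sigma are computed on the log scale and
#' exponentiated. Deterministic given `config$seed`.
#'
#' @param trials Trial data frame covering the experiment's full design.
#' @param config An [analysis_config()] matching the design.
#' @return Object of class `experiment_report` (see Details); if
#'   `config$output_dir` is set the report is also written there via
#'   [write_report()].
#' @export
analyze_experiment <- function(trials, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (!is.data.frame(trials) || nrow(trials) == 0) {
    stop("design mismatch: empty trial table", call. = FALSE)
  }
  validate_trials(trials)
  report <- if (config$experiment %in% c(1, 2)) {
    analyze_factorial(trials, config)
  } else {
    analyze_mixed_list(trials, config)
  }
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

check_factorial_design <- function(trials) {
  need <- c("strength_cond", "variability_cond")
  if (!all(need %in% names(trials)) ||
      !all(trials$strength_cond %in% c("high", "low"))) {
    stop(paste("design mismatch: factorial analysis needs strength_cond",
               "(high/low) and variability_cond (high/low) columns"),
         call. = FALSE)
  }
  cells <- unique(trials[, need])
  if (nrow(cells) != 4) {
    stop("design mismatch: expected 4 strength x variability cells",
         call. = FALSE)
  }
}

analyze_factorial <- function(trials, config) {
  check_factorial_design(trials)
  conds <- expand.grid(strength_cond = c("high", "low"),
                       variability_cond = c("high", "low"),
                       stringsAsFactors = FALSE)
  cond_label <- function(s, v) paste0(substr(s, 1, 1), "s_", substr(v, 1, 1), "v")
  ids <- unique(trials$participant_id)
  counts <- aggregate_counts(trials, by = c("participant_id", "strength_cond",
                                            "variability_cond", "item_type"))

  rows <- list()
  for (id in ids) {
    for (i in seq_len(nrow(conds))) {
      sc <- conds$strength_cond[i]; vc <- conds$variability_cond[i]
      sel <- counts$participant_id == id & counts$strength_cond == sc &
        counts$variability_cond == vc
      i_old <- which(sel & counts$item_type == "old")
      i_new <- which(sel & counts$item_type == "new")
      if (!length(i_old) || !length(i_new)) {
        stop(sprintf("design mismatch: participant %s lacks %s/%s trials",
                     id, sc, vc), call. = FALSE)
      }
      f <- fit_uvsd(counts_row(counts, i_old), counts_row(counts, i_new),
                    n_restarts = config$n_restarts,
                    seed = sub_seed(config$seed, c(id, sc, vc)))
      old_cell <- trials[trials$participant_id == id &
                           trials$strength_cond == sc &
                           trials$variability_cond == vc &
                           trials$item_type == "old", ]
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = id, strength_cond = sc, variability_cond = vc,
        condition = cond_label(sc, vc),
        d = f$estimates$d, sigma_o = f$estimates$sigma_o,
        log_sigma = f$log_sigma_o, logL = f$logL, converged = f$converged,
        r2 = cell_r2(old_cell), stringsAsFactors = FALSE)
    }
  }
  params <- do.call(rbind, rows)

  excl <- apply_exclusions(params, trials, config)
  kept <- params[params$participant_id %in% excl$retained, ]

  to_matrix <- function(value_col) {
    wide <- stats::reshape(kept[, c("participant_id", "condition", value_col)],
                           idvar = "participant_id", timevar = "condition",
                           direction = "wide")
    m <- as.matrix(wide[, paste(value_col,
                                c("hs_hv", "hs_lv", "ls_hv", "ls_lv"),
                                sep = "."), drop = FALSE])
    rownames(m) <- wide$participant_id
    m
  }

  anovas <- list()
  for (dv in c("d", "log_sigma", "r2")) {
    m <- to_matrix(dv)
    if (anyNA(m)) next
    a <- rm_anova(m, design = "2x2",
                  factor_names = c("strength", "variability"))
    a$dv <- dv
    anovas[[dv]] <- a
  }
  tests <- do.call(rbind, anovas)
  rownames(tests) <- NULL

  scaling <- lapply(split(kept, kept$condition), function(cc) {
    if (nrow(cc) >= 5) sequential_scaling_fit(cc$d, cc$sigma_o) else NULL
  })

  cond_means <- do.call(rbind, lapply(split(kept, kept$condition), function(cc) {
    data.frame(condition = cc$condition[1],
               d = mean(cc$d),
               sigma_o = exp(mean(cc$log_sigma)),
               r2 = mean(cc$r2, na.rm = TRUE),
               n = nrow(cc), stringsAsFactors = FALSE)
  }))
  rownames(cond_means) <- NULL

  structure(list(experiment = config$experiment, design = "factorial",
                 parameters = params, exclusions = excl$log,
                 retained = excl$retained, condition_means = cond_means,
                 tests = tests, scaling = scaling, config = config),
            class = "experiment_report")
}

analyze_mixed_list <- function(trials, config) {
  if (!("variability_cond" %in% names(trials)) ||
      ("strength_cond" %in% names(trials) &&
       !all(trials$strength_cond == "none"))) {
    stop(paste("design mismatch: mixed-list analysis needs variability_cond",
               "and no strength manipulation"), call. = FALSE)
  }
  ids <- unique(trials$participant_id)
  counts <- aggregate_counts(trials, by = c("participant_id",
                                            "variability_cond", "item_type"))

  rows <- list()
  for (id in ids) {
    sel <- counts$participant_id == id
    key <- paste(counts$item_type, counts$variability_cond, sep = "_")
    cl <- lapply(stats::setNames(extended_conditions, extended_conditions),
                 function(cc) {
                   i <- which(sel & key == cc)
                   if (!length(i)) {
                     stop(sprintf("design mismatch: participant %s lacks %s trials",
                                  id, cc), call. = FALSE)
                   }
                   counts_row(counts, i)
                 })
    f <- fit_extended(cl, n_restarts = config$n_restarts,
                      seed = sub_seed(config$seed, id))
    e <- f$estimates
    dm <- discriminability(e)
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = id,
      mu_nh = e$mu_nh, mu_ol = e$mu_ol, mu_oh = e$mu_oh,
      sigma_nh = e$sigma_nh, sigma_ol = e$sigma_ol, sigma_oh = e$sigma_oh,
      log_sigma_nh = log(e$sigma_nh), log_sigma_ol = log(e$sigma_ol),
      log_sigma_oh = log(e$sigma_oh),
      d_high = dm$d_high, d_low = dm$d_low,
      logL = f$logL, converged = f$converged, stringsAsFactors = FALSE)
  }
  params <- do.call(rbind, rows)

  # outlier screen over both d measures and all free log sigmas
  screen <- rbind(
    data.frame(participant_id = params$participant_id, d = params$d_high,
               log_sigma = params$log_sigma_oh),
    data.frame(participant_id = params$participant_id, d = params$d_low,
               log_sigma = params$log_sigma_ol),
    data.frame(participant_id = params$participant_id, d = params$d_low,
               log_sigma = params$log_sigma_nh))
  excl <- apply_exclusions(screen, trials, config)
  kept <- params[params$participant_id %in% excl$retained, ]

  sig_mat <- as.matrix(kept[, c("log_sigma_oh", "log_sigma_ol",
                                "log_sigma_nh")])
  aov1 <- rm_anova(sig_mat, design = "oneway")
  aov1$dv <- "log_sigma"

  pair <- function(a, b) t_test(kept[[a]], kept[[b]], mode = "paired")
  pw <- list(oh_vs_ol = pair("log_sigma_oh", "log_sigma_ol"),
             oh_vs_nh = pair("log_sigma_oh", "log_sigma_nh"),
             ol_vs_nh = pair("log_sigma_ol", "log_sigma_nh"))
  pw_p <- bonferroni_adjust(vapply(pw, `[[`, numeric(1), "p"), m = 3)
  pairwise <- data.frame(comparison = names(pw),
                         t = vapply(pw, `[[`, numeric(1), "t"),
                         df = vapply(pw, `[[`, numeric(1), "df"),
                         p_adjusted = pw_p,
                         d_z = vapply(pw, `[[`, numeric(1), "d_z"),
                         stringsAsFactors = FALSE)
  rownames(pairwise) <- NULL

  one_sample <- list(
    log_sigma_nh_vs_0 = t_test(kept$log_sigma_nh, mu = 0, mode = "one-sample"),
    mu_nh_vs_0 = t_test(kept$mu_nh, mu = 0, mode = "one-sample"))
  paired_means <- list(
    mu_oh_vs_mu_ol = t_test(kept$mu_oh, kept$mu_ol, mode = "paired"),
    d_high_vs_d_low = t_test(kept$d_high, kept$d_low, mode = "paired"))

  scaling <- list(
    old_high = if (nrow(kept) >= 5)
      sequential_scaling_fit(kept$d_high, kept$sigma_oh) else NULL,
    old_low = if (nrow(kept) >= 5)
      sequential_scaling_fit(kept$d_low, kept$sigma_ol) else NULL)

  r2_rows <- list()
  for (id in excl$retained) {
    for (it in c("old", "new")) {
      for (vc in c("high", "low")) {
        cell <- trials[trials$participant_id == id &
                         trials$item_type == it &
                         trials$variability_cond == vc, ]
        r2_rows[[length(r2_rows) + 1L]] <- data.frame(
          participant_id = id, item_type = it, variability_cond = vc,
          r2 = cell_r2(cell), stringsAsFactors = FALSE)
      }
    }
  }
  r2_table <- do.call(rbind, r2_rows)
  r2_anova <- NULL
  if (!anyNA(r2_table$r2)) {
    # columns: item type x variability -> (old,hi)(old,lo)(new,hi)(new,lo)
    m <- cbind(
      r2_table$r2[r2_table$item_type == "old" & r2_table$variability_cond == "high"],
      r2_table$r2[r2_table$item_type == "old" & r2_table$variability_cond == "low"],
      r2_table$r2[r2_table$item_type == "new" & r2_table$variability_cond == "high"],
      r2_table$r2[r2_table$item_type == "new" & r2_table$variability_cond == "low"])
    r2_anova <- rm_anova(m, design = "2x2",
                         factor_names = c("item_type", "variability"))
    r2_anova$dv <- "r2"
  }

  cond_means <- data.frame(
    parameter = c("mu_nh", "mu_ol", "mu_oh", "sigma_nh", "sigma_ol",
                  "sigma_oh", "d_high", "d_low"),
    mean = c(mean(kept$mu_nh), mean(kept$mu_ol), mean(kept$mu_oh),
             exp(mean(kept$log_sigma_nh)), exp(mean(kept$log_sigma_ol)),
             exp(mean(kept$log_sigma_oh)),
             mean(kept$d_high), mean(kept$d_low)),
    stringsAsFactors = FALSE)

  structure(list(experiment = 3, design = "mixed_list",
                 parameters = params, exclusions = excl$log,
                 retained = excl$retained, condition_means = cond_means,
                 tests = aov1, pairwise = pairwise,
                 one_sample = one_sample, paired_means = paired_means,
                 scaling = scaling, r2_table = r2_table,
                 r2_anova = r2_anova, config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment report (%s design): %d participants, %d retained\n",
              x$design, nrow(x$exclusions), length(x$retained)))
  cat("\nCondition means (sigma exponentiated from the log scale):\n")
  print(x$condition_means, digits = 3)
  cat("\nANOVA table:\n")
  print(x$tests, digits = 3)
  if (!is.null(x$pairwise)) {
    cat("\nPairwise sigma comparisons (Bonferroni-adjusted):\n")
    print(x$pairwise, digits = 3)
  }
  invisible(x)
}

#' Write an experiment report to disk
#'
#' Emits tidy CSVs (`parameters.csv`, `exclusions.csv`,
#' `condition_means.csv`, `tests.csv`), a JSON summary, and a short text
#' narrative. Apart from the timestamp header line of the narrative, output
#' is byte-identical across runs with the same inputs and seed.
#'
#' @param report An `experiment_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$parameters, file.path(dir, "parameters.csv"),
                   row.names = FALSE)
  utils::write.csv(report$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  utils::write.csv(report$condition_means, file.path(dir, "condition_means.csv"),
                   row.names = FALSE)
  utils::write.csv(report$tests, file.path(dir, "tests.csv"),
                   row.names = FALSE)
  summary <- list(experiment = report$experiment, design = report$design,
                  n_participants = nrow(report$exclusions),
                  n_retained = length(report$retained),
                  condition_means = report$condition_means,
                  tests = report$tests)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  lines <- c(sprintf("generated: %s", format(Sys.time())),
             sprintf("experiment %s (%s design)", report$experiment,
                     report$design),
             sprintf("%d participants, %d retained after exclusions",
                     nrow(report$exclusions), length(report$retained)),
             "condition means (sigma from exponentiated log scale):",
             utils::capture.output(print(report$condition_means, digits = 3)),
             "tests:",
             utils::capture.output(print(report$tests, digits = 3)))
  writeLines(lines, file.path(dir, "narrative.txt"))
  invisible(dir)
}
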
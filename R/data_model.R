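#' Column mapping for trial CSV files
#'
#' Trial tables are long-format CSVs, one row per test trial. The dialect
#' maps the canonical field names used throughout the package onto the
#' column names found in a particular file, so exports from other logging
#' conventions can be read without code changes.
#'
#' Canonical fields: `participant_id`, `experiment`, `strength_cond`
#' (high/low/none), `variability_cond` (high/low), `item_type` (old/new),
#' `rating` (integer 1-6 on the scale 1 Sure New ... 6 Sure Old), and the
#' optional item characteristics `frequency` (Zipf-like log frequency),
#' `concreteness` (1-5 rating scale), `aoa` (age of acquisition, years),
#' `length` (character count).
#'
#' @param ... Named overrides, e.g. `rating = "resp"` if the file calls the
#'   rating column "resp".
#' @return Named character vector mapping canonical names to file columns.
#' @export
trial_dialect <- function(...) {
  d <- c(participant_id = "participant_id", experiment = "experiment",
         strength_cond = "strength_cond", variability_cond = "variability_cond",
         item_type = "item_type", rating = "rating",
         frequency = "frequency", concreteness = "concreteness",
         aoa = "aoa", length = "length")
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(d))
    if (length(bad)) {
      stop(sprintf("unknown trial fields in dialect: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    d[names(over)] <- over
  }
  d
}

trial_required <- c("participant_id", "item_type", "rating")
trial_characteristics <- c("frequency", "concreteness", "aoa", "length")

#' Validate a trial table
#'
#' Checks the trial-level invariants: ratings are integers in 1..6,
#' item types are old/new, condition labels are from their allowed sets, and
#' characteristic values (when present) are finite with positive integer
#' lengths. Violations are reported with the offending row numbers.
#'
#' @param trials Data frame in canonical column names.
#' @return The validated data frame, invisibly.
#' @export
validate_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  missing <- setdiff(trial_required, names(trials))
  if (length(missing)) {
    stop(sprintf("trial table schema error: missing required column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad_rows <- function(ok, what) {
    if (!all(ok)) {
      rows <- which(!ok)
      stop(sprintf("invalid %s on row(s) %s", what,
                   paste(utils::head(rows, 10), collapse = ", ")),
           call. = FALSE)
    }
  }
  r <- trials$rating
  bad_rows(is.finite(r) & r == round(r) & r >= 1 & r <= 6,
           "rating (must be an integer 1-6)")
  bad_rows(trials$item_type %in% c("old", "new"), "item_type (old/new)")
  if ("strength_cond" %in% names(trials)) {
    bad_rows(trials$strength_cond %in% c("high", "low", "none"),
             "strength_cond (high/low/none)")
  }
  if ("variability_cond" %in% names(trials)) {
    bad_rows(trials$variability_cond %in% c("high", "low"),
             "variability_cond (high/low)")
  }
  for (ch in intersect(trial_characteristics, names(trials))) {
    bad_rows(is.finite(trials[[ch]]), sprintf("%s (must be finite)", ch))
  }
  if ("length" %in% names(trials)) {
    bad_rows(trials$length >= 1 & trials$length == round(trials$length),
             "length (positive integer)")
  }
  invisible(trials)
}

#' Read a long-format trial CSV
#'
#' @param path CSV file path.
#' @param dialect Column mapping from [trial_dialect()].
#' @return Validated trial data frame with canonical column names.
#' @export
read_trials <- function(path, dialect = trial_dialect()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  present <- dialect[dialect %in% names(raw)]
  missing <- setdiff(trial_required, names(present))
  if (length(missing)) {
    stop(sprintf("trial table schema error: missing required column(s) %s",
                 paste(dialect[missing], collapse = ", ")), call. = FALSE)
  }
  trials <- raw[, unname(present), drop = FALSE]
  names(trials) <- names(present)
  validate_trials(trials)
  trials
}

#' Write a trial table to CSV
#'
#' Columns are emitted in the canonical order, so writing is deterministic
#' and `read_trials(write_trials(x))` round-trips.
#'
#' @param trials Trial data frame (canonical names).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  order <- intersect(names(trial_dialect()), names(trials))
  utils::write.csv(trials[, order, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Aggregate trials into 6-category rating counts
#'
#' Produces one row per grouping cell (by default participant x condition x
#' item type) with counts `n1..n6` of each confidence rating and the total
#' `N`. This is the sufficient statistic the UVSD likelihood is computed
#' from; totals are conserved (`sum(N)` equals the number of trials).
#'
#' @param trials Validated trial data frame.
#' @param by Grouping columns; defaults to those of the canonical schema
#'   present in `trials` (excluding rating and characteristics).
#' @return Data frame with the grouping columns, `n1`..`n6`, and `N`.
#' @export
aggregate_counts <- function(trials,
                             by = intersect(c("participant_id", "experiment",
                                              "strength_cond",
                                              "variability_cond", "item_type"),
                                            names(trials))) {
  validate_trials(trials)
  stopifnot(length(by) >= 1, all(by %in% names(trials)))
  key <- interaction(trials[by], drop = TRUE, lex.order = TRUE, sep = "\r")
  idx <- split(seq_len(nrow(trials)), key)
  groups <- do.call(rbind, lapply(idx, function(i) trials[i[1], by, drop = FALSE]))
  counts <- t(vapply(idx, function(i) tabulate(trials$rating[i], nbins = 6),
                     numeric(6)))
  colnames(counts) <- paste0("n", 1:6)
  out <- cbind(groups, as.data.frame(counts), N = rowSums(counts))
  rownames(out) <- NULL
  out
}

# Extract the 6-vector of counts for one row of an aggregate_counts() table.
counts_row <- function(counts, i) {
  as.numeric(unlist(counts[i, paste0("n", 1:6)]))
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("config must be a .yaml/.yml or .json file", call. = FALSE)
  }
}
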
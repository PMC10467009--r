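# Internal helpers shared across modules.

# Run code with a temporary RNG state. `seed = NULL` leaves the global RNG
# untouched (and advancing), which callers use for "give me fresh randomness".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible sub-seed from a base seed and a stable key.
# Kept below 2^31 so it is always a valid R integer seed.
sub_seed <- function(seed, key) {
  h <- sum(utf8ToInt(paste0(key, collapse = "/")) * seq_along(utf8ToInt(paste0(key, collapse = "/"))))
  (as.numeric(seed) * 7919 + h) %% 2147483629
}

is_count_vector <- function(n) {
  is.numeric(n) && length(n) == 6L && all(is.finite(n)) && all(n >= 0) &&
    all(abs(n - round(n)) < 1e-8)
}

check_counts <- function(n, what = "counts") {
  if (!is_count_vector(n)) {
    stop(sprintf("'%s' must be 6 non-negative integer counts (ratings 1-6)", what),
         call. = FALSE)
  }
  as.numeric(round(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
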
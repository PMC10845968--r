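# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state on
#' exit, so seeded routines do not perturb the global random stream. A `NULL`
#' seed evaluates `code` against the current stream unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stopf("`seed` must be a single integer or NULL")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed derived from a parent seed; keeps results in
# 32-bit range so downstream set.seed() always accepts them.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483629 + 104729 * index) %% 2147483629)
}

# single positive integer check
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      abs(x - round(x)) > 1e-8 || x < min) {
    stopf("`%s` must be a single integer >= %d (got %s)", name, min,
          paste(format(x), collapse = ","))
  }
  as.integer(round(x))
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stopf("`%s` must be a single number in [%g, %g]", name, lo, hi)
  }
  as.numeric(x)
}

# create parent directories for an output path
ensure_parent_dir <- function(path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  invisible(path)
}
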
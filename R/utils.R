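# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Deterministic per-stage sub-seed: a single user seed fans out into
# independent streams for expression, survival, grade, folds, ... so adding
# a stage never perturbs the draws of another.
stage_seed <- function(seed, stage) {
  stages <- c(expression = 1, outlier = 2, survival = 3, grade = 4,
              idh1 = 5, folds = 6, baseline = 7, generic = 8)
  off <- stages[[match.arg(stage, names(stages))]]
  as.integer((as.numeric(seed) * 1000003 + off * 7919) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 0

# match a lambda value against a stored path with relative tolerance
match_lambda <- function(lambda, path_lambdas, tol = 1e-8) {
  rel <- abs(path_lambdas - lambda) / pmax(abs(lambda), 1e-300)
  i <- which.min(rel)
  if (rel[i] > tol) return(NA_integer_)
  i
}
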
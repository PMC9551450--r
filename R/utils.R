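#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a master seed, so independent
# pipeline stages consume independent streams (changing the number of null
# draws in one stage must not perturb another stage's results).
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

ra_log <- function(level, ...) {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  paste0(..., collapse = "")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Upper-triangle (i < j) unfolding of a square labelled matrix, the pair
# vector all distance-matrix statistics operate on.
upper_vec <- function(m) m[upper.tri(m)]
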
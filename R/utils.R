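# Internal utilities shared across modules.

# Run expr with a temporary RNG state so generators are pure functions of
# (params, seed) and never disturb the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, kept within the
# 32-bit integer range R requires.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rayleigh deviates (multiplicative speckle model).
rrayleigh <- function(n, scale) {
  scale * sqrt(-2 * log(stats::runif(n)))
}

# Merge user params over defaults, rejecting unknown names.
merge_params <- function(defaults, params, what = "params") {
  if (is.null(params) || length(params) == 0L) return(defaults)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown %s: %s", what, paste(unknown, collapse = ", ")))
  }
  defaults[names(params)] <- params
  defaults
}
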
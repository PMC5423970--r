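# internal helpers

# Evaluate `code` under a temporary RNG seed, restoring .Random.seed after.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Spawn reproducible child seeds from a master seed (kept below 2^31).
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Wrap orientation angles (period 180 degrees) into [-90, 90).
wrap_orientation <- function(theta) {
  ((theta + 90) %% 180) - 90
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    abort(sprintf("`%s` must be positive", name))
  invisible(x)
}
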
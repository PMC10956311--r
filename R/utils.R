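# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. A NULL seed evaluates the code as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Truncated normal draws by inverse-CDF; exact and vectorised.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_binary01 <- function(y) {
  (is.numeric(y) || is.logical(y)) && all(y %in% c(0, 1))
}

# Coerce an outcome column to 0/1, erroring on anything non-binary.
as_outcome01 <- function(y, what = "outcome") {
  if (is.logical(y)) y <- as.integer(y)
  if (!is_binary01(y)) {
    stop(sprintf("`%s` must be binary (0/1 or logical)", what), call. = FALSE)
  }
  as.integer(y)
}
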
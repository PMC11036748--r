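# internal helpers shared across modules

#' @importFrom stats runif rnorm rgamma quantile sd var coef vcov logLik
#'   uniroot density setNames update predict
#' @importFrom utils head tail read.csv write.csv read.table write.table
#' @importFrom survival clogit strata coxph Surv
NULL

# wrap an angle (radians) into (-pi, pi]
wrap_angle <- function(a) {
  r <- a - 2 * pi * floor((a + pi) / (2 * pi))
  r[r <= -pi] <- pi
  r
}

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

# derive a child seed from a parent seed and an arbitrary key (kept < 2^31)
child_seed <- function(seed, key) {
  h <- if (is.character(key)) sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) else as.numeric(key)
  as.integer((as.numeric(seed) * 69069 + h * 1013 + 7) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
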
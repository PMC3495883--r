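# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a stage-specific seed from the master seed; stays below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483629) * 7919 + 104729 * offset) %% 2147483629L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, what) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stopf("%s must lie in [0, 1]", what)
  invisible(x)
}

# sample() treats a length-1 numeric vector as 1:x; resample never does
resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

gcd_all <- function(x) Reduce(gcd2, x)
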
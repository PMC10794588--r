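# Internal helpers shared across modules.

# Derive a reproducible 32-bit sub-seed for an independent RNG stream.
# Each model component and each training epoch gets its own stream so that
# adding or removing one component (e.g. the state regressor) never shifts
# the draws seen by another.
subSeed <- function(seed, stream) {
  ((as.double(seed) %% 100000) * 7919 + as.double(stream) * 104729) %%
    2147483629 + 1
}

assertFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  x
}

assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      x < min)
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

assertNumber <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= min) || (!strict && x < min))
    stop(sprintf("'%s' must be a finite number %s %s", name,
                 if (strict) ">" else ">=", format(min)), call. = FALSE)
  as.double(x)
}

popSD <- function(x) sqrt(mean((x - mean(x))^2))
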
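# Internal helpers shared across modules.

# Deterministically derive a 31-bit sub-seed from a base seed and a stream of
# integer tags, so that independent stages of the pipeline consume
# independent, reproducible RNG streams.
deriveSeed <- function(seed, ...) {
  tags <- c(seed, ...)
  x <- 0
  for (tag in tags) {
    if (is.character(tag))
      tag <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    x <- (x * 48271 + (as.numeric(tag) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(x)
}

stopDomain <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("flimDomainError", "error")))
}

stopValidation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("flimValidationError", "error")))
}
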
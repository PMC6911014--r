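# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stopf("'%s' must be a single number in [%s, %s]", name, min, max)
  invisible(x)
}

# deterministic per-stage seed derivation; keeps values well below 2^31
stage_seed <- function(seed, stage) {
  stages <- c("genome", "peaks", "expression", "nexus", "proseq", "rnaseq",
              "montecarlo", "pipeline")
  k <- match(stage, stages)
  if (is.na(k)) stopf("unknown seed stage '%s'", stage)
  (as.integer(seed) * 97L + k * 1009L) %% 2147480000L
}
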
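# Seed hygiene: all stochastic operations take an explicit seed and run
# under a temporarily-set RNG, leaving the caller's RNG state untouched.
# seed = NULL means "use the current RNG stream" (still reproducible if the
# caller seeded it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# muffle only Biostrings' note that unused mcols are dropped on
# coercion/subsetting; everything else propagates
quiet_mcols <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("metadata columns", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

# number of methylated CpGs per pattern string ("0110" -> 2)
pattern_class <- function(patterns) {
  vapply(strsplit(patterns, "", fixed = TRUE),
         function(b) sum(b == "1"), integer(1))
}
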
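# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. A NULL seed runs the code on the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# Deterministic per-replicate sub-seeds drawn from one parent stream, kept
# below 2^31 so they are valid R integer seeds.
split_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
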
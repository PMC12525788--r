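# Derive a reproducible sub-seed from a root seed and a stream label, so
# that one top-level seed drives independent named randomness streams
# (simulation, cross-validation plans, validation splits) without coupling
# their draws. Kept below 2^31 - 1 to stay a valid R integer seed.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) %% 65011 + 1) * 32749 + h) %% 2147483647L
}

# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}
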
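# evaluate `code` under a fixed RNG state, restoring the caller's stream
with_rng_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic split of one user seed into component streams,
# kept below 2^31 - 1
sub_seed <- function(seed, offset) {
  (abs(as.numeric(seed)) %% 1e9) * 2 + offset
}
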